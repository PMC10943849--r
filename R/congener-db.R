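# Structural model of PCB congeners in chlorophenyl-ring notation.
#
# A biphenyl ring is described by the set of chlorine-bearing carbons drawn
# from {2,3,4,5,6}; carbon 1 carries the ring-ring bond and cannot be
# substituted. Positions 2/6 are ortho, 3/5 meta, 4 para. Flipping a ring
# (rotation about the ring-ring bond) maps 2<->6, 3<->5, 4->4; together with
# swapping the two rings this generates the order-8 symmetry group under
# which congener labels are canonicalized.

.RING_POSITIONS <- 2:6

.POSITION_CLASS <- c("2" = "ortho", "3" = "meta", "4" = "para",
                     "5" = "meta", "6" = "ortho")

# intra-ring adjacency among chlorinatable carbons (2-3, 3-4, 4-5, 5-6)
.RING_NEIGHBOURS <- list("2" = 3L, "3" = c(2L, 4L), "4" = c(3L, 5L),
                         "5" = c(4L, 6L), "6" = 5L)

.pcb_env <- new.env(parent = emptyenv())

ring_flip <- function(positions) sort(8L - as.integer(positions))

ring_string <- function(positions) {
  if (length(positions) == 0L) "0" else paste(sort(positions), collapse = "")
}

# flip-minimal representation of one ring
ring_canonical <- function(positions) {
  a <- sort(as.integer(positions))
  b <- ring_flip(positions)
  if (ring_string(b) < ring_string(a)) b else a
}

# ring ordering for the two-ring label: digit strings compared
# lexicographically; the bare ring "0" always renders second
.ring_lt <- function(sa, sb) {
  if (sa == "0") return(FALSE)
  if (sb == "0") return(TRUE)
  sa < sb
}

new_congener <- function(ring_a, ring_b) {
  ra <- ring_canonical(ring_a)
  rb <- ring_canonical(ring_b)
  if (!.ring_lt(ring_string(ra), ring_string(rb)) &&
      ring_string(ra) != ring_string(rb)) {
    tmp <- ra; ra <- rb; rb <- tmp
  }
  pos <- c(ra, rb)
  n_cl <- length(pos)
  if (n_cl < 1L || n_cl > 10L)
    stop("a congener carries between 1 and 10 chlorines, got ", n_cl)
  cls <- .POSITION_CLASS[as.character(pos)]
  out <- list(
    ring_a = ra, ring_b = rb,
    label = paste(ring_string(ra), ring_string(rb), sep = "-"),
    n_cl = n_cl,
    n_ortho = sum(cls == "ortho"),
    n_meta = sum(cls == "meta"),
    n_para = sum(cls == "para"))
  class(out) <- "pcb_congener"
  out
}

#' Parse a chlorophenyl-ring congener label
#'
#' Labels are two dash-separated digit runs, one per phenyl ring, using the
#' substitutable positions 2-6 (e.g. `"2345-245"` for
#' 2,2',3,4,4',5,5'-heptachlorobiphenyl). An unsubstituted ring is written
#' `"0"` (`"245-0"`); a single run (`"245"`) is accepted for one-ring
#' congeners. The result is canonical under ring flips and ring swap, so
#' `"245-25"` and `"25-245"` parse to the same congener.
#'
#' @param label character scalar in ring notation, or a `pcb_congener`
#'   (returned unchanged).
#' @return A `pcb_congener`: list with `ring_a`, `ring_b` (integer position
#'   vectors in canonical order), `label`, `n_cl`, `n_ortho`, `n_meta`,
#'   `n_para`.
#' @examples
#' parse_congener("25-245")$label     # "245-25"
#' parse_congener("236-25")$n_ortho   # 3
#' @export
parse_congener <- function(label) {
  if (inherits(label, "pcb_congener")) return(label)
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop("congener label must be a single character string")
  lab <- trimws(label)
  cached <- .pcb_env$parse_cache[[lab]]
  if (!is.null(cached)) return(cached)
  parts <- strsplit(lab, "-", fixed = TRUE)[[1]]
  parts <- if (length(parts) == 0L) "" else parts
  if (length(parts) > 2L)
    stop("malformed congener label '", label, "': more than two rings")
  if (length(parts) == 1L) parts <- c(parts, "0")
  rings <- lapply(parts, function(tok) {
    if (tok %in% c("", "0")) return(integer(0))
    chars <- strsplit(tok, "", fixed = TRUE)[[1]]
    bad <- setdiff(chars, as.character(.RING_POSITIONS))
    if (length(bad))
      stop("malformed congener label '", label, "': ring token '", tok,
           "' contains position(s) ", paste(bad, collapse = ", "),
           " outside 2-6")
    posv <- as.integer(chars)
    if (anyDuplicated(posv))
      stop("malformed congener label '", label,
           "': repeated position in ring token '", tok, "'")
    posv
  })
  if (length(rings[[1]]) + length(rings[[2]]) == 0L)
    stop("label '", label, "' denotes unchlorinated biphenyl, ",
         "which is outside the 209-congener set")
  out <- new_congener(rings[[1]], rings[[2]])
  if (is.null(.pcb_env$parse_cache))
    .pcb_env$parse_cache <- new.env(parent = emptyenv())
  assign(lab, out, envir = .pcb_env$parse_cache)
  out
}

#' Canonical label of a congener
#'
#' @param x congener label or `pcb_congener`.
#' @return Canonical ring-notation string.
#' @export
congener_label <- function(x) parse_congener(x)$label

#' Enumerate all 209 PCB congeners
#'
#' Enumerates every distinct chlorine substitution pattern on the biphenyl
#' scaffold (1-10 chlorines) once, in canonical form, by pairing the 20
#' flip-minimal single-ring patterns and dropping the unchlorinated pair.
#'
#' @return A data.frame with one row per congener, ordered by `n_cl` then
#'   label: columns `label`, `n_cl`, `n_ortho`, `n_meta`, `n_para`,
#'   `homolog` (mono ... deca).
#' @examples
#' nrow(enumerate_congeners())  # 209
#' table(enumerate_congeners()$n_cl)
#' @export
enumerate_congeners <- function() {
  if (!is.null(.pcb_env$congener_table)) return(.pcb_env$congener_table)
  subsets <- lapply(0:31, function(bits) .RING_POSITIONS[
    bitwAnd(bits, 2L^(0:4)) > 0L])
  reps <- unique(lapply(subsets, ring_canonical))
  labels <- character(0)
  n <- length(reps)
  for (i in seq_len(n)) for (j in i:n) {
    if (length(reps[[i]]) + length(reps[[j]]) == 0L) next
    labels <- c(labels, new_congener(reps[[i]], reps[[j]])$label)
  }
  labels <- unique(labels)
  cong <- lapply(labels, parse_congener)
  homolog_names <- c("mono", "di", "tri", "tetra", "penta",
                     "hexa", "hepta", "octa", "nona", "deca")
  tab <- data.frame(
    label = vapply(cong, `[[`, character(1), "label"),
    n_cl = vapply(cong, `[[`, integer(1), "n_cl"),
    n_ortho = vapply(cong, `[[`, integer(1), "n_ortho"),
    n_meta = vapply(cong, `[[`, integer(1), "n_meta"),
    n_para = vapply(cong, `[[`, integer(1), "n_para"),
    stringsAsFactors = FALSE)
  tab$homolog <- homolog_names[tab$n_cl]
  tab <- tab[order(tab$n_cl, tab$label, method = "radix"), , drop = FALSE]
  rownames(tab) <- tab$label
  .pcb_env$congener_table <- tab
  tab
}

#' Write the congener list to CSV
#'
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_congener_list <- function(path) {
  utils::write.csv(enumerate_congeners(), path, row.names = FALSE)
  invisible(path)
}

#' Ortho/meta/para chlorine counts of a congener
#'
#' @param x congener label or `pcb_congener`.
#' @return Named numeric vector `c(ortho =, meta =, para =)`; the components
#'   sum to the total chlorine number.
#' @examples
#' positional_counts("2345-245")  # 2 ortho, 3 meta, 2 para
#' @export
positional_counts <- function(x) {
  cg <- parse_congener(x)
  c(ortho = cg$n_ortho, meta = cg$n_meta, para = cg$n_para)
}

# positional info for a vector of labels ("biphenyl" allowed, zero row)
congener_info <- function(labels) {
  rows <- lapply(labels, function(l) {
    if (identical(l, "biphenyl"))
      return(c(n_cl = 0, ortho = 0, meta = 0, para = 0))
    cg <- parse_congener(l)
    c(n_cl = cg$n_cl, ortho = cg$n_ortho, meta = cg$n_meta, para = cg$n_para)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- labels
  out
}

#' Flanking context of a chlorine on one ring
#'
#' A chlorine is flanked when an adjacent ring carbon (adjacency 2-3, 3-4,
#' 4-5, 5-6; positions 2 and 6 have a single chlorinatable neighbour) also
#' carries a chlorine. Flanking is an intra-ring property, so only the ring
#' pattern and the position are needed.
#'
#' @param ring ring pattern: digit string (e.g. `"2345"`) or integer vector.
#' @param position chlorinated position (2-6) whose context is requested.
#' @return `"unflanked"`, `"singly-flanked"` or `"doubly-flanked"`.
#' @examples
#' flank_context("2345", 4)  # doubly-flanked
#' flank_context("245", 4)   # singly-flanked
#' @export
flank_context <- function(ring, position) {
  pos <- if (is.character(ring)) {
    if (ring %in% c("", "0")) integer(0)
    else as.integer(strsplit(ring, "", fixed = TRUE)[[1]])
  } else as.integer(ring)
  if (!all(pos %in% .RING_POSITIONS))
    stop("invalid ring pattern: positions must lie in 2-6")
  position <- as.integer(position)
  if (!position %in% pos)
    stop("position ", position, " carries no chlorine on ring '",
         ring_string(pos), "'")
  k <- sum(.RING_NEIGHBOURS[[as.character(position)]] %in% pos)
  c("unflanked", "singly-flanked", "doubly-flanked")[k + 1L]
}

#' Single-dechlorination products of a congener
#'
#' Removes each chlorine in turn and canonicalizes the product. Channels
#' that are equivalent under the congener's symmetry (same product, removed
#' position class and flanking context) are merged, with the number of
#' equivalent chlorines recorded as `multiplicity`. Removing the final
#' chlorine yields the terminal (non-congener) biphenyl, reported with
#' product label `"biphenyl"`.
#'
#' @param x congener label or `pcb_congener`.
#' @return data.frame with columns `product`, `position`
#'   (ortho/meta/para), `flank`, `multiplicity`.
#' @examples
#' dechlorination_products("2345-245")
#' nrow(dechlorination_products("23456-23456"))  # 3
#' @export
dechlorination_products <- function(x) {
  cg <- parse_congener(x)
  rows <- list()
  rings <- list(cg$ring_a, cg$ring_b)
  for (r in 1:2) {
    this <- rings[[r]]
    other <- rings[[3 - r]]
    for (p in this) {
      rest <- setdiff(this, p)
      product <- if (length(rest) + length(other) == 0L) "biphenyl"
                 else new_congener(rest, other)$label
      rows[[length(rows) + 1L]] <- data.frame(
        product = product,
        position = unname(.POSITION_CLASS[as.character(p)]),
        flank = flank_context(this, p),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(list(multiplicity = rep(1L, nrow(df))),
                          by = df[c("product", "position", "flank")],
                          FUN = sum)
  agg <- agg[order(agg$product, agg$position, agg$flank,
                   method = "radix"), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
print.pcb_congener <- function(x, ...) {
  cat("PCB congener ", x$label, " (", x$n_cl, " Cl: ",
      x$n_ortho, " ortho, ", x$n_meta, " meta, ", x$n_para, " para)\n",
      sep = "")
  invisible(x)
}
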