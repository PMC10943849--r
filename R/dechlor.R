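# Dechlorination statistics over congener concentration time series.
#
# The central activity statistic is Cl/PCB, the mole-fraction-weighted mean
# number of chlorines per biphenyl skeleton; its decrease from day 0
# quantifies dechlorination, with the abiotic-control decrease (0.05) as
# the default activity threshold.

#' Construct a microcosm congener time series
#'
#' @param conc numeric matrix of concentrations (uM) or mole fractions,
#'   rows = congeners (rownames in ring notation; the terminal product
#'   `"biphenyl"` is also accepted), columns = timepoints.
#' @param days numeric vector of sampling days; strictly increasing,
#'   starting at 0.
#' @param id microcosm identifier.
#' @param replicate replicate identifier.
#' @param control optional linked abiotic-control `microcosm_series`.
#' @return A `microcosm_series` object.
#' @export
microcosm_series <- function(conc, days, id = "microcosm", replicate = NA,
                             control = NULL) {
  conc <- as.matrix(conc)
  if (is.null(rownames(conc)))
    stop("'conc' must have congener labels as rownames")
  if (ncol(conc) != length(days))
    stop("ncol(conc) must equal length(days)")
  if (length(days) < 1L || days[1] != 0)
    stop("the first sampled timestamp must be day 0")
  if (length(days) > 1L && any(diff(days) <= 0))
    stop("sampling days must be strictly increasing")
  if (any(conc < 0))
    stop("concentrations must be non-negative")
  canon <- vapply(rownames(conc), function(l)
    if (identical(l, "biphenyl")) "biphenyl" else congener_label(l), "")
  if (anyDuplicated(canon))
    stop("duplicate congeners after canonicalization: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  rownames(conc) <- unname(canon)
  colnames(conc) <- paste0("day_", days)
  if (!is.null(control) && !inherits(control, "microcosm_series"))
    stop("'control' must be a microcosm_series")
  structure(list(conc = conc, days = as.numeric(days), id = id,
                 replicate = replicate, control = control),
            class = "microcosm_series")
}

#' @export
print.microcosm_series <- function(x, ...) {
  cat("microcosm_series '", x$id, "'",
      if (!is.na(x$replicate)) paste0(" (replicate ", x$replicate, ")"),
      ": ", nrow(x$conc), " congeners x ", length(x$days),
      " timepoints (day ", x$days[1], "-", max(x$days), ")",
      if (!is.null(x$control)) ", linked abiotic control", "\n", sep = "")
  invisible(x)
}

#' Extract the profile at a sampled day
#'
#' @param series a `microcosm_series`.
#' @param t a sampled day.
#' @return Named concentration vector.
#' @export
profile_at <- function(series, t) {
  i <- match(t, series$days)
  if (is.na(i))
    stop("day ", t, " was not sampled (no interpolation is performed); ",
         "sampled days: ", paste(series$days, collapse = ", "))
  stats::setNames(series$conc[, i], rownames(series$conc))
}

#' Average chlorines per biphenyl of a congener profile
#'
#' Computes `sum_i x_i * n_i` where `x_i` is the mole fraction of congener
#' i among detected congeners and `n_i` its chlorine count. Invariant to
#' uniform rescaling of concentrations.
#'
#' @param profile named non-negative numeric vector (names = congener
#'   labels, `"biphenyl"` allowed with 0 chlorines).
#' @return Chlorines per biphenyl.
#' @examples
#' cl_per_pcb(c("2345-245" = 2, "245-245" = 1, "25-25" = 1))  # 6
#' @export
cl_per_pcb <- function(profile) {
  w <- .profile_weights(profile)
  info <- congener_info(names(w))
  sum(w * info[, "n_cl"])
}

#' Positional decomposition of chlorines per biphenyl
#'
#' @inheritParams cl_per_pcb
#' @return Named vector `c(ortho =, meta =, para =)` summing to
#'   [cl_per_pcb()].
#' @examples
#' positional_cl_per_pcb(c("25-25" = 1))  # (2, 2, 0)
#' @export
positional_cl_per_pcb <- function(profile) {
  w <- .profile_weights(profile)
  info <- congener_info(names(w))
  c(ortho = sum(w * info[, "ortho"]),
    meta = sum(w * info[, "meta"]),
    para = sum(w * info[, "para"]))
}

.profile_weights <- function(profile) {
  if (is.null(names(profile)) || !is.numeric(profile))
    stop("a congener profile is a named numeric vector")
  if (any(profile < 0)) stop("concentrations must be non-negative")
  tot <- sum(profile)
  if (tot <= 0)
    stop("undefined statistic: profile has no positive abundance")
  profile / tot
}

#' Decrease in Cl/PCB from day 0
#'
#' `delta_cl(series, t)` is Cl/PCB at day 0 minus Cl/PCB at day `t`, with
#' the same difference computed per ortho/meta/para class. The positional
#' components sum to the total by construction.
#'
#' @param series a `microcosm_series`.
#' @param t sampled day (default: final day).
#' @return List with `total` and `by_position` (ortho, meta, para).
#' @export
delta_cl <- function(series, t = max(series$days)) {
  p0 <- profile_at(series, 0)
  pt <- profile_at(series, t)
  list(total = cl_per_pcb(p0) - cl_per_pcb(pt),
       by_position = positional_cl_per_pcb(p0) - positional_cl_per_pcb(pt))
}

# delta Cl/PCB at every sampled day (day 0 gives 0)
delta_cl_curve <- function(series) {
  vapply(series$days, function(t) delta_cl(series, t)$total, numeric(1))
}

#' Call dechlorination activity
#'
#' A microcosm is active when the decrease in Cl/PCB reaches the threshold
#' at any sampled day (inclusive comparison). The default threshold 0.05 is
#' the abiotic-control decrease; passing `threshold = NULL` takes the
#' maximum decrease observed in the linked abiotic-control series instead.
#'
#' @param series a `microcosm_series` with at least 2 timepoints.
#' @param threshold activity threshold on the Cl/PCB decrease (default
#'   0.05), or `NULL` to derive it from `series$control`.
#' @return Logical.
#' @export
call_activity <- function(series, threshold = 0.05) {
  if (length(series$days) < 2L)
    stop("activity calling needs at least 2 timepoints")
  threshold <- .resolve_threshold(series, threshold)
  max(delta_cl_curve(series)) >= threshold
}

.resolve_threshold <- function(series, threshold) {
  if (is.null(threshold)) {
    if (is.null(series$control))
      stop("threshold = NULL requires a linked abiotic-control series")
    threshold <- max(delta_cl_curve(series$control))
  }
  threshold
}

#' Lag time before onset of dechlorination
#'
#' The onset is the earliest sampled day at which the Cl/PCB decrease
#' reaches the threshold. Because sampling is discrete the lag is reported
#' as the interval (previous sample, onset sample].
#'
#' @inheritParams call_activity
#' @return Named vector `c(lower =, upper =)` in days.
#' @export
lag_time <- function(series, threshold = 0.05) {
  threshold <- .resolve_threshold(series, threshold)
  dc <- delta_cl_curve(series)
  hit <- which(dc >= threshold & series$days > 0)
  if (length(hit) == 0L)
    stop("lag time undefined: series never reaches the activity threshold (",
         threshold, ")")
  i <- hit[1]
  c(lower = series$days[i - 1L], upper = series$days[i])
}

#' Classify para- vs meta-dechlorination preference
#'
#' Compares the final para- and meta-position Cl/PCB decreases across
#' replicate microcosms by one-way ANOVA. A significant difference (at
#' `alpha`) with the larger mean on the para (meta) side gives
#' `"para-preferential"` (`"meta-preferential"`); otherwise the microcosm
#' removed comparable amounts from both positions.
#'
#' @param replicates list of >= 2 active `microcosm_series` replicates.
#' @param alpha significance level (default 0.05).
#' @param threshold activity threshold used to verify the replicates are
#'   active.
#' @return One of `"para-preferential"`, `"meta-preferential"`,
#'   `"comparable"`.
#' @export
preference_class <- function(replicates, alpha = 0.05, threshold = 0.05) {
  if (!is.list(replicates) || length(replicates) < 2L)
    stop("insufficient replication: preference classification needs >= 2 ",
         "replicate series")
  active <- vapply(replicates, call_activity, logical(1),
                   threshold = threshold)
  if (!all(active))
    stop("preference classification requires active replicates; ",
         sum(!active), " replicate(s) inactive")
  fin <- t(vapply(replicates,
                  function(s) delta_cl(s)$by_position, numeric(3)))
  para <- fin[, "para"]; meta <- fin[, "meta"]
  if (isTRUE(all.equal(para, meta, tolerance = 1e-12)) ||
      (stats::var(para) + stats::var(meta)) == 0) {
    if (mean(para) == mean(meta)) return("comparable")
    return(if (mean(para) > mean(meta)) "para-preferential"
           else "meta-preferential")
  }
  dat <- data.frame(delta = c(para, meta),
                    position = factor(rep(c("para", "meta"),
                                          each = length(para))))
  p <- summary(stats::aov(delta ~ position, data = dat))[[1]][["Pr(>F)"]][1]
  if (is.na(p) || p >= alpha) return("comparable")
  if (mean(para) > mean(meta)) "para-preferential" else "meta-preferential"
}

#' Per-microcosm dechlorination summary
#'
#' @param series a `microcosm_series`.
#' @param threshold activity threshold (see [call_activity()]).
#' @return One-row data.frame: id, replicate, final-day total and
#'   positional Cl/PCB decreases, activity call and lag interval
#'   (NA when inactive).
#' @export
dechlor_stats <- function(series, threshold = 0.05) {
  thr <- .resolve_threshold(series, threshold)
  d <- delta_cl(series)
  active <- call_activity(series, threshold = thr)
  lag <- if (active) lag_time(series, threshold = thr)
         else c(lower = NA_real_, upper = NA_real_)
  data.frame(id = series$id, replicate = series$replicate,
             delta_cl_total = d$total,
             delta_ortho = unname(d$by_position["ortho"]),
             delta_meta = unname(d$by_position["meta"]),
             delta_para = unname(d$by_position["para"]),
             active = active,
             lag_lower = unname(lag["lower"]),
             lag_upper = unname(lag["upper"]),
             threshold = thr,
             stringsAsFactors = FALSE)
}
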