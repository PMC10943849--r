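# Readers and writers for the package's table dialects: congener
# concentration tables (wide or long CSV), qPCR result tables (CSV) and
# taxon-by-sample abundance tables (TSV).

#' Read a congener concentration table
#'
#' Two dialects are accepted. Long format: CSV with columns `sample`,
#' `day`, `congener`, `value` (one series per sample). Wide format: first
#' column `congener`, remaining columns named by day number (`0`, `30`, ...
#' or `day_0`, `day_30`, ...), holding a single series. Labels are
#' validated against the 209-congener set and canonicalized; duplicate
#' (sample, day, congener) records and negative values are rejected.
#'
#' @param path CSV file.
#' @param sample sample id for wide files (default: file base name).
#' @return Named list of `microcosm_series`.
#' @export
read_congener_table <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  long <- all(c("sample", "day", "congener", "value") %in% names(df))
  if (long) return(.series_from_long(df, path))
  if (!("congener" %in% names(df)) && ncol(df) >= 2)
    names(df)[1] <- "congener"
  days <- suppressWarnings(as.numeric(sub("^day[_ ]?", "",
                                          setdiff(names(df), "congener"))))
  if (any(is.na(days)))
    stop(path, ": wide congener tables need day-number column names")
  longdf <- data.frame(
    sample = sample %||% sub("\\.[^.]*$", "", basename(path)),
    day = rep(days, each = nrow(df)),
    congener = rep(df$congener, times = length(days)),
    value = unlist(df[setdiff(names(df), "congener")], use.names = FALSE))
  .series_from_long(longdf, path)
}

.series_from_long <- function(df, path = "<data>") {
  if (any(!is.finite(df$value)))
    stop(path, ": non-numeric or missing concentration values")
  if (any(df$value < 0)) {
    i <- which(df$value < 0)[1]
    stop(path, ": negative value for congener '", df$congener[i],
         "' (sample ", df$sample[i], ", day ", df$day[i], ")")
  }
  df$canon <- vapply(as.character(df$congener), function(l) {
    if (identical(l, "biphenyl")) return("biphenyl")
    tryCatch(congener_label(l),
             error = function(e) stop(path, ": ", conditionMessage(e),
                                      call. = FALSE))
  }, "")
  key <- paste(df$sample, df$day, df$canon, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop(path, ": duplicate record for (sample ", d$sample, ", day ",
         d$day, ", congener ", d$canon, ")")
  }
  out <- lapply(split(df, df$sample), function(sd) {
    days <- sort(unique(sd$day))
    labs <- sort(unique(sd$canon))
    conc <- matrix(0, length(labs), length(days),
                   dimnames = list(labs, NULL))
    conc[cbind(match(sd$canon, labs), match(sd$day, days))] <- sd$value
    microcosm_series(conc, days, id = as.character(sd$sample[1]))
  })
  out[order(names(out))]
}

#' Write congener series to CSV
#'
#' @param series a `microcosm_series` or list of them.
#' @param path output CSV path.
#' @param format `"long"` (default; multi-sample) or `"wide"` (single
#'   series).
#' @return The path, invisibly.
#' @export
write_congener_table <- function(series, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (inherits(series, "microcosm_series")) series <- list(series)
  if (format == "wide") {
    if (length(series) != 1L)
      stop("wide format holds a single series; use format = 'long'")
    s <- series[[1]]
    df <- data.frame(congener = rownames(s$conc), s$conc,
                     check.names = FALSE)
    names(df)[-1] <- paste0("day_", s$days)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    rows <- lapply(series, function(s) data.frame(
      sample = s$id,
      day = rep(s$days, each = nrow(s$conc)),
      congener = rep(rownames(s$conc), times = length(s$days)),
      value = as.vector(s$conc)))
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a qPCR result table
#'
#' CSV with columns `sample`, `target`, `Cq`, `dilution_factor` and
#' optionally `role` (`"standard"`/`"unknown"`) and `copies` (nominal
#' copies/mL for standards).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_qpcr_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "target", "Cq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (!"dilution_factor" %in% names(df)) df$dilution_factor <- 1
  if (!"role" %in% names(df)) df$role <- "unknown"
  df
}

#' Read a taxon-by-sample abundance table
#'
#' TSV: first column taxon id, optional `taxonomy` column, remaining
#' columns one per sample.
#'
#' @param path TSV file.
#' @return List: `counts` (taxa x samples matrix) and `taxonomy`.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  taxa <- as.character(df[[1]])
  df <- df[-1]
  taxonomy <- if ("taxonomy" %in% names(df)) {
    tx <- df$taxonomy; df$taxonomy <- NULL; tx
  } else taxa
  counts <- as.matrix(df)
  if (!is.numeric(counts)) stop(path, ": non-numeric abundances")
  if (any(counts < 0)) stop(path, ": negative abundances")
  rownames(counts) <- taxa
  list(counts = counts, taxonomy = taxonomy)
}

#' Write a taxon-by-sample abundance table
#'
#' @param counts taxa x samples matrix.
#' @param path output TSV path.
#' @param taxonomy optional taxonomy column.
#' @return The path, invisibly.
#' @export
write_abundance_table <- function(counts, path, taxonomy = NULL) {
  df <- data.frame(taxon = rownames(counts), check.names = FALSE)
  if (!is.null(taxonomy)) df$taxonomy <- taxonomy
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
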