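# qPCR standard-curve calibration and quantification of
# organohalide-respiring bacteria (OHRB) and PCB reductive-dehalogenase
# (RDase) genes, plus ratio-band and dominance analyses.

#' Default OHRB genus targets
#' @return Character vector of the three well-characterized OHRB genera.
#' @export
ohrb_targets <- function() c("Dehalococcoides", "Dehalogenimonas",
                             "Dehalobacter")

#' Default PCB-RDase gene targets
#' @return Character vector of the characterized PCB-RDase genes.
#' @export
rdase_targets <- function() c("pcbA1", "pcbA4", "pcbA5")

#' Fit a log-linear qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies) over a plasmid dilution
#' series. The amplification efficiency is `10^(-1/slope) - 1`; a perfect
#' doubling per cycle gives slope -3.3219 and efficiency 100%. The curve is
#' flagged unacceptable when r-squared falls below `min_r_squared` or the
#' efficiency leaves `efficiency_bounds`.
#'
#' @param x data.frame with columns `copies` (nominal copies/mL) and `Cq`,
#'   or a list with those elements; >= 3 distinct dilution levels required.
#' @param target target name carried through to results.
#' @param efficiency_bounds acceptable efficiency range as fractions
#'   (default `c(0.90, 1.10)`).
#' @param min_r_squared minimum acceptable r-squared (default 0.99).
#' @return A `standard_curve`: list with `target`, `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `acceptable`, `flags`, `n_levels`.
#' @examples
#' d <- data.frame(copies = 10^(2:8), Cq = 40 - 3.3219 * (2:8))
#' fit_standard_curve(d)$efficiency  # 1.0
#' @export
fit_standard_curve <- function(x, target = "target",
                               efficiency_bounds = c(0.90, 1.10),
                               min_r_squared = 0.99) {
  copies <- x$copies
  cq <- x$Cq
  if (is.null(copies) || is.null(cq))
    stop("dilution series needs 'copies' and 'Cq'")
  if (!is.null(x$target)) target <- x$target[1]
  keep <- is.finite(copies) & is.finite(cq) & copies > 0
  copies <- copies[keep]; cq <- cq[keep]
  if (any(cq <= 0)) stop("Cq values must be positive")
  lx <- log10(copies)
  if (length(unique(lx)) < 3L)
    stop("standard-curve fit needs >= 3 distinct dilution levels")
  fit <- stats::lm(cq ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  eff <- if (slope < 0) 10^(-1 / slope) - 1 else NA_real_
  flags <- character(0)
  if (slope >= 0) flags <- c(flags, "non-negative slope")
  if (!is.na(eff) && (eff < efficiency_bounds[1] || eff > efficiency_bounds[2]))
    flags <- c(flags, sprintf("efficiency %.1f%% outside [%.1f%%, %.1f%%]",
                              100 * eff, 100 * efficiency_bounds[1],
                              100 * efficiency_bounds[2]))
  if (r2 < min_r_squared)
    flags <- c(flags, sprintf("r-squared %.4f < %.2f", r2, min_r_squared))
  structure(list(target = target, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency = eff,
                 acceptable = length(flags) == 0L, flags = flags,
                 n_levels = length(unique(lx))),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve '%s': Cq = %.4f + %.4f log10(copies), r2 = %.4f, efficiency = %.1f%% [%s]\n",
    x$target, x$intercept, x$slope, x$r_squared, 100 * x$efficiency,
    if (x$acceptable) "acceptable" else paste(x$flags, collapse = "; ")))
  invisible(x)
}

#' Quantify gene copies from Cq values
#'
#' Inverts the standard curve: `copies/mL = dilution_factor *
#' 10^((Cq - intercept)/slope)`. The below-LOD flag is raised when the
#' estimated copies per reaction (copies/mL of template times the template
#' volume per reaction) fall below `lod`.
#'
#' @param Cq finite numeric vector of quantification cycles.
#' @param curve a `standard_curve`.
#' @param dilution_factor template dilution factor(s) to undo.
#' @param sample optional sample id(s).
#' @param reaction_volume_mL template volume per reaction in mL (default
#'   0.02, i.e. a 20-uL reaction).
#' @param lod limit of detection in copies per reaction (default 6, the
#'   conservative end of the 6-9 copies/reaction band).
#' @return data.frame: sample, target, Cq, copies_per_ml,
#'   copies_per_reaction, below_lod, lod.
#' @export
quantify <- function(Cq, curve, dilution_factor = 1, sample = NA,
                     reaction_volume_mL = 0.02, lod = 6) {
  if (!inherits(curve, "standard_curve")) stop("'curve' is not a standard_curve")
  if (!curve$acceptable)
    warning("quantifying against a curve flagged unacceptable (",
            paste(curve$flags, collapse = "; "), ")")
  if (any(!is.finite(Cq))) stop("Cq values must be finite")
  base <- 10^((Cq - curve$intercept) / curve$slope)
  per_reaction <- base * reaction_volume_mL
  data.frame(sample = sample, target = curve$target, Cq = Cq,
             copies_per_ml = dilution_factor * base,
             copies_per_reaction = per_reaction,
             below_lod = per_reaction < lod, lod = lod,
             stringsAsFactors = FALSE)
}

#' RDase-gene to OHRB-cell abundance ratio with uncertainty band
#'
#' Per sample, the ratio of summed PCB-RDase gene copies (pcbA1 + pcbA4 +
#' pcbA5) to summed OHRB cells (Dehalococcoides + Dehalogenimonas +
#' Dehalobacter; genus 16S copies are treated as cells 1:1). Band flags use
#' a 10-fold band around the 1:1 line, the estimated maximum qPCR
#' quantification uncertainty: strictly above 10 is `"above-10x"`, strictly
#' below 0.1 is `"below-0.1"` (a signature of RDase genes not covered by
#' the assay panel), otherwise `"within-band"`.
#'
#' @param quants data.frame with columns `sample`, `target`,
#'   `copies_per_ml` (e.g. rows of [quantify()] output). Missing targets
#'   are treated as 0 with a warning.
#' @param rdase,ohrb target name sets forming numerator and denominator.
#' @param copies_per_cell named per-genus 16S copy numbers used to convert
#'   genus copies to cells (default 1 for all).
#' @return data.frame: sample, rdase_copies, ohrb_cells, ratio, band.
#'   A zero denominator yields `ratio = NA` and band
#'   `"undefined-denominator"`.
#' @export
rdase_ohrb_ratio <- function(quants, rdase = rdase_targets(),
                             ohrb = ohrb_targets(),
                             copies_per_cell = NULL) {
  .check_quants(quants)
  if (is.null(copies_per_cell))
    copies_per_cell <- stats::setNames(rep(1, length(ohrb)), ohrb)
  samples <- unique(quants$sample)
  missing <- character(0)
  rows <- lapply(samples, function(s) {
    q <- quants[quants$sample == s, , drop = FALSE]
    get <- function(tg) {
      v <- q$copies_per_ml[q$target == tg]
      if (length(v) == 0L) { missing <<- c(missing, paste0(s, ":", tg)); 0 }
      else sum(v)
    }
    num <- sum(vapply(rdase, get, numeric(1)))
    den <- sum(vapply(ohrb, function(tg) get(tg) / copies_per_cell[[tg]],
                      numeric(1)))
    ratio <- if (den == 0) NA_real_ else num / den
    band <- if (den == 0) "undefined-denominator"
            else if (ratio > 10) "above-10x"
            else if (ratio < 0.1) "below-0.1"
            else "within-band"
    data.frame(sample = s, rdase_copies = num, ohrb_cells = den,
               ratio = ratio, band = band, stringsAsFactors = FALSE)
  })
  if (length(missing))
    warning("targets missing (treated as 0): ",
            paste(unique(missing), collapse = ", "))
  do.call(rbind, rows)
}

#' OHRB dominance classification
#'
#' A sample is solely dominated when a single OHRB genus strictly exceeds
#' 90% (by default) of the summed OHRB abundance; otherwise it is
#' codominated, or undetected when no OHRB genus was measured above zero.
#'
#' @inheritParams rdase_ohrb_ratio
#' @param genera genus targets considered (default [ohrb_targets()]).
#' @param threshold dominance fraction (default 0.9, strict).
#' @return data.frame: sample, dominant share and label
#'   (`"solely-dominated:<genus>"`, `"codominated"`, `"undetected"`).
#' @export
dominance <- function(quants, genera = ohrb_targets(), threshold = 0.9) {
  .check_quants(quants)
  samples <- unique(quants$sample)
  rows <- lapply(samples, function(s) {
    q <- quants[quants$sample == s & quants$target %in% genera, , drop = FALSE]
    v <- vapply(genera, function(tg) sum(q$copies_per_ml[q$target == tg]),
                numeric(1))
    tot <- sum(v)
    if (tot == 0)
      return(data.frame(sample = s, top_genus = NA_character_,
                        top_share = NA_real_, label = "undetected",
                        stringsAsFactors = FALSE))
    share <- v / tot
    top <- which.max(share)
    label <- if (share[top] > threshold)
      paste0("solely-dominated:", genera[top]) else "codominated"
    data.frame(sample = s, top_genus = genera[top],
               top_share = unname(share[top]), label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.check_quants <- function(quants) {
  need <- c("sample", "target", "copies_per_ml")
  if (!is.data.frame(quants) || !all(need %in% names(quants)))
    stop("'quants' needs columns ", paste(need, collapse = ", "))
  if (any(quants$copies_per_ml < 0, na.rm = TRUE))
    stop("copy densities must be non-negative")
}

#' Correlate gene abundance with dechlorination activity
#'
#' @param x gene/cell quantities (optionally log10-transformed first).
#' @param y paired Cl/PCB decreases.
#' @param method `"pearson"` or `"spearman"`.
#' @param log10_transform log10-transform `x` before correlating (requires
#'   positive values).
#' @return List with `r`, `p`, `n`, `method`.
#' @export
correlate_abundance_activity <- function(x, y,
                                         method = c("pearson", "spearman"),
                                         log10_transform = FALSE) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("'x' and 'y' must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("correlation needs n >= 3 finite pairs")
  if (log10_transform) {
    if (any(x <= 0)) stop("log10 transform requires positive quantities")
    x <- log10(x)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}
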