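# Study orchestration: configuration, the end-to-end pipeline over a study
# directory, the run manifest, and a miniature fixture-study writer.

#' Study configuration
#'
#' Collects input paths and every analysis threshold with its conventional
#' default: activity threshold 0.05 Cl/PCB, network cutoffs |rho| > 0.6
#' and BH-adjusted p < 0.01, > 50% prevalence, NST boundary 50% with 1000
#' randomizations, efficiency bounds 90-110%, LOD 6 copies/reaction,
#' > 90% dominance, 0.1-10x ratio band.
#'
#' @param congener_table,qpcr_table,abundance_table,metadata input paths
#'   (any may be NULL; stages without inputs are skipped).
#' @param out_dir output directory.
#' @param activity_threshold Cl/PCB decrease calling activity.
#' @param rho_cutoff,network_alpha co-occurrence edge cutoffs.
#' @param prevalence_min_frac prevalence filter fraction (strict).
#' @param nst_boundary,nst_randomizations NST boundary (%) and null draws.
#' @param efficiency_bounds,min_r_squared standard-curve acceptability.
#' @param lod limit of detection, copies/reaction.
#' @param dominance_threshold sole-dominance fraction (strict).
#' @param ratio_band lower/upper RDase:OHRB ratio band edges.
#' @param ohrb_taxa OHRB screen list.
#' @param n_activity_groups number of activity groups for networks/NST.
#' @param seed RNG seed propagated to all randomized steps.
#' @return A validated `study_config` list.
#' @export
study_config <- function(congener_table = NULL, qpcr_table = NULL,
                         abundance_table = NULL, metadata = NULL,
                         out_dir = "pcbdechlor-out",
                         activity_threshold = 0.05, rho_cutoff = 0.6,
                         network_alpha = 0.01, prevalence_min_frac = 0.5,
                         nst_boundary = 50, nst_randomizations = 1000,
                         efficiency_bounds = c(0.90, 1.10),
                         min_r_squared = 0.99, lod = 6,
                         dominance_threshold = 0.9,
                         ratio_band = c(0.1, 10),
                         ohrb_taxa = ohrb_default_taxa(),
                         n_activity_groups = 4, seed = 1) {
  cfg <- list(congener_table = congener_table, qpcr_table = qpcr_table,
              abundance_table = abundance_table, metadata = metadata,
              out_dir = out_dir, activity_threshold = activity_threshold,
              rho_cutoff = rho_cutoff, network_alpha = network_alpha,
              prevalence_min_frac = prevalence_min_frac,
              nst_boundary = nst_boundary,
              nst_randomizations = nst_randomizations,
              efficiency_bounds = efficiency_bounds,
              min_r_squared = min_r_squared, lod = lod,
              dominance_threshold = dominance_threshold,
              ratio_band = ratio_band, ohrb_taxa = ohrb_taxa,
              n_activity_groups = n_activity_groups, seed = seed)
  stopifnot(activity_threshold >= 0, rho_cutoff > 0, rho_cutoff < 1,
            network_alpha > 0, network_alpha < 1,
            prevalence_min_frac >= 0, prevalence_min_frac < 1,
            nst_boundary > 0, nst_boundary < 100,
            nst_randomizations >= 1, lod >= 0,
            dominance_threshold > 0.5, dominance_threshold < 1,
            length(ratio_band) == 2, ratio_band[1] < ratio_band[2],
            n_activity_groups >= 1)
  class(cfg) <- "study_config"
  cfg
}

#' Load / save a study configuration (YAML)
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param path YAML file.
#' @return [load_study_config()] returns a `study_config`.
#' @export
load_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals)
}

#' @rdname load_study_config
#' @param cfg a `study_config`.
#' @export
save_study_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, for whichever inputs the configuration provides:
#' dechlorination statistics per microcosm (activity, lag, positional
#' decomposition), qPCR calibration and quantification with ratio bands
#' and dominance, OHRB screening, alpha diversity, activity correlations,
#' per-activity-group co-occurrence networks and NST. Writes CSV/TSV/JSON
#' outputs plus `manifest.json` recording package version, seed, all
#' thresholds, input checksums and the count surviving every filter.
#'
#' @param cfg a `study_config`.
#' @param quiet suppress progress messages.
#' @return Invisible list of stage results.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (!inherits(cfg, "study_config")) stop("'cfg' must be a study_config")
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  decisions <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(cfg$congener_table)) {
    results$dechlor <- stage("dechlorination", {
      series <- read_congener_table(cfg$congener_table)
      say("dechlorination: ", length(series), " series read")
      stats <- do.call(rbind, lapply(series, dechlor_stats,
                                     threshold = cfg$activity_threshold))
      rownames(stats) <- NULL
      decisions$n_microcosms <- nrow(stats)
      decisions$n_active <- sum(stats$active)
      say("dechlorination: ", sum(stats$active), " of ", nrow(stats),
          " series active at threshold ", cfg$activity_threshold)
      utils::write.csv(stats, file.path(cfg$out_dir, "dechlor_results.csv"),
                       row.names = FALSE)
      list(series = series, stats = stats)
    })
  }

  if (!is.null(cfg$qpcr_table)) {
    results$qpcr <- stage("quantification", {
      qt <- read_qpcr_table(cfg$qpcr_table)
      std <- qt[qt$role == "standard", , drop = FALSE]
      unk <- qt[qt$role != "standard", , drop = FALSE]
      curves <- lapply(split(std, std$target), function(s)
        fit_standard_curve(list(copies = s$copies, Cq = s$Cq,
                                target = s$target[1]),
                           efficiency_bounds = cfg$efficiency_bounds,
                           min_r_squared = cfg$min_r_squared))
      curve_report <- do.call(rbind, lapply(curves, function(cv)
        data.frame(target = cv$target, slope = cv$slope,
                   intercept = cv$intercept, r_squared = cv$r_squared,
                   efficiency = cv$efficiency, acceptable = cv$acceptable,
                   flags = paste(cv$flags, collapse = "; "))))
      utils::write.csv(curve_report,
                       file.path(cfg$out_dir, "standard_curves.csv"),
                       row.names = FALSE)
      quants <- do.call(rbind, lapply(split(unk, unk$target), function(u) {
        cv <- curves[[u$target[1]]]
        if (is.null(cv)) stop("no standard curve for target ", u$target[1])
        ok <- is.finite(u$Cq)
        quantify(u$Cq[ok], cv, dilution_factor = u$dilution_factor[ok],
                 sample = u$sample[ok], lod = cfg$lod)
      }))
      rownames(quants) <- NULL
      decisions$n_quantified <- nrow(quants)
      decisions$n_below_lod <- sum(quants$below_lod)
      ratios <- suppressWarnings(rdase_ohrb_ratio(quants))
      doms <- dominance(quants, threshold = cfg$dominance_threshold)
      utils::write.csv(quants, file.path(cfg$out_dir, "gene_quants.csv"),
                       row.names = FALSE)
      utils::write.csv(ratios, file.path(cfg$out_dir, "rdase_ohrb_ratios.csv"),
                       row.names = FALSE)
      utils::write.csv(doms, file.path(cfg$out_dir, "ohrb_dominance.csv"),
                       row.names = FALSE)
      say("quantification: ", length(curves), " curves, ",
          nrow(quants), " quantifications (", sum(quants$below_lod),
          " below LOD)")
      list(curves = curves, quants = quants, ratios = ratios,
           dominance = doms)
    })
  }

  if (!is.null(cfg$abundance_table)) {
    results$ecology <- stage("community_ecology", {
      ab <- read_abundance_table(cfg$abundance_table)
      screen <- ohrb_screen(ab$counts, ab$taxonomy, taxa = cfg$ohrb_taxa)
      alpha <- alpha_diversity(ab$counts)
      utils::write.csv(screen$per_sample,
                       file.path(cfg$out_dir, "ohrb_screen.csv"),
                       row.names = FALSE)
      utils::write.csv(alpha, file.path(cfg$out_dir, "alpha_diversity.csv"),
                       row.names = FALSE)
      decisions$ohrb_occurrence_frequency <- screen$occurrence_frequency
      say("ecology: OHRB occurrence frequency ",
          sprintf("%.1f%%", 100 * screen$occurrence_frequency))

      networks <- NULL; nst_res <- NULL; correlations <- NULL
      if (!is.null(results$dechlor)) {
        st <- results$dechlor$stats
        common <- intersect(colnames(ab$counts), st$id)
        if (length(common) >= max(8, 2 * cfg$n_activity_groups)) {
          delta <- st$delta_cl_total[match(common, st$id)]
          grp <- activity_quartiles(delta, cfg$n_activity_groups)
          sub <- ab$counts[, common, drop = FALSE]
          networks <- list(); kept <- integer(0)
          for (g in levels(grp)) {
            gc <- sub[, grp == g, drop = FALSE]
            if (ncol(gc) < 4) next
            filt <- prevalence_filter(gc, min_frac = cfg$prevalence_min_frac)
            kept[g] <- nrow(filt)
            net <- suppressWarnings(build_cooccurrence_network(
              filt, rho_cutoff = cfg$rho_cutoff,
              alpha = cfg$network_alpha))
            write_network_edges(net, file.path(
              cfg$out_dir, paste0("network_group", g, "_edges.tsv")))
            write_network_graphml(net, file.path(
              cfg$out_dir, paste0("network_group", g, ".graphml")))
            networks[[g]] <- net
          }
          decisions$genera_after_prevalence_filter <- kept
          nst_res <- nst(round(sub), groups = grp,
                         B = cfg$nst_randomizations,
                         boundary = cfg$nst_boundary, seed = cfg$seed)
          jsonlite::write_json(nst_res,
                               file.path(cfg$out_dir, "nst.json"),
                               dataframe = "rows", auto_unbox = TRUE,
                               digits = NA)
          utils::write.csv(attr(nst_res, "pairs"),
                           file.path(cfg$out_dir, "nst_pairs.csv"),
                           row.names = FALSE)
          corr_alpha <- correlate_abundance_activity(
            alpha$shannon[match(common, alpha$sample)], delta)
          corr_ohrb <- correlate_abundance_activity(
            screen$per_sample$ohrb_relabund[
              match(common, screen$per_sample$sample)], delta,
            method = "spearman")
          correlations <- data.frame(
            comparison = c("shannon_vs_delta_cl", "ohrb_relabund_vs_delta_cl"),
            method = c("pearson", "spearman"),
            r = c(corr_alpha$r, corr_ohrb$r),
            p = c(corr_alpha$p, corr_ohrb$p), n = length(common))
          utils::write.csv(correlations,
                           file.path(cfg$out_dir, "correlations.csv"),
                           row.names = FALSE)
          say("ecology: ", length(networks), " group networks, NST per group")
        } else {
          say("ecology: too few samples shared with the congener table; ",
              "skipping grouped networks/NST")
        }
      }
      list(screen = screen, alpha = alpha, networks = networks,
           nst = nst_res, correlations = correlations)
    })
  }

  inputs <- Filter(Negate(is.null),
                   cfg[c("congener_table", "qpcr_table", "abundance_table",
                         "metadata")])
  manifest <- list(
    package = "pcbdechlor",
    version = as.character(utils::packageVersion("pcbdechlor")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    thresholds = cfg[c("activity_threshold", "rho_cutoff", "network_alpha",
                       "prevalence_min_frac", "nst_boundary",
                       "nst_randomizations", "efficiency_bounds",
                       "min_r_squared", "lod", "dominance_threshold",
                       "ratio_band", "n_activity_groups")],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    filter_decisions = decisions)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("manifest written to ", file.path(cfg$out_dir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

#' Write a miniature synthetic study to disk
#'
#' Simulates a complete small study (dechlorinating microcosms with
#' replicates, one inactive microcosm, per-target qPCR standards and
#' unknowns, and a community table whose OHRB abundances track simulated
#' activity) and writes it in the package's input dialects.
#'
#' @param dir output directory.
#' @param n_microcosms number of microcosms (default 8; the first is
#'   rate-free, i.e. inactive).
#' @param replicates observed replicates per microcosm.
#' @param days sampling days.
#' @param seed RNG seed.
#' @return List of file paths plus the simulation ground truth, invisibly.
#' @export
write_fixture_study <- function(dir, n_microcosms = 8, replicates = 2,
                                days = seq(0, 180, by = 30), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(seed, {
    scale <- stats::runif(n_microcosms, 0.5, 1.6)
    scale[1] <- 0  # planted inactive microcosm
    lags <- sample(c(0, 30, 60), n_microcosms, replace = TRUE)
    sims <- lapply(seq_len(n_microcosms), function(i) {
      simulate_microcosm(rates = default_rate_table() * scale[i],
                         days = days, lag_days = lags[i],
                         noise_cv = 0.02, replicates = replicates,
                         seed = seed * 1000L + i,
                         id = sprintf("m%02d", i))
    })
    all_series <- list(); truth_delta <- numeric(0)
    for (i in seq_along(sims)) {
      tr <- truth_series(sims[[i]], include_terminal = FALSE)
      truth_delta[sims[[i]]$series[[1]]$id] <- delta_cl(tr)$total
      for (r in seq_len(replicates)) {
        s <- sims[[i]]$series[[r]]
        s$id <- sprintf("%s_r%d", s$id, r)
        all_series[[s$id]] <- s
      }
    }
    congener_path <- file.path(dir, "congeners_long.csv")
    write_congener_table(all_series, congener_path)

    # qPCR: per-sample OHRB cells and RDase copies coupled to activity
    samples <- names(all_series)
    act <- rep(truth_delta, each = replicates)
    targets <- c(ohrb_targets(), rdase_targets())
    base <- c(1e5, 2e4, 5e3, 2e2, 8e4, 9e4)
    qrows <- list()
    for (k in seq_along(targets)) {
      copies <- base[k] * (0.2 + 4 * act) *
        stats::rlnorm(length(samples), 0, 0.3)
      sim <- simulate_qpcr(stats::setNames(copies, samples),
                           intercept = 36 + k, sigma_cq = 0.15,
                           target = targets[k], seed = seed * 100L + k)
      qrows[[k]] <- rbind(
        data.frame(sample = "standard", target = targets[k],
                   Cq = sim$standards$Cq, dilution_factor = 1,
                   copies = sim$standards$copies, role = "standard"),
        data.frame(sample = sim$samples$sample, target = targets[k],
                   Cq = sim$samples$Cq, dilution_factor = 1,
                   copies = NA, role = "unknown"))
    }
    qpcr_path <- file.path(dir, "qpcr.csv")
    utils::write.csv(do.call(rbind, qrows), qpcr_path, row.names = FALSE)

    comm <- simulate_communities(
      n_samples = length(samples), activity = act,
      coupling_slope = 5, mode = "stochastic",
      seed = seed + 77L)
    colnames(comm$counts) <- samples
    abundance_path <- file.path(dir, "abundance.tsv")
    write_abundance_table(comm$counts, abundance_path,
                          taxonomy = comm$taxonomy)

    meta_path <- file.path(dir, "metadata.csv")
    utils::write.csv(data.frame(sample = samples,
                                microcosm = rep(names(truth_delta),
                                                each = replicates),
                                replicate = rep(seq_len(replicates),
                                                times = n_microcosms),
                                true_delta_cl = act),
                     meta_path, row.names = FALSE)
    invisible(list(congener_table = congener_path, qpcr_table = qpcr_path,
                   abundance_table = abundance_path, metadata = meta_path,
                   truth = list(delta_cl = truth_delta, scale = scale,
                                lags = lags, activity = act)))
  })
}
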