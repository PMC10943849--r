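# Seeded forward models emulating the statistical structure of the study
# inputs: first-order sequential dechlorination kinetics over the congener
# graph, log-linear qPCR dilution series with Gaussian Cq noise, and
# community count tables assembled stochastically (multinomial draws from a
# regional pool) or deterministically (group templates).

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default synthetic Aroclor 1260-like congener mixture
#'
#' A documented synthetic hexa/hepta-dominated starting mixture (initial
#' Cl/PCB about 6.1) standing in for the commercial Aroclor 1260
#' composition, which is not tabulated here. Fully replaceable by any named
#' mole-fraction vector.
#'
#' @return Named mole-fraction vector summing to 1.
#' @export
default_aroclor1260_mixture <- function() {
  c("2345-245" = 0.14, "2345-234" = 0.07, "2356-245" = 0.08,
    "245-245" = 0.16, "234-245" = 0.15, "236-245" = 0.12,
    "234-234" = 0.05, "2345-25" = 0.08, "245-25" = 0.10,
    "245-34" = 0.05)
}

#' Default dechlorination rate table
#'
#' First-order rate constants (per day) by removed-position class and
#' flanking context. Defaults encode flanked-para and flanked-meta removal
#' as the dominant channels with minor ortho activity, sized so that 180
#' days of incubation decreases Cl/PCB by a few tenths of a chlorine.
#'
#' @return 3 x 3 numeric matrix, rows ortho/meta/para, columns
#'   unflanked/singly-flanked/doubly-flanked.
#' @export
default_rate_table <- function() {
  matrix(c(3e-5, 1e-4, 1.5e-4,   # unflanked: ortho, meta, para
           1.2e-4, 5e-4, 7e-4,   # singly-flanked
           2.5e-4, 9e-4, 1.4e-3),# doubly-flanked
         nrow = 3, dimnames = list(
           c("ortho", "meta", "para"),
           c("unflanked", "singly-flanked", "doubly-flanked")))
}

#' Reaction network reachable from a congener set
#'
#' Breadth-first closure of [dechlorination_products()] from the given
#' congeners, down to the terminal biphenyl.
#'
#' @param labels starting congener labels.
#' @return List: `nodes` (labels, terminal last) and `edges` (parent,
#'   product, position, flank, multiplicity).
#' @export
congener_reaction_network <- function(labels) {
  start <- vapply(labels, congener_label, "")
  key <- paste(sort(unique(start)), collapse = ";")
  cached <- .pcb_env$network_cache[[key]]
  if (!is.null(cached)) return(cached)
  seen <- character(0)
  queue <- unique(start)
  edges <- list()
  while (length(queue)) {
    lab <- queue[[1]]; queue <- queue[-1]
    if (lab %in% seen || identical(lab, "biphenyl")) next
    seen <- c(seen, lab)
    prods <- dechlorination_products(lab)
    prods$parent <- lab
    edges[[length(edges) + 1L]] <- prods
    new <- setdiff(prods$product, c(seen, queue, "biphenyl"))
    queue <- c(queue, new)
  }
  edges <- do.call(rbind, edges)
  nodes <- c(sort(seen), if ("biphenyl" %in% edges$product) "biphenyl")
  out <- list(nodes = nodes,
              edges = edges[, c("parent", "product", "position", "flank",
                                "multiplicity")])
  if (is.null(.pcb_env$network_cache))
    .pcb_env$network_cache <- new.env(parent = emptyenv())
  assign(key, out, envir = .pcb_env$network_cache)
  out
}

#' Simulate a dechlorinating microcosm
#'
#' Integrates first-order sequential dechlorination on the congener graph:
#' each chlorine of each congener is removed at rate
#' `rates[position, flank] * multiplicity * C`, products routed per
#' [dechlorination_products()]. Rates are zero before `lag_days`. The
#' noise-free ground truth (which conserves total biphenyl molarity,
#' terminal node included) is returned alongside observed replicate series
#' carrying multiplicative lognormal measurement noise.
#'
#' @param mixture named initial mole-fraction vector (sums to 1).
#' @param rates rate table as in [default_rate_table()] (per day).
#' @param total_conc total PCB concentration in uM (default 26.9, the
#'   nominal spiking level).
#' @param days sampling days starting at 0.
#' @param lag_days lag phase before dechlorination starts.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise per congener per timepoint.
#' @param replicates number of observed replicate series.
#' @param seed RNG seed for the measurement noise.
#' @param track_fluxes also integrate per-edge cumulative fluxes (ground
#'   truth for flux attribution).
#' @param id microcosm identifier.
#' @return A `microcosm_sim`: list with `series` (list of observed
#'   `microcosm_series`), `truth` (noise-free node x day concentration
#'   matrix incl. terminal, plus per-edge cumulative `fluxes` when
#'   tracked), `graph`, and the parameters.
#' @export
simulate_microcosm <- function(mixture = default_aroclor1260_mixture(),
                               rates = default_rate_table(),
                               total_conc = 26.9,
                               days = seq(0, 180, by = 30),
                               lag_days = 0, noise_cv = 0.05,
                               replicates = 2, seed = NULL,
                               track_fluxes = FALSE, id = "sim") {
  if (abs(sum(mixture) - 1) > 1e-6)
    stop("initial mole fractions must sum to 1")
  if (any(mixture < 0) || any(rates < 0))
    stop("mole fractions and rates must be non-negative")
  if (days[1] != 0 || any(diff(days) <= 0))
    stop("sampling days must start at 0 and increase")
  if (lag_days < 0) stop("lag_days must be >= 0")
  names(mixture) <- vapply(names(mixture), congener_label, "")
  net <- congener_reaction_network(names(mixture))
  nodes <- net$nodes
  ed <- net$edges
  ed$rate <- rates[cbind(ed$position, ed$flank)] * ed$multiplicity
  ed <- ed[ed$rate > 0 | TRUE, , drop = FALSE]  # keep all for bookkeeping
  nN <- length(nodes); nE <- nrow(ed)
  pi_ <- match(ed$parent, nodes)
  ci_ <- match(ed$product, nodes)
  M <- matrix(0, nN, nN)
  for (e in seq_len(nE)) {
    M[pi_[e], pi_[e]] <- M[pi_[e], pi_[e]] - ed$rate[e]
    M[ci_[e], pi_[e]] <- M[ci_[e], pi_[e]] + ed$rate[e]
  }
  y0 <- stats::setNames(rep(0, nN), nodes)
  y0[names(mixture)] <- total_conc * mixture
  tt <- pmax(days - lag_days, 0)
  utt <- sort(unique(c(0, tt)))
  rate_vec <- ed$rate
  deriv <- if (track_fluxes) {
    function(t, y, parms) {
      conc <- y[seq_len(nN)]
      list(c(drop(M %*% conc), rate_vec * conc[pi_]))
    }
  } else {
    function(t, y, parms) list(drop(M %*% y))
  }
  state0 <- if (track_fluxes) c(y0, rep(0, nE)) else y0
  if (length(utt) < 2L) {
    sol <- matrix(rep(unname(state0), each = length(tt)), nrow = length(tt))
  } else {
    jac <- if (track_fluxes) {
      J <- matrix(0, nN + nE, nN + nE)
      J[seq_len(nN), seq_len(nN)] <- M
      J[cbind(nN + seq_len(nE), pi_)] <- rate_vec
      function(t, y, parms) J
    } else {
      function(t, y, parms) M
    }
    sol <- deSolve::ode(y = unname(state0), times = utt, func = deriv,
                        parms = NULL, method = "lsoda",
                        jacfunc = jac, jactype = "fullusr",
                        rtol = 1e-10, atol = 1e-12)
    sol <- sol[match(tt, utt), -1, drop = FALSE]
  }
  truth_conc <- t(sol[, seq_len(nN), drop = FALSE])
  rownames(truth_conc) <- nodes
  colnames(truth_conc) <- paste0("day_", days)
  truth <- list(conc = truth_conc)
  if (track_fluxes) {
    fl <- t(sol[, nN + seq_len(nE), drop = FALSE])
    colnames(fl) <- paste0("day_", days)
    truth$fluxes <- cbind(ed[, c("parent", "product", "position", "flank",
                                 "multiplicity")],
                          cumulative = fl[, ncol(fl)])
    truth$flux_by_day <- fl
  }
  congener_nodes <- setdiff(nodes, "biphenyl")
  sdlog <- sqrt(log(1 + noise_cv^2))
  series <- .with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      noise <- matrix(stats::rlnorm(length(congener_nodes) * length(days),
                                    meanlog = -sdlog^2 / 2, sdlog = sdlog),
                      nrow = length(congener_nodes))
      obs <- truth_conc[congener_nodes, , drop = FALSE] * noise
      microcosm_series(obs, days, id = id, replicate = r)
    })
  })
  structure(list(series = series, truth = truth, graph = net,
                 params = list(mixture = mixture, rates = rates,
                               total_conc = total_conc, days = days,
                               lag_days = lag_days, noise_cv = noise_cv,
                               replicates = replicates, seed = seed,
                               edge_rates = ed$rate)),
            class = "microcosm_sim")
}

#' Noise-free series from a simulation
#'
#' @param sim a `microcosm_sim`.
#' @param include_terminal keep the terminal biphenyl row (default TRUE).
#' @return A `microcosm_series` of the ground-truth concentrations.
#' @export
truth_series <- function(sim, include_terminal = TRUE) {
  conc <- sim$truth$conc
  if (!include_terminal)
    conc <- conc[setdiff(rownames(conc), "biphenyl"), , drop = FALSE]
  microcosm_series(conc, sim$params$days,
                   id = paste0(sim$series[[1]]$id), replicate = "truth")
}

#' Simulate qPCR standards and unknowns
#'
#' Forward model `Cq = intercept + slope * log10(copies) + N(0, sigma_cq)`.
#' Non-positive true copies are emitted as non-detects (`Cq = NA`).
#'
#' @param copies named vector of true copies/mL per unknown sample.
#' @param slope,intercept standard-curve parameters (defaults -3.3219 /
#'   38, i.e. 100% efficiency).
#' @param sigma_cq Gaussian Cq noise SD.
#' @param standards nominal copies/mL of the dilution series (default
#'   `10^(2:8)`).
#' @param dilution_factor dilution factor recorded for the unknowns.
#' @param target target name.
#' @param seed RNG seed.
#' @return List: `standards` (data.frame target, copies, Cq, role) and
#'   `samples` (sample, target, Cq, dilution_factor, role).
#' @export
simulate_qpcr <- function(copies, slope = -3.3219, intercept = 38,
                          sigma_cq = 0.1, standards = 10^(2:8),
                          dilution_factor = 1, target = "target",
                          seed = NULL) {
  if (sigma_cq < 0) stop("sigma_cq must be >= 0")
  .with_seed(seed, {
    std_cq <- intercept + slope * log10(standards) +
      stats::rnorm(length(standards), 0, sigma_cq)
    samp <- names(copies) %||% paste0("s", seq_along(copies))
    cq <- ifelse(copies > 0,
                 intercept + slope * log10(pmax(copies, 1e-300)) +
                   stats::rnorm(length(copies), 0, sigma_cq),
                 NA_real_)
    list(standards = data.frame(target = target, copies = standards,
                                Cq = std_cq, role = "standard",
                                stringsAsFactors = FALSE),
         samples = data.frame(sample = samp, target = target, Cq = cq,
                              dilution_factor = dilution_factor,
                              role = "unknown", stringsAsFactors = FALSE))
  })
}

#' Simulate community count tables
#'
#' Stochastic mode draws each sample as a multinomial of size `depth` from
#' a regional pool (lognormal rank-abundance); deterministic mode rounds a
#' fixed group template perturbed by small multiplicative noise. Designated
#' OHRB taxa are scaled by `1 + coupling_slope * activity` per sample
#' before normalization, planting the abundance-activity correlation.
#'
#' @param n_taxa number of taxa in the regional pool.
#' @param n_samples number of samples.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param depth reads per sample (>= 100).
#' @param groups optional group labels per sample (deterministic templates
#'   are per group; default one group).
#' @param activity per-sample Cl/PCB decreases (default seeded
#'   `runif(n, 0, 0.6)`).
#' @param ohrb_taxa names of planted OHRB taxa (subset of the taxonomy
#'   produced; default the three genus names).
#' @param coupling_slope strength of the OHRB abundance-activity coupling
#'   (default 0, no planted correlation).
#' @param template_noise_cv multiplicative noise around deterministic
#'   templates (default 0.02).
#' @param seed RNG seed.
#' @return List: `counts` (taxa x samples integer matrix), `taxonomy`,
#'   `groups`, `activity`, `mode`, `pool`, `ohrb_taxa`, `seed`.
#' @export
simulate_communities <- function(n_taxa = 80, n_samples = 21,
                                 mode = c("stochastic", "deterministic"),
                                 depth = 5000, groups = NULL,
                                 activity = NULL,
                                 ohrb_taxa = ohrb_targets(),
                                 coupling_slope = 0,
                                 template_noise_cv = 0.02, seed = NULL) {
  mode <- match.arg(mode)
  if (depth < 100) stop("sample depth must be >= 100")
  if (n_taxa < length(ohrb_taxa) + 2)
    stop("n_taxa too small for the requested OHRB taxa")
  .with_seed(seed, {
    taxonomy <- c(ohrb_taxa,
                  paste0("Genus_", sprintf("%03d", seq_len(n_taxa -
                                                             length(ohrb_taxa)))))
    # lognormal rank-abundance pool; OHRB taxa forced to minor abundances
    pool <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = 1.2)
    pool[seq_along(ohrb_taxa)] <-
      stats::runif(length(ohrb_taxa), 0.1, 0.5) * stats::median(pool)
    pool <- pool / sum(pool)
    names(pool) <- taxonomy
    if (is.null(groups)) groups <- rep("all", n_samples)
    groups <- as.character(groups)
    if (length(groups) != n_samples) stop("'groups' must label every sample")
    if (is.null(activity)) activity <- stats::runif(n_samples, 0, 0.6)
    templates <- lapply(unique(groups), function(g) {
      tpl <- pool * stats::rlnorm(n_taxa, 0, 1)
      tpl / sum(tpl)
    })
    names(templates) <- unique(groups)
    counts <- sapply(seq_len(n_samples), function(j) {
      base <- if (mode == "stochastic") pool else templates[[groups[j]]]
      pj <- base
      idx <- match(ohrb_taxa, taxonomy)
      pj[idx] <- pj[idx] * (1 + coupling_slope * activity[j])
      pj <- pj / sum(pj)
      if (mode == "stochastic") {
        drop(stats::rmultinom(1, depth, pj))
      } else {
        sdl <- sqrt(log(1 + template_noise_cv^2))
        round(depth * pj * stats::rlnorm(n_taxa, -sdl^2 / 2, sdl))
      }
    })
    rownames(counts) <- taxonomy
    colnames(counts) <- paste0("sample_", sprintf("%02d", seq_len(n_samples)))
    list(counts = counts, taxonomy = taxonomy, groups = groups,
         activity = stats::setNames(activity, colnames(counts)),
         mode = mode, pool = pool, ohrb_taxa = ohrb_taxa, seed = seed)
  })
}

#' Simulate an abundance table with planted Spearman correlations
#'
#' Gaussian-copula generator: latent standard normals, with designated
#' genus pairs given latent correlation `rho`, pushed through a lognormal
#' quantile map (a monotone transform, so rank correlations are
#' preserved up to sampling noise) and scaled to counts.
#'
#' @param n_genera number of genera.
#' @param n_samples number of samples.
#' @param planted data.frame with columns `g1`, `g2` (genus indices) and
#'   `rho` (latent correlation).
#' @param depth reads per sample.
#' @param seed RNG seed.
#' @return List: `counts`, `taxonomy`, `planted`.
#' @export
simulate_cooccurrence_table <- function(n_genera = 30, n_samples = 21,
                                        planted = NULL, depth = 5000,
                                        seed = NULL) {
  .with_seed(seed, {
    Z <- matrix(stats::rnorm(n_samples * n_genera), n_samples, n_genera)
    if (!is.null(planted)) {
      for (k in seq_len(nrow(planted))) {
        a <- planted$g1[k]; b <- planted$g2[k]; r <- planted$rho[k]
        Z[, b] <- r * Z[, a] + sqrt(1 - r^2) * stats::rnorm(n_samples)
      }
    }
    meanlog <- stats::rnorm(n_genera, 0, 0.5)
    rel <- exp(sweep(Z * 0.8, 2, meanlog, "+"))
    rel <- sweep(rel, 1, rowSums(rel), "/")
    counts <- t(round(rel * depth))
    rownames(counts) <- paste0("Genus_", sprintf("%03d", seq_len(n_genera)))
    colnames(counts) <- paste0("sample_", sprintf("%02d", seq_len(n_samples)))
    list(counts = counts,
         taxonomy = rownames(counts),
         planted = planted)
  })
}
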