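# Community ecology on taxon-by-sample abundance tables: OHRB screening,
# alpha diversity, Bray-Curtis / principal coordinates, prevalence-filtered
# Spearman co-occurrence networks with Benjamini-Hochberg control, and a
# normalized stochasticity ratio (NST) null model.

#' Default OHRB taxon screen list
#'
#' The three well-characterized organohalide-respiring genera plus the
#' uncultivated Dehalococcoidia lineages carrying putative reductive
#' dehalogenase genes.
#'
#' @return Character vector of taxon name patterns (matched as fixed
#'   substrings of taxonomy labels).
#' @export
ohrb_default_taxa <- function() {
  c("Dehalococcoides", "Dehalogenimonas", "Dehalobacter",
    "S085", "vadinBA26", "GIF9", "DscP2", "t0.6.f")
}

#' Screen an abundance table for OHRB taxa
#'
#' Matches taxonomy labels against a configurable OHRB list (fixed
#' substring match) and reports, per sample, the summed relative abundance
#' of matching taxa and a presence flag; the occurrence frequency is the
#' fraction of samples with at least one OHRB taxon present.
#'
#' @param counts taxa x samples matrix (counts or relative abundances),
#'   taxa as rownames.
#' @param taxonomy taxonomy label per taxon (default: rownames).
#' @param taxa OHRB name patterns (default [ohrb_default_taxa()]).
#' @return List: `per_sample` (data.frame sample, ohrb_relabund, present),
#'   `occurrence_frequency`, `matched_taxa`.
#' @export
ohrb_screen <- function(counts, taxonomy = rownames(counts),
                        taxa = ohrb_default_taxa()) {
  counts <- as.matrix(counts)
  if (is.null(taxonomy) || length(taxonomy) != nrow(counts) ||
      all(!nzchar(taxonomy)))
    stop("taxonomy labels are required (one per taxon)")
  is_ohrb <- vapply(taxonomy, function(lab)
    any(vapply(taxa, function(p) grepl(p, lab, fixed = TRUE), logical(1))),
    logical(1))
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("every sample needs positive total abundance")
  rel <- colSums(counts[is_ohrb, , drop = FALSE]) / tot
  per_sample <- data.frame(
    sample = colnames(counts) %||% as.character(seq_len(ncol(counts))),
    ohrb_relabund = unname(rel), present = unname(rel > 0),
    stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       occurrence_frequency = mean(per_sample$present),
       matched_taxa = taxonomy[is_ohrb])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alpha diversity per sample
#'
#' Richness (taxa with positive abundance), Shannon entropy
#' `H = -sum p_i ln p_i` (natural log, via vegan) and Pielou evenness
#' `H / ln(richness)` (undefined for a single taxon).
#'
#' @param counts taxa x samples matrix or a single sample vector.
#' @return data.frame: sample, richness, shannon, pielou.
#' @export
alpha_diversity <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1,
                                             dimnames = list(NULL, "sample"))
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("abundances must be non-negative")
  if (any(colSums(counts) <= 0)) stop("zero-total sample: diversity undefined")
  h <- vegan::diversity(t(counts), index = "shannon")
  rich <- colSums(counts > 0)
  data.frame(sample = colnames(counts) %||% as.character(seq_len(ncol(counts))),
             richness = unname(rich), shannon = unname(h),
             pielou = unname(ifelse(rich > 1, h / log(rich), NA_real_)),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum |x_i - y_i| / sum (x_i + y_i)`, in \[0, 1\].
#'
#' @param x,y equal-length non-negative vectors, not both all-zero.
#' @return Dissimilarity scalar.
#' @examples
#' bray_curtis(c(2, 1, 0), c(0, 1, 2))  # 2/3
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  den <- sum(x + y)
  if (den == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(x - y)) / den
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes (via `stats::cmdscale`).
#' Axis fractions are eigenvalues over the sum of positive eigenvalues;
#' negative eigenvalues (non-Euclidean dissimilarities) are reported, not
#' corrected.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal, or a `dist`.
#' @param k number of axes (default 2).
#' @return List: `points` (samples x k), `eig`, `explained` (fractions for
#'   the k axes), `negative_eig`.
#' @export
pcoa_ord <- function(d, k = 2) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("dissimilarity matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12))
      stop("dissimilarity matrix must have a zero diagonal")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  k <- min(k, n - 1L)
  sc <- stats::cmdscale(d, k = k, eig = TRUE)
  eig <- sc$eig
  pos <- eig[eig > 1e-8 * max(abs(eig))]
  explained <- eig[seq_len(k)] / sum(pos)
  list(points = sc$points, eig = eig, explained = explained,
       negative_eig = eig[eig < -1e-8 * max(abs(eig))])
}

#' Prevalence filter for network analysis
#'
#' Keeps genera detected (abundance > 0) in strictly more than `min_frac`
#' of the samples, and removes singleton genera (integer total abundance of
#' exactly 1 across the group).
#'
#' @param counts taxa x samples matrix for one sample group (>= 2 samples).
#' @param min_frac prevalence fraction; strict threshold (default 0.5).
#' @param drop_singletons remove total-count-1 genera (default TRUE; only
#'   applied when the table is integer-valued).
#' @return The filtered matrix.
#' @export
prevalence_filter <- function(counts, min_frac = 0.5,
                              drop_singletons = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("prevalence filtering needs >= 2 samples")
  prev_ok <- rowSums(counts > 0) > min_frac * ncol(counts)
  keep <- prev_ok
  if (drop_singletons) {
    integral <- apply(counts, 1, function(r) all(r == round(r)))
    keep <- keep & !(integral & rowSums(counts) == 1)
  }
  counts[keep, , drop = FALSE]
}

# Spearman p-value: t-approximation for n >= 10, full permutation
# enumeration below (n <= 9, 9! = 362,880 permutations, vectorised)
spearman_p <- function(rho, n, ranks_x = NULL, ranks_y = NULL) {
  if (abs(rho) >= 1) return(0)
  if (n >= 10 || is.null(ranks_x)) {
    tstat <- abs(rho) * sqrt((n - 2) / (1 - rho^2))
    return(2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE))
  }
  perms <- .all_permutations(n)
  rxc <- ranks_x - mean(ranks_x)
  ry <- ranks_y
  denom <- sqrt(sum(rxc^2)) * stats::sd(ry) * sqrt(n - 1)
  rho_perm <- (matrix(ry[perms], nrow = nrow(perms)) %*% rxc -
                 nrow(perms) * 0) / denom
  mean(abs(rho_perm) >= abs(rho) - 1e-12)
}

.all_permutations <- function(n) {
  if (n > 9) stop("permutation enumeration capped at n = 9")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

#' Build a Spearman co-occurrence network
#'
#' Tests every genus pair by Spearman correlation on per-sample relative
#' abundances (average ranks for ties; t-approximation p-values for
#' n >= 10, exact permutation below). P-values are Benjamini-Hochberg
#' adjusted over all tested pairs; an edge requires `|rho| > rho_cutoff`
#' and adjusted p `< alpha`. Constant genera are excluded from testing
#' with a warning.
#'
#' @param counts filtered taxa x samples matrix (>= 4 samples, >= 2
#'   genera), counts or relative abundances.
#' @param rho_cutoff correlation magnitude cutoff, strict (default 0.6).
#' @param alpha adjusted-p cutoff, strict (default 0.01).
#' @return A `cooccurrence_network`: list with `nodes`, `tested_pairs`
#'   (source, target, rho, p, p_adj), `edges` (the significant subset with
#'   `sign`), and `topology` (n_nodes, n_edges, average_degree).
#' @export
build_cooccurrence_network <- function(counts, rho_cutoff = 0.6,
                                       alpha = 0.01) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 4L) stop("network inference needs >= 4 samples")
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("every sample needs positive total abundance")
  rel <- sweep(counts, 2, tot, "/")
  constant <- apply(rel, 1, function(r) stats::var(r) == 0)
  if (any(constant)) {
    warning("excluding constant genera from testing: ",
            paste(rownames(rel)[constant], collapse = ", "))
    rel <- rel[!constant, , drop = FALSE]
  }
  if (nrow(rel) < 2L) stop("network inference needs >= 2 non-constant genera")
  n <- ncol(rel)
  ranks <- t(apply(rel, 1, rank))  # average ranks
  rho_mat <- stats::cor(t(ranks))
  idx <- which(upper.tri(rho_mat), arr.ind = TRUE)
  rho <- rho_mat[idx]
  p <- vapply(seq_len(nrow(idx)), function(i)
    spearman_p(rho[i], n, ranks[idx[i, 1], ], ranks[idx[i, 2], ]),
    numeric(1))
  pairs <- data.frame(
    source = rownames(rel)[idx[, 1]], target = rownames(rel)[idx[, 2]],
    rho = rho, p = p, p_adj = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  edges <- pairs[abs(pairs$rho) > rho_cutoff & pairs$p_adj < alpha, ,
                 drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  rownames(edges) <- NULL
  net <- structure(list(nodes = rownames(rel), tested_pairs = pairs,
                        edges = edges, rho_cutoff = rho_cutoff,
                        alpha = alpha),
                   class = "cooccurrence_network")
  net$topology <- network_topology(net)
  net
}

#' Network topology summary
#'
#' @param net a `cooccurrence_network` (or any list with `nodes` and
#'   `edges`).
#' @return Named vector: `n_nodes`, `n_edges`, `average_degree`
#'   (`2L/n`, 0 for the empty graph).
#' @export
network_topology <- function(net) {
  n <- length(net$nodes)
  L <- nrow(net$edges)
  c(n_nodes = n, n_edges = L,
    average_degree = if (n > 0) 2 * L / n else 0)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "cooccurrence_network: n = %d genera, L = %d edges (|rho| > %.2f, BH-adjusted p < %.3g), average degree %.2f\n",
    x$topology["n_nodes"], x$topology["n_edges"], x$rho_cutoff, x$alpha,
    x$topology["average_degree"]))
  invisible(x)
}

#' Write a network edge list as TSV
#' @param net a `cooccurrence_network`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_network_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a co-occurrence network as GraphML
#' @param net a `cooccurrence_network`.
#' @param path output path (.graphml).
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Normalized stochasticity ratio (NST)
#'
#' Null-model statistic classifying community assembly. Per group, a
#' regional pool is built from the summed counts; each sample is replaced
#' by `B` multinomial null draws of its observed size with taxon
#' probabilities proportional to regional relative abundance. For every
#' sample pair the observed Bray-Curtis dissimilarity `D_obs` is compared
#' with the null mean `E_null`; the pair's stochasticity ratio is
#' `min(D_obs, E_null) / max(D_obs, E_null)` and NST is the group mean
#' times 100%. Assemblies with NST above 50% are stochastic-dominated;
#' below, deterministic-dominated. This magnitude-ratio form is this
#' package's contract for the statistic (the family of NST estimators
#' varies in its normalization); it is validated behaviourally: data drawn
#' from the null model itself scores > 50%, templated near-replicate
#' communities score < 50%.
#'
#' @param counts integer taxa x samples count matrix.
#' @param groups group assignment per sample (default: one group).
#' @param B number of null randomizations (default 1000; < 100 warns).
#' @param boundary stochastic/deterministic boundary in percent
#'   (default 50).
#' @param seed RNG seed for the null draws (recorded in the output).
#' @return data.frame with one row per group: group, nst (percent), label,
#'   n_samples, n_pairs, B, seed; per-pair diagnostics in
#'   `attr(, "pairs")`.
#' @export
nst <- function(counts, groups = NULL, B = 1000, boundary = 50,
                seed = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("NST requires integer counts (counts mode)")
  if (B < 100) warning("B = ", B, " randomizations is low; ",
                       "1000 is the conventional choice")
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("'groups' must assign every sample")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  res <- list(); pair_res <- list()
  for (g in unique(groups)) {
    X <- counts[, groups == g, drop = FALSE]
    m <- ncol(X)
    if (m < 3L) stop("group '", g, "' has fewer than 3 samples")
    pool <- rowSums(X)
    if (sum(pool) == 0) stop("group '", g, "' has no observations")
    p <- pool / sum(pool)
    nulls <- lapply(seq_len(m), function(j)
      stats::rmultinom(B, size = sum(X[, j]), prob = p))
    pr <- utils::combn(m, 2)
    ratios <- numeric(ncol(pr)); dobs <- numeric(ncol(pr))
    dnull <- numeric(ncol(pr))
    for (k in seq_len(ncol(pr))) {
      i <- pr[1, k]; j <- pr[2, k]
      dobs[k] <- bray_curtis(X[, i], X[, j])
      num <- colSums(abs(nulls[[i]] - nulls[[j]]))
      den <- colSums(nulls[[i]] + nulls[[j]])
      dnull[k] <- mean(num / den)
      hi <- max(dobs[k], dnull[k])
      ratios[k] <- if (hi == 0) 1 else min(dobs[k], dnull[k]) / hi
    }
    val <- 100 * mean(ratios)
    res[[g]] <- data.frame(
      group = g, nst = val,
      label = if (val > boundary) "stochastic-dominated"
              else "deterministic-dominated",
      n_samples = m, n_pairs = ncol(pr), B = B,
      seed = if (is.null(seed)) NA_integer_ else seed,
      stringsAsFactors = FALSE)
    pair_res[[g]] <- data.frame(
      group = g,
      sample_i = colnames(X)[pr[1, ]] %||% pr[1, ],
      sample_j = colnames(X)[pr[2, ]] %||% pr[2, ],
      d_obs = dobs, d_null_mean = dnull, ratio = ratios,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "pairs") <- do.call(rbind, pair_res)
  out
}

#' One-way ANOVA group comparison
#'
#' @param values numeric response.
#' @param labels group labels (>= 2 groups of >= 2 values each).
#' @return List with `F`, `p`, `df` (between/within degrees of freedom).
#' @export
compare_groups <- function(values, labels) {
  labels <- factor(labels)
  if (length(values) != length(labels)) stop("'values' and 'labels' differ")
  sizes <- table(labels)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("ANOVA needs >= 2 groups with >= 2 values each")
  ft <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(F = unname(ft$statistic), p = ft$p.value,
       df = unname(ft$parameter))
}

#' Split samples into activity groups
#'
#' Ranks samples by their Cl/PCB decrease and splits them into
#' `n_groups` equal-size groups (group 1 = lowest activity).
#'
#' @param delta numeric Cl/PCB decreases.
#' @param n_groups number of groups (default 4, quartiles).
#' @return Integer factor of group assignments.
#' @export
activity_quartiles <- function(delta, n_groups = 4) {
  rk <- rank(delta, ties.method = "first")
  factor(ceiling(rk * n_groups / length(delta)), levels = seq_len(n_groups))
}
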