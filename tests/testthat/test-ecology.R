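# Community ecology: OHRB screening, alpha diversity, Bray-Curtis, PCoA,
# prevalence filtering, co-occurrence networks and the NST null model.

test_that("OHRB screening matches planted prevalence exactly", {
  counts <- matrix(10, nrow = 4, ncol = 6,
                   dimnames = list(c("Dehalobacter", "Genus_A", "Genus_B",
                                     "Dehalococcoidia_S085"),
                                   paste0("s", 1:6)))
  counts["Dehalobacter", 4:6] <- 0
  counts["Dehalococcoidia_S085", 2:6] <- 0
  sc <- ohrb_screen(counts)
  # samples 1-3 have Dehalobacter, sample 1 also the uncultivated lineage
  expect_equal(sc$per_sample$present, c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                        FALSE))
  expect_equal(sc$occurrence_frequency, 0.5)
  expect_setequal(sc$matched_taxa, c("Dehalobacter", "Dehalococcoidia_S085"))
  # a single listed taxon at trace abundance counts as present
  tiny <- matrix(c(1, 9999), ncol = 1,
                 dimnames = list(c("Dehalobacter", "Genus_A"), "s1"))
  expect_true(ohrb_screen(tiny)$per_sample$present)
  none <- matrix(5, 2, 2, dimnames = list(c("Genus_A", "Genus_B"), NULL))
  expect_equal(ohrb_screen(none)$occurrence_frequency, 0)
  # planted OHRB in synthetic tables are recovered
  comm <- simulate_communities(n_samples = 12, seed = 5)
  expect_equal(ohrb_screen(comm$counts)$occurrence_frequency, 1)
})

test_that("alpha diversity gives the textbook values", {
  u10 <- rep(5, 10)
  a <- alpha_diversity(u10)
  expect_equal(a$shannon, log(10), tolerance = 1e-12)
  expect_equal(a$richness, 10)
  expect_equal(a$pielou, 1, tolerance = 1e-12)
  one <- alpha_diversity(c(7, 0, 0))
  expect_equal(one$shannon, 0)
  expect_true(is.na(one$pielou))
  h <- alpha_diversity(c(4, 3, 2, 1))$shannon
  p <- c(4, 3, 2, 1) / 10
  expect_equal(h, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(round(h, 4), 1.2799)
  expect_error(alpha_diversity(c(0, 0)), "undefined")
})

test_that("Bray-Curtis agrees with the formula and with vegan", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(2, 1, 0), c(0, 1, 2)), 2 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(7)
  for (i in 1:10) {
    x <- runif(8); y <- runif(8)
    expect_equal(bray_curtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(9)
  pts <- cbind(runif(7), runif(7))
  D <- as.matrix(dist(pts))
  ord <- pcoa_ord(D, k = 2)
  expect_equal(as.matrix(dist(ord$points)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  # three equidistant points: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  ord3 <- pcoa_ord(D3, k = 2)
  pos <- ord3$eig[ord3$eig > 1e-9]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  # axis fractions agree with an independent eigendecomposition
  comm <- simulate_communities(n_samples = 6, seed = 12)
  B <- as.matrix(vegan::vegdist(t(comm$counts), "bray"))
  ord6 <- pcoa_ord(B, k = 2)
  n <- nrow(B)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (B^2) %*% J
  ev <- eigen(G, symmetric = TRUE)$values
  expect_equal(ord6$explained[1], ev[1] / sum(ev[ev > 1e-8]),
               tolerance = 1e-8)
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("prevalence filtering is strict at 50% and drops singletons", {
  n <- 21
  counts <- rbind(
    in10 = c(rep(3, 10), rep(0, 11)),
    in11 = c(rep(3, 11), rep(0, 10)),
    everywhere = rep(2, n),
    singleton = c(1, rep(0, n - 1)))
  kept <- rownames(prevalence_filter(counts))
  expect_false("in10" %in% kept)   # 10/21 = 47.6% removed
  expect_true("in11" %in% kept)    # 11/21 = 52.4% kept
  expect_true("everywhere" %in% kept)
  expect_false("singleton" %in% kept)
  # a genus in exactly half the samples fails the strict threshold
  counts2 <- rbind(half = c(rep(1, 5), rep(0, 5)), all = rep(5, 10))
  expect_false("half" %in% rownames(prevalence_filter(counts2)))
})

test_that("Spearman p-values: permutation enumeration matches the exact test", {
  set.seed(15)
  x <- c(2.2, 5.1, 1.3, 4.4, 7.9, 0.2, 6.1)
  y <- c(1.1, 4.0, 2.9, 5.2, 6.6, 0.4, 3.3)
  rho <- cor(x, y, method = "spearman")
  p_perm <- pcbdechlor:::spearman_p(rho, length(x), rank(x), rank(y))
  p_exact <- cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  expect_equal(p_perm, p_exact, tolerance = 1e-12)
  # t-approximation at n = 21 agrees with cor.test's asymptotic branch
  x2 <- rnorm(21); y2 <- rnorm(21)
  rho2 <- cor(x2, y2, method = "spearman")
  p_t <- pcbdechlor:::spearman_p(rho2, 21)
  expect_equal(p_t, cor.test(x2, y2, method = "spearman",
                             exact = FALSE)$p.value, tolerance = 0.03)
})

test_that("co-occurrence networks recover planted correlations under BH", {
  tab <- simulate_cooccurrence_table(
    n_genera = 30, n_samples = 21,
    planted = data.frame(g1 = c(1, 3), g2 = c(2, 4), rho = c(0.9, 0.4)),
    seed = 42)
  net <- build_cooccurrence_network(tab$counts)
  key <- paste(net$edges$source, net$edges$target)
  expect_true("Genus_001 Genus_002" %in% key)
  expect_false("Genus_003 Genus_004" %in% key)
  # every emitted edge satisfies both cutoffs
  expect_true(all(abs(net$edges$rho) > 0.6 & net$edges$p_adj < 0.01))
  # BH never increases the edge count over raw p
  raw_edges <- sum(abs(net$tested_pairs$rho) > 0.6 &
                     net$tested_pairs$p < 0.01)
  expect_lte(nrow(net$edges), raw_edges)
  # constant genera (in relative abundance) are excluded with a warning
  a <- rep(c(0.05, 0.45), 6)
  rel <- rbind(flat = rep(0.25, 12), a = a, b = 0.5 - a,
               c2 = rep(0.25, 12))
  expect_warning(net2 <- build_cooccurrence_network(rel), "constant")
  expect_false("flat" %in% net2$nodes)
  expect_setequal(net2$nodes, c("a", "b"))
})

test_that("topology metrics match an igraph recount", {
  tri <- list(nodes = c("a", "b", "c"),
              edges = data.frame(source = c("a", "b", "c"),
                                 target = c("b", "c", "a")))
  expect_equal(network_topology(tri),
               c(n_nodes = 3, n_edges = 3, average_degree = 2))
  empty <- list(nodes = character(0),
                edges = data.frame(source = character(0),
                                   target = character(0)))
  expect_equal(network_topology(empty),
               c(n_nodes = 0, n_edges = 0, average_degree = 0))
  tab <- simulate_cooccurrence_table(
    planted = data.frame(g1 = c(1, 3, 5), g2 = c(2, 4, 6),
                         rho = c(0.95, 0.9, 0.85)), seed = 8)
  net <- build_cooccurrence_network(tab$counts)
  g <- igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  expect_equal(unname(net$topology["n_edges"]), igraph::gsize(g))
  expect_equal(unname(net$topology["average_degree"]),
               mean(igraph::degree(g)))
})

test_that("NST separates null-generated from templated communities", {
  stoch <- simulate_communities(mode = "stochastic", n_samples = 12,
                                seed = 61)
  r_st <- nst(stoch$counts, B = 200, seed = 62)
  expect_gt(r_st$nst, 50)
  expect_equal(r_st$label, "stochastic-dominated")
  det <- simulate_communities(mode = "deterministic", n_samples = 12,
                              seed = 61)
  r_dt <- nst(det$counts, B = 200, seed = 62)
  expect_lt(r_dt$nst, 50)
  expect_equal(r_dt$label, "deterministic-dominated")
  # bounded statistic, recorded diagnostics
  expect_true(all(c(r_st$nst, r_dt$nst) >= 0 & c(r_st$nst, r_dt$nst) <= 100))
  pairs <- attr(r_st, "pairs")
  expect_equal(nrow(pairs), choose(12, 2))
  expect_true(all(pairs$ratio >= 0 & pairs$ratio <= 1))
  # determinism under a fixed seed, bit-identical
  expect_identical(nst(stoch$counts, B = 100, seed = 99)$nst,
                   nst(stoch$counts, B = 100, seed = 99)$nst)
  # observed dissimilarities invariant to taxon relabelling
  perm <- sample(nrow(stoch$counts))
  r_perm <- nst(stoch$counts[perm, ], B = 100, seed = 99)
  expect_equal(sort(attr(r_perm, "pairs")$d_obs),
               sort(attr(nst(stoch$counts, B = 100, seed = 99),
                         "pairs")$d_obs))
  expect_error(nst(matrix(c(0.5, 1, 2, 3), 2, 2)), "integer")
  expect_warning(nst(stoch$counts[, 1:4], B = 50, seed = 1), "low")
})

test_that("one-way ANOVA matches the textbook F on a toy table", {
  vals <- c(1, 2, 3, 2, 3, 4)
  labs <- rep(c("a", "b"), each = 3)
  res <- compare_groups(vals, labs)
  # hand computation: grand mean 2.5, SSB = 6*(0.5^2) = 1.5, SSW = 4
  # F = (1.5/1) / (4/4) = 1.5
  expect_equal(res$F, 1.5, tolerance = 1e-12)
  expect_equal(res$p, stats::pf(1.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  set.seed(77)
  v2 <- c(rnorm(20, 0), rnorm(20, 5))
  expect_lt(compare_groups(v2, rep(1:2, each = 20))$p, 0.001)
  expect_error(compare_groups(1:3, c("a", "a", "b")), ">= 2 groups")
})

test_that("activity grouping produces equal quartiles by rank", {
  set.seed(3)
  delta <- runif(84)
  g <- activity_quartiles(delta)
  expect_equal(as.vector(table(g)), rep(21, 4))
  expect_true(max(delta[g == 1]) <= min(delta[g == 4]))
})
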