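# Dechlorination statistics: Cl/PCB, positional decomposition, activity
# threshold behaviour, lag intervals and preference classification.

make_series <- function(profiles, days, id = "m1", ...) {
  labs <- unique(unlist(lapply(profiles, names)))
  conc <- do.call(cbind, lapply(profiles, function(p) {
    v <- stats::setNames(rep(0, length(labs)), labs)
    v[names(p)] <- p
    v
  }))
  conc <- matrix(conc, nrow = length(labs), dimnames = list(labs, NULL))
  microcosm_series(conc, days, id = id, ...)
}

test_that("Cl/PCB is the mole-fraction-weighted chlorine count", {
  expect_equal(cl_per_pcb(c("23456-23456" = 1)), 10)
  expect_equal(cl_per_pcb(c("245-25" = 0.5, "25-25" = 0.5)), 4.5)
  expect_equal(cl_per_pcb(c("2345-245" = 2, "245-245" = 1, "25-25" = 1)), 6)
  # invariance to uniform rescaling
  p <- c("2345-245" = 0.3, "236-25" = 1.7, "24-0" = 0.4)
  expect_equal(cl_per_pcb(p), cl_per_pcb(1000 * p))
  expect_error(cl_per_pcb(c("25-25" = 0)), "no positive abundance")
})

test_that("positional components sum to Cl/PCB for random profiles", {
  expect_equal(positional_cl_per_pcb(c("23456-23456" = 1)),
               c(ortho = 4, meta = 4, para = 2))
  expect_equal(positional_cl_per_pcb(c("25-25" = 1)),
               c(ortho = 2, meta = 2, para = 0))
  expect_equal(positional_cl_per_pcb(c("2345-245" = 1, "25-25" = 1)),
               c(ortho = 2, meta = 2.5, para = 1))
  set.seed(11)
  labels <- enumerate_congeners()$label
  for (i in 1:25) {
    p <- random_profile(labels, n = sample(2:12, 1))
    expect_equal(sum(positional_cl_per_pcb(p)), cl_per_pcb(p),
                 tolerance = 1e-9)
  }
})

test_that("delta Cl/PCB decomposes by position and needs sampled days", {
  s <- make_series(list(c("2345-245" = 1), c("245-245" = 1)), c(0, 180))
  d <- delta_cl(s, 180)
  expect_equal(d$total, 1)
  expect_equal(d$by_position, c(ortho = 0, meta = 1, para = 0))
  expect_equal(sum(d$by_position), d$total, tolerance = 1e-12)
  expect_error(delta_cl(s, 90), "not sampled")
  # identical profiles: zero everywhere
  s0 <- make_series(list(c("245-25" = 1), c("245-25" = 1)), c(0, 30))
  expect_equal(delta_cl(s0, 30)$total, 0)
})

test_that("activity threshold is inclusive and control-replaceable", {
  mk <- function(final_cl_drop) {
    # mix deca with nona to hit an exact Cl/PCB decrease
    make_series(list(c("23456-23456" = 1),
                     c("23456-23456" = 1 - final_cl_drop,
                       "23456-2345" = final_cl_drop)), c(0, 180))
  }
  expect_false(call_activity(mk(0.04)))
  expect_true(call_activity(mk(0.05)))   # boundary inclusive
  expect_true(call_activity(mk(0.36)))
  # control-derived threshold
  ctrl <- mk(0.08)
  s <- mk(0.07)
  s$control <- ctrl
  expect_true(call_activity(s, threshold = 0.05))
  expect_false(call_activity(s, threshold = NULL))
  expect_error(call_activity(mk(0.2), threshold = NULL), "abiotic-control")
})

test_that("lag time is the onset interval at sampling resolution", {
  days <- seq(0, 180, by = 30)
  profs <- lapply(c(0, 0.01, 0.30, 0.40, 0.45, 0.50, 0.50), function(d)
    c("23456-23456" = 1 - d, "23456-2345" = d))
  s <- make_series(profs, days)
  expect_equal(lag_time(s), c(lower = 30, upper = 60))
  # active at the first post-zero sample
  s2 <- make_series(list(c("23456-23456" = 1),
                         c("23456-23456" = 0.5, "23456-2345" = 0.5)),
                    c(0, 30))
  expect_equal(lag_time(s2), c(lower = 0, upper = 30))
  s3 <- make_series(list(c("23456-23456" = 1), c("23456-23456" = 1)),
                    c(0, 30))
  expect_error(lag_time(s3), "never reaches")
  d <- dechlor_stats(s)
  expect_true(d$active)
  expect_equal(d$lag_upper, 60)
})

test_that("preference classification separates para, meta and comparable", {
  meta_only <- lapply(1:3, function(r)
    make_series(list(c("2345-245" = 1), c("245-245" = 1)), c(0, 180),
                id = "m", replicate = r))
  expect_equal(preference_class(meta_only), "meta-preferential")
  para_only <- lapply(1:3, function(r)
    make_series(list(c("2345-245" = 1), c("235-245" = 1)), c(0, 180),
                id = "m", replicate = r))
  expect_equal(preference_class(para_only), "para-preferential")
  # identical para and meta removal: comparable
  both <- lapply(1:3, function(r)
    make_series(list(c("2345-245" = 2), c("245-245" = 1, "235-245" = 1)),
                c(0, 180), id = "m", replicate = r))
  expect_equal(preference_class(both), "comparable")
  expect_error(preference_class(meta_only[1]), "insufficient")
  inact <- make_series(list(c("2345-245" = 1), c("2345-245" = 1)), c(0, 180))
  expect_error(preference_class(list(inact, inact)), "inactive")
})

test_that("preference recovery from simulated 3:1 para:meta kinetics", {
  pref_rates <- default_rate_table()
  pref_rates["para", ] <- 3 * pref_rates["meta", ]
  hits <- vapply(1:10, function(s) {
    sim <- simulate_microcosm(rates = pref_rates, noise_cv = 0.05,
                              replicates = 8, seed = 4000 + s)
    preference_class(sim$series) == "para-preferential"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pathway graphs connect observed single-step relations only", {
  s <- make_series(list(c("2345-245" = 2, "245-245" = 0.1, "25-25" = 0.05),
                        c("2345-245" = 1, "245-245" = 1, "25-25" = 0.05)),
                   c(0, 90))
  g <- build_pathway_graph(s)
  expect_equal(nrow(g$nodes), 3)
  e <- g$edges
  expect_equal(nrow(e), 1)  # 245-245 and 25-25 differ by 2 Cl: no edge
  expect_equal(e$parent, "2345-245")
  expect_equal(e$daughter, "245-245")
  expect_equal(e$position, "meta")
  expect_equal(e$flank, "doubly-flanked")
  # orphan: daughter appearing later with no observed parent
  s2 <- make_series(list(c("2345-245" = 1), c("2345-245" = 0.9,
                                              "245-24" = 0.1)), c(0, 90))
  g2 <- build_pathway_graph(s2)
  expect_true(g2$nodes$orphan[g2$nodes$label == congener_label("245-24")])
  expect_false(g2$nodes$orphan[g2$nodes$label == "2345-245"])
})

test_that("flux attribution solves simple mass balances exactly", {
  # linear chain: parent loss = daughter gain = 1
  s <- make_series(list(c("2345-245" = 2, "245-245" = 0),
                        c("2345-245" = 1, "245-245" = 1)), c(0, 30))
  g <- attribute_fluxes(build_pathway_graph(s), s)
  expect_equal(g$edges$flux, 1, tolerance = 1e-5)
  # two parents, one daughter: fluxes follow the parent losses
  s2 <- make_series(list(c("234-245" = 1, "245-245" = 1, "245-24" = 0),
                         c("234-245" = 0.4, "245-245" = 0.6,
                           "245-24" = 1)), c(0, 30))
  g2 <- attribute_fluxes(build_pathway_graph(s2), s2)
  f <- stats::setNames(g2$edges$flux, g2$edges$parent)
  expect_equal(unname(f["234-245"]), 0.6, tolerance = 1e-4)
  expect_equal(unname(f["245-245"]), 0.4, tolerance = 1e-4)
  # infeasible balance warns but returns
  s3 <- make_series(list(c("2345-245" = 2, "245-245" = 0),
                         c("2345-245" = 1, "245-245" = 3)), c(0, 30))
  expect_warning(attribute_fluxes(build_pathway_graph(s3), s3),
                 "residual")
})

test_that("flux recovery on a noise-free simulated cascade", {
  rates <- default_rate_table() * 0
  rates["meta", "doubly-flanked"] <- 4e-3
  rates["para", "singly-flanked"] <- 3e-3
  sim <- simulate_microcosm(mixture = c("2345-25" = 1), rates = rates,
                            noise_cv = 0, replicates = 1,
                            track_fluxes = TRUE, id = "cascade")
  ts <- truth_series(sim)
  g <- attribute_fluxes(build_pathway_graph(ts), ts)
  truth <- sim$truth$fluxes
  truth <- truth[truth$cumulative > 1e-9, ]
  m <- merge(g$edges, truth,
             by.x = c("parent", "daughter"),
             by.y = c("parent", "product"))
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(abs(m$flux - m$cumulative) / m$cumulative < 0.01))
})

test_that("pathway exports are readable edge lists and GraphML", {
  s <- make_series(list(c("2345-245" = 2, "245-245" = 0),
                        c("2345-245" = 1, "245-245" = 1)), c(0, 30))
  g <- attribute_fluxes(build_pathway_graph(s), s)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_pathway_edges(g, tsv)
  back <- read.delim(tsv)
  expect_equal(back$parent, "2345-245")
  write_pathway_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), 2)
  expect_equal(igraph::gsize(ig), 1)
})
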