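test_that("simulation is a pure function of its seed", {
  cfg <- sim_config("tiny", seed = 123)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$truth$eaf, s2$truth$eaf)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  s3 <- simulate_experiment(sim_config("tiny", seed = 124))
  expect_false(identical(s1$table, s3$table))
})

test_that("gradient replicate respects depth and the band-sd limits", {
  cfg <- sim_config("tiny", seed = 1, qpcr_cv = 0)
  set.seed(2)
  centers <- setNames(c(1.70, 1.715, 1.73), c("a", "b", "c"))
  ab <- c(a = 0.5, b = 0.3, c = 0.2)
  g <- simulate_gradient_replicate(centers, ab, cfg)
  # multinomial constraint: every fraction sums to the configured depth
  expect_true(all(colSums(g$counts) == cfg$depth))
  # band_sd -> 0: all of a taxon's mass lands in the single nearest fraction
  cfg0 <- sim_config("tiny", seed = 1, band_sd = 0, qpcr_cv = 0)
  g0 <- simulate_gradient_replicate(centers, ab, cfg0)
  for (i in 1:3) {
    nz <- which(g0$counts[i, ] > 0)
    expect_identical(nz, which.min(abs(cfg0$densities - centers[i])))
  }
})

test_that("measured WADs converge to the analytic discretized-band mean", {
  # depth 1e5, no qPCR noise: recomputed WAD within 1e-3 of the analytic
  # discretized-Gaussian mean
  cfg <- sim_config("tiny", n_taxa = 4L, depth = 100000L, qpcr_cv = 0,
                    n_contaminants = 0L, seed = 31)
  sim <- simulate_experiment(cfg)
  w <- wad_matrix(sim$table, sim$metadata)
  tubes <- attr(w, "tubes")
  ctl <- tubes$tube[tubes$label == "control"]
  for (tb in ctl) {
    expect_equal(unname(w[, tb]),
                 unname(sim$truth$expected_wad_light),
                 tolerance = 1e-3)
  }
  lab <- tubes$tube[tubes$label == "13C" & tubes$treatment == "bicarbonate-H2"]
  for (tb in lab) {
    expect_equal(unname(w[, tb]),
                 unname(sim$truth$expected_wad_labeled[, "bicarbonate-H2"]),
                 tolerance = 1e-3)
  }
})

test_that("the noise-free analytic path round-trips true EAF to 1e-6", {
  # on a fine gradient grid the discretized band mean is numerically exact,
  # so chaining expected WADs through the estimator recovers the truth
  cfg <- sim_config("tiny", n_taxa = 30L,
                    densities = seq(1.600, 1.820, length.out = 221L),
                    seed = 77)
  set.seed(77)
  gc <- runif(30, 0.3, 0.7)
  a_true <- runif(30, 0, 0.6)
  w_light <- expected_wads(expected_band_center(gc, 0),
                           cfg$densities, cfg$band_sd)
  w_lab <- expected_wads(expected_band_center(gc, a_true),
                         cfg$densities, cfg$band_sd)
  a_hat <- eaf_point(w_light, w_lab)
  expect_lt(max(abs(a_hat - a_true)), 1e-6)
})

test_that("simulated peak shifts sit in the reported order of magnitude", {
  set.seed(5)
  gc <- runif(200, 0.3, 0.7)
  a <- runif(200, 0.05, 0.4)
  shift <- expected_band_center(gc, a) - expected_band_center(gc, 0)
  expect_true(all(shift >= 0.001 & shift <= 0.06))
})

test_that("contaminant taxa are seeded so the 10x rule removes them", {
  sim <- simulate_experiment(sim_config("tiny", seed = 6))
  out <- filter_contaminants(sim$table, sim$contaminants)
  expect_true(all(startsWith(out$report$removed_otus, "contam_")))
  expect_false(any(startsWith(rownames(out$table), "contam_")))
  # no contaminants configured -> empty profile, nothing removed
  sim0 <- simulate_experiment(sim_config("tiny", n_contaminants = 0L,
                                         seed = 6))
  expect_identical(length(sim0$contaminants), 0L)
  out0 <- filter_contaminants(sim0$table, sim0$contaminants)
  expect_identical(out0$report$removed_otus, character(0))
})

test_that("top-k fraction selection keeps the strongest qPCR signals", {
  sim <- simulate_experiment(sim_config("tiny", top_k_fractions = 10L,
                                        seed = 9))
  per_tube <- table(sim$metadata$tube)
  expect_true(all(per_tube == 10))
  # analysis still runs on the reduced fraction set
  fit <- qsip(sim$table, sim$metadata, n_boot = 50, seed = 9)
  expect_gt(sum(fit$results$evaluable), 0)
})

test_that("written simulation files read back through the package readers", {
  sim <- simulate_experiment(sim_config("tiny", seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  tab <- read_otu_table(paths[["otu_table"]])
  expect_identical(tab, sim$table)
  md <- read_fraction_metadata(paths[["metadata"]])
  expect_identical(md$sample_id, sim$metadata$sample_id)
  expect_equal(md$density_g_ml, sim$metadata$density_g_ml)
  contam <- read_contaminant_profile(paths[["contaminants"]])
  expect_equal(contam, setNames(as.numeric(sim$contaminants),
                                names(sim$contaminants)))
  tree <- ape::read.tree(paths[["tree"]])
  expect_setequal(tree$tip.label, sim$tree$tip.label)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_identical(length(truth$otu_id), nrow(sim$table))
})
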