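test_that("labeled percentages reproduce the treatment-table arithmetic", {
  expect_equal(fraction_labeled(81, 58), 58.3)
  expect_equal(fraction_labeled(26, 61), 29.9)
  expect_equal(fraction_labeled(73, 79), 48.0)
  expect_equal(fraction_labeled(81, 17), 82.7)
  expect_equal(fraction_labeled(59, 6), 90.8)
  expect_equal(fraction_labeled(37, 129), 22.3)
  expect_equal(fraction_labeled(107, 203), 34.5)
  expect_equal(fraction_labeled(0, 10), 0.0)
  expect_error(fraction_labeled(0, 0), "no labeled")
})

test_that("percent change matches the reported H2 effect arithmetic", {
  expect_equal(round(percent_change(0.13, 0.32)), 146)
  expect_equal(percent_change(0.2, 0.2), 0)
  expect_equal(round(percent_change(0.32, 0.14)), -56)
  expect_error(percent_change(0, 0.3), "zero")
})

test_that("h2_effect compares substrate arms with bootstrap uncertainty", {
  sim <- simulate_experiment(sim_config("tiny", seed = 8))
  fit <- qsip(sim$table, sim$metadata, n_boot = 100, seed = 8)
  e <- h2_effect(fit, "bicarbonate", n_boot = 200, seed = 1)
  r <- fit$results[fit$results$evaluable, ]
  expect_equal(e$mean_eaf_noH2,
               mean(r$eaf[r$treatment == "bicarbonate-H2"]))
  expect_equal(e$mean_eaf_H2,
               mean(r$eaf[r$treatment == "bicarbonate+H2"]))
  expect_equal(e$percent_change,
               percent_change(e$mean_eaf_noH2, e$mean_eaf_H2))
  expect_gt(e$uncertainty, 0)
  expect_error(h2_effect(fit, "formate"), "formate")
})

test_that("group EAF table aggregates lineages at the requested rank", {
  sim <- simulate_experiment(sim_config("tiny", seed = 3))
  fit <- qsip(sim$table, sim$metadata, n_boot = 50, seed = 3)
  otus <- rownames(sim$table)
  tax <- setNames(
    ifelse(seq_along(otus) %% 2 == 0,
           "Bacteria; Proteobacteria; Gamma",
           "Bacteria; Nitrospirae; Nitrospira"),
    otus)
  tax[1] <- ""  # unclassified -> "unassigned"
  g <- group_eaf_table(fit, tax, rank = 2)
  expect_setequal(unique(g$group),
                  c("Proteobacteria", "Nitrospirae", "unassigned"))
  # group means equal hand-computed means of member OTUs
  r <- fit$results[fit$results$evaluable, ]
  for (i in seq_len(nrow(g))) {
    members <- names(tax)[vapply(strsplit(tax, ";"), function(p) {
      length(p) >= 2 && trimws(p[2]) == g$group[i]
    }, TRUE)]
    if (g$group[i] == "unassigned") members <- names(tax)[tax == ""]
    sel <- r$otu_id %in% members & r$treatment == g$treatment[i]
    expect_equal(g$mean_eaf[i], mean(r$eaf[sel]))
    expect_equal(g$any_labeled[i], any(r$labeled[sel]))
  }
  # one group, one OTU -> its own EAF; {0.2, 0.4} -> 0.3 by the same path
  expect_error(group_eaf_table(fit, tax, rank = -1), "unknown")
})

test_that("Chao1 follows the singleton/doubleton formula with its branches", {
  # no singletons: estimate equals observed richness
  expect_equal(chao1(c(3, 5, 2, 2)), 4)
  # S_obs = 10, f1 = 2, f2 = 1 -> 10 + 4/2 = 12
  x <- c(1, 1, 2, rep(3, 7))
  expect_equal(chao1(x), 12)
  # bias-corrected branch: S_obs = 5, f1 = 3, f2 = 0 -> 5 + 3*2/2 = 8
  expect_equal(chao1(c(1, 1, 1, 4, 5)), 8)
  expect_error(chao1(c(0, 0)), "all-zero")
  # Chao1 >= S_obs on random samples
  set.seed(4)
  for (i in 1:30) {
    y <- rpois(50, 2)
    if (sum(y) == 0) next
    expect_gte(chao1(y), sum(y > 0))
  }
})

test_that("richness comparison is a Welch t-test on per-sample Chao1", {
  a <- matrix(c(5L, 5L, 3L, 0L,
                2L, 1L, 1L, 1L,
                4L, 0L, 2L, 0L), ncol = 3)
  rownames(a) <- paste0("o", 1:4)
  ht <- compare_richness(a, a)
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 1)
  # clearly shifted groups separate decisively
  set.seed(12)
  rich <- replicate(10, tabulate(sample(500, 600, TRUE), nbins = 600))
  poor <- replicate(10, tabulate(sample(50, 600, TRUE), nbins = 600))
  ht2 <- compare_richness(rich, poor)
  expect_lt(ht2$p.value, 0.001)
  expect_error(compare_richness(a[, 1, drop = FALSE], a), "2 samples")
})

test_that("ANOSIM matches a brute-force oracle on a 6-sample toy matrix", {
  set.seed(21)
  pts <- rbind(matrix(rnorm(9, 0), 3), matrix(rnorm(9, 3), 3))
  d <- as.matrix(dist(pts))
  grp <- rep(c("A", "B"), each = 3)
  res <- anosim_groups(d, grp, n_perm = 999, seed = 1)
  expect_equal(res$R, anosim_R_oracle(d, grp), tolerance = 1e-12)
  # exact null over all 720 label permutations
  null_R <- anosim_null_oracle(d, grp)
  p_exact <- mean(null_R >= res$R - 1e-12)
  expect_lt(abs(res$p - p_exact), 0.05)
  expect_true(res$R >= -1 && res$R <= 1)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("ANOSIM hits R = 1 under maximal separation and ~0 under the null", {
  # all between-distances exceed all within-distances -> R = 1
  pts <- rbind(matrix(runif(8, 0, 0.1), 4), matrix(runif(8, 10, 10.1), 4))
  d <- as.matrix(dist(pts))
  grp <- rep(c("A", "B"), each = 4)
  expect_equal(anosim_groups(d, grp, n_perm = 99, seed = 1)$R, 1)
  # labels permuted independently of distances -> E[R] ~ 0
  set.seed(31)
  r_null <- replicate(30, {
    pts <- matrix(rnorm(24), 8)
    anosim_groups(as.matrix(dist(pts)), sample(grp), n_perm = 19)$R
  })
  expect_lt(abs(mean(r_null)), 0.15)
  expect_error(anosim_groups(d, rep("A", 8)), "2 groups")
})
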