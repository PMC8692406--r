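test_that("tree VCV matches hand-computed shared path lengths", {
  # star tree: C = t * I
  star <- ape::read.tree(text = "(a:2,b:2,c:2,d:2):0;")
  expect_equal(unname(tree_vcv(star)), diag(2, 4))
  # 2-tip tree, branches (a, b): diagonal (a, b), zero covariance
  two <- ape::read.tree(text = "(a:1.5,b:0.5);")
  expect_equal(unname(tree_vcv(two)), matrix(c(1.5, 0, 0, 0.5), 2))
  # 4-tip balanced tree: ((a:1,b:1):2,(c:1,d:1):2);
  bal <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  C <- tree_vcv(bal)[c("a", "b", "c", "d"), c("a", "b", "c", "d")]
  expect_equal(unname(C),
               matrix(c(3, 2, 0, 0,
                        2, 3, 0, 0,
                        0, 0, 3, 2,
                        0, 0, 2, 3), 4, byrow = TRUE))
  # error contracts
  noBL <- ape::read.tree(text = "((a,b),(c,d));")
  expect_error(tree_vcv(noBL), "branch lengths")
  unrooted <- ape::unroot(ape::rtree(5))
  expect_error(tree_vcv(unrooted), "rooted")
})

test_that("Blomberg's K is affine-invariant and near 1 under BM", {
  set.seed(101)
  tree <- ape::rphylo(40, 1, 0)
  x <- ape::rTraitCont(tree, model = "BM")
  k1 <- blomberg_k(tree, x, n_perm = 0)
  k2 <- blomberg_k(tree, 3.7 * x + 11, n_perm = 0)
  expect_equal(k1$estimate, k2$estimate, tolerance = 1e-10)
  # BM traits: mean K over replicates close to 1 (quick version)
  ks <- replicate(60, {
    y <- ape::rTraitCont(tree, model = "BM")
    blomberg_k(tree, y, n_perm = 0)$estimate
  })
  expect_gt(mean(ks), 0.8)
  expect_lt(mean(ks), 1.25)
  # tree-independent traits: small K, permutation test rarely rejects
  z <- setNames(rnorm(40), tree$tip.label)
  kz <- blomberg_k(tree, z, n_perm = 199, seed = 1)
  expect_lt(kz$estimate, 1)
  expect_gt(kz$p_value, 0.01)
})

test_that("K agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(7)
  tree <- ape::rphylo(30, 1, 0)
  x <- ape::rTraitCont(tree, model = "BM")
  ours <- blomberg_k(tree, x, n_perm = 0)$estimate
  theirs <- unname(phytools::phylosig(tree, x, method = "K"))
  expect_equal(ours, as.numeric(theirs), tolerance = 1e-6)
})

test_that("K precondition failures are reported", {
  tree <- ape::rphylo(8, 1, 0)
  x <- setNames(rnorm(3), tree$tip.label[1:3])
  expect_error(blomberg_k(tree, x), "at least 4")
  const <- setNames(rep(1, 8), tree$tip.label)
  expect_error(blomberg_k(tree, const), "constant")
})

test_that("Pagel's lambda recovers BM and flags independence", {
  set.seed(55)
  tree <- ape::rphylo(60, 1, 0)
  x <- ape::rTraitCont(tree, model = "BM")
  fit <- pagels_lambda(tree, x)
  expect_gt(fit$estimate, 0.8)
  expect_lt(fit$p_value, 0.05)
  # optimality: likelihood at the optimum beats lambda = 0 and 1
  ll <- function(l) isosip:::lambda_loglik(l, tree_vcv(tree), x)
  expect_gte(fit$logL[["logL_hat"]], ll(0) - 1e-8)
  expect_gte(fit$logL[["logL_hat"]], ll(1) - 1e-8)
  # tree-independent trait: lambda near 0, LRT usually not significant
  set.seed(56)
  res <- replicate(20, {
    z <- setNames(rnorm(60), tree$tip.label)
    f <- pagels_lambda(tree, z)
    c(f$estimate, f$p_value)
  })
  expect_lt(median(res[1, ]), 0.2)
  expect_gt(mean(res[2, ] > 0.05), 0.6)
})

test_that("lambda at 0 reduces to independent heteroscedastic normals", {
  set.seed(9)
  tree <- ape::rphylo(12, 1, 0.2)
  x <- setNames(rnorm(12), tree$tip.label)
  C <- tree_vcv(tree)
  ll0 <- isosip:::lambda_loglik(0, C, x)
  # independent normals with variances s2 * C[i,i], GLS mean, profiled s2
  v <- diag(C)
  mu <- sum(x / v) / sum(1 / v)
  s2 <- mean((x - mu)^2 / v)
  ll_ind <- sum(dnorm(x, mu, sqrt(s2 * v), log = TRUE))
  expect_equal(ll0, ll_ind, tolerance = 1e-8)
})

test_that("lambda optimizer agrees with a fine grid search", {
  skip_if_not_installed("phytools")
  set.seed(77)
  for (i in 1:4) {
    tree <- ape::rphylo(40, 1, 0)
    C <- tree_vcv(tree)
    lam_true <- runif(1, 0.2, 0.9)
    V <- C * lam_true
    diag(V) <- diag(C)
    x <- setNames(as.numeric(t(chol(V)) %*% rnorm(40)), tree$tip.label)
    fit <- pagels_lambda(tree, x)
    grid <- seq(0, fit$lambda_max, by = 1e-3)
    ll <- vapply(grid, isosip:::lambda_loglik, numeric(1), C = C, y = x)
    expect_lt(abs(fit$estimate - grid[which.max(ll)]), 2e-3)
    # and with an independent ML implementation
    ph <- phytools::phylosig(tree, x, method = "lambda")
    expect_equal(fit$estimate, ph$lambda, tolerance = 5e-3)
  }
})

test_that("lambda is flagged non-identifiable on a star tree", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1):0;")
  x <- setNames(rnorm(5), star$tip.label)
  expect_warning(fit <- pagels_lambda(star, x), "not identifiable")
  expect_false(fit$identifiable)
  expect_true(is.na(fit$estimate))
})

test_that("phylo_signal tests each treatment on the pruned EAF trait", {
  sim <- simulate_experiment(sim_config(
    "tiny", n_taxa = 16L,
    eaf_rule = list(mode = "tree", lambda = 1, mean = 0.12, sd = 0.25,
                    max = 0.9),
    seed = 14))
  fit <- qsip(sim$table, sim$metadata, n_boot = 50, seed = 14)
  sig <- phylo_signal(fit, sim$tree, trait = "eaf", n_perm = 99, seed = 3)
  expect_setequal(unique(sig$statistic), c("K", "lambda"))
  expect_identical(nrow(sig), 2L * length(fit$treatments))
  expect_true(all(sig$n_tips <= 16))
  bin <- phylo_signal(fit, sim$tree, trait = "binary", n_perm = 49, seed = 3)
  expect_identical(nrow(bin), nrow(sig))
})
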