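#' Brownian-motion covariance matrix of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `C[i, i]` the root-to-tip depth. Requires a rooted tree with branch
#' lengths and positive depth.
#'
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @return The tip variance-covariance matrix.
#' @export
tree_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  C <- ape::vcv.phylo(tree)
  if (max(diag(C)) <= 0) stop("tree has zero depth", call. = FALSE)
  C
}

# Align a named trait vector with the tree, prune unmatched tips, guard
# against zero-length terminal branches (singular C).
prep_signal <- function(tree, trait, min_tips = 4L) {
  trait <- trait[!is.na(trait)]
  if (is.null(names(trait))) stop("trait must be named by tip label", call. = FALSE)
  tips <- intersect(tree$tip.label, names(trait))
  if (length(tips) < min_tips) {
    stop("need at least ", min_tips, " matched tips (got ", length(tips), ")",
         call. = FALSE)
  }
  tree <- ape::keep.tip(tree, tips)
  trait <- trait[tree$tip.label]
  if (!all(is.finite(trait))) stop("non-finite trait values", call. = FALSE)
  if (sd(trait) == 0) stop("trait is constant across tips", call. = FALSE)
  term <- tree$edge[, 2L] <= length(tree$tip.label)
  depth <- max(ape::node.depth.edgelength(tree))
  zi <- which(term & tree$edge.length == 0)
  if (length(zi) > 0L) {
    warning("zero-length terminal branches perturbed by 1e-8 of tree depth",
            call. = FALSE)
    tree$edge.length[zi] <- 1e-8 * depth
  }
  list(tree = tree, trait = trait)
}

#' Blomberg's K with a tip-permutation test
#'
#' K compares the observed ratio of the non-phylogenetic mean squared error
#' (deviations of tip values from the phylogenetically corrected, GLS, mean)
#' to the generalized least-squares error under the Brownian covariance C,
#' against the value of that ratio expected under Brownian motion,
#' `(tr(C) - n / sum(C^-1)) / (n - 1)`. K near 1 indicates Brownian-like
#' phylogenetic signal; K near 0, independence from the tree. Significance
#' is assessed by permuting trait values across tips: p is the fraction of
#' permutations (observed included) whose MSE0/MSE ratio is at least the
#' observed one.
#'
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @param trait Named numeric vector (names = tip labels); tips without
#'   trait values are pruned. At least 4 tips, non-constant.
#' @param n_perm Number of permutations (default 999; 0 skips the test).
#' @param seed Optional seed for the permutations.
#' @return A list of class `signal_result`: `statistic = "K"`, `estimate`,
#'   `p_value`, `n_tips`, `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  ready <- prep_signal(tree, trait)
  tree <- ready$tree
  y <- ready$trait
  n <- length(y)
  C <- tree_vcv(tree)
  Ci <- tryCatch(chol2inv(chol(C)),
                 error = function(e) stop("singular phylogenetic covariance",
                                          call. = FALSE))
  one <- rep(1, n)
  denom_gls <- sum(Ci)
  ratio_fun <- function(z) {
    a <- sum(Ci %*% z) / denom_gls
    r <- z - a
    mse0 <- sum(r^2) / (n - 1)
    mse <- as.numeric(crossprod(r, Ci %*% r)) / (n - 1)
    mse0 / mse
  }
  obs <- ratio_fun(y)
  expected <- (sum(diag(C)) - n / denom_gls) / (n - 1)
  k <- obs / expected
  p <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    perm <- replicate(n_perm, ratio_fun(sample(y)))
    p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  structure(list(statistic = "K", estimate = k, p_value = p,
                 n_tips = n, n_perm = n_perm),
            class = "signal_result")
}

# Profile log-likelihood of the lambda model: off-diagonal of C scaled by
# lambda, GLS mean and variance profiled out analytically.
lambda_loglik <- function(lambda, C, y) {
  n <- length(y)
  V <- C * lambda
  diag(V) <- diag(C)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  logdet <- 2 * sum(log(diag(L)))
  Vi_y <- backsolve(L, forwardsolve(t(L), y))
  Vi_1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  q <- as.numeric(crossprod(r, backsolve(L, forwardsolve(t(L), r))))
  s2 <- q / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' The lambda transform multiplies the off-diagonal entries of the Brownian
#' covariance C by lambda, leaving tip variances unchanged; lambda = 1 is
#' Brownian motion, lambda = 0 phylogenetic independence. The mean and rate
#' are profiled analytically and lambda maximised on `[0, lambda_max]`
#' (lambda_max keeps C(lambda) positive-definite; 1 for ultrametric trees).
#' Significance is a likelihood-ratio test of lambda-hat against lambda = 0
#' with a boundary-corrected null (50:50 mixture of chi-square 1 df and a
#' point mass at 0).
#'
#' On a star tree lambda is non-identifiable (there is no off-diagonal
#' covariance to scale); the estimate is returned as `NA` with
#' `identifiable = FALSE`.
#'
#' @inheritParams blomberg_k
#' @param tol Optimizer tolerance on lambda (default 1e-8).
#' @return A list of class `signal_result`: `statistic = "lambda"`,
#'   `estimate`, `p_value`, `n_tips`, `logL` (at the optimum and at 0),
#'   `lambda_max`, `identifiable`.
#' @export
pagels_lambda <- function(tree, trait, tol = 1e-8) {
  ready <- prep_signal(tree, trait)
  tree <- ready$tree
  y <- ready$trait
  n <- length(y)
  C <- tree_vcv(tree)
  off <- C[upper.tri(C)]
  if (max(off) <= 1e-12 * max(diag(C))) {
    warning("star tree: lambda is not identifiable", call. = FALSE)
    return(structure(list(statistic = "lambda", estimate = NA_real_,
                          p_value = NA_real_, n_tips = n,
                          logL = c(NA_real_, NA_real_),
                          lambda_max = NA_real_, identifiable = FALSE),
                     class = "signal_result"))
  }
  lmax <- if (ape::is.ultrametric(tree, tol = 1e-8)) {
    1
  } else {
    max(diag(C)) / max(off)
  }
  while (!is.finite(lambda_loglik(lmax, C, y)) && lmax > tol) {
    lmax <- lmax * 0.999
  }
  opt <- optimize(lambda_loglik, c(0, lmax), C = C, y = y,
                  maximum = TRUE, tol = tol)
  cand_l <- c(opt$maximum, 0, lmax)
  cand_ll <- c(opt$objective, lambda_loglik(0, C, y),
               lambda_loglik(lmax, C, y))
  best <- which.max(cand_ll)
  lambda_hat <- cand_l[best]
  ll_hat <- cand_ll[best]
  ll0 <- cand_ll[2L]
  if (!is.finite(ll_hat)) {
    stop("lambda likelihood search failed (non-finite likelihood); ",
         "n_tips = ", n, ", lambda_max = ", signif(lmax, 4), call. = FALSE)
  }
  lr <- max(0, 2 * (ll_hat - ll0))
  p <- if (lr == 0) 1 else 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  structure(list(statistic = "lambda", estimate = lambda_hat, p_value = p,
                 n_tips = n, logL = c(logL_hat = ll_hat, logL_0 = ll0),
                 lambda_max = lmax, identifiable = TRUE),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  if (isFALSE(x$identifiable)) {
    cat("Phylogenetic signal (lambda): not identifiable (star tree),",
        x$n_tips, "tips\n")
    return(invisible(x))
  }
  cat(sprintf("Phylogenetic signal %s = %.4g (p = %.4g, %d tips)\n",
              x$statistic, x$estimate, x$p_value, x$n_tips))
  invisible(x)
}

#' Phylogenetic signal of 13C assimilation per treatment
#'
#' Runs Blomberg's K and Pagel's lambda on the per-OTU EAF trait (or the
#' binary labeled/unlabeled indicator) of each treatment in a qSIP fit,
#' pruning OTUs not evaluable in that treatment from the tree.
#'
#' @param fit A [qsip()] fit.
#' @param tree A rooted `ape::phylo` whose tip labels are OTU ids.
#' @param trait `"eaf"` (continuous, default) or `"binary"`
#'   (labeled = 1 / unlabeled = 0).
#' @param treatments Treatments to test (default all in the fit).
#' @param n_perm Permutations for the K test (default 999).
#' @param seed Optional seed.
#' @return A data.frame: `treatment`, `statistic`, `estimate`, `p_value`,
#'   `n_tips`.
#' @export
phylo_signal <- function(fit, tree, trait = c("eaf", "binary"),
                         treatments = NULL, n_perm = 999, seed = NULL) {
  stopifnot(inherits(fit, "qsip_fit"))
  trait <- match.arg(trait)
  trts <- treatments %||% fit$treatments
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(trts, function(tr) {
    d <- fit$results[fit$results$treatment == tr & fit$results$evaluable, ,
                     drop = FALSE]
    x <- if (trait == "eaf") d$eaf else as.numeric(d$labeled)
    names(x) <- d$otu_id
    k <- blomberg_k(tree, x, n_perm = n_perm)
    l <- pagels_lambda(tree, x)
    data.frame(treatment = tr,
               statistic = c("K", "lambda"),
               estimate = c(k$estimate, l$estimate),
               p_value = c(k$p_value, l$p_value),
               n_tips = c(k$n_tips, l$n_tips),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
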