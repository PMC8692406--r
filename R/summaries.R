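#' Percentage of OTUs called 13C-labeled
#'
#' @param n_labeled,n_unlabeled Non-negative counts of labeled and unlabeled
#'   OTUs in a treatment.
#' @param digits Decimal places in the reported percentage (default 1, the
#'   convention used in treatment summary tables).
#' @return `100 * n_labeled / (n_labeled + n_unlabeled)`, rounded.
#' @examples
#' fraction_labeled(81, 58)   # 58.3
#' fraction_labeled(37, 129)  # 22.3
#' @export
fraction_labeled <- function(n_labeled, n_unlabeled, digits = 1) {
  stopifnot(n_labeled >= 0, n_unlabeled >= 0)
  if (n_labeled + n_unlabeled == 0) {
    stop("no labeled or unlabeled OTUs to summarise", call. = FALSE)
  }
  round(100 * n_labeled / (n_labeled + n_unlabeled), digits)
}

#' Percent change of mean EAF with H2 amendment
#'
#' @param mean_ref Mean EAF without H2 (baseline; must be nonzero).
#' @param mean_h2 Mean EAF with H2.
#' @return `100 * (mean_h2 - mean_ref) / mean_ref`, full precision (reports
#'   round to whole percent).
#' @examples
#' round(percent_change(0.13, 0.32))  # 146
#' @export
percent_change <- function(mean_ref, mean_h2) {
  stopifnot(is.finite(mean_ref), is.finite(mean_h2))
  if (mean_ref == 0) stop("baseline mean EAF is zero", call. = FALSE)
  100 * (mean_h2 - mean_ref) / mean_ref
}

#' Effect of H2 on mean 13C assimilation for one substrate
#'
#' Compares mean EAF over evaluated OTUs between the -H2 and +H2 arms of a
#' substrate and reports the percent change, with a bootstrap-over-OTUs
#' uncertainty (SD of the percent change across resamples).
#'
#' @param fit A [qsip()] fit covering both arms of `substrate`.
#' @param substrate Substrate name, e.g. `"bicarbonate"`.
#' @param labeled_only Restrict means to labeled OTUs (default `FALSE`: all
#'   evaluated OTUs).
#' @param n_boot Bootstrap resamples for the uncertainty (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return A list: `substrate`, `mean_eaf_noH2`, `mean_eaf_H2`,
#'   `percent_change`, `uncertainty` (bootstrap SD, in percent), `n_noH2`,
#'   `n_H2`.
#' @export
h2_effect <- function(fit, substrate, labeled_only = FALSE, n_boot = 1000,
                      seed = NULL) {
  stopifnot(inherits(fit, "qsip_fit"))
  if (!is.null(seed)) set.seed(seed)
  pick <- function(arm) {
    d <- fit$results[fit$results$treatment == arm & fit$results$evaluable, ,
                     drop = FALSE]
    if (labeled_only) d <- d[d$labeled, , drop = FALSE]
    d$eaf
  }
  a <- pick(paste0(substrate, "-H2"))
  b <- pick(paste0(substrate, "+H2"))
  if (length(a) == 0L || length(b) == 0L) {
    stop("substrate '", substrate, "' lacks evaluated OTUs in one arm",
         call. = FALSE)
  }
  pc <- percent_change(mean(a), mean(b))
  boot <- replicate(n_boot, {
    ma <- mean(sample(a, replace = TRUE))
    mb <- mean(sample(b, replace = TRUE))
    if (ma == 0) NA_real_ else 100 * (mb - ma) / ma
  })
  list(substrate = substrate,
       mean_eaf_noH2 = mean(a), mean_eaf_H2 = mean(b),
       percent_change = pc,
       uncertainty = sd(boot, na.rm = TRUE),
       n_noH2 = length(a), n_H2 = length(b))
}

#' Mean EAF per taxonomic group and treatment
#'
#' Aggregates evaluated per-OTU EAF estimates to a chosen taxonomic rank:
#' per (group, treatment), the mean EAF and whether any member OTU was
#' called labeled. OTUs without a classification at the rank are grouped as
#' `"unassigned"`.
#'
#' @param fit A [qsip()] fit.
#' @param taxonomy Named character vector of semicolon-separated lineage
#'   strings (names are OTU ids), or a data.frame of rank columns with OTU
#'   ids as row names.
#' @param rank Rank to aggregate at: a 1-based lineage level (for lineage
#'   strings) or a column name (for a data.frame).
#' @return A long-format data.frame: `group`, `treatment`, `n_otus`,
#'   `mean_eaf`, `any_labeled` — suitable for heatmap-style plotting.
#' @export
group_eaf_table <- function(fit, taxonomy, rank = 2) {
  stopifnot(inherits(fit, "qsip_fit"))
  r <- fit$results[fit$results$evaluable, , drop = FALSE]
  if (is.data.frame(taxonomy)) {
    if (!is.character(rank) || !rank %in% names(taxonomy)) {
      stop("unknown taxonomic rank: ", rank, call. = FALSE)
    }
    grp <- setNames(as.character(taxonomy[[rank]]), rownames(taxonomy))
  } else {
    if (!is.numeric(rank) || rank < 1) {
      stop("unknown taxonomic rank: ", rank, call. = FALSE)
    }
    grp <- vapply(strsplit(as.character(taxonomy), ";"), function(p) {
      if (length(p) >= rank) trimws(p[[rank]]) else NA_character_
    }, character(1))
    names(grp) <- names(taxonomy)
  }
  g <- grp[r$otu_id]
  g[is.na(g) | g == ""] <- "unassigned"
  out <- do.call(rbind, lapply(
    split(r, list(g, r$treatment), drop = TRUE, sep = "\r"),
    function(d) {
      data.frame(treatment = d$treatment[1L], n_otus = nrow(d),
                 mean_eaf = mean(d$eaf), any_labeled = any(d$labeled),
                 stringsAsFactors = FALSE)
    }))
  out$group <- sub("\r.*$", "", rownames(out))
  rownames(out) <- NULL
  out[, c("group", "treatment", "n_otus", "mean_eaf", "any_labeled")]
}

#' Chao1 richness estimator
#'
#' Classic nonparametric richness estimate from singleton and doubleton
#' counts: `S_obs + f1^2 / (2 f2)` when doubletons are present, and the
#' bias-corrected form `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` when `f2 = 0`.
#'
#' @param counts Non-negative integer count vector for one sample.
#' @return The Chao1 estimate (always `>= S_obs`).
#' @examples
#' chao1(c(5, 5, 3, 3, 1, 1, 2, 2, 2, 2))
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0), all(abs(counts - round(counts)) < 1e-8))
  if (sum(counts) == 0) stop("all-zero sample", call. = FALSE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' Compare Chao1 richness between two sample groups
#'
#' Welch two-sample t-test (two-sided) on per-sample Chao1 estimates.
#'
#' @param counts_a,counts_b Count matrices (OTUs x samples) or lists of
#'   count vectors, one per sample; at least 2 samples per group.
#' @return The `htest` object from [stats::t.test()] with the per-sample
#'   Chao1 values attached as attribute `"chao1"`.
#' @export
compare_richness <- function(counts_a, counts_b) {
  per_sample <- function(x) {
    if (is.matrix(x)) x <- lapply(seq_len(ncol(x)), function(j) x[, j])
    vapply(x, chao1, numeric(1))
  }
  a <- per_sample(counts_a)
  b <- per_sample(counts_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = FALSE)
  attr(ht, "chao1") <- list(a = a, b = b)
  ht
}

#' ANOSIM community comparison
#'
#' Analysis of similarities on a dissimilarity matrix:
#' `R = (mean between-group rank - mean within-group rank) / (n (n - 1) / 4)`
#' with a permutation p value. Computed with [vegan::anosim()]; community
#' matrices are first converted to Bray-Curtis dissimilarities of relative
#' abundances.
#'
#' @param x A `dist`, a symmetric dissimilarity matrix, or a community
#'   count matrix (samples x taxa).
#' @param grouping Group labels, one per sample; at least 2 groups with at
#'   least 2 members.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional seed for the permutations.
#' @param distance Dissimilarity index for community matrices
#'   (default `"bray"`).
#' @return A list: `R`, `p`, `n_perm`, and the underlying `vegan::anosim`
#'   object as `fit`.
#' @export
anosim_groups <- function(x, grouping, n_perm = 999, seed = NULL,
                          distance = "bray") {
  grouping <- as.factor(grouping)
  tab <- table(grouping)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  if (inherits(x, "dist")) {
    d <- x
  } else if (is.matrix(x) && isSymmetric(unname(x)) &&
             all(abs(diag(x)) < 1e-12)) {
    d <- stats::as.dist(x)
  } else {
    rel <- sweep(x, 1L, rowSums(x), `/`)
    d <- vegan::vegdist(rel, method = distance)
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(d, grouping, permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif, n_perm = n_perm, fit = fit)
}
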