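#' Bootstrap excess atom fraction 13C for one OTU
#'
#' Point estimate and percentile bootstrap confidence interval for a single
#' taxon in one treatment. The point estimate is
#' `eaf_point(mean(control_wads), mean(labeled_wads))`. Bootstrap replicates
#' resample the labeled and control replicate WADs independently with
#' replacement and recompute the EAF; the CI is the two-sided percentile
#' interval at `conf_level`. The taxon is called 13C-labeled when the lower
#' CI bound exceeds the 0% EAF cutoff.
#'
#' Uses the current RNG state; seed upstream (e.g. in [qsip()]) for
#' reproducibility.
#'
#' @param labeled_wads Replicate WADs (g/ml) from the 13C incubations.
#' @param control_wads Replicate WADs (g/ml) from the unlabeled controls.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param conf_level Two-sided confidence level (default 0.90).
#' @param params Model constants, see [isotope_params()].
#' @return A list: `eaf`, `ci_low`, `ci_high`, `labeled`, `w_light`, `gc`,
#'   `n_labeled_reps`, `n_control_reps`.
#' @export
bootstrap_eaf <- function(labeled_wads, control_wads, n_boot = 1000,
                          conf_level = 0.90, params = isotope_params()) {
  labeled_wads <- labeled_wads[!is.na(labeled_wads)]
  control_wads <- control_wads[!is.na(control_wads)]
  nl <- length(labeled_wads)
  nc <- length(control_wads)
  if (nl < 1L || nc < 1L) {
    stop("need at least one labeled and one control replicate WAD",
         call. = FALSE)
  }
  w_light <- mean(control_wads)
  gc <- suppressWarnings(gc_from_density(w_light, params))
  a_hat <- eaf_point(w_light, mean(labeled_wads), params)
  wl_star <- .colMeans(labeled_wads[sample.int(nl, nl * n_boot, replace = TRUE)],
                       nl, n_boot)
  wc_star <- .colMeans(control_wads[sample.int(nc, nc * n_boot, replace = TRUE)],
                       nc, n_boot)
  a_star <- eaf_point(wc_star, wl_star, params)
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(a_star, c(alpha, 1 - alpha), names = FALSE))
  list(eaf = a_hat, ci_low = ci[1L], ci_high = ci[2L],
       labeled = ci[1L] > 0, w_light = w_light, gc = as.numeric(gc),
       n_labeled_reps = nl, n_control_reps = nc)
}

#' Fit a qSIP model: per-OTU excess atom fraction 13C with bootstrap CIs
#'
#' The central estimator of the package. For every treatment (substrate x H2
#' arm) with paired 13C-labeled and unlabeled-control gradients, each OTU's
#' copy-weighted average buoyant density (WAD) is computed per replicate
#' gradient, the control replicates give the light density baseline
#' `W_light`, and the density shift of the labeled replicates is converted
#' to an excess atom fraction 13C via the GC/molecular-weight isotope model
#' (see [eaf_point()]). Uncertainty comes from bootstrap resampling of
#' replicate WADs ([bootstrap_eaf()]); an OTU is called a 13C-assimilator
#' when the lower bound of its percentile CI is above 0% EAF.
#'
#' OTUs absent from a treatment's controls are reported as not evaluable
#' (`evaluable = FALSE`, EAF `NA`) — distinct from unlabeled.
#'
#' @param counts Filtered OTU count matrix (OTUs x fraction samples); see
#'   [filter_contaminants()] and [filter_low_abundance()].
#' @param metadata Fraction metadata, see [validate_metadata()].
#' @param n_boot Bootstrap replicates per OTU (default 1000).
#' @param conf_level Two-sided CI level (default 0.90).
#' @param seed Optional integer seed; makes the fit reproducible.
#' @param params Model constants, see [isotope_params()].
#' @param keep Optional logical matrix (OTUs x treatments) from
#'   [filter_low_abundance()] restricting which OTUs are evaluated per
#'   treatment.
#' @param treatments Optional character vector restricting the treatments
#'   analysed.
#' @return An object of class `qsip_fit`: a list with `results` (one row per
#'   OTU per treatment: `otu_id`, `treatment`, `eaf`, `ci_low`, `ci_high`,
#'   `labeled`, `evaluable`, `w_light`, `w_labeled`, `delta_wad`, `gc`,
#'   `n_labeled_reps`, `n_control_reps`), the settings, and the call.
#'   Methods: [print.qsip_fit()], [summary.qsip_fit()], [coef.qsip_fit()],
#'   [confint.qsip_fit()], [plot.qsip_fit()].
#' @examples
#' sim <- simulate_experiment(sim_config("tiny", seed = 1))
#' fit <- qsip(sim$table, sim$metadata, n_boot = 200, seed = 1)
#' summary(fit)
#' @export
qsip <- function(counts, metadata, n_boot = 1000, conf_level = 0.90,
                 seed = NULL, params = isotope_params(), keep = NULL,
                 treatments = NULL) {
  stopifnot(n_boot >= 1, conf_level > 0, conf_level < 1)
  counts <- validate_otu_table(counts)
  metadata <- validate_metadata(metadata)
  check_samples_resolve(counts, metadata)
  if (!is.null(seed)) set.seed(seed)
  w <- wad_matrix(counts, metadata)
  tubes <- attr(w, "tubes")
  trts <- treatments %||% unique(tubes$treatment)
  rows <- vector("list", length(trts))
  otus <- rownames(counts)
  for (ti in seq_along(trts)) {
    tr <- trts[ti]
    lab_cols <- tubes$tube[tubes$treatment == tr & tubes$label == "13C"]
    ctl_cols <- tubes$tube[tubes$treatment == tr & tubes$label == "control"]
    if (length(ctl_cols) == 0L) {
      stop("treatment '", tr, "' has no unlabeled-control samples",
           call. = FALSE)
    }
    if (length(lab_cols) == 0L) {
      stop("treatment '", tr, "' has no 13C-labeled samples", call. = FALSE)
    }
    use <- if (is.null(keep)) {
      rep(TRUE, length(otus))
    } else {
      as.logical(keep[otus, tr])
    }
    n_o <- length(otus)
    res <- data.frame(
      otu_id = otus, treatment = rep(tr, n_o), eaf = rep(NA_real_, n_o),
      ci_low = rep(NA_real_, n_o), ci_high = rep(NA_real_, n_o),
      labeled = rep(NA, n_o), evaluable = rep(FALSE, n_o),
      w_light = rep(NA_real_, n_o), w_labeled = rep(NA_real_, n_o),
      delta_wad = rep(NA_real_, n_o), gc = rep(NA_real_, n_o),
      n_labeled_reps = rep(0L, n_o), n_control_reps = rep(0L, n_o),
      stringsAsFactors = FALSE
    )
    for (i in seq_along(otus)) {
      if (!use[i]) next
      wl <- w[i, lab_cols]
      wc <- w[i, ctl_cols]
      wl <- wl[!is.na(wl)]
      wc <- wc[!is.na(wc)]
      if (length(wc) == 0L || length(wl) == 0L) next
      b <- bootstrap_eaf(wl, wc, n_boot = n_boot, conf_level = conf_level,
                         params = params)
      res$eaf[i] <- b$eaf
      res$ci_low[i] <- b$ci_low
      res$ci_high[i] <- b$ci_high
      res$labeled[i] <- b$labeled
      res$evaluable[i] <- TRUE
      res$w_light[i] <- b$w_light
      res$w_labeled[i] <- mean(wl)
      res$delta_wad[i] <- mean(wl) - b$w_light
      res$gc[i] <- b$gc
      res$n_labeled_reps[i] <- b$n_labeled_reps
      res$n_control_reps[i] <- b$n_control_reps
    }
    rows[[ti]] <- res
  }
  out <- list(
    results = do.call(rbind, rows),
    treatments = trts,
    n_boot = n_boot,
    conf_level = conf_level,
    seed = seed,
    params = params,
    wads = w,
    call = match.call()
  )
  class(out) <- "qsip_fit"
  out
}

#' @export
print.qsip_fit <- function(x, ...) {
  r <- x$results
  cat("qSIP fit: per-OTU excess atom fraction 13C\n")
  cat(sprintf("  %d OTUs x %d treatments; %d bootstrap replicates; %g%% CI\n",
              length(unique(r$otu_id)), length(x$treatments),
              x$n_boot, 100 * x$conf_level))
  ev <- r[r$evaluable, , drop = FALSE]
  cat(sprintf("  %d evaluable OTU-treatment pairs, %d called 13C-labeled\n",
              nrow(ev), sum(ev$labeled)))
  invisible(x)
}

#' Treatment-level summary of a qSIP fit
#'
#' Per treatment: numbers of labeled, unlabeled and not-evaluable OTUs, the
#' percentage labeled (of evaluated OTUs, to one decimal in printed output),
#' and the mean and SD of EAF over evaluated OTUs.
#'
#' @param object A [qsip()] fit.
#' @param labeled_only If `TRUE`, `mean_eaf`/`sd_eaf` are computed over
#'   labeled OTUs only (sensitivity analysis); default all evaluated OTUs.
#' @param ... Unused.
#' @return A data.frame of class `summary.qsip_fit`.
#' @export
summary.qsip_fit <- function(object, labeled_only = FALSE, ...) {
  r <- object$results
  out <- do.call(rbind, lapply(split(r, r$treatment), function(d) {
    ev <- d[d$evaluable, , drop = FALSE]
    n_lab <- sum(ev$labeled)
    n_unlab <- sum(!ev$labeled)
    sub <- if (labeled_only) ev[ev$labeled, , drop = FALSE] else ev
    data.frame(
      treatment = d$treatment[1L],
      n_evaluable = nrow(ev),
      n_labeled = n_lab,
      n_unlabeled = n_unlab,
      percent_labeled = if (nrow(ev) > 0) fraction_labeled(n_lab, n_unlab)
                        else NA_real_,
      mean_eaf = if (nrow(sub) > 0) mean(sub$eaf) else NA_real_,
      sd_eaf = if (nrow(sub) > 1) sd(sub$eaf) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("summary.qsip_fit", "data.frame")
  out
}

#' @export
print.summary.qsip_fit <- function(x, ...) {
  cat("qSIP treatment summary (percent labeled of evaluated OTUs):\n")
  y <- as.data.frame(x)
  y$percent_labeled <- round(y$percent_labeled, 1)
  y$mean_eaf <- signif(y$mean_eaf, 3)
  y$sd_eaf <- signif(y$sd_eaf, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Extract EAF point estimates
#'
#' @param object A [qsip()] fit.
#' @param ... Unused.
#' @return A numeric matrix (OTUs x treatments) of EAF estimates; `NA` for
#'   not-evaluable pairs.
#' @export
coef.qsip_fit <- function(object, ...) {
  r <- object$results
  otus <- unique(r$otu_id)
  m <- matrix(NA_real_, length(otus), length(object$treatments),
              dimnames = list(otus, object$treatments))
  m[cbind(match(r$otu_id, otus), match(r$treatment, object$treatments))] <-
    r$eaf
  m
}

#' Bootstrap confidence intervals of a qSIP fit
#'
#' @param object A [qsip()] fit.
#' @param parm Optional OTU ids to subset.
#' @param level Ignored; the level is fixed at fit time (`conf_level`).
#' @param ... Unused.
#' @return A data.frame: `otu_id`, `treatment`, `ci_low`, `ci_high`.
#' @export
confint.qsip_fit <- function(object, parm = NULL, level = NULL, ...) {
  r <- object$results[, c("otu_id", "treatment", "ci_low", "ci_high")]
  if (!is.null(parm)) r <- r[r$otu_id %in% parm, , drop = FALSE]
  r
}

#' Plot per-OTU EAF with confidence intervals
#'
#' One panel per treatment: evaluated OTUs ordered by EAF, point estimates
#' with vertical CI bars, labeled OTUs filled, the 0% EAF cutoff as a
#' horizontal line.
#'
#' @param x A [qsip()] fit.
#' @param treatments Treatments to plot (default all in the fit).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.qsip_fit <- function(x, treatments = NULL, ...) {
  trts <- treatments %||% x$treatments
  old <- graphics::par(mfrow = c(1, length(trts)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (tr in trts) {
    d <- x$results[x$results$treatment == tr & x$results$evaluable, ,
                   drop = FALSE]
    d <- d[order(d$eaf), , drop = FALSE]
    n <- nrow(d)
    if (n == 0L) next
    plot(seq_len(n), d$eaf, ylim = range(c(d$ci_low, d$ci_high, 0)),
         pch = ifelse(d$labeled, 19, 1), xlab = "OTU (ranked)",
         ylab = "excess atom fraction 13C", main = tr, ...)
    graphics::segments(seq_len(n), d$ci_low, seq_len(n), d$ci_high,
                       col = "grey50")
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
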