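#' Configuration of a synthetic qSIP experiment
#'
#' Bundles every knob of the gradient simulator. The `"full"` preset
#' emulates the statistical design of a rock-hosted-community 13C qSIP
#' study: 600 taxa with lognormal abundances, three substrates
#' (bicarbonate, acetate, formate) each with and without H2, 3 labeled plus
#' 3 unlabeled-control replicate gradients per arm, a 20-fraction CsCl
#' gradient spanning 1.640--1.780 g/ml, Gaussian DNA bands of SD 0.006 g/ml,
#' 10,000 reads per fraction, 20% lognormal qPCR noise, and laboratory
#' contaminant taxa. The `"tiny"` preset (8 taxa, one substrate) runs in
#' well under a second and is used throughout the tests.
#'
#' @param preset `"full"` (default) or `"tiny"`.
#' @param ... Named overrides of any configuration field below.
#' @return A list of class `sim_config` with fields: `n_taxa`, `substrates`,
#'   `h2_levels`, `n_replicates`, `abundance_sigma` (lognormal sdlog),
#'   `gc_shape` (Beta parameters), `gc_range`, `densities` (gradient grid,
#'   g/ml, strictly increasing), `band_sd` (g/ml), `depth` (reads per
#'   fraction), `qpcr_cv`, `total_copies` (16S copies per gradient,
#'   arbitrary consistent units), `top_k_fractions` (`NULL` = sequence all
#'   fractions, or keep the k with highest qPCR signal per gradient),
#'   `eaf_rule` (true-labeling assignment: `mode = "iid"` with
#'   `prop_labeled`, `mean`, `sd`, `min`, `max`; or `mode = "tree"` with
#'   `lambda`, `mean`, `sd` for a tree-structured trait), `n_contaminants`,
#'   `contaminant_reads`, `contaminant_leakage` (mean relative abundance of
#'   contaminants in the community), and `seed`.
#' @export
sim_config <- function(preset = c("full", "tiny"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_taxa = 600L,
    substrates = c("bicarbonate", "acetate", "formate"),
    h2_levels = c(FALSE, TRUE),
    n_replicates = 3L,
    abundance_sigma = 1.5,
    gc_shape = c(5, 5),
    gc_range = c(0.3, 0.7),
    densities = seq(1.640, 1.780, length.out = 20L),
    band_sd = 0.006,
    depth = 10000L,
    qpcr_cv = 0.20,
    total_copies = 1e8,
    top_k_fractions = NULL,
    eaf_rule = list(mode = "iid", prop_labeled = 0.35, mean = 0.25,
                    sd = 0.15, min = 0.02, max = 0.9,
                    lambda = 1),
    n_contaminants = 20L,
    contaminant_reads = 500,
    contaminant_leakage = 1e-5,
    seed = 42L
  )
  if (preset == "tiny") {
    cfg$n_taxa <- 8L
    cfg$substrates <- "bicarbonate"
    cfg$n_contaminants <- 2L
    cfg$abundance_sigma <- 0.8
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L) stop("unknown sim_config field: ", bad[1L], call. = FALSE)
  if ("eaf_rule" %in% names(dots)) {
    cfg$eaf_rule[names(dots$eaf_rule)] <- dots$eaf_rule
    dots$eaf_rule <- NULL
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_taxa >= 2L, cfg$n_replicates >= 2L,
            all(diff(cfg$densities) > 0), cfg$band_sd >= 0,
            cfg$depth > 0, cfg$qpcr_cv >= 0)
  structure(cfg, class = "sim_config")
}

#' Analytic discretized-band weighted average density
#'
#' The noise-free WAD of a taxon whose DNA bands as a Gaussian of SD
#' `band_sd` centered at `band_centers`, observed on the discrete fraction
#' grid `densities`: the dnorm weights at the grid points are normalized and
#' averaged against the grid. This is the deterministic limit of the
#' simulator (infinite depth, no qPCR noise) and serves as the oracle for
#' WAD recovery tests.
#'
#' @param band_centers Band-center densities, g/ml (vector).
#' @param densities Fraction grid, g/ml.
#' @param band_sd Band SD, g/ml; 0 collapses each taxon onto its nearest
#'   fraction.
#' @return Vector of WADs, one per band center.
#' @export
expected_wads <- function(band_centers, densities, band_sd) {
  vapply(band_centers, function(ct) {
    w <- band_weights(ct, densities, band_sd)
    sum(densities * w)
  }, numeric(1))
}

# Discretized Gaussian band profile over the fraction grid (sums to 1).
band_weights <- function(center, densities, band_sd) {
  if (band_sd <= 0) {
    w <- numeric(length(densities))
    w[which.min(abs(densities - center))] <- 1
    return(w)
  }
  w <- dnorm(densities, mean = center, sd = band_sd)
  s <- sum(w)
  if (s <= 0) {
    w <- numeric(length(densities))
    w[which.min(abs(densities - center))] <- 1
    return(w)
  }
  w / s
}

#' Simulate one replicate density gradient
#'
#' Distributes each taxon's DNA mass over the fraction grid as a discretized
#' Gaussian band, then generates the two measured quantities per fraction:
#' the total 16S copy number (sum of taxon masses scaled by `total_copies`,
#' under multiplicative lognormal qPCR noise of the configured CV) and the
#' sequencing counts (multinomial draw of `depth` reads from the taxon mass
#' proportions within the fraction).
#'
#' Uses the current RNG state; [simulate_experiment()] seeds it once.
#'
#' @param band_centers Per-taxon band-center densities, g/ml.
#' @param abundance Per-taxon relative DNA abundances (summing to 1).
#' @param config A [sim_config()].
#' @return A list: `counts` (taxa x fractions integer matrix), `qpcr`
#'   (per-fraction total copies), `densities`.
#' @export
simulate_gradient_replicate <- function(band_centers, abundance, config) {
  stopifnot(length(band_centers) == length(abundance))
  x <- config$densities
  K <- length(x)
  w <- t(vapply(band_centers, band_weights, numeric(K),
                densities = x, band_sd = config$band_sd))
  mass <- abundance * w                      # taxa x fractions
  frac_mass <- colSums(mass)
  noise <- if (config$qpcr_cv > 0) {
    sdlog <- sqrt(log(1 + config$qpcr_cv^2))
    rlnorm(K, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    rep(1, K)
  }
  qpcr <- config$total_copies * frac_mass * noise
  counts <- matrix(0L, nrow(mass), K)
  for (k in seq_len(K)) {
    if (frac_mass[k] > 0) {
      counts[, k] <- rmultinom(1L, size = config$depth,
                               prob = mass[, k] / frac_mass[k])[, 1L]
    }
  }
  rownames(counts) <- names(band_centers)
  list(counts = counts, qpcr = qpcr, densities = x)
}

#' Simulate a complete ground-truthed qSIP experiment
#'
#' Generates everything the analysis pipeline consumes — OTU count table,
#' fraction metadata, contaminant profile, phylogenetic tree — together with
#' the ground truth (per-taxon GC, abundance, true EAF per treatment, and
#' analytic noise-free WADs) needed for recovery and calibration tests.
#'
#' Community abundances are lognormal; GC contents Beta-distributed on the
#' configured range; the tree is a unit-depth birth-death (pure-birth)
#' phylogeny. True EAF values are assigned per taxon and treatment either
#' i.i.d. (a configured fraction of taxa labeled, truncated-normal levels)
#' or as a tree-structured trait (Brownian motion at a chosen Pagel's
#' lambda, clamped to the valid range). Laboratory contaminant taxa carry
#' true EAF 0, appear in the contaminant profile at the configured read
#' load, and leak into the community at low relative abundance so the
#' 10x contamination rule removes them with high probability. All
#' randomness flows from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `qsip_sim`: `table` (integer count matrix),
#'   `metadata` (fraction metadata data.frame), `contaminants` (named
#'   vector of contaminant-profile read counts), `tree` (`ape::phylo`),
#'   `truth` (list: `gc`, `abundance`, `eaf` matrix taxa x treatments,
#'   `labeled` matrix, `expected_wad_light`, `expected_wad_labeled`
#'   matrices), and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_taxa
  otu_ids <- sprintf("otu_%04d", seq_len(n))
  nc <- config$n_contaminants
  contam_ids <- if (nc > 0) sprintf("contam_%02d", seq_len(nc)) else character(0)
  all_ids <- c(otu_ids, contam_ids)

  abund <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sigma)
  leak <- if (nc > 0) {
    config$contaminant_leakage * rlnorm(nc, 0, 0.5) * sum(abund)
  } else {
    numeric(0)
  }
  abundance <- c(abund, leak)
  abundance <- abundance / sum(abundance)
  names(abundance) <- all_ids

  gc <- rbeta(n + nc, config$gc_shape[1L], config$gc_shape[2L])
  gc <- config$gc_range[1L] + gc * diff(config$gc_range)
  names(gc) <- all_ids

  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- otu_ids

  arms <- expand.grid(substrate = config$substrates, h2 = config$h2_levels,
                      stringsAsFactors = FALSE)
  arms$treatment <- paste0(arms$substrate, ifelse(arms$h2, "+H2", "-H2"))

  eaf <- matrix(0, n + nc, nrow(arms), dimnames = list(all_ids, arms$treatment))
  rule <- config$eaf_rule
  if (rule$mode == "tree") {
    C <- ape::vcv.phylo(tree)
    Vl <- C * rule$lambda
    diag(Vl) <- diag(C)
    L <- chol(Vl)
    for (a in seq_len(nrow(arms))) {
      z <- rule$mean + rule$sd * as.numeric(t(L) %*% rnorm(n))
      eaf[otu_ids, a] <- pmin(pmax(z, 0), rule$max)
    }
  } else {
    for (a in seq_len(nrow(arms))) {
      lab <- rbinom(n, 1L, rule$prop_labeled) == 1L
      lev <- pmin(pmax(rnorm(n, rule$mean, rule$sd), rule$min), rule$max)
      eaf[otu_ids, a] <- ifelse(lab, lev, 0)
    }
  }

  w_light_center <- expected_band_center(gc, 0)
  counts_list <- list()
  md_rows <- list()
  for (a in seq_len(nrow(arms))) {
    centers_lab <- expected_band_center(gc, eaf[, a])
    for (label in c("13C", "control")) {
      centers <- if (label == "13C") centers_lab else w_light_center
      for (rep_i in seq_len(config$n_replicates)) {
        g <- simulate_gradient_replicate(centers, abundance, config)
        keep_k <- seq_along(g$densities)
        if (!is.null(config$top_k_fractions)) {
          keep_k <- order(g$qpcr, decreasing = TRUE)[
            seq_len(min(config$top_k_fractions, length(g$qpcr)))]
          keep_k <- sort(keep_k)
        }
        ids <- sprintf("%s.%s.r%d.f%02d", arms$treatment[a],
                       ifelse(label == "13C", "13C", "ctl"), rep_i, keep_k)
        cts <- g$counts[, keep_k, drop = FALSE]
        colnames(cts) <- ids
        counts_list[[length(counts_list) + 1L]] <- cts
        md_rows[[length(md_rows) + 1L]] <- data.frame(
          sample_id = ids,
          substrate = arms$substrate[a],
          h2 = arms$h2[a],
          label = label,
          replicate = rep_i,
          fraction = keep_k,
          density_g_ml = g$densities[keep_k],
          qpcr_copies = g$qpcr[keep_k],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  table <- do.call(cbind, counts_list)
  rownames(table) <- all_ids
  storage.mode(table) <- "integer"
  metadata <- validate_metadata(do.call(rbind, md_rows))

  contaminants <- if (nc > 0) {
    setNames(rpois(nc, config$contaminant_reads), contam_ids)
  } else {
    setNames(numeric(0), character(0))
  }

  ew_light <- expected_wads(w_light_center, config$densities, config$band_sd)
  ew_lab <- apply(eaf, 2L, function(a) {
    expected_wads(expected_band_center(gc, a), config$densities,
                  config$band_sd)
  })
  truth <- list(gc = gc, abundance = abundance, eaf = eaf,
                labeled = eaf > 0,
                expected_wad_light = setNames(ew_light, all_ids),
                expected_wad_labeled = ew_lab)
  structure(list(table = table, metadata = metadata,
                 contaminants = contaminants, tree = tree,
                 truth = truth, config = config),
            class = "qsip_sim")
}

#' @export
print.qsip_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic qSIP experiment ('%s'): %d taxa (+%d contaminants), %d samples\n",
    x$config$preset, x$config$n_taxa, x$config$n_contaminants,
    ncol(x$table)))
  cat(sprintf("  treatments: %s\n",
              paste(colnames(x$truth$eaf), collapse = ", ")))
  invisible(x)
}

#' Write a simulated experiment in the pipeline's input formats
#'
#' Emits exactly the files the analysis readers consume: `otu_table.tsv`
#' (tab-separated, `#OTU ID` header), `metadata.csv`, `contaminants.tsv`,
#' `tree.nwk` (newick), and `truth.json` (ground truth for recovery
#' checks).
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "qsip_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    otu_table = file.path(dir, "otu_table.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    contaminants = file.path(dir, "contaminants.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  tab <- data.frame(`#OTU ID` = rownames(sim$table), sim$table,
                    check.names = FALSE)
  utils::write.table(tab, paths["otu_table"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md <- sim$metadata[, c("sample_id", "substrate", "h2", "label", "replicate",
                         "fraction", "density_g_ml", "qpcr_copies")]
  write.csv(md, paths["metadata"], row.names = FALSE)
  utils::write.table(
    data.frame(otu_id = names(sim$contaminants),
               count = as.numeric(sim$contaminants)),
    paths["contaminants"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ape::write.tree(sim$tree, paths["tree"])
  jsonlite::write_json(
    list(gc = as.list(sim$truth$gc),
         abundance = as.list(sim$truth$abundance),
         eaf = as.data.frame(sim$truth$eaf),
         otu_id = rownames(sim$truth$eaf),
         seed = sim$config$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
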