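#' Run the full qSIP analysis pipeline
#'
#' Orchestrates the stages end to end: read and validate inputs, remove
#' contaminant OTUs (10x rule), remove low-abundance OTUs (>12 reads per
#' replicate), fit the qSIP model ([qsip()]), write treatment summaries and
#' H2 effect sizes, and — when a tree is supplied — phylogenetic-signal
#' tests. Every stage output is written to `outdir` as tab-separated text,
#' plus a JSON run manifest recording the configuration, seed, package
#' version and MD5 checksums of the inputs, so a run can be replayed and
#' verified.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Recognised keys (defaults in parentheses): `paths` (with
#'   `otu_table`, `metadata`, optional `contaminants` and `tree`), `outdir`,
#'   `format` ("tsv" or "biom"), `filters$contaminant_ratio` (10),
#'   `filters$min_reads` (12), `qsip$n_boot` (1000), `qsip$conf_level`
#'   (0.90), `qsip$seed` (1), `signal$trait` ("eaf"), `signal$n_perm`
#'   (999).
#' @return Invisibly, a list with the fit, reports, summaries, signal
#'   results and written file paths.
#' @export
run_qsip_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$paths),
            !is.null(config$paths$otu_table), !is.null(config$paths$metadata),
            !is.null(config$outdir))
  filters <- config$filters %||% list()
  ratio <- filters$contaminant_ratio %||% 10
  min_reads <- filters$min_reads %||% 12
  qs <- config$qsip %||% list()
  n_boot <- qs$n_boot %||% 1000
  conf_level <- qs$conf_level %||% 0.90
  seed <- as.integer(qs$seed %||% 1L)
  sg <- config$signal %||% list()

  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  counts <- read_otu_table(config$paths$otu_table,
                           format = config$format %||% "tsv")
  metadata <- read_fraction_metadata(config$paths$metadata)
  contaminants <- if (!is.null(config$paths$contaminants)) {
    read_contaminant_profile(config$paths$contaminants)
  } else {
    numeric(0)
  }

  fc <- filter_contaminants(counts, contaminants, ratio = ratio)
  fa <- filter_low_abundance(fc$table, metadata, min_reads = min_reads)
  reports <- list(fc$report, fa$report)

  fit <- qsip(fa$table, metadata, n_boot = n_boot, conf_level = conf_level,
              seed = seed, keep = fa$keep)
  summ <- summary(fit)

  substrates <- unique(metadata$substrate)
  h2 <- lapply(substrates, function(s) {
    both <- all(paste0(s, c("-H2", "+H2")) %in% fit$treatments)
    if (!both) return(NULL)
    h2_effect(fit, s, seed = seed)
  })
  h2 <- h2[!vapply(h2, is.null, TRUE)]
  h2_tab <- if (length(h2) > 0) {
    do.call(rbind, lapply(h2, function(e) {
      data.frame(substrate = e$substrate,
                 mean_eaf_noH2 = e$mean_eaf_noH2,
                 mean_eaf_H2 = e$mean_eaf_H2,
                 percent_change = round(e$percent_change),
                 uncertainty = e$uncertainty,
                 stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }

  signal <- NULL
  if (!is.null(config$paths$tree)) {
    tree <- ape::read.tree(config$paths$tree)
    signal <- phylo_signal(fit, tree, trait = sg$trait %||% "eaf",
                           n_perm = sg$n_perm %||% 999, seed = seed)
  }

  paths <- c(eaf_table = file.path(outdir, "eaf_table.tsv"),
             summary = file.path(outdir, "treatment_summary.tsv"),
             filter_report = file.path(outdir, "filter_report.json"),
             manifest = file.path(outdir, "manifest.json"))
  write_tsv <- function(d, p) {
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(fit$results, paths["eaf_table"])
  write_tsv(as.data.frame(summ), paths["summary"])
  if (!is.null(h2_tab)) {
    paths["h2_effects"] <- file.path(outdir, "h2_effects.tsv")
    write_tsv(h2_tab, paths["h2_effects"])
  }
  if (!is.null(signal)) {
    paths["signal"] <- file.path(outdir, "signal.tsv")
    write_tsv(signal, paths["signal"])
  }

  combined <- removal_summary(list(
    new_filter_report("contaminant", fc$report$removed_otus,
                      fc$report$reads_removed, fc$report$reads_total,
                      n_otus_removed_contaminant =
                        fc$report$n_otus_removed_contaminant),
    fa$report))
  jsonlite::write_json(
    list(contaminant = unclass(fc$report)[
           c("n_otus_removed_contaminant", "reads_removed", "reads_total",
             "percent_reads_removed")],
         low_abundance = unclass(fa$report)[
           c("n_otus_removed_low_abundance", "reads_removed", "reads_total",
             "percent_reads_removed")],
         combined = unclass(combined)[
           c("reads_removed", "reads_total", "percent_reads_removed")]),
    paths["filter_report"], auto_unbox = TRUE, digits = NA)

  inputs <- unlist(config$paths)
  manifest <- list(
    package = "isosip",
    version = as.character(packageVersion("isosip")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    n_boot = n_boot,
    conf_level = conf_level,
    contaminant_ratio = ratio,
    min_reads = min_reads,
    input_checksums = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)

  invisible(list(fit = fit, summary = summ, reports = reports,
                 h2_effects = h2_tab, signal = signal, paths = paths,
                 manifest = manifest))
}
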