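#' Remove laboratory contaminant OTUs
#'
#' An OTU is kept only if its total read count across all samples is strictly
#' greater than `ratio` times its aggregated read count in the contamination
#' controls; otherwise it is treated as a laboratory contaminant and removed.
#' OTUs absent from the contaminant profile have contaminant count 0 and are
#' always kept.
#'
#' @param counts OTU count matrix (OTUs x samples).
#' @param contaminants Named numeric vector of contaminant read counts per
#'   OTU (see [read_contaminant_profile()]); may be empty.
#' @param ratio Positive multiplier; default 10 (keep iff
#'   `sample reads > 10 x contaminant reads`).
#' @return A list with elements `table` (filtered count matrix) and `report`
#'   (a `filter_report`, see [removal_summary()]).
#' @examples
#' m <- matrix(c(100L, 100L), 2, 1,
#'             dimnames = list(c("a", "b"), "s1"))
#' filter_contaminants(m, c(b = 9))$report$n_otus_removed   # 0: 100 > 90
#' filter_contaminants(m, c(b = 10))$report$n_otus_removed  # 1: 100 <= 100
#' @export
filter_contaminants <- function(counts, contaminants = numeric(0), ratio = 10) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio > 0)
  counts <- validate_otu_table(counts)
  totals <- rowSums(counts)
  contam <- rep(0, nrow(counts))
  names(contam) <- rownames(counts)
  hit <- intersect(names(contaminants), rownames(counts))
  contam[hit] <- contaminants[hit]
  keep <- totals > ratio * contam
  report <- new_filter_report(
    step = "contaminant",
    removed_otus = rownames(counts)[!keep],
    reads_removed = sum(totals[!keep]),
    reads_total = sum(totals),
    n_otus_removed_contaminant = sum(!keep)
  )
  list(table = counts[keep, , drop = FALSE], report = report)
}

#' Remove low-abundance OTUs ahead of qSIP
#'
#' Low-abundance taxa produce artificially volatile weighted-average-density
#' estimates, so qSIP analyses drop them: within each treatment (substrate x
#' H2 arm), an OTU is retained for that treatment only if its reads summed
#' across all density fractions exceed `min_reads` (strictly) in every
#' replicate gradient of that treatment, in both the labeled and the
#' unlabeled-control incubations. An OTU failing the rule in one treatment
#' may still be analysed in another; OTUs retained in no treatment are
#' dropped from the returned table.
#'
#' @param counts OTU count matrix (OTUs x samples).
#' @param metadata Fraction metadata (see [validate_metadata()]).
#' @param min_reads Strict per-replicate read threshold; default 12
#'   (i.e. an OTU needs >12 reads in each replicate).
#' @return A list with `table` (OTUs kept in at least one treatment), `keep`
#'   (logical matrix, all input OTUs x treatments), and `report`.
#' @export
filter_low_abundance <- function(counts, metadata, min_reads = 12) {
  counts <- validate_otu_table(counts)
  metadata <- validate_metadata(metadata)
  check_samples_resolve(counts, metadata)
  treatments <- unique(metadata$treatment)
  keep <- matrix(TRUE, nrow(counts), length(treatments),
                 dimnames = list(rownames(counts), treatments))
  for (tr in treatments) {
    tubes <- unique(metadata$tube[metadata$treatment == tr])
    for (tb in tubes) {
      ids <- metadata$sample_id[metadata$tube == tb]
      ids <- intersect(ids, colnames(counts))
      tot <- if (length(ids) > 0L) {
        rowSums(counts[, ids, drop = FALSE])
      } else {
        rep(0, nrow(counts))
      }
      keep[, tr] <- keep[, tr] & (tot > min_reads)
    }
  }
  any_keep <- rowSums(keep) > 0L
  totals <- rowSums(counts)
  report <- new_filter_report(
    step = "low_abundance",
    removed_otus = rownames(counts)[!any_keep],
    reads_removed = sum(totals[!any_keep]),
    reads_total = sum(totals),
    n_otus_removed_low_abundance = sum(!any_keep)
  )
  list(table = counts[any_keep, , drop = FALSE],
       keep = keep, report = report)
}

new_filter_report <- function(step, removed_otus, reads_removed, reads_total,
                              ...) {
  structure(
    list(step = step,
         removed_otus = removed_otus,
         reads_removed = as.numeric(reads_removed),
         reads_total = as.numeric(reads_total),
         percent_reads_removed = if (reads_total > 0) {
           100 * reads_removed / reads_total
         } else {
           0
         },
         ...),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("OTU filter [%s]: removed %d OTUs, %s of %s reads (%.2f%%)\n",
              x$step, length(x$removed_otus),
              format(x$reads_removed, big.mark = ","),
              format(x$reads_total, big.mark = ","),
              x$percent_reads_removed))
  invisible(x)
}

#' Aggregate filter reports
#'
#' Combines the reports of successive filtering steps into one summary on a
#' common denominator: the read total of the first (pre-filter) report. The
#' percentage is retained at full precision; rendered output rounds to two
#' decimals.
#'
#' @param reports A list of `filter_report` objects (or a single one),
#'   sharing the read-total basis of the first.
#' @return A `filter_report` with aggregated counts.
#' @export
removal_summary <- function(reports) {
  if (inherits(reports, "filter_report")) reports <- list(reports)
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, TRUE, "filter_report")))
  total <- reports[[1L]]$reads_total
  if (total == 0) stop("reads_total is zero; nothing was filtered", call. = FALSE)
  removed <- sum(vapply(reports, `[[`, 0, "reads_removed"))
  n_contam <- sum(vapply(reports, function(r) {
    r$n_otus_removed_contaminant %||% 0L
  }, 0L))
  n_low <- sum(vapply(reports, function(r) {
    r$n_otus_removed_low_abundance %||% 0L
  }, 0L))
  new_filter_report(
    step = "combined",
    removed_otus = unique(unlist(lapply(reports, `[[`, "removed_otus"))),
    reads_removed = removed,
    reads_total = total,
    n_otus_removed_contaminant = n_contam,
    n_otus_removed_low_abundance = n_low
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
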