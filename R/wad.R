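#' Per-taxon 16S copy numbers per fraction
#'
#' Scales relative sequence abundances by the fraction's total qPCR-measured
#' 16S copy number: `copies_ik = f_k * count_ik / sum_i count_ik`. Fractions
#' with zero sequencing depth (column sum 0) or zero qPCR copies yield zero
#' copies for every OTU.
#'
#' @param counts OTU count matrix (OTUs x samples).
#' @param metadata Fraction metadata with `sample_id` and `qpcr_copies`.
#' @return Numeric matrix of estimated copies, same dimensions as `counts`.
#' @export
taxon_copies <- function(counts, metadata) {
  counts <- validate_otu_table(counts)
  metadata <- validate_metadata(metadata)
  check_samples_resolve(counts, metadata)
  f <- setNames(metadata$qpcr_copies, metadata$sample_id)[colnames(counts)]
  if (any(f < 0)) stop("negative qpcr_copies", call. = FALSE)
  depth <- colSums(counts)
  scale <- ifelse(depth > 0, f / depth, 0)
  sweep(counts, 2L, scale, `*`)
}

#' Copy-weighted average buoyant density (WAD)
#'
#' The WAD of one taxon in one gradient is the copy-weighted mean of the
#' fraction densities: `W = sum_k x_k y_ik` with portions
#' `y_ik = copies_ik / sum_k copies_ik`. Undefined (NA) when the taxon has
#' no copies in the gradient.
#'
#' @param copies Numeric vector of per-fraction copy numbers for one taxon.
#' @param densities Matching vector of fraction densities, g/ml.
#' @return The weighted average density (g/ml), or `NA_real_` if all copies
#'   are zero.
#' @examples
#' weighted_average_density(c(10, 30), c(1.66, 1.70))  # 1.69
#' @export
weighted_average_density <- function(copies, densities) {
  stopifnot(length(copies) == length(densities), all(copies >= 0))
  tot <- sum(copies)
  if (tot <= 0) return(NA_real_)
  sum(densities * copies) / tot
}

#' WADs for every OTU in every gradient tube
#'
#' Computes [weighted_average_density()] per OTU per physical gradient
#' (treatment x label x replicate), from [taxon_copies()].
#'
#' @param counts OTU count matrix (OTUs x samples).
#' @param metadata Fraction metadata, see [validate_metadata()].
#' @return A numeric matrix (OTUs x tubes, NA where a taxon is absent from a
#'   gradient) with a `tubes` attribute: a data.frame of tube, treatment,
#'   label and replicate.
#' @export
wad_matrix <- function(counts, metadata) {
  counts <- validate_otu_table(counts)
  metadata <- validate_metadata(metadata)
  check_samples_resolve(counts, metadata)
  copies <- taxon_copies(counts, metadata)
  dens <- setNames(metadata$density_g_ml, metadata$sample_id)
  tubes <- unique(metadata[, c("tube", "treatment", "label", "replicate")])
  w <- matrix(NA_real_, nrow(counts), nrow(tubes),
              dimnames = list(rownames(counts), tubes$tube))
  for (j in seq_len(nrow(tubes))) {
    ids <- intersect(metadata$sample_id[metadata$tube == tubes$tube[j]],
                     colnames(counts))
    if (length(ids) == 0L) next
    cp <- copies[, ids, drop = FALSE]
    tot <- rowSums(cp)
    x <- dens[ids]
    w[, j] <- ifelse(tot > 0, as.numeric(cp %*% x) / tot, NA_real_)
  }
  attr(w, "tubes") <- tubes
  w
}
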