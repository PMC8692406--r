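#' Read an OTU count table
#'
#' Reads a per-density-fraction OTU count table from tab-separated text or a
#' BIOM file. The TSV dialect is: first column OTU identifiers (a leading
#' header cell of `"#OTU ID"` is accepted), remaining columns one per
#' fraction sample, cells non-negative integer read counts.
#'
#' @param path Path to the table.
#' @param format `"tsv"` (default) or `"biom"` (BIOM 2.1 / 1.0, read via the
#'   \pkg{biomformat} package).
#' @return An integer matrix (OTUs in rows, fraction samples in columns) with
#'   unique row and column names, validated by [validate_otu_table()].
#' @seealso [read_fraction_metadata()], [read_contaminant_profile()]
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("OTU table not found: ", path, call. = FALSE)
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")
    storage.mode(counts) <- "integer"
    return(validate_otu_table(counts))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L) {
    stop("malformed OTU table header in ", path, call. = FALSE)
  }
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 1L) stop("malformed OTU table: no columns", call. = FALSE)
  otu_ids <- as.character(tab[[1L]])
  counts <- tab[, -1L, drop = FALSE]
  sample_ids <- colnames(counts)
  num <- suppressWarnings(vapply(counts, as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 0L) {
    counts <- matrix(integer(0), nrow = 0L, ncol = length(sample_ids),
                     dimnames = list(character(0), sample_ids))
    return(validate_otu_table(counts))
  }
  num <- matrix(num, nrow = nrow(tab), dimnames = list(otu_ids, sample_ids))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric count at OTU '%s', sample '%s'",
                 otu_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]), call. = FALSE)
  }
  validate_otu_table(num)
}

#' Validate an OTU count matrix
#'
#' Checks the invariants required of a count table: named rows (OTUs) and
#' columns (samples) without duplicates, and non-negative whole-number
#' counts. Counts are coerced to integer storage.
#'
#' @param counts Numeric matrix, OTUs in rows, samples in columns.
#' @return The validated integer matrix, invisibly classed as-is.
#' @export
validate_otu_table <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix", call. = FALSE)
  if (nrow(counts) > 0L && is.null(rownames(counts))) {
    stop("counts must have OTU ids as row names", call. = FALSE)
  }
  if (ncol(counts) > 0L && is.null(colnames(counts))) {
    stop("counts must have sample ids as column names", call. = FALSE)
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup) > 0L) {
    stop("duplicate OTU id: ", dup[1L], call. = FALSE)
  }
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup) > 0L) {
    stop("duplicate sample id: ", dup[1L], call. = FALSE)
  }
  if (length(counts) > 0L) {
    neg <- which(counts < 0, arr.ind = TRUE)
    if (nrow(neg) > 0L) {
      stop(sprintf("negative count at OTU '%s', sample '%s'",
                   rownames(counts)[neg[1L, 1L]],
                   colnames(counts)[neg[1L, 2L]]), call. = FALSE)
    }
    if (any(abs(counts - round(counts)) > 1e-8)) {
      stop("counts must be whole numbers", call. = FALSE)
    }
  }
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  counts
}

#' Read fraction metadata
#'
#' Reads the per-fraction sample sheet: one row per sequenced density
#' fraction, CSV with columns `sample_id`, `substrate`, `h2`, `label`,
#' `replicate`, `fraction`, `density_g_ml`, `qpcr_copies` (an optional
#' `treatment` column is recomputed). `h2` is logical (or "TRUE"/"FALSE",
#' "+H2"/"-H2"); `label` is `"13C"` for labeled incubations or `"control"`
#' for unlabeled controls.
#'
#' @param path Path to the CSV file.
#' @return A validated metadata `data.frame`, see [validate_metadata()].
#' @export
read_fraction_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' Validate fraction metadata
#'
#' Enforces the metadata invariants: required columns present, buoyant
#' densities within the plausible CsCl range 1.55--1.85 g/ml, non-negative
#' qPCR copy numbers, and unique (treatment, label, replicate, fraction)
#' keys. Adds derived columns `treatment` (substrate crossed with H2
#' amendment) and `tube` (one physical gradient: treatment x label x
#' replicate).
#'
#' @param md A data.frame of per-fraction metadata.
#' @return The validated, augmented data.frame.
#' @export
validate_metadata <- function(md) {
  need <- c("sample_id", "substrate", "h2", "label", "replicate",
            "fraction", "density_g_ml", "qpcr_copies")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0L) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id: ", md$sample_id[duplicated(md$sample_id)][1L],
         call. = FALSE)
  }
  if (is.character(md$h2)) {
    md$h2 <- md$h2 %in% c("TRUE", "true", "+H2", "yes", "1")
  }
  md$h2 <- as.logical(md$h2)
  if (!all(md$label %in% c("13C", "control"))) {
    stop("label must be '13C' or 'control'", call. = FALSE)
  }
  md$replicate <- as.integer(md$replicate)
  if (any(md$replicate < 1L)) stop("replicate must be >= 1", call. = FALSE)
  md$density_g_ml <- as.numeric(md$density_g_ml)
  if (any(md$density_g_ml < 1.55 | md$density_g_ml > 1.85)) {
    stop("fraction density outside [1.55, 1.85] g/ml", call. = FALSE)
  }
  md$qpcr_copies <- as.numeric(md$qpcr_copies)
  if (any(md$qpcr_copies < 0)) stop("qpcr_copies must be >= 0", call. = FALSE)
  md$treatment <- paste0(md$substrate, ifelse(md$h2, "+H2", "-H2"))
  md$tube <- paste(md$treatment, md$label, md$replicate, sep = "|")
  key <- paste(md$tube, md$fraction)
  if (anyDuplicated(key)) {
    stop("duplicate (treatment, label, replicate, fraction) key: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  md
}

#' Read a contaminant read-count profile
#'
#' Two-column tab-separated file `otu_id<TAB>count` giving, per OTU, the read
#' count aggregated over laboratory contamination-control samples (e.g. dust
#' blanks). OTUs absent from the profile are treated as having zero
#' contaminant reads.
#'
#' @param path Path to the two-column TSV.
#' @return A named numeric vector of contaminant read counts.
#' @export
read_contaminant_profile <- function(path) {
  if (!file.exists(path)) {
    stop("contaminant profile not found: ", path, call. = FALSE)
  }
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("contaminant profile needs 2 columns", call. = FALSE)
  counts <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(counts)) stop("non-numeric contaminant count", call. = FALSE)
  if (any(counts < 0)) stop("negative contaminant count", call. = FALSE)
  setNames(counts, as.character(tab[[1L]]))
}

# Check that every table sample id resolves in the metadata.
check_samples_resolve <- function(counts, md) {
  missing <- setdiff(colnames(counts), md$sample_id)
  if (length(missing) > 0L) {
    stop("sample(s) without metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
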