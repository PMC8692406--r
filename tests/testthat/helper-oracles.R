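# Independent oracles used by the tests. These deliberately re-derive
# quantities by brute force / enumeration, never by calling the code paths
# they check.

# Exhaustive bootstrap distribution of the EAF for small replicate sets:
# all n^n ordered with-replacement resamples per arm, crossed.
enumerate_eaf_boot <- function(labeled_wads, control_wads,
                               params = isotope_params()) {
  nl <- length(labeled_wads)
  nc <- length(control_wads)
  lab_idx <- as.matrix(expand.grid(rep(list(seq_len(nl)), nl)))
  ctl_idx <- as.matrix(expand.grid(rep(list(seq_len(nc)), nc)))
  lab_means <- apply(lab_idx, 1L, function(i) mean(labeled_wads[i]))
  ctl_means <- apply(ctl_idx, 1L, function(i) mean(control_wads[i]))
  grid <- expand.grid(l = lab_means, c = ctl_means)
  eaf_point(grid$c, grid$l, params)
}

# ANOSIM R computed from first principles on a dissimilarity matrix.
anosim_R_oracle <- function(d, grouping) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  rk <- rank(as.vector(d))
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  within <- grouping[idx[, 1L]] == grouping[idx[, 2L]]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

# Exact ANOSIM permutation null over all label permutations (small n only).
anosim_null_oracle <- function(d, grouping) {
  n <- length(grouping)
  perms <- permutations_all(n)
  apply(perms, 1L, function(p) anosim_R_oracle(d, grouping[p]))
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Minimal valid fraction metadata for constructed tables: one treatment arm,
# labeled + control tubes, `n_frac` fractions each.
toy_metadata <- function(n_rep = 3L, n_frac = 4L,
                         densities = seq(1.68, 1.74, length.out = n_frac),
                         qpcr = 1000) {
  rows <- expand.grid(fraction = seq_len(n_frac), replicate = seq_len(n_rep),
                      label = c("13C", "control"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("s_%s_r%d_f%d", ifelse(rows$label == "13C", "L", "C"),
                        rows$replicate, rows$fraction),
    substrate = "bicarbonate", h2 = FALSE, label = rows$label,
    replicate = rows$replicate, fraction = rows$fraction,
    density_g_ml = densities[rows$fraction], qpcr_copies = qpcr,
    stringsAsFactors = FALSE
  )
}

write_tsv_table <- function(counts, path) {
  lines <- c(paste(c("#OTU ID", colnames(counts)), collapse = "\t"),
             if (nrow(counts) > 0) {
               apply(cbind(rownames(counts), counts), 1L, paste,
                     collapse = "\t")
             })
  writeLines(lines, path)
  path
}
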