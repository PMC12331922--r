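#' Global MS2-level signal normalization
#'
#' Equalizes the per-sample median log2 fragment intensity to the grand
#' median (the median over all non-missing log2 intensities pooled across
#' samples) by a single multiplicative factor per sample. Missing values are
#' untouched. Samples with no finite intensities are flagged and left
#' unscaled.
#'
#' @param fragment_table Long data frame with at least `sample` and `area`.
#' @return The table with `area` rescaled; per-sample log2 scale factors in
#'   `attr(, "scale_log2")` and flagged samples in `attr(, "unscaled")`.
#' @export
normalize_ms2 <- function(fragment_table) {
  stopifnot(all(c("sample", "area") %in% names(fragment_table)))
  lg <- log2(fragment_table$area)
  ok <- is.finite(lg)
  grand <- stats::median(lg[ok])
  meds <- tapply(lg[ok], fragment_table$sample[ok], stats::median)
  all_samples <- unique(fragment_table$sample)
  shift <- stats::setNames(rep(NA_real_, length(all_samples)), all_samples)
  shift[names(meds)] <- grand - meds
  unscaled <- all_samples[is.na(shift)]
  shift[is.na(shift)] <- 0
  fragment_table$area <- fragment_table$area *
    2^shift[fragment_table$sample]
  attr(fragment_table, "scale_log2") <- shift
  attr(fragment_table, "unscaled") <- unscaled
  fragment_table
}

mean_top3 <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  mean(sort(x, decreasing = TRUE)[seq_len(min(3L, length(x)))])
}

#' Top-3 roll-up to peptide and protein quantities
#'
#' Within each sample, a peptide's quantity is the mean of the peak areas of
#' its three most intense fragment ions (all of them when fewer than three),
#' and a protein's quantity is the mean of its three most abundant peptides.
#'
#' @param fragment_table Long data frame with `sample`, `protein_id`, `key`
#'   (peptide), `fragment`, `area`.
#' @return A `QuantMatrix`: list with `intensity` (protein-by-sample matrix,
#'   `NA` where unobserved), `n_peptides` (matching matrix of peptides
#'   quantified per cell), `peptide_intensity` (peptide-by-sample matrix) and
#'   `peptides_per_protein` (total distinct peptides supporting each
#'   protein).
#' @export
rollup_top3 <- function(fragment_table) {
  stopifnot(all(c("sample", "protein_id", "key", "area") %in%
                  names(fragment_table)))
  ft <- fragment_table[is.finite(fragment_table$area), , drop = FALSE]
  if (any(ft$area < 0)) stop("fragment areas must be non-negative",
                             call. = FALSE)
  samples <- sort(unique(ft$sample))
  pep_q <- tapply(ft$area, list(ft$key, ft$sample), mean_top3)
  pep_q <- pep_q[, samples, drop = FALSE]
  pep2prot <- tapply(ft$protein_id, ft$key, function(p) p[1])
  prots <- sort(unique(ft$protein_id))
  intensity <- matrix(NA_real_, length(prots), length(samples),
                      dimnames = list(prots, samples))
  n_pep <- matrix(0L, length(prots), length(samples),
                  dimnames = list(prots, samples))
  for (pr in prots) {
    keys <- rownames(pep_q)[pep2prot[rownames(pep_q)] == pr]
    sub <- pep_q[keys, , drop = FALSE]
    intensity[pr, ] <- apply(sub, 2, mean_top3)
    n_pep[pr, ] <- colSums(!is.na(sub))
  }
  structure(list(
    intensity = intensity, n_peptides = n_pep,
    peptide_intensity = pep_q,
    peptides_per_protein = stats::setNames(
      as.integer(table(pep2prot)[prots]), prots)
  ), class = "QuantMatrix")
}

#' @export
print.QuantMatrix <- function(x, ...) {
  cat(sprintf("QuantMatrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$intensity), ncol(x$intensity),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' Differential expression with the filter cascade
#'
#' Welch t-test on log2 protein intensities between two groups, with
#' Benjamini-Hochberg q-values, applying the filter cascade in order:
#' presence (protein quantified in at least `min_presence` of the samples of
#' each group), peptide support (at least `min_peptides` distinct peptides),
#' q-value threshold, then the fold-change threshold. A protein is
#' significant only if it passes all four. The default fold-change threshold
#' `log2(1.5) = 0.585` corresponds to a 50% expression difference. Tests use
#' available values only (no imputation); proteins absent from an entire
#' group have an undefined fold change and are excluded with a flag.
#'
#' @param qm A `QuantMatrix`.
#' @param groups Named character vector (sample -> "A"/"B") or factor over
#'   the matrix columns.
#' @param fc_threshold_log2 Absolute log2 fold-change threshold.
#' @param q_threshold BH q-value threshold.
#' @param min_peptides Minimum distinct peptides per protein.
#' @param min_presence Minimum fraction of samples per group with a value.
#' @return A `DEResult` data frame: per protein `log2fc` (B vs A), `p_value`,
#'   `q_value`, `unique_peptides`, `presence_a`, `presence_b` and logical
#'   flags `pass_presence`, `pass_peptides`, `pass_q`, `pass_fc`,
#'   `excluded`, `significant`.
#' @export
differential_expression <- function(qm, groups, fc_threshold_log2 = 0.585,
                                    q_threshold = 0.05, min_peptides = 2L,
                                    min_presence = 0.5) {
  stopifnot(inherits(qm, "QuantMatrix"))
  m <- qm$intensity
  groups <- groups[colnames(m)]
  if (any(is.na(groups))) stop("groups must cover every sample column",
                               call. = FALSE)
  gl <- sort(unique(as.character(groups)))
  if (length(gl) != 2) stop("exactly two groups are required", call. = FALSE)
  a <- groups == gl[1]; b <- groups == gl[2]
  if (sum(a) < 2 || sum(b) < 2) stop("each group needs >= 2 samples",
                                     call. = FALSE)

  res <- data.frame(
    protein_id = rownames(m),
    presence_a = rowMeans(!is.na(m[, a, drop = FALSE])),
    presence_b = rowMeans(!is.na(m[, b, drop = FALSE])),
    unique_peptides = qm$peptides_per_protein[rownames(m)],
    log2fc = NA_real_, p_value = NA_real_, q_value = NA_real_
  )
  res$excluded <- res$presence_a == 0 | res$presence_b == 0
  res$pass_presence <- !res$excluded &
    res$presence_a >= min_presence & res$presence_b >= min_presence
  res$pass_peptides <- res$pass_presence &
    res$unique_peptides >= min_peptides

  tested <- which(res$pass_peptides)
  for (i in tested) {
    xa <- log2(m[i, a]); xb <- log2(m[i, b])
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    res$log2fc[i] <- mean(xb) - mean(xa)
    res$p_value[i] <- if (length(xa) >= 2 && length(xb) >= 2 &&
                          (stats::sd(xa) > 0 || stats::sd(xb) > 0)) {
      stats::t.test(xb, xa, var.equal = FALSE)$p.value
    } else 1
  }
  res$q_value[tested] <- stats::p.adjust(res$p_value[tested], method = "BH")
  res$pass_q <- !is.na(res$q_value) & res$q_value < q_threshold
  res$pass_fc <- !is.na(res$log2fc) & abs(res$log2fc) >= fc_threshold_log2
  res$significant <- res$pass_presence & res$pass_peptides &
    res$pass_q & res$pass_fc
  # fold change also reported for excluded-from-test proteins where defined
  rownames(res) <- NULL
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Coefficient-of-variation distribution over replicates
#'
#' Per-protein CV% (`100 * sd / mean`) over replicate columns; zero-mean or
#' single-observation proteins are excluded.
#'
#' @param x A `QuantMatrix` or a protein-by-replicate matrix.
#' @return List with `median_cv` (%), `frac_below_20` (fraction of proteins
#'   with CV < 20%) and the per-protein `cv` vector.
#' @export
cv_distribution <- function(x) {
  m <- if (inherits(x, "QuantMatrix")) x$intensity else x
  if (ncol(m) < 2) stop("at least 2 replicates are required", call. = FALSE)
  cv <- apply(m, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  })
  cv <- cv[!is.na(cv)]
  list(median_cv = stats::median(cv), frac_below_20 = mean(cv < 20), cv = cv)
}

#' Export differential-expression results as TSV
#' @param de A `DEResult`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
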