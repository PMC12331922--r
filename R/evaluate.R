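# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Eisenberg consensus hydrophobicity, used as the default residue
# retention-coefficient scale for the hydrophobicity index (swappable).
EISENBERG_CONSENSUS <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85, E = -0.74,
  G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50, M = 0.64, F = 1.19,
  P = 0.12, S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08
)

#' Peptide physicochemical properties
#'
#' Length, monoisotopic mass, GRAVY (mean Kyte-Doolittle hydropathy over the
#' residues) and a hydrophobicity index (sum of per-residue retention
#' coefficients; Eisenberg consensus scale by default, swappable).
#'
#' @param sequence Amino-acid string (standard residues).
#' @param hydrophobicity_scale Named per-residue coefficient vector.
#' @return List with `length`, `mass` (Da, monoisotopic, unmodified),
#'   `gravy` and `hydrophobicity_index`.
#' @export
peptide_properties <- function(sequence,
                               hydrophobicity_scale = EISENBERG_CONSENSUS) {
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% names(KYTE_DOOLITTLE))) {
    stop("unknown residue in sequence: ", sequence, call. = FALSE)
  }
  list(length = length(aa),
       mass = peptide_mass(sequence),
       gravy = mean(KYTE_DOOLITTLE[aa]),
       hydrophobicity_index = sum(hydrophobicity_scale[aa]))
}

#' Per-run completeness
#'
#' Fraction of the replicate-union proteome identified in each run:
#' `|proteins in run| / |union over runs| * 100`.
#'
#' @param per_run_protein_sets Named list of protein identifier vectors.
#' @return Named numeric vector of percentages.
#' @export
completeness <- function(per_run_protein_sets) {
  if (length(per_run_protein_sets) < 2) {
    stop("at least 2 runs are required", call. = FALSE)
  }
  u <- unique(unlist(per_run_protein_sets))
  if (!length(u)) stop("empty union of protein sets", call. = FALSE)
  vapply(per_run_protein_sets,
         function(s) 100 * length(unique(s)) / length(u), numeric(1))
}

#' Library recovery
#'
#' Percentage of library proteins identified in the samples:
#' `|identified intersect library| / |library| * 100`.
#'
#' @param identified_proteins,library_proteins Protein identifier vectors.
#' @return Percentage.
#' @export
library_recovery <- function(identified_proteins, library_proteins) {
  lib <- unique(library_proteins)
  if (!length(lib)) stop("empty library", call. = FALSE)
  100 * length(intersect(unique(identified_proteins), lib)) / length(lib)
}

#' Explained total ion current
#'
#' Percentage of the run's MS2 ion current carried by peaks matching (within
#' `tol_ppm`) the library fragments of accepted identifications, counting a
#' fragment only in the isolation windows that cover its precursor.
#'
#' @param run A `DiaRun`.
#' @param ids Identifications from [score_and_fdr()].
#' @param library The `IonLibrary` used for identification.
#' @param tol_ppm Match tolerance (ppm).
#' @param accepted_only Restrict to identifications at the q-value cutoff.
#' @return Percentage of MS2 TIC explained.
#' @export
explained_tic <- function(run, ids, library, tol_ppm = 10,
                          accepted_only = TRUE) {
  total <- run_tic(run)
  if (total == 0) stop("run has zero MS2 ion current", call. = FALSE)
  use <- if (accepted_only) ids$key[ids$accepted] else ids$key
  if (!length(use)) return(0)
  w <- run$scheme$windows
  ent <- library$entries[match(use, library$entries$key), ]
  # per window: the fragment m/z values of accepted entries it isolates
  frag_by_window <- lapply(seq_len(nrow(w)), function(i) {
    keys <- ent$key[ent$precursor_mz >= w$nominal_lower[i] &
                      ent$precursor_mz < w$nominal_upper[i]]
    sort(unique(unlist(lapply(library$fragments[keys], `[[`, "mz"))))
  })
  matched <- 0
  for (s in ms2_spectra(run)) {
    tg <- frag_by_window[[s$window]]
    if (!length(tg) || !nrow(s$peaks)) next
    pk <- s$peaks
    hit <- vapply(pk[, "mz"], function(mz) {
      j <- findInterval(mz, tg)
      (j >= 1 && mz - tg[j] <= mz * tol_ppm * 1e-6) ||
        (j < length(tg) && tg[j + 1] - mz <= mz * tol_ppm * 1e-6)
    }, logical(1))
    matched <- matched + sum(pk[hit, "intensity"])
  }
  100 * matched / total
}

#' Venn region counts for named identification sets
#'
#' Counts all `2^k - 1` exclusive regions of up to k named sets at a chosen
#' identification level.
#'
#' @param sets Named list (>= 2) of identifier vectors.
#' @return Data frame with `region` (set names joined by `&`) and `count`;
#'   region counts sum to the union size.
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2) stop("at least 2 sets are required", call. = FALSE)
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1,
                                       dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  k <- length(sets)
  combos <- unlist(lapply(seq_len(k), function(m) {
    apply(utils::combn(names(sets), m), 2, paste, collapse = "&")
  }))
  counts <- vapply(combos, function(cb) sum(pat == cb), numeric(1))
  data.frame(region = combos, count = as.integer(counts),
             row.names = NULL)
}

#' Protein abundance rank distribution
#'
#' Proteins sorted by mean log10 intensity, descending.
#'
#' @param x A `QuantMatrix` or protein-by-sample matrix.
#' @return Data frame with `rank`, `protein_id`, `mean_log10`.
#' @export
rank_distribution <- function(x) {
  m <- if (inherits(x, "QuantMatrix")) x$intensity else x
  ml <- apply(m, 1, function(v) mean(log10(v[is.finite(v) & v > 0])))
  ml <- ml[is.finite(ml)]
  ord <- order(ml, decreasing = TRUE)
  data.frame(rank = seq_along(ord), protein_id = names(ml)[ord],
             mean_log10 = ml[ord], row.names = NULL)
}

#' Pearson correlation of two methods' quantities on shared keys
#'
#' @param quant_a,quant_b Named numeric vectors of quantities (or
#'   `QuantMatrix` objects, compared on row means).
#' @return Pearson r of log10 quantities over the key intersection.
#' @export
cross_method_correlation <- function(quant_a, quant_b) {
  to_vec <- function(q) {
    if (inherits(q, "QuantMatrix")) {
      apply(q$intensity, 1, function(v) mean(v[is.finite(v)]))
    } else q
  }
  a <- to_vec(quant_a); b <- to_vec(quant_b)
  shared <- intersect(names(a)[is.finite(a) & a > 0],
                      names(b)[is.finite(b) & b > 0])
  if (length(shared) < 3) stop("fewer than 3 shared keys", call. = FALSE)
  stats::cor(log10(a[shared]), log10(b[shared]))
}

#' Library comparison report
#'
#' Aggregates the per-method metric suite: identification counts,
#' completeness, library recovery, explained TIC, XIC window width, CV
#' summary and z-scored peptide-property radar values.
#'
#' @param methods Named list; each element a list with `ids` (accepted
#'   identification data frame), `library` (`IonLibrary`) and optionally
#'   `quant` (`QuantMatrix`).
#' @return Data frame with one row per method.
#' @export
comparison_report <- function(methods) {
  rows <- lapply(names(methods), function(nm) {
    m <- methods[[nm]]
    acc <- m$ids[m$ids$accepted, , drop = FALSE]
    props <- vapply(unique(acc$key), function(k) {
      seq <- m$library$entries$sequence[match(k, m$library$entries$key)]
      p <- peptide_properties(seq)
      c(p$mass, p$gravy, p$hydrophobicity_index, p$length)
    }, numeric(4))
    data.frame(
      method = nm,
      n_precursors = nrow(acc),
      n_peptides = length(unique(sub("/\\d+$", "", acc$key))),
      n_proteins = length(unique(acc$protein_id)),
      library_size = nrow(m$library$entries),
      xic_window_minutes = m$library$xic_window_minutes,
      mean_mass = if (length(props)) mean(props[1, ]) else NA,
      mean_gravy = if (length(props)) mean(props[2, ]) else NA,
      mean_hydrophobicity = if (length(props)) mean(props[3, ]) else NA,
      mean_length = if (length(props)) mean(props[4, ]) else NA
    )
  })
  out <- do.call(rbind, rows)
  # z-score the radar columns across methods (presentation convention)
  for (col in c("mean_mass", "mean_gravy", "mean_hydrophobicity",
                "mean_length")) {
    v <- out[[col]]
    out[[paste0("z_", sub("mean_", "", col))]] <-
      if (length(v) > 1 && stats::sd(v, na.rm = TRUE) > 0)
        (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE) else 0
  }
  out
}
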