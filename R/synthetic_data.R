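# Monoisotopic residue masses (Da), unmodified side chains.
RESIDUE_MASS <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276385,
  V = 99.06841391, T = 101.04767846, C = 103.00918496, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496301, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)
PROTON_MASS <- 1.00727646677
WATER_MASS  <- 18.01056468
CARBAMIDOMETHYL <- 57.02146372  # fixed Cys modification

residue_masses <- function(carbamidomethyl = TRUE) {
  m <- RESIDUE_MASS
  if (carbamidomethyl) m["C"] <- m["C"] + CARBAMIDOMETHYL
  m
}

#' Monoisotopic peptide mass and precursor m/z
#'
#' @param sequence Amino-acid string (standard 20 residues).
#' @param charge Precursor charge for `precursor_mz`.
#' @param carbamidomethyl Apply the fixed +57.02146 Cys modification.
#' @return Neutral monoisotopic mass (Da) or precursor m/z (Th).
#' @export
peptide_mass <- function(sequence, carbamidomethyl = FALSE) {
  aa <- strsplit(sequence, "")[[1]]
  m <- residue_masses(carbamidomethyl)
  if (!all(aa %in% names(m))) {
    stop("unknown residue in sequence: ", sequence, call. = FALSE)
  }
  sum(m[aa]) + WATER_MASS
}

#' @rdname peptide_mass
#' @export
precursor_mz <- function(sequence, charge, carbamidomethyl = FALSE) {
  (peptide_mass(sequence, carbamidomethyl) + charge * PROTON_MASS) / charge
}

# Singly charged b/y fragment m/z for every cleavage position 1..L-1.
fragment_mz_table <- function(sequence, carbamidomethyl = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  m <- residue_masses(carbamidomethyl)[aa]
  n <- length(m)
  cs <- cumsum(m)
  idx <- seq_len(n - 1L)
  data.frame(
    type  = rep(c("b", "y"), each = n - 1L),
    index = c(idx, idx),
    mz    = c(cs[idx] + PROTON_MASS,                      # b_i
              cs[n] - cs[n - idx] + WATER_MASS + PROTON_MASS)  # y_i
  )
}

# Tryptic digestion: cleave C-terminal to K/R; cleave_before_proline = TRUE
# ("Trypsin/P") also cuts when the next residue is proline.
digest_tryptic <- function(sequence, missed = 0:2,
                           cleave_before_proline = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut <- which(aa %in% c("K", "R"))
  if (!cleave_before_proline) {
    cut <- cut[!(cut < n & aa[pmin(cut + 1L, n)] == "P")]
  }
  cut <- cut[cut < n]
  bounds <- c(0L, cut, n)  # peptide i spans bounds[i]+1 .. bounds[i+1]
  out <- list()
  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    for (mc in missed) {
      j <- i + 1L + mc
      if (j > nb) break
      out[[length(out) + 1L]] <- list(
        sequence = paste(aa[(bounds[i] + 1L):bounds[j]], collapse = ""),
        missed_cleavages = mc
      )
    }
  }
  out
}

random_protein <- function(length = 300L) {
  # residue frequencies loosely matching vertebrate proteome composition
  freq <- c(A = .08, R = .055, N = .04, D = .054, C = .02, Q = .04, E = .07,
            G = .07, H = .025, I = .05, L = .095, K = .06, M = .022, F = .038,
            P = .05, S = .08, T = .055, W = .012, Y = .03, V = .065)
  paste(sample(names(freq), length, replace = TRUE, prob = freq), collapse = "")
}

#' Generate ground-truthed synthetic tryptic peptides
#'
#' In-silico digests proteins (random sequences or a FASTA file) with tryptic
#' specificity, assigns charges, indexed retention times (iRT) and
#' protein/peptide abundances, and builds each precursor's fragment set: all
#' singly charged b/y ions are generated, relative intensities are drawn once
#' from a symmetric Dirichlet(1), fragments outside 300--1800 Th are
#' discarded and the 3--6 most intense survivors are kept. Peptides shorter
#' than 7 or longer than 35 residues, with more than `max_missed` missed
#' cleavages, or with fewer than 3 in-range fragments are dropped.
#'
#' @param source `"random"` or a path to a protein FASTA file (requires the
#'   Biostrings package).
#' @param n_proteins Number of proteins to digest (random source) or read.
#' @param seed Integer seed; the peptide set is fully reproducible.
#' @param max_missed Maximum missed cleavages retained (default 2). Fully
#'   cleaved peptides are always emitted; missed-cleavage products are
#'   sampled with probability `missed_rate` per extra cleavage site.
#' @param missed_rate Emission probability of 1- and 2-missed-cleavage forms.
#' @param cleave_before_proline Tryptic "/P" rule: cleave K/R-P bonds too.
#' @param abundance_meanlog,abundance_sdlog Log-normal protein abundance
#'   parameters (natural-log scale).
#' @param protein_length Residue length of random proteins.
#' @return A `PeptideSet`: list with `table` (one row per precursor:
#'   `peptide_id`, `key`, `sequence`, `charge`, `precursor_mz`, `irt`,
#'   `protein_id`, `abundance`, `missed_cleavages`, `n_fragments`) and
#'   `fragments` (named list of per-precursor data frames `type`, `index`,
#'   `mz`, `rel_intensity` with max intensity 1).
#' @export
generate_peptides <- function(source = "random", n_proteins = 20L,
                              seed = 1L, max_missed = 2L, missed_rate = 0.15,
                              cleave_before_proline = TRUE,
                              abundance_meanlog = log(1e6),
                              abundance_sdlog = 1.0,
                              protein_length = 300L) {
  if (n_proteins < 1) stop("n_proteins must be >= 1", call. = FALSE)
  set.seed(seed)
  if (identical(source, "random")) {
    proteins <- stats::setNames(
      replicate(n_proteins, random_protein(protein_length)),
      sprintf("PROT%04d", seq_len(n_proteins)))
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package", call. = FALSE)
    }
    ss <- Biostrings::readAAStringSet(source)
    if (length(ss) == 0) stop("empty FASTA source", call. = FALSE)
    ss <- ss[seq_len(min(n_proteins, length(ss)))]
    proteins <- stats::setNames(as.character(ss),
                                vapply(strsplit(names(ss), "\\s+"), `[`, "", 1))
  }

  rows <- list()
  frags <- list()
  for (pid in names(proteins)) {
    prot_abund <- stats::rlnorm(1, abundance_meanlog, abundance_sdlog)
    peps <- digest_tryptic(proteins[[pid]], missed = 0:max_missed,
                           cleave_before_proline = cleave_before_proline)
    for (pep in peps) {
      L <- nchar(pep$sequence)
      if (L < 7 || L > 35) next
      if (pep$missed_cleavages > 0 &&
          stats::runif(1) > missed_rate) next
      if (grepl("[^A-Z]", pep$sequence)) next
      if (!all(strsplit(pep$sequence, "")[[1]] %in% names(RESIDUE_MASS))) next
      charge <- sample(2:4, 1, prob = c(0.6, 0.3, 0.1))
      ft <- fragment_mz_table(pep$sequence)
      ft$rel_intensity <- stats::rexp(nrow(ft))  # Dirichlet(1) up to scale
      ft <- ft[ft$mz >= 300 & ft$mz <= 1800, , drop = FALSE]
      if (nrow(ft) < 3) next
      ft <- ft[order(-ft$rel_intensity), , drop = FALSE][seq_len(min(6L, nrow(ft))), ]
      ft$rel_intensity <- ft$rel_intensity / max(ft$rel_intensity)
      ft <- ft[order(ft$mz), , drop = FALSE]
      rownames(ft) <- NULL
      key <- paste0(pep$sequence, "/", charge)
      if (!is.null(frags[[key]])) next  # unique (sequence, charge) keys
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, sequence = pep$sequence, charge = charge,
        precursor_mz = precursor_mz(pep$sequence, charge,
                                    carbamidomethyl = TRUE),
        irt = stats::runif(1, 0, 100),
        protein_id = pid,
        abundance = prot_abund * stats::rlnorm(1, 0, 0.5),
        missed_cleavages = pep$missed_cleavages,
        n_fragments = nrow(ft)
      )
      frags[[key]] <- ft
    }
  }
  if (!length(rows)) stop("no peptides generated; increase n_proteins",
                          call. = FALSE)
  tab <- do.call(rbind, rows)
  tab$peptide_id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, fragments = frags, seed = seed),
            class = "PeptideSet")
}

#' @export
print.PeptideSet <- function(x, ...) {
  cat(sprintf("PeptideSet: %d precursors from %d proteins (seed %d)\n",
              nrow(x$table), length(unique(x$table$protein_id)), x$seed))
  invisible(x)
}

#' Default simulator noise model
#'
#' Shot noise is Poisson-like (variance proportional to the mean: observed
#' intensity ~ Normal(I, `shot_factor` * I), truncated at zero). Chemical
#' noise adds `chemical_rate` uniform-m/z peaks per MS2 scan with
#' Exponential(`1/chemical_mean`) intensities.
#'
#' @param shot_factor Variance-to-mean ratio of signal peaks (0 = none).
#' @param chemical_rate Expected chemical-noise peaks per MS2 scan.
#' @param chemical_mean Mean intensity of chemical-noise peaks.
#' @return A `noise_model` list.
#' @export
noise_model <- function(shot_factor = 0, chemical_rate = 0,
                        chemical_mean = 1e3) {
  structure(list(shot_factor = shot_factor, chemical_rate = chemical_rate,
                 chemical_mean = chemical_mean), class = "noise_model")
}

gaussian_sd_from_fwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Default affine iRT-to-retention-time map
#'
#' Maps iRT 0--100 onto the central 80% of the gradient.
#' @param gradient_minutes Gradient length (min).
#' @return List with `slope` and `intercept` (seconds per iRT unit, seconds).
#' @export
default_rt_map <- function(gradient_minutes) {
  g <- gradient_minutes * 60
  list(slope = 0.8 * g / 100, intercept = 0.1 * g)
}

#' Simulate a staggered-window DIA run
#'
#' Plays the acquisition cycle of `scheme` over a gradient: at each cycle the
#' windows are acquired in order with an MS1 survey scan inserted after every
#' `scheme$ms1_every` MS2 scans. Every peptide elutes as a Gaussian of the
#' stated FWHM centered at its iRT-mapped retention time; an MS2 scan
#' contains the fragment peaks of all peptides whose precursor m/z falls in
#' that isolation window, scaled by the elution profile at the scan time,
#' plus optional shot and chemical noise.
#'
#' @param peptides A `PeptideSet` from [generate_peptides()].
#' @param scheme A `WindowScheme`.
#' @param abundances Optional named vector (by peptide `key`) overriding the
#'   peptide set's abundances; `NA` drops the peptide from this run.
#' @param gradient_minutes Gradient length (min).
#' @param cycle_ms Full cycle time (ms); default 3180.
#' @param peak_fwhm_s Chromatographic peak FWHM (s); default 17.
#' @param noise A [noise_model()]; `NULL` for a noiseless run.
#' @param seed Integer seed for the noise draws.
#' @param rt_map Affine iRT map (`list(slope, intercept)`), default
#'   [default_rt_map()].
#' @param rt_jitter_s SD of a per-run random shift added to the map intercept
#'   (emulates between-run retention drift); 0 disables.
#' @param rt_mode `"cycle"`: all scans of a cycle share the cycle start time
#'   (instantaneous-cycle simplification); `"spread"`: scans are spaced
#'   evenly across the cycle.
#' @param detection_floor Peptides whose apex intensity falls below this are
#'   absent from the run.
#' @return A `DiaRun`. `metadata$excluded_out_of_range` counts peptides whose
#'   precursor lies outside the scheme's window coverage;
#'   `metadata$planted_tic` is the noise-free total MS2 ion current.
#' @export
simulate_run <- function(peptides, scheme, abundances = NULL,
                         gradient_minutes = 10, cycle_ms = 3180,
                         peak_fwhm_s = 17, noise = noise_model(),
                         seed = 1L, rt_map = NULL, rt_jitter_s = 0,
                         rt_mode = c("cycle", "spread"),
                         detection_floor = 0) {
  stopifnot(inherits(peptides, "PeptideSet"), inherits(scheme, "WindowScheme"))
  if (cycle_ms <= 0) stop("cycle_ms must be positive", call. = FALSE)
  rt_mode <- match.arg(rt_mode)
  set.seed(seed)
  if (is.null(rt_map)) rt_map <- default_rt_map(gradient_minutes)
  if (rt_jitter_s > 0) {
    rt_map$intercept <- rt_map$intercept + stats::rnorm(1, 0, rt_jitter_s)
  }

  tab <- peptides$table
  if (!is.null(abundances)) {
    tab$abundance <- abundances[tab$key]
    tab <- tab[!is.na(tab$abundance), , drop = FALSE]
  }
  cov <- scheme_coverage(scheme)
  in_range <- tab$precursor_mz >= cov[1] & tab$precursor_mz < cov[2]
  n_excluded <- sum(!in_range)
  tab <- tab[in_range, , drop = FALSE]
  if (detection_floor > 0) {
    tab <- tab[tab$abundance >= detection_floor, , drop = FALSE]
  }
  tab$apex_rt <- rt_map$intercept + rt_map$slope * tab$irt
  sd_s <- gaussian_sd_from_fwhm(peak_fwhm_s)

  win <- scheme$windows
  # peptides per window (nominal geometry, half-open intervals)
  pep_by_window <- lapply(seq_len(nrow(win)), function(i) {
    which(tab$precursor_mz >= win$nominal_lower[i] &
            tab$precursor_mz < win$nominal_upper[i])
  })

  cycle_s <- cycle_ms / 1000
  cycle_starts <- seq(0, gradient_minutes * 60, by = cycle_s)
  n_win <- nrow(win)
  ms1_every <- scheme$ms1_every
  n_ms1 <- if (ms1_every > 0) floor(n_win / ms1_every) else 0L
  scans_per_cycle <- n_win + n_ms1
  noiseless <- is.null(noise) ||
    (noise$shot_factor == 0 && noise$chemical_rate == 0)

  spectra <- vector("list", length(cycle_starts) * scans_per_cycle)
  si <- 0L
  planted_tic <- 0
  for (ci in seq_along(cycle_starts)) {
    t0 <- cycle_starts[ci]
    pos <- 0L
    ms2_done <- 0L
    for (wi in seq_len(n_win)) {
      rt <- if (rt_mode == "cycle") t0 else t0 + pos * cycle_s / scans_per_cycle
      idx <- pep_by_window[[wi]]
      mzv <- numeric(0); inv <- numeric(0)
      for (p in idx) {
        g <- tab$abundance[p] *
          exp(-((rt - tab$apex_rt[p])^2) / (2 * sd_s^2))
        if (g <= 0) next
        fr <- peptides$fragments[[tab$key[p]]]
        mzv <- c(mzv, fr$mz)
        inv <- c(inv, fr$rel_intensity * g)
      }
      planted_tic <- planted_tic + sum(inv)
      if (!noiseless && length(inv) && noise$shot_factor > 0) {
        inv <- pmax(0, inv + stats::rnorm(length(inv),
                                          0, sqrt(noise$shot_factor * inv)))
      }
      if (!noiseless && noise$chemical_rate > 0) {
        k <- stats::rpois(1, noise$chemical_rate)
        if (k > 0) {
          mzv <- c(mzv, stats::runif(k, 300, 1800))
          inv <- c(inv, stats::rexp(k, 1 / noise$chemical_mean))
        }
      }
      keep <- inv > 0
      si <- si + 1L
      spectra[[si]] <- list(ms_level = 2, rt = rt, cycle = ci,
                            window = wi,
                            peaks = cbind(mz = mzv[keep],
                                          intensity = inv[keep]))
      pos <- pos + 1L
      ms2_done <- ms2_done + 1L
      if (ms1_every > 0 && ms2_done %% ms1_every == 0) {
        rt1 <- if (rt_mode == "cycle") t0 else
          t0 + pos * cycle_s / scans_per_cycle
        g <- tab$abundance * exp(-((rt1 - tab$apex_rt)^2) / (2 * sd_s^2))
        keep <- g > 0
        si <- si + 1L
        spectra[[si]] <- list(ms_level = 1, rt = rt1, cycle = ci,
                              window = NA_integer_,
                              peaks = cbind(mz = tab$precursor_mz[keep],
                                            intensity = g[keep]))
        pos <- pos + 1L
      }
    }
  }
  spectra <- spectra[seq_len(si)]
  new_dia_run(spectra, scheme, rt_map = rt_map,
              metadata = list(seed = seed, cycle_ms = cycle_ms,
                              peak_fwhm_s = peak_fwhm_s,
                              gradient_minutes = gradient_minutes,
                              excluded_out_of_range = n_excluded,
                              planted_tic = planted_tic,
                              noiseless = noiseless,
                              run_id = sprintf("run-seed%d", seed)))
}

#' Simulate one run per gas-phase fractionation segment
#'
#' @param peptides A `PeptideSet`.
#' @param plan A `GPFPlan` from [build_gpf_plan()].
#' @param seed Base seed; segment k uses `seed + k - 1`.
#' @param ... Passed to [simulate_run()] (shared elution model across runs).
#' @return List of `DiaRun`, one per segment.
#' @export
simulate_gpf_runs <- function(peptides, plan, seed = 1L, ...) {
  stopifnot(inherits(plan, "GPFPlan"))
  lapply(seq_along(plan$segments), function(k) {
    run <- simulate_run(peptides, plan$segments[[k]]$scheme,
                        seed = seed + k - 1L, ...)
    run$metadata$segment <- k
    run$metadata$run_id <- sprintf("gpf%d-seed%d", k, seed)
    run
  })
}

#' Simulate a two-group label-free study
#'
#' Emulates a two-group (e.g. normal vs impaired glucose tolerance) design:
#' protein base abundances are log-normal; a fraction `frac_de` of proteins
#' is shifted by `log2fc` (random sign) in group B; per-sample biological
#' variation is log-normal with coefficient of variation `cv_within` at the
#' protein level, identical for all peptides of a protein; fragment areas add
#' a small log-normal measurement error. Peptides whose abundance falls
#' below `detection_floor` in a sample are missing there.
#'
#' By default the study is generated at the quantification level (a long
#' fragment-area table ready for [normalize_ms2()] and [rollup_top3()]);
#' full raw runs for each sample can be materialized with
#' `materialize_runs = TRUE` for small designs.
#'
#' @param n_samples_a,n_samples_b Group sizes (default 26 and 22 samples).
#' @param frac_de Fraction of proteins with a planted effect.
#' @param log2fc Planted log2 fold change magnitude (default 0.585, i.e. a
#'   50% expression difference).
#' @param cv_within Within-group biological CV at the protein level.
#' @param seed Integer seed.
#' @param n_proteins Number of synthetic proteins.
#' @param peptides Optional pre-built `PeptideSet` (overrides `n_proteins`).
#' @param cv_measurement CV of the fragment-level measurement error.
#' @param detection_floor Per-sample peptide detection limit (intensity).
#' @param materialize_runs If `TRUE`, also simulate a `DiaRun` per sample.
#' @param scheme Scheme for materialized runs (default 400--1000, 24 Th).
#' @param ... Passed to [simulate_run()] when materializing.
#' @return List with `fragment_table` (long data frame: `sample`, `group`,
#'   `protein_id`, `key`, `fragment`, `area`), `ground_truth` (list with the
#'   peptide table, `sample_abundances` peptide-by-sample matrix,
#'   `group_labels`, `de_table` of planted signed log2 fold changes, `seed`)
#'   and `runs` (`NULL` unless materialized).
#' @export
simulate_two_group_study <- function(n_samples_a = 26L, n_samples_b = 22L,
                                     frac_de = 0.1, log2fc = 0.585,
                                     cv_within = 0.2, seed = 1L,
                                     n_proteins = 100L, peptides = NULL,
                                     cv_measurement = 0.05,
                                     detection_floor = 5e4,
                                     materialize_runs = FALSE,
                                     scheme = NULL, ...) {
  stopifnot(n_samples_a >= 1, n_samples_b >= 1,
            frac_de >= 0, frac_de <= 1)
  set.seed(seed)
  if (is.null(peptides)) {
    peptides <- generate_peptides(n_proteins = n_proteins,
                                  seed = seed + 1000L)
  }
  tab <- peptides$table
  prots <- unique(tab$protein_id)
  n_de <- round(frac_de * length(prots))
  de_prots <- if (n_de > 0) sample(prots, n_de) else character(0)
  de_lfc <- stats::setNames(rep(0, length(prots)), prots)
  if (n_de > 0) {
    de_lfc[de_prots] <- log2fc * sample(c(-1, 1), n_de, replace = TRUE)
  }

  samples <- c(sprintf("A%02d", seq_len(n_samples_a)),
               sprintf("B%02d", seq_len(n_samples_b)))
  groups <- stats::setNames(rep(c("A", "B"), c(n_samples_a, n_samples_b)),
                            samples)
  sig_bio <- sqrt(log(1 + cv_within^2))
  sig_meas <- sqrt(log(1 + cv_measurement^2))

  # protein-level per-sample factors (biology + planted effect)
  prot_factor <- matrix(
    exp(stats::rnorm(length(prots) * length(samples), 0, sig_bio)),
    nrow = length(prots), dimnames = list(prots, samples))
  inB <- groups == "B"
  prot_factor[, inB] <- prot_factor[, inB] * 2^de_lfc[prots]

  pep_abund <- matrix(tab$abundance, nrow = nrow(tab),
                      ncol = length(samples),
                      dimnames = list(tab$key, samples))
  pep_abund <- pep_abund * prot_factor[tab$protein_id, , drop = FALSE]
  pep_abund[pep_abund < detection_floor] <- NA_real_

  # long fragment-area table
  frag_rows <- lapply(seq_len(nrow(tab)), function(i) {
    fr <- peptides$fragments[[tab$key[i]]]
    obs <- pep_abund[i, ]
    present <- which(!is.na(obs))
    if (!length(present)) return(NULL)
    nf <- nrow(fr)
    data.frame(
      sample = rep(samples[present], each = nf),
      group = rep(groups[present], each = nf),
      protein_id = tab$protein_id[i],
      key = tab$key[i],
      fragment = rep(paste0(fr$type, fr$index), length(present)),
      area = as.vector(outer(fr$rel_intensity, obs[present])) *
        exp(stats::rnorm(nf * length(present), 0, sig_meas))
    )
  })
  fragment_table <- do.call(rbind, frag_rows)
  rownames(fragment_table) <- NULL

  runs <- NULL
  if (isTRUE(materialize_runs)) {
    if (is.null(scheme)) scheme <- build_staggered_scheme(400, 1000, 24)
    runs <- lapply(seq_along(samples), function(s) {
      run <- simulate_run(peptides, scheme,
                          abundances = pep_abund[, s],
                          seed = seed + 100L + s, ...)
      run$metadata$sample <- samples[s]
      run
    })
    names(runs) <- samples
  }

  list(
    fragment_table = fragment_table,
    ground_truth = list(
      peptides = peptides,
      sample_abundances = pep_abund,
      group_labels = groups,
      de_table = data.frame(protein_id = prots, log2fc = de_lfc[prots],
                            is_de = prots %in% de_prots),
      seed = seed
    ),
    runs = runs
  )
}
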