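#' Robust affine iRT calibration
#'
#' Fits `rt = intercept + slope * irt` from anchor pairs. With five or more
#' anchors the fit is least absolute deviations (iteratively reweighted least
#' squares), which resists single mis-assigned anchors; with three or four
#' anchors it falls back to ordinary least squares. The residual standard
#' deviation feeds the extracted-ion-chromatogram (XIC) window width.
#'
#' @param anchors Data frame with columns `irt` and `rt` (seconds).
#' @return An `RTCalibration`: list with `slope`, `intercept`, `residual_sd`
#'   and `n_anchors`.
#' @export
calibrate_irt <- function(anchors) {
  anchors <- anchors[stats::complete.cases(anchors[, c("irt", "rt")]), ]
  n <- nrow(anchors)
  if (n < 3) stop("at least 3 anchors are required", call. = FALSE)
  if (stats::sd(anchors$irt) < 1e-12) {
    stop("degenerate anchors: iRT values are collinear", call. = FALSE)
  }
  x <- anchors$irt; y <- anchors$rt
  fit <- stats::lm.fit(cbind(1, x), y)
  beta <- fit$coefficients
  if (n >= 5) {
    for (it in 1:50) {
      r <- y - beta[1] - beta[2] * x
      w <- 1 / pmax(abs(r), 1e-8)
      beta_new <- stats::lm.wfit(cbind(1, x), y, w)$coefficients
      if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
      beta <- beta_new
    }
  }
  r <- y - beta[1] - beta[2] * x
  structure(list(slope = unname(beta[2]), intercept = unname(beta[1]),
                 residual_sd = stats::sd(r), n_anchors = n),
            class = "RTCalibration")
}

predict_rt <- function(cal, irt) cal$intercept + cal$slope * irt

# Observed elution apex of a set of fragment channels in a raw run: retention
# time of the scan (within windows covering the precursor) with the highest
# summed fragment-matched intensity.
observed_apex_rt <- function(run, fragment_mz, precursor, tol_ppm = 10) {
  w <- run$scheme$windows
  cover <- which(precursor >= w$nominal_lower & precursor < w$nominal_upper)
  best_rt <- NA_real_; best <- 0
  for (s in ms2_spectra(run)) {
    if (!(s$window %in% cover) || !nrow(s$peaks)) next
    tot <- sum_matched(s$peaks, fragment_mz, tol_ppm)
    if (tot > best) { best <- tot; best_rt <- s$rt }
  }
  list(rt = best_rt, intensity = best)
}

sum_matched <- function(peaks, targets, tol_ppm) {
  if (!nrow(peaks) || !length(targets)) return(0)
  tot <- 0
  for (t in targets) {
    d <- abs(peaks[, "mz"] - t)
    tot <- tot + sum(peaks[d <= t * tol_ppm * 1e-6, "intensity"])
  }
  tot
}

#' Assemble an ion-chromatogram library
#'
#' Pools library entries across fraction runs (gas-phase or offline
#' fractions), uniting them on the (sequence, charge) key and recording each
#' entry's source runs. Retention-time calibration is fit on iRT anchors from
#' the fraction runs; when unfractionated whole-sample (`mixed`) runs are
#' supplied — the hybrid-library mode — the calibration is refit on the mixed
#' runs only, which removes between-fraction retention drift from the
#' residuals and narrows the XIC extraction window:
#' `xic_window_minutes = 2 * k * residual SD` (floored at
#' `min_window_minutes`).
#'
#' In synthetic mode the entry source is the simulator's `PeptideSet`; an
#' entry enters the library if its precursor falls in the window coverage of
#' at least one fraction run. Externally searched libraries can be imported
#' with [read_library_tsv()].
#'
#' @param fraction_runs List of `DiaRun` (one per fraction/segment).
#' @param peptides The `PeptideSet` entry source.
#' @param mixed_runs Optional list of whole-sample `DiaRun`s (hybrid mode).
#' @param k Half-width multiple of the residual SD (default 3).
#' @param n_anchors Calibration anchors taken per run (most abundant
#'   detectable peptides).
#' @param tol_ppm Fragment tolerance for apex location.
#' @param min_window_minutes Lower bound on the XIC window (min).
#' @return An `IonLibrary`: list with `entries` (data frame), `fragments`
#'   (per-key data frames), `rt_cal`, `xic_window_minutes`, `mode` and
#'   `provenance`.
#' @export
assemble_library <- function(fraction_runs, peptides, mixed_runs = NULL,
                             k = 3, n_anchors = 11L, tol_ppm = 10,
                             min_window_minutes = 0.5) {
  if (!length(fraction_runs)) stop("at least one source run is required",
                                   call. = FALSE)
  tab <- peptides$table
  prov <- vector("list", nrow(tab))
  covered <- rep(FALSE, nrow(tab))
  for (run in fraction_runs) {
    cov <- scheme_coverage(run$scheme)
    hit <- tab$precursor_mz >= cov[1] & tab$precursor_mz < cov[2]
    covered <- covered | hit
    rid <- run$metadata$run_id
    for (i in which(hit)) prov[[i]] <- c(prov[[i]], rid)
  }
  entries <- tab[covered, , drop = FALSE]
  prov <- prov[covered]
  # unique keys: duplicates across fractions collapse (first kept,
  # provenance merged)
  dup <- duplicated(entries$key)
  if (any(dup)) {
    for (key in unique(entries$key[dup])) {
      ii <- which(entries$key == key)
      prov[[ii[1]]] <- unique(unlist(prov[ii]))
    }
    entries <- entries[!dup, , drop = FALSE]
    prov <- prov[!dup]
  }
  rownames(entries) <- NULL
  entries$provenance <- vapply(prov, function(p) paste(unique(p), collapse = ";"),
                               character(1))

  cal_runs <- if (length(mixed_runs)) mixed_runs else fraction_runs
  anchors <- do.call(rbind, lapply(cal_runs, function(run) {
    cov <- scheme_coverage(run$scheme)
    cand <- tab[tab$precursor_mz >= cov[1] & tab$precursor_mz < cov[2], ]
    cand <- cand[order(-cand$abundance), , drop = FALSE]
    cand <- cand[seq_len(min(n_anchors, nrow(cand))), , drop = FALSE]
    res <- lapply(seq_len(nrow(cand)), function(i) {
      ap <- observed_apex_rt(run, peptides$fragments[[cand$key[i]]]$mz,
                             cand$precursor_mz[i], tol_ppm)
      if (is.na(ap$rt)) return(NULL)
      data.frame(irt = cand$irt[i], rt = ap$rt)
    })
    do.call(rbind, res)
  }))
  if (is.null(anchors) || nrow(anchors) < 3) {
    stop("not enough detectable calibration anchors", call. = FALSE)
  }
  cal <- calibrate_irt(anchors)
  xic_window <- max(2 * k * cal$residual_sd / 60, min_window_minutes)

  structure(list(
    entries = entries,
    fragments = peptides$fragments[entries$key],
    rt_cal = cal,
    xic_window_minutes = xic_window,
    mode = if (length(mixed_runs)) "hybrid" else "fraction",
    provenance = list(
      fraction_runs = vapply(fraction_runs,
                             function(r) r$metadata$run_id %||% "", ""),
      mixed_runs = vapply(mixed_runs %||% list(),
                          function(r) r$metadata$run_id %||% "", ""))
  ), class = "IonLibrary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.IonLibrary <- function(x, ...) {
  cat(sprintf("IonLibrary (%s): %d entries, %d proteins, XIC window %.2f min\n",
              x$mode, nrow(x$entries), length(unique(x$entries$protein_id)),
              x$xic_window_minutes))
  invisible(x)
}

#' Extract per-fragment ion chromatograms
#'
#' For every library entry, collects the intensity trace of each library
#' fragment over the calibrated retention-time window. The input may be a
#' raw `DiaRun` (traces read from the isolation windows covering the
#' precursor, averaged per cycle) or the output of [demultiplex_run()]
#' (traces read from the half-width bin containing the precursor).
#'
#' @param x A `DiaRun` or a list of demultiplexed spectra.
#' @param library An `IonLibrary`.
#' @param tol_ppm Fragment match tolerance (ppm).
#' @return Named list (by entry key): each element has `rts` (scan times),
#'   `mat` (time-by-fragment intensity matrix) and `pred_rt`.
#' @export
extract_xics <- function(x, library, tol_ppm = 10) {
  stopifnot(inherits(library, "IonLibrary"))
  half <- library$xic_window_minutes * 60 / 2
  cal <- library$rt_cal

  if (inherits(x, "DiaRun")) {
    spectra <- ms2_spectra(x)
    lows <- x$scheme$windows$nominal_lower
    ups <- x$scheme$windows$nominal_upper
    spec_key <- vapply(spectra, function(s) s$window, numeric(1))
    covers <- function(pre) which(pre >= lows & pre < ups)
  } else {
    spectra <- x
    spec_key <- seq_along(spectra)
    blo <- vapply(spectra, function(s) s$bin_lower, numeric(1))
    bup <- vapply(spectra, function(s) s$bin_upper, numeric(1))
  }
  rts_all <- vapply(spectra, function(s) s$rt, numeric(1))

  out <- vector("list", nrow(library$entries))
  names(out) <- library$entries$key
  for (i in seq_len(nrow(library$entries))) {
    e <- library$entries[i, ]
    fr <- library$fragments[[e$key]]
    pred <- predict_rt(cal, e$irt)
    if (inherits(x, "DiaRun")) {
      sel <- which(rts_all >= pred - half & rts_all <= pred + half &
                     spec_key %in% covers(e$precursor_mz))
    } else {
      sel <- which(rts_all >= pred - half & rts_all <= pred + half &
                     e$precursor_mz >= blo & e$precursor_mz < bup)
    }
    if (!length(sel)) {
      out[[i]] <- list(rts = numeric(0),
                       mat = matrix(0, 0, nrow(fr)), pred_rt = pred)
      next
    }
    tr <- matrix(0, length(sel), nrow(fr))
    for (j in seq_along(sel)) {
      pk <- spectra[[sel[j]]]$peaks
      if (!nrow(pk)) next
      for (f in seq_len(nrow(fr))) {
        d <- abs(pk[, "mz"] - fr$mz[f])
        tr[j, f] <- sum(pk[d <= fr$mz[f] * tol_ppm * 1e-6, "intensity"])
      }
    }
    # average duplicate time points (two covering windows per cycle)
    t_sel <- rts_all[sel]
    if (anyDuplicated(t_sel)) {
      ut <- sort(unique(t_sel))
      tr <- t(vapply(ut, function(tt)
        colMeans(tr[t_sel == tt, , drop = FALSE]), numeric(ncol(tr))))
      if (ncol(fr) == 1) tr <- matrix(tr, ncol = nrow(fr))
      t_sel <- ut
    } else {
      ord <- order(t_sel)
      tr <- tr[ord, , drop = FALSE]
      t_sel <- t_sel[ord]
    }
    out[[i]] <- list(rts = t_sel, mat = tr, pred_rt = pred)
  }
  out
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

coelution_score <- function(mat) {
  if (nrow(mat) < 3 || ncol(mat) < 2) return(1)
  cors <- c()
  for (i in seq_len(ncol(mat) - 1)) {
    for (j in (i + 1):ncol(mat)) {
      si <- stats::sd(mat[, i]); sj <- stats::sd(mat[, j])
      cors <- c(cors, if (si == 0 || sj == 0) 0 else
        stats::cor(mat[, i], mat[, j]))
    }
  }
  max(0, min(1, mean(cors)))
}

score_xic <- function(xic, rel_intensity) {
  if (!nrow(xic$mat) || sum(xic$mat) == 0) {
    return(list(score = 0, apex_rt = NA_real_,
                areas = rep(0, length(rel_intensity))))
  }
  tot <- rowSums(xic$mat)
  apex <- which.max(tot)
  areas <- colSums(xic$mat)
  list(score = cosine_sim(rel_intensity, areas) * coelution_score(xic$mat),
       apex_rt = xic$rts[apex], areas = areas)
}

#' Build a decoy library by fragment shifting and intensity shuffling
#'
#' Decoys keep each target's precursor coordinates and retention time but
#' shift every fragment m/z by `shift * copy` Th and permute the relative
#' intensities, preserving the length/charge structure of the target space.
#'
#' @param library An `IonLibrary`.
#' @param copy Decoy copy index (1..decoy_factor).
#' @param shift Base m/z shift (Th).
#' @param seed Seed for the intensity permutations.
#' @return An `IonLibrary` of decoy entries (keys suffixed `_DECOYi`).
#' @export
decoy_library <- function(library, copy = 1L, shift = 10, seed = 1L) {
  set.seed(seed + copy)
  lib <- library
  lib$entries$key <- paste0(library$entries$key, "_DECOY", copy)
  frs <- lapply(library$fragments, function(fr) {
    fr$mz <- fr$mz + shift * copy
    fr$rel_intensity <- sample(fr$rel_intensity)
    fr
  })
  names(frs) <- lib$entries$key
  lib$fragments <- frs
  lib
}

#' Score precursors and estimate q-values by target-decoy competition
#'
#' Each library entry is scored against its extracted chromatograms: the
#' cosine similarity between the library fragment intensity pattern and the
#' observed fragment areas, multiplied by a co-elution term (the mean
#' pairwise Pearson correlation of the fragment traces, clamped to [0, 1]).
#' Decoy entries (shifted fragments, shuffled intensities; see
#' [decoy_library()]) are scored identically, and the q-value at score `s`
#' is `(#decoys >= s) / decoy_factor / (#targets >= s)`, monotonized.
#' Ties are broken deterministically by entry key.
#'
#' @param x A `DiaRun` or demultiplexed spectra list.
#' @param library An `IonLibrary`.
#' @param tol_ppm Fragment tolerance (ppm).
#' @param decoy_factor Decoy copies per target (>= 1).
#' @param q_cutoff Acceptance threshold (default 0.01, the universal 1% FDR
#'   cutoff).
#' @param decoy_shift Base decoy fragment shift (Th).
#' @param seed Seed for decoy intensity shuffles.
#' @param run_id Run identifier stored on the identifications.
#' @return Data frame of target identifications (`key`, `protein_id`,
#'   `run_id`, `apex_rt`, `score`, `q_value`, `accepted`) sorted by
#'   decreasing score, with the decoy score table in `attr(, "decoys")` and
#'   per-target fragment areas in `attr(, "areas")`.
#' @export
score_and_fdr <- function(x, library, tol_ppm = 10, decoy_factor = 1L,
                          q_cutoff = 0.01, decoy_shift = 10, seed = 1L,
                          run_id = NULL) {
  if (decoy_factor < 1) stop("decoy_factor must be >= 1 (no decoys generated)",
                             call. = FALSE)
  if (is.null(run_id)) {
    run_id <- if (inherits(x, "DiaRun")) x$metadata$run_id %||% "run" else "run"
  }
  xt <- extract_xics(x, library, tol_ppm)
  tgt <- lapply(seq_len(nrow(library$entries)), function(i) {
    key <- library$entries$key[i]
    sc <- score_xic(xt[[key]], library$fragments[[key]]$rel_intensity)
    list(key = key, score = sc$score, apex_rt = sc$apex_rt, areas = sc$areas)
  })
  dec_scores <- numeric(0)
  for (cp in seq_len(decoy_factor)) {
    dl <- decoy_library(library, copy = cp, shift = decoy_shift, seed = seed)
    xd <- extract_xics(x, dl, tol_ppm)
    dec_scores <- c(dec_scores, vapply(seq_len(nrow(dl$entries)), function(i) {
      key <- dl$entries$key[i]
      score_xic(xd[[key]], dl$fragments[[key]]$rel_intensity)$score
    }, numeric(1)))
  }

  ids <- data.frame(
    key = vapply(tgt, `[[`, "", "key"),
    run_id = run_id,
    apex_rt = vapply(tgt, function(t) t$apex_rt, numeric(1)),
    score = vapply(tgt, function(t) t$score, numeric(1))
  )
  ids$protein_id <- library$entries$protein_id[match(ids$key,
                                                     library$entries$key)]
  ids <- ids[order(-ids$score, ids$key), , drop = FALSE]
  # q-values by target-decoy competition, monotone in score rank
  n_dec_ge <- vapply(ids$score, function(s) sum(dec_scores >= s), numeric(1))
  raw_q <- (n_dec_ge / decoy_factor) / pmax(1, seq_len(nrow(ids)))
  ids$q_value <- rev(cummin(rev(pmin(raw_q, 1))))
  ids$accepted <- ids$q_value <= q_cutoff & ids$score > 0
  rownames(ids) <- NULL
  areas <- stats::setNames(lapply(tgt, `[[`, "areas"),
                           vapply(tgt, `[[`, "", "key"))
  attr(ids, "areas") <- areas
  attr(ids, "decoys") <- data.frame(score = sort(dec_scores, decreasing = TRUE))
  ids
}

#' Fragment-area table from accepted identifications
#'
#' Converts the per-target fragment areas attached by [score_and_fdr()] into
#' a long table suitable for [normalize_ms2()] and [rollup_top3()].
#'
#' @param ids Identifications from [score_and_fdr()].
#' @param library The `IonLibrary` used for scoring.
#' @param sample Sample label for the `sample` column.
#' @param accepted_only Keep only identifications at the q-value cutoff.
#' @return Data frame with `sample`, `protein_id`, `key`, `fragment`, `area`.
#' @export
id_fragment_table <- function(ids, library, sample = "S1",
                              accepted_only = TRUE) {
  areas <- attr(ids, "areas")
  use <- if (accepted_only) ids$key[ids$accepted] else ids$key
  rows <- lapply(use, function(key) {
    fr <- library$fragments[[key]]
    a <- areas[[key]]
    if (is.null(a) || sum(a) == 0) return(NULL)
    data.frame(sample = sample,
               protein_id = library$entries$protein_id[
                 match(key, library$entries$key)],
               key = key, fragment = paste0(fr$type, fr$index), area = a)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a transition-list library TSV
#'
#' One row per fragment: `sequence`, `modification`, `charge`,
#' `precursor_mz`, `irt`, `protein_id`, `fragment_type`, `fragment_index`,
#' `fragment_mz`, `rel_intensity`. Round-trips an `IonLibrary` losslessly up
#' to the retention-time calibration, which is stored in a sidecar header
#' comment line.
#'
#' @param library An `IonLibrary`.
#' @param path TSV file path.
#' @return `path` (write) or an `IonLibrary` (read).
#' @export
write_library_tsv <- function(library, path) {
  rows <- lapply(seq_len(nrow(library$entries)), function(i) {
    e <- library$entries[i, ]
    fr <- library$fragments[[e$key]]
    data.frame(sequence = e$sequence, modification = "", charge = e$charge,
               precursor_mz = e$precursor_mz, irt = e$irt,
               protein_id = e$protein_id, fragment_type = fr$type,
               fragment_index = fr$index, fragment_mz = fr$mz,
               rel_intensity = fr$rel_intensity)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rt_cal slope=%.10g intercept=%.10g residual_sd=%.10g xic_window_minutes=%.10g mode=%s",
                     library$rt_cal$slope, library$rt_cal$intercept,
                     library$rt_cal$residual_sd, library$xic_window_minutes,
                     library$mode), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  header <- readLines(path, n = 1)
  tab <- utils::read.delim(path, comment.char = "#")
  tab$modification[is.na(tab$modification)] <- ""
  key <- paste0(tab$sequence, "/", tab$charge)
  keys <- unique(key)
  entries <- tab[!duplicated(key),
                 c("sequence", "charge", "precursor_mz", "irt", "protein_id")]
  entries$key <- keys
  entries$provenance <- ""
  rownames(entries) <- NULL
  fragments <- lapply(keys, function(k) {
    f <- tab[key == k, c("fragment_type", "fragment_index", "fragment_mz",
                         "rel_intensity")]
    data.frame(type = f$fragment_type, index = f$fragment_index,
               mz = f$fragment_mz, rel_intensity = f$rel_intensity)
  })
  names(fragments) <- keys
  num <- function(field) as.numeric(sub(sprintf(".*%s=([-0-9.e+]+).*", field),
                                        "\\1", header))
  structure(list(
    entries = entries, fragments = fragments,
    rt_cal = structure(list(slope = num("slope"), intercept = num("intercept"),
                            residual_sd = num("residual_sd"), n_anchors = NA),
                       class = "RTCalibration"),
    xic_window_minutes = num("xic_window_minutes"),
    mode = sub(".*mode=(\\S+).*", "\\1", header),
    provenance = list()
  ), class = "IonLibrary")
}
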