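#' Map isolation windows to demultiplexing bins
#'
#' Derives, from the scheme geometry alone, which half-width demux bins each
#' window covers (one or two per window, using the nominal unsnapped edges
#' and half-open intervals).
#'
#' @param scheme A `WindowScheme`.
#' @return A `BinMap`: list with `window_bins` (list, per window order index,
#'   of covered bin indices into `scheme$demux_bins`) and `bin_windows` (the
#'   inverse map).
#' @export
build_bin_map <- function(scheme) {
  stopifnot(inherits(scheme, "WindowScheme"))
  w <- scheme$windows
  b <- scheme$demux_bins
  window_bins <- lapply(seq_len(nrow(w)), function(i) {
    which(b$lower >= w$nominal_lower[i] - 1e-9 &
            b$upper <= w$nominal_upper[i] + 1e-9)
  })
  bin_windows <- lapply(seq_len(nrow(b)), function(j) {
    which(vapply(window_bins, function(v) j %in% v, logical(1)))
  })
  structure(list(window_bins = window_bins, bin_windows = bin_windows),
            class = "BinMap")
}

# Greedy m/z channel clustering: sort peaks by m/z and split where the gap to
# the previous peak exceeds the ppm tolerance. Centroids are
# intensity-weighted means. Deterministic, so re-grouping at the same
# tolerance reproduces the same channels.
group_channels <- function(mz, tol_ppm) {
  ord <- order(mz)
  mzs <- mz[ord]
  cl <- integer(length(mzs))
  if (length(mzs)) {
    cl[1] <- 1L
    for (i in seq_along(mzs)[-1]) {
      cl[i] <- if ((mzs[i] - mzs[i - 1]) <= mzs[i - 1] * tol_ppm * 1e-6)
        cl[i - 1] else cl[i - 1] + 1L
    }
  }
  out <- integer(length(mz))
  out[ord] <- cl
  out
}

# Linear interpolation of one window's channel intensities to time t from its
# measurements (rt1, peaks1) and (rt2, peaks2); channel matching at tol_ppm.
interp_window <- function(rt1, peaks1, rt2, peaks2, t, tol_ppm) {
  if (is.null(peaks2) || rt2 == rt1) return(peaks1)
  w <- (t - rt1) / (rt2 - rt1)
  mz <- c(peaks1[, "mz"], peaks2[, "mz"])
  if (!length(mz)) return(empty_peaks())
  src <- rep(1:2, c(nrow(peaks1), nrow(peaks2)))
  int <- c(peaks1[, "intensity"], peaks2[, "intensity"])
  cl <- group_channels(mz, tol_ppm)
  res <- lapply(split(seq_along(mz), cl), function(ii) {
    i1 <- sum(int[ii][src[ii] == 1])
    i2 <- sum(int[ii][src[ii] == 2])
    c(stats::weighted.mean(mz[ii], pmax(int[ii], 1e-12)),
      max(0, i1 * (1 - w) + i2 * w))
  })
  m <- do.call(rbind, res)
  colnames(m) <- c("mz", "intensity")
  m[m[, "intensity"] > 0, , drop = FALSE]
}

# Non-negative least squares by the Lawson-Hanson active-set algorithm.
# Tolerances are scaled to the problem so exactly tied measurements (common
# in noiseless staggered data, where both covering windows read the same
# value) terminate cleanly.
nnls_solve <- function(A, y, itmax = 50L * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  P <- logical(n)
  w <- as.numeric(crossprod(A, y))
  tol <- 1e-10 * max(1, max(abs(w)))
  it <- 0L
  while (any(!P) && max(w[!P]) > tol && it < itmax) {
    it <- it + 1L
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- numeric(n)
      fit <- stats::lm.fit(A[, P, drop = FALSE], y)
      cz <- fit$coefficients
      cz[is.na(cz)] <- 0  # aliased columns in rank-deficient passive sets
      z[P] <- cz
      if (all(z[P] > tol)) break
      neg <- P & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      P[P & x <= tol] <- FALSE
      if (!any(P)) { z <- numeric(n); break }
    }
    x <- z
    w <- as.numeric(crossprod(A, y - A %*% x))
  }
  pmax(x, 0)
}

solve_nnls <- function(A, y, ridge = 1e-6) {
  sol <- tryCatch(nnls_solve(A, y), error = function(e) NULL)
  if (is.null(sol)) {
    # degenerate fallback: ridge-regularized normal equations, clipped
    lam <- ridge * max(abs(y), 1)
    sol <- solve(crossprod(A) + lam * diag(ncol(A)), crossprod(A, y))
    sol <- pmax(0, as.numeric(sol))
  }
  sol
}

#' Demultiplex a staggered-window run onto half-width bins
#'
#' For each acquisition cycle, every window's fragment channels are brought
#' to the cycle reference time (the cycle's first scan) by linear
#' interpolation between that window's two temporally nearest measurements;
#' channels are then grouped across windows at `tol_ppm`, and for each
#' channel the per-bin intensities are solved by non-negative least squares
#' `min ||Ax - y||^2, x >= 0`, where `A` is the window-to-bin incidence
#' restricted to the bins of the windows in which the channel was observed.
#' Bins covered by a single window are thereby solved directly from that
#' window. Intensities below `noise_floor` are zeroed.
#'
#' @param run A `DiaRun` whose MS2 spectra carry window order indices
#'   matching `scheme`.
#' @param scheme The `WindowScheme` the run was acquired with.
#' @param tol_ppm Fragment channel grouping tolerance (ppm).
#' @param noise_floor Post-solve intensity floor (0 disables).
#' @param ridge Relative ridge penalty used only when the NNLS solver fails
#'   on a degenerate system (the spectrum is then flagged).
#' @param keep_edge_bins Also emit the two half-width bins outside the
#'   precursor range.
#' @return List of demultiplexed spectra, each a list with `bin`,
#'   `bin_lower`, `bin_upper`, `rt`, `cycle` and `peaks` (all intensities
#'   non-negative).
#' @export
demultiplex_run <- function(run, scheme, tol_ppm = 10, noise_floor = 0,
                            ridge = 1e-6, keep_edge_bins = TRUE) {
  stopifnot(inherits(run, "DiaRun"), inherits(scheme, "WindowScheme"))
  bm <- build_bin_map(scheme)
  bins <- scheme$demux_bins
  n_win <- nrow(scheme$windows)
  ms2 <- ms2_spectra(run)
  if (!length(ms2)) return(list())
  wins <- vapply(ms2, function(s) s$window, numeric(1))
  if (any(is.na(wins)) || any(wins < 1 | wins > n_win)) {
    stop("MS2 window annotation does not match the scheme", call. = FALSE)
  }
  cycles <- vapply(ms2, function(s) s$cycle, numeric(1))
  rts <- vapply(ms2, function(s) s$rt, numeric(1))
  cyc_ids <- sort(unique(cycles))

  # index scans by (cycle, window)
  scan_lookup <- matrix(NA_integer_, nrow = length(cyc_ids), ncol = n_win)
  for (i in seq_along(ms2)) {
    scan_lookup[match(cycles[i], cyc_ids), wins[i]] <- i
  }

  out <- list()
  for (ci in seq_along(cyc_ids)) {
    row <- scan_lookup[ci, ]
    if (anyNA(row)) {
      warning(sprintf("cycle %d incomplete (missing windows); skipped",
                      cyc_ids[ci]))
      next
    }
    t_ref <- min(rts[row])
    # per-window channel table at t_ref
    win_peaks <- vector("list", n_win)
    for (wi in seq_len(n_win)) {
      cur <- ms2[[row[wi]]]
      if (abs(cur$rt - t_ref) < 1e-9) {
        win_peaks[[wi]] <- cur$peaks
      } else {
        # bracket t_ref with the same window's scan in the previous cycle
        prev <- if (ci > 1 && !is.na(scan_lookup[ci - 1, wi]))
          ms2[[scan_lookup[ci - 1, wi]]] else NULL
        win_peaks[[wi]] <- if (is.null(prev)) cur$peaks else
          interp_window(prev$rt, prev$peaks, cur$rt, cur$peaks,
                        t_ref, tol_ppm)
      }
    }
    np <- vapply(win_peaks, nrow, integer(1))
    if (sum(np) == 0) next
    all_mz <- unlist(lapply(win_peaks, function(p) p[, "mz"]))
    all_int <- unlist(lapply(win_peaks, function(p) p[, "intensity"]))
    all_win <- rep(seq_len(n_win), np)
    ch <- group_channels(all_mz, tol_ppm)

    bin_acc <- vector("list", nrow(bins))
    for (g in split(seq_along(ch), ch)) {
      obs_win <- unique(all_win[g])
      cand_bins <- sort(unique(unlist(bm$window_bins[obs_win])))
      sys_win <- sort(unique(unlist(bm$bin_windows[cand_bins])))
      A <- matrix(0, nrow = length(sys_win), ncol = length(cand_bins))
      for (r in seq_along(sys_win)) {
        A[r, match(intersect(bm$window_bins[[sys_win[r]]], cand_bins),
                   cand_bins)] <- 1
      }
      y <- numeric(length(sys_win))
      for (k in g) {
        y[match(all_win[k], sys_win)] <-
          y[match(all_win[k], sys_win)] + all_int[k]
      }
      x <- solve_nnls(A, y, ridge = ridge)
      cmz <- stats::weighted.mean(all_mz[g], pmax(all_int[g], 1e-12))
      for (j in seq_along(cand_bins)) {
        if (x[j] > noise_floor && x[j] > 0) {
          bin_acc[[cand_bins[j]]] <-
            rbind(bin_acc[[cand_bins[j]]], c(cmz, x[j]))
        }
      }
    }
    for (b in seq_len(nrow(bins))) {
      if (!keep_edge_bins && !bins$in_range[b]) next
      pk <- bin_acc[[b]]
      if (is.null(pk)) pk <- empty_peaks() else {
        colnames(pk) <- c("mz", "intensity")
        pk <- pk[order(pk[, "mz"]), , drop = FALSE]
      }
      out[[length(out) + 1L]] <- list(
        bin = b, bin_lower = bins$lower[b], bin_upper = bins$upper[b],
        rt = t_ref, cycle = cyc_ids[ci], peaks = pk)
    }
  }
  out
}
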