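# Averagine mass spacing between consecutive peptide nominal masses (Th per Da).
AVERAGINE_DELTA <- 1.00045475

#' Build a staggered-window DIA isolation scheme
#'
#' Constructs one acquisition cycle of staggered isolation windows: two
#' interleaved banks of constant-width windows offset from each other by half
#' a window width (the stagger). Windows are acquired in ascending m/z order,
#' so the banks alternate scan-by-scan, and an MS1 survey scan is inserted
#' after every `ms1_every` MS2 scans. The scheme carries the half-width
#' demultiplexing bins that tile the precursor range.
#'
#' The window count convention is `n = span / stagger + 2`, where
#' `span = mz_max - mz_min`: window lower edges run from `mz_min - stagger`
#' to `mz_max` in steps of one stagger, so each bank holds `span/width + 1`
#' windows and the offset bank extends half a window below the precursor
#' range. For the classic 400--1000 m/z range with 24 m/z windows this gives
#' 52 windows per cycle (26 per bank).
#'
#' @param mz_min,mz_max Precursor m/z range to cover (Th).
#' @param width Isolation window width (Th). The stagger is `width/2`.
#' @param ms1_every Number of MS2 scans between MS1 survey scans (default 26,
#'   i.e. one survey per bank pass of the 52-window scheme).
#' @param snap_boundaries If `TRUE`, window edges are moved onto the nearest
#'   peptide forbidden-zone grid point (see [snap_to_forbidden_zone()]);
#'   demultiplexing geometry keeps the nominal (unsnapped) edges.
#' @param reference_charge Charge state used for forbidden-zone snapping.
#' @return A `WindowScheme` object: a list with `windows` (data frame with
#'   `lower_mz`, `upper_mz`, `nominal_lower`, `nominal_upper`, `bank`,
#'   `order`), `demux_bins` (half-width bins with an `in_range` flag),
#'   `mz_min`, `mz_max`, `width`, `stagger` and `ms1_every`.
#' @examples
#' sch <- build_staggered_scheme(400, 1000, 24)
#' nrow(sch$windows)  # 52
#' @export
build_staggered_scheme <- function(mz_min, mz_max, width, ms1_every = 26L,
                                   snap_boundaries = FALSE,
                                   reference_charge = 2L) {
  if (!is.finite(width) || width <= 0) {
    stop("window width must be positive", call. = FALSE)
  }
  if (mz_max <= mz_min) {
    stop("degenerate precursor range: mz_max must exceed mz_min", call. = FALSE)
  }
  stagger <- width / 2
  span <- mz_max - mz_min
  if (span < width) {
    stop("degenerate precursor range: span smaller than one window",
         call. = FALSE)
  }
  n_steps <- span / stagger
  if (abs(n_steps - round(n_steps)) > 1e-6) {
    stop("precursor span must be divisible by half the window width",
         call. = FALSE)
  }
  n_steps <- round(n_steps)

  lowers <- mz_min - stagger + stagger * seq_len(n_steps + 2L) - stagger
  # lowers run mz_min - stagger, mz_min, ..., mz_max
  uppers <- lowers + width
  # bank 0: windows aligned to mz_min; bank 1: offset by half a width
  bank <- ifelse(abs((lowers - mz_min) / width -
                       round((lowers - mz_min) / width)) < 1e-9, 0L, 1L)
  windows <- data.frame(
    lower_mz      = lowers,
    upper_mz      = uppers,
    nominal_lower = lowers,
    nominal_upper = uppers,
    bank          = bank,
    order         = seq_along(lowers)
  )
  if (isTRUE(snap_boundaries)) {
    windows$lower_mz <- vapply(windows$nominal_lower, snap_to_forbidden_zone,
                               numeric(1), reference_charge = reference_charge)
    windows$upper_mz <- vapply(windows$nominal_upper, snap_to_forbidden_zone,
                               numeric(1), reference_charge = reference_charge)
  }

  n_bins <- span / stagger
  bin_lower <- c(mz_min - stagger, mz_min + stagger * (seq_len(n_bins) - 1L),
                 mz_max)
  demux_bins <- data.frame(
    lower    = bin_lower,
    upper    = bin_lower + stagger,
    in_range = c(FALSE, rep(TRUE, n_bins), FALSE)
  )

  structure(list(
    windows = windows, demux_bins = demux_bins,
    mz_min = mz_min, mz_max = mz_max,
    width = width, stagger = stagger,
    ms1_every = as.integer(ms1_every)
  ), class = "WindowScheme")
}

#' @export
print.WindowScheme <- function(x, ...) {
  cat(sprintf(
    "WindowScheme: %d staggered windows of %.3g Th (stagger %.3g Th) over %.5g-%.5g m/z\n",
    nrow(x$windows), x$width, x$stagger, x$mz_min, x$mz_max))
  cat(sprintf("  %d demux bins (%d in range), MS1 every %d MS2 scans\n",
              nrow(x$demux_bins), sum(x$demux_bins$in_range), x$ms1_every))
  invisible(x)
}

#' Analyzable precursor coverage of a scheme
#'
#' The m/z range the scheme can demultiplex faithfully: the union of its
#' half-width demux bins, `[mz_min - stagger, mz_max + stagger)`. The
#' outermost window extends half a window further, but that sliver is covered
#' by no demux bin and is excluded from simulation and library assembly.
#'
#' @param scheme A `WindowScheme`.
#' @return Numeric length-2 vector `(lower, upper)`.
#' @export
scheme_coverage <- function(scheme) {
  c(min(scheme$demux_bins$lower), max(scheme$demux_bins$upper))
}

#' Snap an isolation-window boundary into a peptide forbidden zone
#'
#' Tryptic peptide precursor m/z values cluster on a near-integer grid set by
#' the averagine mass-defect periodicity; the sparsely populated "forbidden
#' zones" between clusters are the preferred place for window edges. The
#' boundary is moved to the nearest point of the quarter-offset grid
#' `(k + 0.25) * delta / z`, with `delta = 1.00045475` and `z` the reference
#' charge, so the shift never exceeds `delta / (2 z)`.
#'
#' @param boundary Window edge to snap (Th), positive.
#' @param reference_charge Reference precursor charge, 2 or 3.
#' @param delta Grid spacing constant (Th per nominal mass unit).
#' @return The snapped boundary (Th).
#' @examples
#' snap_to_forbidden_zone(500, reference_charge = 2)
#' @export
snap_to_forbidden_zone <- function(boundary, reference_charge = 2L,
                                   delta = AVERAGINE_DELTA) {
  if (!is.finite(boundary) || boundary <= 0) {
    stop("boundary must be positive", call. = FALSE)
  }
  if (!reference_charge %in% c(2L, 3L)) {
    stop("reference_charge must be 2 or 3", call. = FALSE)
  }
  step <- delta / reference_charge
  k <- round(boundary / step - 0.25)
  (k + 0.25) * step
}

#' Plan gas-phase fractionation segments
#'
#' Splits a precursor range into `n_segments` equal steps, extends each
#' segment by `overlap` Th above its step so that adjacent segments share a
#' small overlap region, and attaches to every segment a staggered-window
#' scheme built on the segment's unique (non-overlapping) span.
#'
#' @param mz_min,mz_max Global precursor range (Th).
#' @param n_segments Number of gas-phase fractions (injections).
#' @param overlap Overlap between adjacent segments (Th).
#' @param window_width Isolation window width within each segment (Th).
#' @param ms1_every MS1 cadence passed to each segment scheme.
#' @return A `GPFPlan`: list with `segments` (list of `list(range, scheme)`),
#'   `step`, `overlap` and the global range.
#' @examples
#' plan <- build_gpf_plan(400, 1000, 6, 2, 4)
#' length(plan$segments)                 # 6
#' plan$segments[[1]]$range              # 400 502
#' nrow(plan$segments[[1]]$scheme$windows)  # 52
#' @export
build_gpf_plan <- function(mz_min, mz_max, n_segments, overlap, window_width,
                           ms1_every = 26L) {
  if (n_segments < 1) stop("n_segments must be >= 1", call. = FALSE)
  if (overlap < 0) stop("overlap must be non-negative", call. = FALSE)
  span <- mz_max - mz_min
  step <- span / n_segments
  if (overlap >= step) stop("overlap must be smaller than the segment step",
                            call. = FALSE)
  if (window_width > step + overlap) {
    stop("window width larger than segment", call. = FALSE)
  }
  segments <- lapply(seq_len(n_segments) - 1L, function(k) {
    lo <- mz_min + k * step
    list(
      range  = c(lo, lo + step + overlap),
      scheme = build_staggered_scheme(lo, lo + step, window_width,
                                      ms1_every = ms1_every)
    )
  })
  structure(list(segments = segments, step = step, overlap = overlap,
                 mz_min = mz_min, mz_max = mz_max,
                 window_width = window_width),
            class = "GPFPlan")
}

#' @export
print.GPFPlan <- function(x, ...) {
  cat(sprintf("GPFPlan: %d segments of %.4g Th (+%.3g overlap) over %.5g-%.5g m/z, %g Th windows\n",
              length(x$segments), x$step, x$overlap, x$mz_min, x$mz_max,
              x$window_width))
  invisible(x)
}

#' Round-robin concatenation plan for offline fractions
#'
#' Pools `n_fractions` chromatographic fractions into `n_pools` concatenated
#' pools in round-robin order (fraction i goes to pool `i mod n_pools`,
#' 0-based), so that each pool combines early, middle and late eluters and
#' the high-pH and low-pH separations stay orthogonal.
#'
#' @param n_fractions Number of collected fractions.
#' @param n_pools Number of final pools; must not exceed `n_fractions`.
#' @return A `ConcatenationPlan`: list with `n_fractions`, `n_pools` and
#'   `assignment`, a data frame mapping 1-based `fraction` to 1-based `pool`.
#' @examples
#' plan_concatenation(18, 6)$assignment$pool[1:7]  # 1 2 3 4 5 6 1
#' @export
plan_concatenation <- function(n_fractions, n_pools) {
  if (n_pools < 1 || n_fractions < 1) {
    stop("fraction and pool counts must be positive", call. = FALSE)
  }
  if (n_pools > n_fractions) {
    stop("n_pools may not exceed n_fractions", call. = FALSE)
  }
  fraction <- seq_len(n_fractions)
  pool <- ((fraction - 1L) %% n_pools) + 1L
  structure(list(
    n_fractions = as.integer(n_fractions),
    n_pools     = as.integer(n_pools),
    assignment  = data.frame(fraction = fraction, pool = pool)
  ), class = "ConcatenationPlan")
}

#' Number of fractions collected over a time window
#'
#' @param collect_minutes Total collection time (min).
#' @param interval_seconds Collection interval per fraction (s).
#' @return Integer fraction count, `floor(collect_minutes * 60 / interval_seconds)`.
#' @examples
#' fraction_count(42, 140)  # 18
#' @export
fraction_count <- function(collect_minutes, interval_seconds) {
  if (interval_seconds <= 0) stop("interval must be positive", call. = FALSE)
  if (collect_minutes < 0) stop("collection time must be non-negative",
                                call. = FALSE)
  as.integer(floor(collect_minutes * 60 / interval_seconds))
}

#' Export an isolation list as CSV
#'
#' Writes one row per window with the window center, width, bank and
#' acquisition order; [read_isolation_list()] reconstructs the scheme
#' losslessly from this file.
#'
#' @param scheme A `WindowScheme`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_isolation_list <- function(scheme, path) {
  w <- scheme$windows
  out <- data.frame(
    center_mz = (w$lower_mz + w$upper_mz) / 2,
    width_mz  = w$upper_mz - w$lower_mz,
    bank      = w$bank,
    order     = w$order
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an isolation list CSV back into a scheme
#'
#' @param path CSV written by [export_isolation_list()].
#' @param ms1_every MS1 cadence to attach (not stored in the CSV).
#' @return A `WindowScheme` rebuilt from the window geometry.
#' @export
read_isolation_list <- function(path, ms1_every = 26L) {
  tab <- utils::read.csv(path)
  tab <- tab[order(tab$order), , drop = FALSE]
  width <- tab$width_mz[1]
  lowers <- tab$center_mz - width / 2
  stagger <- width / 2
  mz_min <- min(lowers) + stagger
  mz_max <- max(lowers)
  sch <- build_staggered_scheme(mz_min, mz_max, width, ms1_every = ms1_every)
  stopifnot(nrow(sch$windows) == nrow(tab))
  sch
}

#' Write / read a scheme as JSON (full fidelity)
#' @param scheme A `WindowScheme`.
#' @param path JSON file path.
#' @return `path` (write) or a `WindowScheme` (read).
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$windows <- as.data.frame(x$windows)
  x$demux_bins <- as.data.frame(x$demux_bins)
  x$ms1_every <- as.integer(x$ms1_every)
  structure(x, class = "WindowScheme")
}
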