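#' Construct a DIA run object
#'
#' A `DiaRun` is the in-memory and on-disk (JSON) representation of one
#' acquisition: a time-ordered list of MS1/MS2 spectra, each carrying its
#' retention time, cycle index, the acquisition-order index of its isolation
#' window (MS2 only) and a two-column peak matrix.
#'
#' @param spectra List of spectra; each a list with `ms_level` (1 or 2),
#'   `rt` (seconds), `cycle` (integer), `window` (window order index, `NA`
#'   for MS1) and `peaks` (numeric matrix with columns `mz`, `intensity`).
#' @param scheme The `WindowScheme` the run was acquired with.
#' @param rt_map Affine iRT-to-RT map used at simulation time, or `NULL`.
#' @param metadata Free-form list (seed, noise settings, exclusions ...).
#' @return A `DiaRun` object.
#' @export
new_dia_run <- function(spectra, scheme, rt_map = NULL, metadata = list()) {
  structure(list(spectra = spectra, scheme = scheme, rt_map = rt_map,
                 metadata = metadata),
            class = "DiaRun")
}

#' @export
print.DiaRun <- function(x, ...) {
  lv <- vapply(x$spectra, function(s) s$ms_level, numeric(1))
  rng <- range(vapply(x$spectra, function(s) s$rt, numeric(1)))
  cat(sprintf("DiaRun: %d spectra (%d MS1, %d MS2), RT %.1f-%.1f s\n",
              length(x$spectra), sum(lv == 1), sum(lv == 2), rng[1], rng[2]))
  invisible(x)
}

ms2_spectra <- function(run) {
  Filter(function(s) s$ms_level == 2, run$spectra)
}

#' Total ion current of a run's MS2 spectra
#' @param run A `DiaRun`.
#' @return Summed intensity over all MS2 peaks.
#' @export
run_tic <- function(run) {
  sum(vapply(ms2_spectra(run), function(s) {
    if (nrow(s$peaks)) sum(s$peaks[, "intensity"]) else 0
  }, numeric(1)))
}

#' Write / read a run as JSON
#'
#' Lossless plain-text serialization of a `DiaRun` (peak matrices stored
#' column-wise at full precision).
#'
#' @param run A `DiaRun`.
#' @param path JSON file path.
#' @return `path` (write) or a `DiaRun` (read).
#' @export
write_run_json <- function(run, path) {
  ser <- list(
    scheme = unclass(run$scheme),
    rt_map = run$rt_map,
    metadata = run$metadata,
    spectra = lapply(run$spectra, function(s) {
      list(ms_level = s$ms_level, rt = s$rt, cycle = s$cycle,
           window = s$window,
           mz = s$peaks[, "mz"], intensity = s$peaks[, "intensity"])
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_run_json
#' @export
read_run_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sch <- x$scheme
  sch$windows <- as.data.frame(sch$windows)
  sch$demux_bins <- as.data.frame(sch$demux_bins)
  sch$ms1_every <- as.integer(sch$ms1_every)
  class(sch) <- "WindowScheme"
  spectra <- lapply(x$spectra, function(s) {
    mz <- unlist(s$mz); int <- unlist(s$intensity)
    list(ms_level = s$ms_level, rt = s$rt, cycle = s$cycle,
         window = if (is.null(s$window)) NA_integer_ else s$window,
         peaks = cbind(mz = as.numeric(mz), intensity = as.numeric(int)))
  })
  new_dia_run(spectra, sch, rt_map = x$rt_map, metadata = x$metadata)
}

empty_peaks <- function() {
  cbind(mz = numeric(0), intensity = numeric(0))
}
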