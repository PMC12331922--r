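# Shared small fixtures, built once per test run.

# memoize: peptide set reused across files
.fx <- new.env(parent = emptyenv())

fx_peptides <- function() {
  if (is.null(.fx$peps)) .fx$peps <- generate_peptides(n_proteins = 8, seed = 11)
  .fx$peps
}

fx_small_scheme <- function() build_staggered_scheme(400, 448, 12, ms1_every = 5)

fx_tiny_scheme <- function() build_staggered_scheme(400, 412, 12, ms1_every = 2)

# one-channel synthetic run on a given scheme: window i reads reads[i] at
# every cycle (constant signal), single fragment channel at `mz`
fx_constant_run <- function(scheme, reads, mz = 500.25, n_cycles = 2) {
  spectra <- list()
  for (ci in seq_len(n_cycles)) {
    for (wi in seq_along(reads)) {
      pk <- if (reads[wi] > 0) cbind(mz = mz, intensity = reads[wi]) else
        cbind(mz = numeric(0), intensity = numeric(0))
      spectra[[length(spectra) + 1L]] <-
        list(ms_level = 2, rt = (ci - 1) * 3.18, cycle = ci, window = wi,
             peaks = pk)
    }
  }
  new_dia_run(spectra, scheme, metadata = list(run_id = "const"))
}

# independent per-bin ground truth for a noiseless cycle-mode run
expected_bin_total <- function(peptides, run, bin_lower, bin_upper, rt,
                               peak_fwhm_s = 17) {
  tab <- peptides$table
  rtm <- run$rt_map
  sd_s <- peak_fwhm_s / (2 * sqrt(2 * log(2)))
  sel <- which(tab$precursor_mz >= bin_lower & tab$precursor_mz < bin_upper)
  sum(vapply(sel, function(p) {
    g <- tab$abundance[p] *
      exp(-((rt - (rtm$intercept + rtm$slope * tab$irt[p]))^2) / (2 * sd_s^2))
    sum(peptides$fragments[[tab$key[p]]]$rel_intensity * g)
  }, numeric(1)))
}

# shared end-to-end fixture: GPF fractions + mixed run over 400-640 m/z
fx_gpf_pipeline <- function() {
  if (!is.null(.fx$pipe)) return(.fx$pipe)
  peps <- fx_peptides()
  plan <- build_gpf_plan(400, 640, 6, 2, 4, ms1_every = 11)
  gpf <- simulate_gpf_runs(peps, plan, seed = 3, gradient_minutes = 4,
                           noise = NULL, rt_jitter_s = 12)
  mix_scheme <- build_staggered_scheme(400, 640, 24, ms1_every = 11)
  mixed <- simulate_run(peps, mix_scheme, seed = 30, gradient_minutes = 4,
                        noise = NULL)
  .fx$pipe <- list(peps = peps, plan = plan, gpf = gpf,
                   mix_scheme = mix_scheme, mixed = mixed)
  .fx$pipe
}

# brute-force non-negative least squares on a regular grid (oracle)
grid_nnls <- function(A, y, upper = NULL, n_grid = 60, refine = 3) {
  k <- ncol(A)
  if (is.null(upper)) upper <- rep(max(y) * 1.5 + 1, k)
  lower <- rep(0, k)
  best <- NULL; best_obj <- Inf
  for (r in seq_len(refine)) {
    grids <- lapply(seq_len(k), function(j) seq(lower[j], upper[j],
                                                length.out = n_grid))
    pts <- as.matrix(expand.grid(grids))
    obj <- colSums((y - A %*% t(pts))^2)
    i <- which.min(obj)
    if (obj[i] < best_obj) { best_obj <- obj[i]; best <- pts[i, ] }
    span <- (upper - lower) / (n_grid - 1)
    lower <- pmax(0, best - 2 * span)
    upper <- best + 2 * span
  }
  best
}
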