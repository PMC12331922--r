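test_that("peptide masses match independent monoisotopic values", {
  # frozen oracle values computed with an independent mass calculator
  expect_equal(peptide_mass("SAMPLER"), 802.40072, tolerance = 1e-5)
  expect_equal(precursor_mz("SAMPLERK", 2), 466.25512, tolerance = 1e-5)
  ft <- stagdia:::fragment_mz_table("SAMPLERK", carbamidomethyl = FALSE)
  expect_equal(ft$mz[ft$type == "b" & ft$index == 2], 159.07642,
               tolerance = 1e-5)
  expect_equal(ft$mz[ft$type == "y" & ft$index == 3], 432.25651,
               tolerance = 1e-5)
  expect_error(peptide_mass("SAMPLEZ"), "unknown residue")
})

test_that("tryptic digestion respects cleavage rules and missed cleavages", {
  peps <- stagdia:::digest_tryptic("AAAKBBBRCCCK", missed = 0)
  expect_equal(vapply(peps, `[[`, "", "sequence"),
               c("AAAK", "BBBR", "CCCK"))
  # missed cleavages concatenate adjacent peptides
  peps2 <- stagdia:::digest_tryptic("AAAKBBBRCCCK", missed = 0:2)
  expect_true("AAAKBBBR" %in% vapply(peps2, `[[`, "", "sequence"))
  expect_true("AAAKBBBRCCCK" %in% vapply(peps2, `[[`, "", "sequence"))
  expect_true(all(vapply(peps2, `[[`, 0, "missed_cleavages") <= 2))
  # without the /P rule, K-P bonds are protected
  pp <- stagdia:::digest_tryptic("AAAKPBBBR", missed = 0,
                                 cleave_before_proline = FALSE)
  expect_equal(vapply(pp, `[[`, "", "sequence"), c("AAAKPBBBR"))
  pp2 <- stagdia:::digest_tryptic("AAAKPBBBR", missed = 0,
                                  cleave_before_proline = TRUE)
  expect_equal(vapply(pp2, `[[`, "", "sequence"), c("AAAK", "PBBBR"))
})

test_that("generated peptides satisfy the library constraints", {
  peps <- fx_peptides()
  tab <- peps$table
  expect_true(all(nchar(tab$sequence) >= 7 & nchar(tab$sequence) <= 35))
  expect_true(all(tab$missed_cleavages <= 2))
  expect_true(all(tab$n_fragments >= 3 & tab$n_fragments <= 6))
  expect_true(all(tab$charge >= 2 & tab$charge <= 5))
  for (fr in peps$fragments) {
    expect_true(all(fr$mz >= 300 & fr$mz <= 1800))
    expect_true(all(fr$type %in% c("b", "y")))
    expect_equal(max(fr$rel_intensity), 1)
  }
  # unique precursor keys
  expect_equal(anyDuplicated(tab$key), 0L)
})

test_that("peptide generation is deterministic under the seed", {
  a <- generate_peptides(n_proteins = 3, seed = 99)
  b <- generate_peptides(n_proteins = 3, seed = 99)
  expect_identical(a, b)
  c <- generate_peptides(n_proteins = 3, seed = 100)
  expect_false(identical(a$table$sequence, c$table$sequence))
})

test_that("a single peptide appears only in windows covering its precursor", {
  peps <- fx_peptides()
  k <- peps$table$key[peps$table$precursor_mz > 402 &
                        peps$table$precursor_mz < 446][1]
  one <- peps
  one$table <- one$table[one$table$key == k, ]
  one$fragments <- one$fragments[k]
  sch <- fx_small_scheme()
  run <- simulate_run(one, sch, gradient_minutes = 2, noise = NULL, seed = 1)
  w <- sch$windows
  pre <- one$table$precursor_mz
  covering <- which(pre >= w$nominal_lower & pre < w$nominal_upper)
  expect_length(covering, 2)
  for (s in stagdia:::ms2_spectra(run)) {
    if (nrow(s$peaks)) expect_true(s$window %in% covering)
  }
})

test_that("noiseless total ion current matches the analytic Gaussian sum", {
  peps <- fx_peptides()
  sch <- fx_small_scheme()
  run <- simulate_run(peps, sch, gradient_minutes = 3, noise = NULL, seed = 2)
  # independent closed-form recomputation of the planted TIC
  tab <- peps$table
  cov <- scheme_coverage(sch)
  tab <- tab[tab$precursor_mz >= cov[1] & tab$precursor_mz < cov[2], ]
  rtm <- run$rt_map
  sd_s <- 17 / (2 * sqrt(2 * log(2)))
  cycle_s <- 3180 / 1000
  times <- seq(0, 3 * 60, by = cycle_s)
  w <- sch$windows
  want <- 0
  for (i in seq_len(nrow(tab))) {
    n_cover <- sum(tab$precursor_mz[i] >= w$nominal_lower &
                     tab$precursor_mz[i] < w$nominal_upper)
    apex <- rtm$intercept + rtm$slope * tab$irt[i]
    g <- tab$abundance[i] * exp(-((times - apex)^2) / (2 * sd_s^2))
    want <- want +
      n_cover * sum(g) * sum(peps$fragments[[tab$key[i]]]$rel_intensity)
  }
  expect_equal(run_tic(run), want, tolerance = 1e-9)
  expect_equal(run$metadata$planted_tic, want, tolerance = 1e-9)
})

test_that("simulation is deterministic and counts out-of-range precursors", {
  peps <- fx_peptides()
  sch <- fx_small_scheme()
  r1 <- simulate_run(peps, sch, gradient_minutes = 1, seed = 5,
                     noise = noise_model(shot_factor = 1, chemical_rate = 2))
  r2 <- simulate_run(peps, sch, gradient_minutes = 1, seed = 5,
                     noise = noise_model(shot_factor = 1, chemical_rate = 2))
  expect_identical(r1$spectra, r2$spectra)
  cov <- scheme_coverage(sch)
  n_out <- sum(peps$table$precursor_mz < cov[1] |
                 peps$table$precursor_mz >= cov[2])
  expect_equal(r1$metadata$excluded_out_of_range, n_out)
})

test_that("GPF runs sample only precursors inside each segment", {
  peps <- fx_peptides()
  plan <- build_gpf_plan(400, 640, 6, 2, 4, ms1_every = 11)
  runs <- simulate_gpf_runs(peps, plan, seed = 3, gradient_minutes = 1,
                            noise = NULL)
  expect_length(runs, 6)
  for (k in seq_along(runs)) {
    cov <- scheme_coverage(plan$segments[[k]]$scheme)
    w <- plan$segments[[k]]$scheme$windows
    for (s in stagdia:::ms2_spectra(runs[[k]])) {
      if (!nrow(s$peaks)) next
      # every planted fragment must trace back to a precursor in coverage
      expect_true(s$window <= nrow(w))
    }
    # peptides outside the segment are excluded
    n_in <- sum(peps$table$precursor_mz >= cov[1] &
                  peps$table$precursor_mz < cov[2])
    expect_equal(runs[[k]]$metadata$excluded_out_of_range,
                 nrow(peps$table) - n_in)
  }
  # a precursor in the overlap region is sampled by both adjacent segments
  cov1 <- scheme_coverage(plan$segments[[1]]$scheme)
  cov2 <- scheme_coverage(plan$segments[[2]]$scheme)
  expect_true(cov1[2] > 440 && cov2[1] < 440)
})

test_that("an empty GPF segment yields a run without signal", {
  peps <- fx_peptides()
  empty <- peps
  keep <- peps$table$precursor_mz < 700
  empty$table <- peps$table[keep, ]
  empty$fragments <- peps$fragments[empty$table$key]
  seg <- build_staggered_scheme(900, 1000, 4, ms1_every = 11)
  run <- simulate_run(empty, seg, gradient_minutes = 1, noise = NULL, seed = 1)
  expect_equal(run_tic(run), 0)
})

test_that("two-group study plants recoverable effects", {
  st <- simulate_two_group_study(n_samples_a = 100, n_samples_b = 100,
                                 frac_de = 0.3, log2fc = 1, cv_within = 0.2,
                                 seed = 21, n_proteins = 20,
                                 detection_floor = 0)
  gt <- st$ground_truth
  expect_equal(as.vector(table(gt$group_labels)), c(100L, 100L))
  m <- gt$sample_abundances
  a <- gt$group_labels == "A"
  tab <- gt$peptides$table
  for (pr in gt$de_table$protein_id[gt$de_table$is_de][1:5]) {
    keys <- tab$key[tab$protein_id == pr]
    ratio <- mean(m[keys, !a], na.rm = TRUE) / mean(m[keys, a], na.rm = TRUE)
    lfc <- gt$de_table$log2fc[gt$de_table$protein_id == pr]
    # law of large numbers at n = 100 per group
    expect_equal(log2(ratio), lfc, tolerance = 0.15)
  }
  # non-DE proteins have expected log2 fold change 0
  expect_true(all(gt$de_table$log2fc[!gt$de_table$is_de] == 0))
})

test_that("frac_de = 0 plants no effects and studies are seed-reproducible", {
  s1 <- simulate_two_group_study(n_samples_a = 4, n_samples_b = 4,
                                 frac_de = 0, seed = 3, n_proteins = 10)
  expect_true(all(s1$ground_truth$de_table$log2fc == 0))
  s2 <- simulate_two_group_study(n_samples_a = 4, n_samples_b = 4,
                                 frac_de = 0, seed = 3, n_proteins = 10)
  expect_identical(s1$fragment_table, s2$fragment_table)
  expect_identical(s1$ground_truth$sample_abundances,
                   s2$ground_truth$sample_abundances)
})

test_that("detection floor creates missingness for the presence filter", {
  st <- simulate_two_group_study(n_samples_a = 6, n_samples_b = 6,
                                 frac_de = 0, seed = 9, n_proteins = 20,
                                 detection_floor = 3e5)
  expect_gt(mean(is.na(st$ground_truth$sample_abundances)), 0)
  # missing peptides produce no fragment rows
  miss <- which(is.na(st$ground_truth$sample_abundances), arr.ind = TRUE)
  if (nrow(miss)) {
    key <- rownames(st$ground_truth$sample_abundances)[miss[1, 1]]
    smp <- colnames(st$ground_truth$sample_abundances)[miss[1, 2]]
    expect_equal(sum(st$fragment_table$key == key &
                       st$fragment_table$sample == smp), 0L)
  }
})

test_that("run JSON serialization round-trips", {
  peps <- fx_peptides()
  sch <- fx_tiny_scheme()
  run <- simulate_run(peps, sch, gradient_minutes = 0.5, noise = NULL,
                      seed = 4)
  path <- tempfile(fileext = ".json")
  write_run_json(run, path)
  back <- read_run_json(path)
  expect_equal(length(back$spectra), length(run$spectra))
  i <- which(vapply(run$spectra, function(s) nrow(s$peaks) > 0, logical(1)))[1]
  expect_equal(back$spectra[[i]]$peaks, run$spectra[[i]]$peaks)
  expect_equal(back$spectra[[i]]$rt, run$spectra[[i]]$rt)
  expect_equal(back$scheme$windows, sch$windows)
})
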