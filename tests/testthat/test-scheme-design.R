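test_that("staggered scheme reproduces printed window counts", {
  # 600 m/z span, 24 m/z windows, 12 m/z stagger
  expect_equal(nrow(build_staggered_scheme(400, 1000, 24)$windows), 52)
  # GPF segment: 100 m/z unique span, 4 m/z windows
  expect_equal(nrow(build_staggered_scheme(400, 500, 4)$windows), 52)
  # smallest staggered scheme: span 12, width 12 -> 12/6 + 2
  tiny <- build_staggered_scheme(400, 412, 12)
  expect_equal(nrow(tiny$windows), 4)
  expect_equal(tiny$demux_bins$lower[tiny$demux_bins$in_range], c(400, 406))
  expect_equal(tiny$demux_bins$upper[tiny$demux_bins$in_range], c(406, 412))
})

test_that("scheme geometry invariants hold across sizes", {
  for (args in list(c(400, 1000, 24), c(400, 500, 4), c(400, 448, 12),
                    c(500, 620, 8))) {
    sch <- build_staggered_scheme(args[1], args[2], args[3])
    w <- sch$windows
    span <- args[2] - args[1]
    expect_equal(nrow(w), span / (args[3] / 2) + 2)
    # constant width
    expect_true(all(abs((w$nominal_upper - w$nominal_lower) - args[3]) < 1e-9))
    # banks alternate in acquisition order
    expect_true(all(abs(diff(w$bank)) == 1))
    # equal bank sizes
    expect_equal(sum(w$bank == 0), sum(w$bank == 1))
    # in-range demux bins tile [mz_min, mz_max) gap- and overlap-free
    b <- sch$demux_bins[sch$demux_bins$in_range, ]
    expect_equal(b$lower[1], args[1])
    expect_equal(b$upper[nrow(b)], args[2])
    expect_true(all(abs(b$lower[-1] - b$upper[-nrow(b)]) < 1e-9))
    # every in-range bin covered by exactly two windows
    bm <- build_bin_map(sch)
    cov_count <- lengths(bm$bin_windows)
    expect_true(all(cov_count[sch$demux_bins$in_range] == 2))
    # exactly two windows cover a single in-range bin
    in_range_per_window <- vapply(bm$window_bins, function(v)
      sum(sch$demux_bins$in_range[v]), numeric(1))
    expect_equal(sum(in_range_per_window == 1), 2)
  }
})

test_that("degenerate scheme inputs error", {
  expect_error(build_staggered_scheme(400, 1000, 0), "positive")
  expect_error(build_staggered_scheme(1000, 400, 24), "degenerate")
  expect_error(build_staggered_scheme(400, 410, 24), "degenerate")
})

test_that("GPF plan matches the printed fractionation design", {
  plan <- build_gpf_plan(400, 1000, 6, 2, 4)
  expect_length(plan$segments, 6)
  # segments 102 m/z wide, first [400, 502]
  expect_equal(plan$segments[[1]]$range, c(400, 502))
  expect_true(all(vapply(plan$segments, function(s) diff(s$range),
                         numeric(1)) == 102))
  # each segment scheme has 52 staggered 4 m/z windows
  expect_true(all(vapply(plan$segments, function(s) nrow(s$scheme$windows),
                         numeric(1)) == 52))
  # adjacent segments overlap by exactly 2 Th
  for (k in 1:5) {
    expect_equal(plan$segments[[k]]$range[2] - plan$segments[[k + 1]]$range[1],
                 2)
  }
  # unique spans jointly cover the global range
  lows <- vapply(plan$segments, function(s) s$range[1], numeric(1))
  expect_equal(lows, seq(400, 900, by = 100))
})

test_that("degenerate GPF plan equals the plain staggered scheme", {
  plan <- build_gpf_plan(400, 1000, 1, 0, 24)
  direct <- build_staggered_scheme(400, 1000, 24)
  expect_equal(plan$segments[[1]]$scheme$windows, direct$windows)
  expect_error(build_gpf_plan(400, 1000, 6, 150, 4), "overlap")
  expect_error(build_gpf_plan(400, 1000, 6, 2, 200), "window width")
})

test_that("forbidden-zone snapping lands on the quarter-offset grid", {
  delta <- 1.00045475
  # fixed point: already on the grid
  x <- (997 + 0.25) * delta / 2
  expect_equal(snap_to_forbidden_zone(x, 2), x)
  # brute-force oracle: nearest grid point within +-1 Th of 500
  ks <- seq(floor((499) * 2 / delta), ceiling((501) * 2 / delta))
  grid <- (ks + 0.25) * delta / 2
  expect_equal(snap_to_forbidden_zone(500, 2),
               grid[which.min(abs(grid - 500))])
  # bound and idempotence over random boundaries
  set.seed(1)
  for (b in runif(50, 350, 1100)) {
    s <- snap_to_forbidden_zone(b, 2)
    expect_lte(abs(s - b), 0.2501)
    expect_equal(snap_to_forbidden_zone(s, 2), s)
  }
  expect_error(snap_to_forbidden_zone(-1), "positive")
  expect_error(snap_to_forbidden_zone(500, 4), "charge")
})

test_that("snapped schemes perturb edges by at most half a stagger", {
  sch <- build_staggered_scheme(400, 1000, 24, snap_boundaries = TRUE)
  expect_true(all(abs(sch$windows$lower_mz - sch$windows$nominal_lower) <= 0.5))
  expect_equal(nrow(sch$windows), 52)
})

test_that("concatenation plan is a round-robin partition", {
  plan <- plan_concatenation(18, 6)
  expect_equal(as.vector(table(plan$assignment$pool)), rep(3L, 6))
  # pool 1 receives fractions 1, 7, 13 (round robin)
  expect_equal(plan$assignment$fraction[plan$assignment$pool == 1],
               c(1L, 7L, 13L))
  # identity when pools == fractions
  expect_equal(plan_concatenation(6, 6)$assignment$pool, 1:6)
  # uneven case: sizes 3, 2, 2
  expect_equal(sort(as.vector(table(plan_concatenation(7, 3)$assignment$pool)),
                    decreasing = TRUE), c(3L, 2L, 2L))
  # every fraction assigned exactly once (bijection onto pools)
  expect_equal(sort(plan$assignment$fraction), 1:18)
  expect_error(plan_concatenation(5, 6), "exceed")
})

test_that("fraction count follows the collection timing", {
  expect_equal(fraction_count(42, 140), 18L)
  expect_equal(fraction_count(0, 140), 0L)
  expect_equal(fraction_count(10, 140), 4L)
  expect_error(fraction_count(10, 0), "positive")
})

test_that("isolation list and scheme JSON round-trip losslessly", {
  sch <- build_staggered_scheme(400, 1000, 24)
  csv <- tempfile(fileext = ".csv")
  export_isolation_list(sch, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 52)
  expect_equal(tab$center_mz,
               (sch$windows$lower_mz + sch$windows$upper_mz) / 2,
               tolerance = 1e-6)
  back <- read_isolation_list(csv)
  expect_equal(back$windows, sch$windows)
  js <- tempfile(fileext = ".json")
  write_scheme_json(sch, js)
  back2 <- read_scheme_json(js)
  expect_equal(back2$windows, sch$windows)
  expect_equal(back2$demux_bins, sch$demux_bins)
})
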