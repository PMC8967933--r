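test_that("change_rate follows the gross/net definition with the zero-area convention", {
  a <- array(0, c(1, 1, 3), dimnames = list("1", "forest", c(2015, 2020, 2025)))
  a[1, 1, ] <- c(100, 110, 110)
  s <- coarse_series(a, c(2015, 2020, 2025))
  expect_equal(change_rate(s, 1, 1, 2), list(gross = 1.1, net = 0.1))
  expect_equal(change_rate(s, 1, 1, 3), list(gross = 1, net = 0))
  a[1, 1, ] <- c(0, 5, 5)
  s0 <- coarse_series(a, c(2015, 2020, 2025))
  expect_equal(change_rate(s0, 1, 1, 2), list(gross = 1, net = 0))
  expect_error(change_rate(s, 1, 1, 1), "t >= 2")
})

test_that("calibrate_step reproduces the branch arithmetic and the urban no-shrink rule", {
  # coarse undershoots the fine area: damped net rate
  expect_equal(calibrate_step(200, 100, 110), 210)
  # coarse overshoots: gross ratio applies directly
  expect_equal(calibrate_step(50, 100, 110), 55)
  # urban with shrinking coarse trend holds
  expect_equal(calibrate_step(30, 100, 90, is_urban = TRUE), 30)
  expect_equal(calibrate_step(30, 100, 110, is_urban = TRUE), 33)
  expect_equal(calibrate_step(0, 100, 110), 0)
  expect_error(calibrate_step(-1, 100, 110), "negative")
})

test_that("harmonize rescales non-urban shares onto the active total", {
  out <- harmonize(c(a = 30, b = 30), urban = 10, total_active = 50)
  expect_equal(out, c(a = 20, b = 20))
  expect_equal(sum(out) + 10, 50)
  # already consistent areas are unchanged
  expect_equal(harmonize(c(a = 25, b = 15), urban = 10, total_active = 50),
               c(a = 25, b = 15))
  # single non-urban share takes the whole active remainder
  expect_equal(harmonize(c(a = 80), urban = 10, total_active = 50), c(a = 40))
  expect_error(harmonize(c(a = 0, b = 0), urban = 10, total_active = 50),
               "zero")
  expect_error(harmonize(c(a = 1), urban = 60, total_active = 50), "exceed")
})

test_that("build_demand conserves totals, keeps urban monotone and freezes water/ice", {
  w <- world_fixture(1)
  yrs <- seq(2015, 2045, 5)
  s <- make_coarse_series(w, yrs, gap_factor = c(forest = 0.6, urban = 1.4),
                          trend = c(forest = 0.96, cropland = 1.04,
                                    urban = 1.06, barren = 0.99))
  d <- build_demand(w$baseline, w$regions, s)
  tot <- apply(d$area[, names(ACTIVE_CLASSES), , drop = FALSE], c(1, 3), sum)
  for (t in seq_along(yrs))
    expect_equal(unname(tot[, t]), d$region_total_active, tolerance = 1e-9)
  urb <- d$area[, "urban", ]
  expect_true(all(apply(urb, 1, function(x) all(diff(x) >= -1e-9))))
  for (f in names(FROZEN_CLASSES))
    for (t in seq_along(yrs))
      expect_equal(unname(d$area[, f, t]), unname(d$frozen_area[, f]))
})

test_that("an all-ones trend propagates the baseline census unchanged", {
  w <- world_fixture(1)
  yrs <- seq(2015, 2035, 5)
  s <- make_coarse_series(w, yrs, gap_factor = 0.5, trend = 1)
  d <- build_demand(w$baseline, w$regions, s)
  for (t in seq_along(yrs)[-1])
    expect_equal(d$area[, , t], d$area[, , 1], tolerance = 1e-12)
})

test_that("zero initial gap with a total-conserving series preserves the coarse trajectory", {
  w <- world_fixture(1)
  yrs <- seq(2015, 2045, 5)
  s <- make_transfer_series(w, yrs, from = c("forest", "grassland"),
                            to = c("cropland", "urban"),
                            fraction_per_step = c(0.07, 0.02))
  d <- build_demand(w$baseline, w$regions, s)
  expect_equal(d$area[, names(ACTIVE_CLASSES), ],
               s$area[, names(ACTIVE_CLASSES), ], tolerance = 1e-9)
})

test_that("demand tables round-trip through CSV and convert to exact cell counts", {
  w <- world_fixture(1)
  yrs <- seq(2015, 2030, 5)
  s <- make_transfer_series(w, yrs)
  d <- build_demand(w$baseline, w$regions, s)
  path <- file.path(tempdir(), "demand.csv")
  write_demand_table(d, path)
  back <- read_demand_table(path)
  expect_equal(back$area, d$area)

  cells <- demand_to_cells(d, w$baseline, w$regions)
  for (r in seq_len(w$regions$n_regions)) {
    inr <- w$regions$region_id == r & !is.na(w$baseline$codes)
    n_active <- sum(w$baseline$codes[inr] %in% ACTIVE_CLASSES)
    for (t in seq_along(yrs))
      expect_identical(sum(cells[r, , t]), n_active)
  }
  # year 0 cell counts equal the baseline census
  r1 <- w$regions$region_id == 1 & !is.na(w$baseline$codes)
  expect_identical(unname(cells[1, , 1]),
                   tabulate(w$baseline$codes[r1], 7)[1:5])
})

test_that("a region missing from the series is reported", {
  w <- world_fixture(1)
  yrs <- seq(2015, 2025, 5)
  s <- make_coarse_series(w, yrs)
  s$area <- s$area[1, , , drop = FALSE]
  expect_error(build_demand(w$baseline, w$regions, s), "absent from series")
})
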