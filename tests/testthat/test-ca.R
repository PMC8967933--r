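test_that("neighbourhood effect counts window shares with truncated edges", {
  m <- matrix(2L, 5, 5)
  m[3, 3] <- 1L
  g <- land_grid(m)
  # interior cell fully surrounded by class 2
  expect_equal(neighborhood(g, 2)[3, 3], 1)
  expect_equal(neighborhood(g, 1)[3, 3], 0)
  # 3 of 8 neighbours
  m2 <- matrix(2L, 5, 5)
  m2[2, 2] <- m2[2, 3] <- m2[2, 4] <- 1L
  expect_equal(neighborhood(land_grid(m2), 1)[3, 3], 0.375)
  # corner cell: 3 available neighbours
  expect_equal(neighborhood(land_grid(m2), 1)[1, 1], 1 / 3)
  expect_error(neighborhood(g, 1, window = 4), "odd")
})

test_that("total probability is the literal product with hard constraint and floor", {
  expect_equal(total_probability(0.7, 0.9, 2, cons = 0), 0)
  expect_equal(total_probability(1, 1, 1, cons = 1), 1)
  expect_equal(total_probability(0.5, 0.5, 1.2, cons = 1), 0.3)
  expect_equal(total_probability(0.5, 0, 1, cons = 1, floor = 1e-4), 5e-5)
  expect_equal(total_probability(0.5, 0, 1, cons = 1, floor = 0), 0)
})

test_that("adaptive inertia scales only when the gap worsens, in the right direction", {
  expect_equal(update_inertia(1.5, 5, 5), 1.5)
  expect_equal(update_inertia(1.5, 3, 5), 1.5)
  expect_equal(update_inertia(2, -10, -5), 1)     # overshoot worsening: halve
  expect_equal(update_inertia(1, 10, 5), 2)       # undershoot worsening: double
  expect_equal(update_inertia(1, -10, 5), 1)      # sign flip: hold
  expect_equal(update_inertia(1, 10, -5), 1)
  expect_error(update_inertia(0, 1, 2), "prev > 0")
})

test_that("roulette draws proportionally to scores", {
  expect_identical(roulette(c(0, 0, 1, 0)), 3L)
  expect_identical(roulette(c(0, 0, 0)), NA_integer_)
  expect_error(roulette(c(-1, 1)), ">= 0")
  set.seed(11)
  draws <- replicate(10000, roulette(c(1, 1, 1, 1)))
  freq <- tabulate(draws, 4) / 10000
  # within 3 binomial standard deviations of 1/4
  sd3 <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < sd3))
})

test_that("allocation at current census is a fixed point and infeasible demand errors", {
  w <- world_fixture(1)
  suit <- constant_suitability(w)
  demand <- region_census(w, 1)
  set.seed(3)
  out <- allocate_step(w$baseline, w$regions, 1, suit, demand)
  expect_identical(out$codes, w$baseline$codes)
  expect_identical(attr(out, "iterations"), 0L)
  bad <- demand
  bad[1] <- bad[1] + 10L
  expect_error(allocate_step(w$baseline, w$regions, 1, suit, bad),
               "infeasible")
})

test_that("allocation meets shifted demand within tolerance using only allowed transitions", {
  w <- world_fixture(1)
  train <- sample_cells(w$baseline, w$regions, 0.1, seed = 21)
  suit <- predict(fit_suitability(train, w$drivers, seed = 22), w$drivers)
  demand <- region_census(w, 1)
  move <- round(0.05 * demand[["barren"]])
  demand[["barren"]] <- demand[["barren"]] - move
  demand[["cropland"]] <- demand[["cropland"]] + move
  set.seed(23)
  out <- allocate_step(w$baseline, w$regions, 1, suit, demand)
  got <- region_census_of(out, w$regions, 1)
  tol <- pmax(1, 0.001 * demand)
  expect_true(all(abs(got - demand) <= tol))
  # transition audit against the constraint matrix
  cons <- default_conversion_matrix()
  in_r <- w$regions$region_id == 1
  from <- w$baseline$codes[in_r]
  to <- out$codes[in_r]
  ok <- !is.na(from) & !is.na(to)
  trans <- table(factor(from[ok], 1:7), factor(to[ok], 1:7))
  expect_true(all(trans[cons == 0] == 0))
  # cells outside the region untouched
  expect_identical(out$codes[!in_r], w$baseline$codes[!in_r])
})

test_that("urban demand growth only ever adds urban cells", {
  w <- world_fixture(1)
  train <- sample_cells(w$baseline, w$regions, 0.1, seed = 31)
  suit <- predict(fit_suitability(train, w$drivers, seed = 32), w$drivers)
  demand <- region_census(w, 1)
  k <- 40L
  demand[["urban"]] <- demand[["urban"]] + k
  demand[["grassland"]] <- demand[["grassland"]] - k
  set.seed(33)
  out <- allocate_step(w$baseline, w$regions, 1, suit, demand)
  was_urban <- w$baseline$codes == LAND_CLASSES[["urban"]] &
    w$regions$region_id == 1
  expect_true(all(out$codes[was_urban] == LAND_CLASSES[["urban"]]))
  gained <- sum(out$codes == LAND_CLASSES[["urban"]] &
                  w$regions$region_id == 1, na.rm = TRUE) -
    sum(was_urban, na.rm = TRUE)
  expect_gte(gained, k - 1L)
})

test_that("multi-step runs conserve the census, freeze water/ice, and reproduce bit-for-bit", {
  w <- world_fixture(2, 200, 200, 2)
  yrs <- seq(2015, 2040, 5)
  s <- make_transfer_series(w, yrs, from = c("forest", "barren"),
                            to = c("cropland", "grassland"),
                            fraction_per_step = c(0.05, 0.04))
  d <- build_demand(w$baseline, w$regions, s)
  train <- sample_cells(w$baseline, w$regions, 0.1, seed = 41)
  suit <- predict(fit_suitability(train, w$drivers, seed = 42), w$drivers)
  cfg <- run_config(seed = 43, horizon_years = yrs)
  sims <- run_simulation(w$baseline, w$regions, suit, d, cfg = cfg)
  expect_identical(names(sims), as.character(yrs))
  n0 <- sum(!is.na(w$baseline$codes))
  frozen <- w$baseline$codes %in% FROZEN_CLASSES
  for (g in sims) {
    expect_identical(sum(!is.na(g$codes)), n0)
    expect_identical(g$codes[frozen], w$baseline$codes[frozen])
  }
  sims2 <- run_simulation(w$baseline, w$regions, suit, d, cfg = cfg)
  expect_identical(lapply(sims, `[[`, "codes"), lapply(sims2, `[[`, "codes"))
  # single-year horizon returns the initial grid only
  d1 <- d
  d1$area <- d$area[, , 1, drop = FALSE]
  d1$years <- yrs[1]
  one <- run_simulation(w$baseline, w$regions, suit, d1, cfg = cfg)
  expect_length(one, 1)
  expect_identical(one[[1]]$codes, w$baseline$codes)
})
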