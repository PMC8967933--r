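test_that("monthly GDD approximation matches closed forms", {
  expect_equal(monthly_gdd(rep(5, 12)), 0)
  expect_equal(monthly_gdd(rep(10, 12)), 5 * 365)
  t <- rep(0, 12); t[1] <- 6
  expect_equal(monthly_gdd(t), 31)
  expect_error(monthly_gdd(rep(10, 11)), "12")
  # monotone non-decreasing in every monthly temperature
  set.seed(1)
  for (i in 1:25) {
    t0 <- runif(12, -20, 30)
    m <- sample.int(12, 1)
    t1 <- t0; t1[m] <- t1[m] + runif(1, 0, 10)
    expect_gte(monthly_gdd(t1), monthly_gdd(t0))
  }
})

test_that("indicator derivation handles both hemispheres and uniform regimes", {
  nr <- 10; nc <- 4
  # grid straddling the equator: top half north, bottom half south
  meta <- grid_meta(nr, nc, cell_km = 100, origin = c(0, 500 / 111.32))
  t_mon <- array(rep(10 + 5 * cos(2 * pi * (1:12 - 7) / 12),
                     each = nr * nc), c(nr, nc, 12))
  p_mon <- array(100, c(nr, nc, 12))
  cn <- climate_normals(t_mon, p_mon, meta)
  ind <- derive_indicators(cn)
  expect_equal(ind$p_ann, matrix(1200, nr, nc))
  expect_equal(ind$p_win, matrix(600, nr, nc))
  expect_equal(ind$p_driest, matrix(100, nr, nc))
  expect_true(all(ind$t_c <= ind$t_w))
  expect_true(all(ind$p_win <= ind$p_ann))
  # all precipitation in January: NH cells put it all in the winter half,
  # SH cells none of it
  p_jan <- array(0, c(nr, nc, 12)); p_jan[, , 1] <- 120
  ind2 <- derive_indicators(climate_normals(t_mon, p_jan, meta))
  north <- row_latitudes(meta) >= 0
  expect_true(all(ind2$p_win[north, ] == ind2$p_ann[north, ]))
  expect_true(all(ind2$p_win[!north, ] == 0))
  # dry-hot month counting
  t_hot <- array(25, c(nr, nc, 12))
  p_dry <- array(20, c(nr, nc, 12)); p_dry[, , 1:4] <- 80
  ind3 <- derive_indicators(climate_normals(t_hot, p_dry, meta))
  expect_true(all(ind3$n_dry_hot == 8))
})

test_that("forest subdivision follows the climate rules with the boreal fallback", {
  bet <- FOREST_PRELIM[["broadleaf_evergreen"]]
  bdt <- FOREST_PRELIM[["broadleaf_deciduous"]]
  net <- FOREST_PRELIM[["needleleaf_evergreen"]]
  ndt <- FOREST_PRELIM[["needleleaf_deciduous"]]
  shr <- FOREST_PRELIM[["shrub"]]
  cf <- function(pl, t_c, gdd = 2000, p_ann = 1000, p_win = 300)
    classify_forest(pl, t_c, gdd, p_ann, p_win)
  expect_identical(cf(bet, 20), PFT_CODES[["bet_tropical"]])
  expect_identical(cf(bet, 15.5), PFT_CODES[["bet_temperate"]])
  expect_identical(cf(bdt, 20), PFT_CODES[["bdt_tropical"]])
  expect_identical(cf(bdt, 0, gdd = 1500), PFT_CODES[["bdt_temperate"]])
  expect_identical(cf(bdt, -20, gdd = 1500), PFT_CODES[["bdt_boreal"]])
  expect_identical(cf(bdt, 0, gdd = 500), PFT_CODES[["bdt_boreal"]])
  # the printed temperate/boreal rules leave 600 < GDD <= 1200 at mild T_c
  # unmatched; the fallback sends it to boreal
  expect_identical(cf(bdt, 0, gdd = 900), PFT_CODES[["bdt_boreal"]])
  expect_identical(cf(net, 0), PFT_CODES[["net_temperate"]])
  expect_identical(cf(net, -20), PFT_CODES[["net_boreal"]])
  expect_identical(cf(net, 0, gdd = 500), PFT_CODES[["net_boreal"]])
  expect_identical(cf(ndt, 0), PFT_CODES[["ndt"]])
  expect_identical(cf(ndt, -40, gdd = 0), PFT_CODES[["ndt"]])
  # shrub: winter-wet temperate is evergreen (450 > 2/3 * 600)
  expect_identical(cf(shr, 0, gdd = 1000, p_ann = 600, p_win = 450),
                   PFT_CODES[["bes_temperate"]])
  expect_identical(cf(shr, 0, gdd = 1000, p_ann = 600, p_win = 350),
                   PFT_CODES[["bds_temperate"]])
  expect_identical(cf(shr, 0, gdd = 1000, p_ann = 500, p_win = 450),
                   PFT_CODES[["bds_temperate"]])
  expect_identical(cf(shr, -20), PFT_CODES[["bds_boreal"]])
  expect_error(classify_forest(9L, 0, 0, 0, 0), "unknown")
})

test_that("grass subdivision applies first-match precedence over the four rules", {
  cg <- function(...) classify_grass(...)
  expect_identical(cg(10, 25, 300, 100, 0), PFT_CODES[["c3_arctic"]])
  expect_identical(cg(10, 20, 500, 100, 0), PFT_CODES[["c3_grass"]])
  # dry-hot clause admits C3 despite a warm summer
  expect_identical(cg(23, 30, 5000, 5, 8), PFT_CODES[["c3_grass"]])
  # C3 precedes C4 but fails here, so C4 fires
  expect_identical(cg(23, 28, 500, 30, 0), PFT_CODES[["c4_grass"]])
  # nothing matches: mixed
  expect_identical(cg(10, 25, 500, 10, 2), PFT_CODES[["c3c4_mixed"]])
  # the non-normative switch moves the C4 temperature clause to T_w
  expect_identical(classify_grass(10, 25, 500, 30, 0, c4_on_warmest = TRUE),
                   PFT_CODES[["c4_grass"]])
})

test_that("preliminary labels transfer by nearest neighbour with row-major tie-break", {
  # future forest everywhere, one labelled baseline cell
  fut <- land_grid(matrix(1L, 3, 3))
  bp <- matrix(NA_integer_, 3, 3)
  bp[2, 2] <- 4L
  out <- assign_preliminary_forest(fut, bp)
  expect_true(all(out == 4L))
  # future mask inside the baseline mask keeps its labels untouched
  bp2 <- matrix(sample(1:5, 9, replace = TRUE), 3, 3)
  out2 <- assign_preliminary_forest(fut, bp2)
  expect_identical(out2, bp2)
  # equidistant sources: the earlier row-major source wins
  bp3 <- matrix(NA_integer_, 3, 3)
  bp3[1, 1] <- 1L   # broadleaf evergreen at row 1
  bp3[3, 1] <- 4L   # needleleaf deciduous at row 3
  fut3 <- land_grid(matrix(c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L), 3, 3))
  out3 <- assign_preliminary_forest(fut3, bp3)
  expect_identical(out3[2, 1], 1L)
  expect_error(assign_preliminary_forest(fut, matrix(NA_integer_, 3, 3)),
               "empty")
})

test_that("subdivision is total, retains managed classes, and collapses back exactly", {
  # all-urban map: all urban PFT code
  u <- land_grid(matrix(LAND_CLASSES[["urban"]], 8, 8))
  cn <- make_climate(8, 8)
  pu <- subdivide(u, matrix(NA_integer_, 8, 8), derive_indicators(cn))
  expect_true(all(pu$codes == PFT_CODES[["urban"]]))

  sw <- make_branch_sweep()
  ind <- derive_indicators(sw$climate)
  p <- subdivide(sw$broad, sw$prelim, ind)
  expect_identical(sum(is.na(p$codes)), sum(is.na(sw$broad$codes)))
  expect_setequal(unique(p$codes[!is.na(p$codes)]), 1:20)
  expect_identical(collapse_pft(p)$codes, sw$broad$codes)

  # collapse is exact on arbitrary random worlds too
  w <- world_fixture(1)
  cw <- make_climate(120, 120)
  pw <- subdivide(w$baseline, w$baseline_prelim_forest,
                  derive_indicators(cw))
  expect_identical(collapse_pft(pw)$codes, w$baseline$codes)
})
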