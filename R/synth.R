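# Synthetic world generator. Emulates the *shapes* and statistical roles of
# the real inputs (baseline categorical map, region mask, driver stack,
# coarse demand series, monthly climate normals): spatially autocorrelated
# class patches, drivers carrying a planted class signal a classifier can
# recover, a deliberate initial-area gap between the coarse series and the
# baseline census, and climate fields spanning every subdivision-rule branch.

#' Preliminary forest-type labels
#'
#' The five preliminary forest types assigned before climate subdivision:
#' 1 broadleaf evergreen tree, 2 broadleaf deciduous tree, 3 needleleaf
#' evergreen tree, 4 needleleaf deciduous tree, 5 shrub.
#' @format Named integer vector of length 5.
#' @export
FOREST_PRELIM <- c(broadleaf_evergreen = 1L, broadleaf_deciduous = 2L,
                   needleleaf_evergreen = 3L, needleleaf_deciduous = 4L,
                   shrub = 5L)

# Smooth standard-normal random field via FFT circular convolution of white
# noise with a Gaussian kernel; `range` is the kernel sd in cells.
smooth_field <- function(n_rows, n_cols, range = 8) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  dr <- pmin(seq_len(n_rows) - 1L, n_rows - (seq_len(n_rows) - 1L))
  dc <- pmin(seq_len(n_cols) - 1L, n_cols - (seq_len(n_cols) - 1L))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * range^2))
  sm <- Re(fft(fft(z) * fft(kern), inverse = TRUE)) / (n_rows * n_cols)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic world
#'
#' Builds a baseline land map (autocorrelated patches of all seven classes),
#' a region mask, a driver stack with a planted class signal, and
#' preliminary forest labels on the baseline forest cells. Deterministic in
#' `seed`.
#'
#' @param seed integer seed.
#' @param n_rows,n_cols grid size (>= 64 each).
#' @param n_regions number of regions (Voronoi partition).
#' @param meta optional `grid_meta`; defaults to a 1-km grid with its
#'   northern edge at 60 degrees N.
#' @return An object of class `synthetic_world`: `baseline` (`land_grid`),
#'   `baseline_prelim_forest` (integer matrix of [FOREST_PRELIM] labels on
#'   forest cells), `regions` (`region_mask`), `drivers` (named list of
#'   matrices), `latent` (per-class latent suitability fields; the planted
#'   signal), `truth` (driver-to-class wiring).
#' @export
make_world <- function(seed, n_rows = 200, n_cols = 200, n_regions = 4,
                       meta = NULL) {
  if (n_rows < 64 || n_cols < 64) stop("world must be at least 64 x 64")
  if (n_regions < 1) stop("n_regions must be >= 1")
  set.seed(seed)
  if (is.null(meta)) meta <- grid_meta(n_rows, n_cols, cell_km = 1,
                                       origin = c(0, 60))

  # regions: nearest of n_regions random seed points
  rs <- cbind(runif(n_regions, 1, n_rows), runif(n_regions, 1, n_cols))
  rows <- row(matrix(0, n_rows, n_cols)); cols <- col(matrix(0, n_rows, n_cols))
  d2 <- array(0, c(n_rows, n_cols, n_regions))
  for (k in seq_len(n_regions))
    d2[, , k] <- (rows - rs[k, 1])^2 + (cols - rs[k, 2])^2
  region_id <- apply(d2, c(1, 2), which.min)

  # baseline classes: argmax of biased smooth latent fields, with the biases
  # tuned so every class holds roughly its target share of cells
  target <- c(forest = 0.24, grassland = 0.20, barren = 0.14,
              cropland = 0.18, urban = 0.06, water = 0.12, snow_ice = 0.06)
  latent <- lapply(seq_len(7), function(k) smooth_field(n_rows, n_cols))
  bias <- rep(0, 7)
  n_cells <- n_rows * n_cols
  for (it in seq_len(80)) {
    sc <- vapply(1:7, function(k) as.vector(latent[[k]] + bias[k]),
                 numeric(n_cells))
    cls <- max.col(sc, ties.method = "first")
    share <- tabulate(cls, 7) / n_cells
    bias <- bias + 0.4 * log(target / pmax(share, 1 / n_cells))
    bias <- bias - mean(bias)
  }
  codes <- matrix(cls, n_rows, n_cols)
  baseline <- land_grid(codes, meta)

  # drivers: the first five carry the latent field of one active class each
  # (the planted monotone signal), the rest are nuisance smooth noise
  truth <- c(socio_a = 1L, socio_b = 2L, access_a = 3L, access_b = 4L,
             phys_a = 5L, phys_b = NA_integer_, phys_c = NA_integer_,
             phys_d = NA_integer_)
  drivers <- lapply(names(truth), function(nm) {
    k <- truth[[nm]]
    if (is.na(k)) smooth_field(n_rows, n_cols)
    else latent[[k]] + bias[k] + 0.25 * smooth_field(n_rows, n_cols, range = 4)
  })
  names(drivers) <- names(truth)

  # preliminary forest labels: argmax of five smooth fields on forest cells;
  # any missing label is forced onto one forest cell (row-major order)
  pf <- lapply(seq_len(5), function(k) smooth_field(n_rows, n_cols, range = 6))
  pscore <- vapply(pf, as.vector, numeric(n_cells))
  plab <- max.col(pscore, ties.method = "first")
  prelim <- matrix(NA_integer_, n_rows, n_cols)
  fmask <- codes == LAND_CLASSES[["forest"]]
  prelim[fmask] <- plab[as.vector(fmask)]
  fidx <- which(fmask)
  missing <- setdiff(1:5, unique(prelim[fidx]))
  if (length(missing) && length(fidx) >= 5)
    prelim[fidx[seq_along(missing)]] <- missing

  structure(list(baseline = baseline, baseline_prelim_forest = prelim,
                 regions = region_mask(matrix(as.integer(region_id),
                                              n_rows, n_cols), meta),
                 drivers = drivers, latent = latent, bias = bias,
                 truth = truth, seed = as.integer(seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> seed %d, %d x %d, %d regions, %d drivers\n",
              x$seed, x$baseline$meta$n_rows, x$baseline$meta$n_cols,
              x$regions$n_regions, length(x$drivers)))
  invisible(x)
}

#' Generate a coarse demand series from a world
#'
#' Initial coarse areas are the world's per-region census times a per-class
#' `gap_factor` (a gap different from 1 exercises the calibration's
#' branch logic); later steps evolve by per-class gross ratios, exactly:
#' `area[r,j,t] = area[r,j,t-1] * trend[j]`.
#'
#' @param world a `synthetic_world`.
#' @param years integer years (uniform step).
#' @param gap_factor per-active-class multiplier on the initial coarse area
#'   (single number or named vector over active classes).
#' @param trend per-active-class per-step gross ratio (> 0; single number or
#'   named vector).
#' @return A `coarse_series` over the five active classes.
#' @export
make_coarse_series <- function(world, years, gap_factor = 1, trend = 1) {
  if (any(trend <= 0)) stop("trend ratios must be > 0")
  acts <- names(ACTIVE_CLASSES)
  gap <- expand_by_class(gap_factor, acts)
  tr <- expand_by_class(trend, acts)
  cell_area <- world$baseline$meta$cell_km^2
  R <- world$regions$n_regions
  area <- array(0, dim = c(R, length(acts), length(years)),
                dimnames = list(region = as.character(seq_len(R)),
                                class = acts, year = as.character(years)))
  for (r in seq_len(R)) {
    inr <- world$regions$region_id == r
    cs <- tabulate(world$baseline$codes[inr & !is.na(world$baseline$codes)], 7)
    area[r, , 1] <- cs[ACTIVE_CLASSES] * cell_area * gap
  }
  for (t in seq_along(years)[-1])
    area[, , t] <- area[, , t - 1] * rep(tr, each = R)
  coarse_series(area, years)
}

expand_by_class <- function(x, classes) {
  if (length(x) == 1 && is.null(names(x))) return(rep(as.numeric(x), length(classes)))
  out <- rep(1, length(classes)); names(out) <- classes
  if (is.null(names(x))) {
    stopifnot(length(x) == length(classes))
    out[] <- x
  } else out[names(x)] <- x
  out
}

#' Default synthetic climate profile
#'
#' A north-south annual-mean temperature gradient with latitude-dependent
#' seasonal amplitude, and four longitudinal precipitation regimes (wet,
#' winter-wet, summer-dry, arid). The defaults are chosen so the derived
#' bioclimatic indicators span every subdivision-rule branch.
#'
#' @param t_top,t_bottom annual-mean temperature (degrees C) at the
#'   northernmost / southernmost row.
#' @param amp_top,amp_bottom seasonal half-amplitude (degrees C) at the
#'   northernmost / southernmost row.
#' @param p_wet,p_moist,p_dry,p_arid monthly precipitation levels (mm) used
#'   by the four regimes.
#' @return A named list of profile parameters.
#' @export
climate_profile <- function(t_top = -18, t_bottom = 30,
                            amp_top = 18, amp_bottom = 6,
                            p_wet = 100, p_moist = 80, p_dry = 10,
                            p_arid = 5) {
  list(t_top = t_top, t_bottom = t_bottom, amp_top = amp_top,
       amp_bottom = amp_bottom, p_wet = p_wet, p_moist = p_moist,
       p_dry = p_dry, p_arid = p_arid)
}

#' Generate synthetic monthly climate normals
#'
#' Temperature: per-row annual mean and seasonal amplitude interpolated
#' linearly between the profile's top and bottom values, with the warm month
#' in July for northern-hemisphere cells and January for southern. Four
#' precipitation regimes in longitudinal bands: uniform wet; winter-wet
#' (Nov-Apr moist, rest dry); summer-dry (Jun-Aug dry, rest moist); arid.
#' Deterministic (no random component).
#'
#' @param n_rows,n_cols grid size.
#' @param profile a [climate_profile()].
#' @param meta optional `grid_meta` (controls hemisphere via row latitude).
#' @return A `climate_normals` object (see [climate_normals()]).
#' @export
make_climate <- function(n_rows, n_cols, profile = climate_profile(),
                         meta = NULL) {
  if (is.null(meta)) meta <- grid_meta(n_rows, n_cols, cell_km = 1,
                                       origin = c(0, 60))
  s <- if (n_rows > 1) (seq_len(n_rows) - 1) / (n_rows - 1) else 0.5
  mean_t <- profile$t_top + (profile$t_bottom - profile$t_top) * s
  amp <- profile$amp_top + (profile$amp_bottom - profile$amp_top) * s
  north <- row_latitudes(meta) >= 0
  months <- 1:12
  t_mon <- array(0, c(n_rows, n_cols, 12))
  for (m in months) {
    phase_n <- cos(2 * pi * (m - 7) / 12)   # NH warm month: July
    phase_s <- cos(2 * pi * (m - 1) / 12)   # SH warm month: January
    phase <- ifelse(north, phase_n, phase_s)
    t_mon[, , m] <- matrix(mean_t + amp * phase, n_rows, n_cols)
  }
  band <- pmin(4L, pmax(1L, ceiling(4 * seq_len(n_cols) / n_cols)))
  p_mon <- array(0, c(n_rows, n_cols, 12))
  winter_nh <- months %in% c(11, 12, 1, 2, 3, 4)
  summer_nh <- months %in% 6:8
  for (m in months) {
    pm <- numeric(n_cols)
    pm[band == 1] <- profile$p_wet
    pm[band == 2] <- if (winter_nh[m]) profile$p_moist else profile$p_dry
    pm[band == 3] <- if (summer_nh[m]) profile$p_dry else profile$p_moist
    pm[band == 4] <- profile$p_arid
    p_mon[, , m] <- matrix(pm, n_rows, n_cols, byrow = TRUE)
  }
  cn <- climate_normals(t_mon, p_mon, meta)
  unreach <- unreachable_branches(cn)
  if (length(unreach))
    warning("climate profile cannot reach rule branches: ",
            paste(unreach, collapse = "; "))
  cn
}

# names of Table-style rule branches that the given climate never reaches
unreachable_branches <- function(climate) {
  ind <- derive_indicators(climate)
  checks <- c(
    "T_c > 15.5"        = any(ind$t_c > 15.5),
    "T_c <= -15"        = any(ind$t_c <= -15),
    "T_c <= -19"        = any(ind$t_c <= -19),
    "-15 < T_c <= 15.5" = any(ind$t_c > -15 & ind$t_c <= 15.5),
    "GDD <= 600"        = any(ind$gdd <= 600),
    "GDD > 1200"        = any(ind$gdd > 1200),
    "GDD < 400"         = any(ind$gdd < 400),
    "T_w <= 22"         = any(ind$t_w <= 22 & ind$gdd >= 400),
    "T_c >= 22"         = any(ind$t_c >= 22 & ind$p_driest > 25),
    "P_ann > 520"       = any(ind$p_ann > 520),
    "P_win > 2/3 P_ann" = any(ind$p_win > 2 / 3 * ind$p_ann),
    "n_dry_hot >= 6"    = any(ind$n_dry_hot >= 6)
  )
  names(checks)[!checks]
}

#' Generate a paired historical change map
#'
#' Returns the baseline map plus a perturbed copy in which approximately
#' `change_fraction` of the classified cells have changed class. Changes are
#' placed preferentially where the planted driver signal favours the
#' destination class, so suitability learning and figure-of-merit evaluation
#' on the pair are meaningful. Frozen classes (water, snow/ice) never change.
#'
#' @param world a `synthetic_world`.
#' @param seed integer seed.
#' @param change_fraction fraction of classified cells to change, in (0, 0.5).
#' @param dest_weights destination-class weights for the change budget;
#'   skewed toward cropland and urban by default so the pair carries net
#'   directional change (as historical land conversion does), not
#'   self-cancelling churn.
#' @return List of two `land_grid`s: `t0` (baseline) and `t1` (changed map).
#' @export
make_history <- function(world, seed, change_fraction,
                         dest_weights = c(forest = 0.10, grassland = 0.15,
                                          barren = 0.05, cropland = 0.45,
                                          urban = 0.25)) {
  if (change_fraction <= 0 || change_fraction >= 0.5)
    stop("change_fraction must be in (0, 0.5)")
  set.seed(seed)
  base <- world$baseline
  codes <- base$codes
  classified <- which(!is.na(codes))
  # urban is never a source: it does not convert away
  active <- which(!is.na(codes) & codes %in% ACTIVE_CLASSES &
                    codes != LAND_CLASSES[["urban"]])
  n_change <- round(change_fraction * length(classified))
  if (n_change > length(active)) stop("change_fraction too large for world")

  # split the change budget across destination classes, then claim the
  # highest-favourability eligible cells per destination (with jitter)
  dest_split <- tabulate(sample.int(5L, n_change, replace = TRUE,
                                    prob = dest_weights[names(ACTIVE_CLASSES)]),
                         5L)
  new_codes <- codes
  taken <- logical(length(codes))
  for (j in seq_len(5L)) {
    need <- dest_split[j]
    if (need == 0) next
    elig <- active[codes[active] != j & !taken[active]]
    fav <- world$latent[[j]][elig] + 0.3 * runif(length(elig))
    pick <- elig[order(fav, decreasing = TRUE)[seq_len(min(need, length(elig)))]]
    new_codes[pick] <- ACTIVE_CLASSES[[j]]
    taken[pick] <- TRUE
  }
  list(t0 = base, t1 = land_grid(new_codes, base$meta))
}

#' Deterministic rule-branch sweep fixture
#'
#' A small world whose broad map cycles all seven classes across columns (so
#' every class occurs in every climate row), whose forest cells cycle all
#' five preliminary labels across rows, paired with the default synthetic
#' climate. Subdividing it reaches all 20 PFT codes.
#'
#' @param n_rows,n_cols grid size.
#' @return List: `broad` (`land_grid`), `prelim` (label matrix), `climate`
#'   (`climate_normals`), `regions` (single-region `region_mask`).
#' @export
make_branch_sweep <- function(n_rows = 120, n_cols = 56) {
  meta <- grid_meta(n_rows, n_cols, cell_km = 1, origin = c(0, 60))
  codes <- matrix(rep_len(1:7, n_rows * n_cols), n_rows, n_cols, byrow = TRUE)
  # stagger rows so every class visits every column band
  for (r in seq_len(n_rows)) codes[r, ] <- rep_len(((r + 0:(n_cols - 1)) %% 7) + 1L, n_cols)
  broad <- land_grid(codes, meta)
  prelim <- matrix(NA_integer_, n_rows, n_cols)
  fmask <- codes == LAND_CLASSES[["forest"]]
  prelim[fmask] <- ((row(codes)[fmask] - 1L) %% 5L) + 1L
  climate <- make_climate(n_rows, n_cols, meta = meta)
  list(broad = broad, prelim = prelim, climate = climate,
       regions = region_mask(matrix(1L, n_rows, n_cols), meta))
}

#' Total-conserving coarse series by area transfer
#'
#' Evolves the coarse areas by moving, at every step, a fraction of the
#' source class's current area to the destination class in each region. The
#' per-region active total is conserved exactly, as in the real coarse land
#' product where the land area of a region is fixed.
#'
#' @param world a `synthetic_world`.
#' @param years integer years (uniform step).
#' @param from,to active class names (source and destination of the
#'   transfer); may be vectors of equal length for several simultaneous
#'   transfers.
#' @param fraction_per_step fraction of the source class's current area
#'   moved each step (recycled along `from`).
#' @param gap_factor per-active-class multiplier on the initial coarse area.
#' @return A `coarse_series` over the five active classes.
#' @export
make_transfer_series <- function(world, years, from = "forest",
                                 to = "cropland", fraction_per_step = 0.05,
                                 gap_factor = 1) {
  stopifnot(length(from) == length(to), all(from %in% names(ACTIVE_CLASSES)),
            all(to %in% names(ACTIVE_CLASSES)))
  fraction_per_step <- rep_len(fraction_per_step, length(from))
  base <- make_coarse_series(world, years, gap_factor = gap_factor, trend = 1)
  area <- base$area
  for (t in seq_along(years)[-1]) {
    area[, , t] <- area[, , t - 1]
    for (i in seq_along(from)) {
      moved <- area[, from[i], t] * fraction_per_step[i]
      area[, from[i], t] <- area[, from[i], t] - moved
      area[, to[i], t] <- area[, to[i], t] + moved
    }
  }
  coarse_series(area, years)
}
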