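# Bioclimatic subdivision of the broad classes into the 20-class plant
# functional type scheme. Forest cells first receive one of five preliminary
# forest types by nearest-neighbour transfer from the baseline, then climate
# rules split them into 11 forest PFTs; grassland splits into 4 grass PFTs;
# barren, cropland, urban, water and snow/ice are retained 1-1.

#' Month lengths of the 365-day year
#' @format Integer vector of length 12.
#' @export
MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

# GDD base temperature (degrees C)
GDD_BASE <- 5

#' PFT code names
#' @format Named integer vector of length 20.
#' @export
PFT_CODES <- c(
  bet_tropical = 1L, bet_temperate = 2L, bdt_tropical = 3L,
  bdt_temperate = 4L, bdt_boreal = 5L, net_temperate = 6L, net_boreal = 7L,
  ndt = 8L, bes_temperate = 9L, bds_temperate = 10L, bds_boreal = 11L,
  c3_arctic = 12L, c3_grass = 13L, c4_grass = 14L, c3c4_mixed = 15L,
  barren = 16L, cropland = 17L, urban = 18L, water = 19L, snow_ice = 20L
)

#' Monthly climate normals
#'
#' @param t_mon array `[n_rows, n_cols, 12]` of monthly mean temperature
#'   (degrees C), January first.
#' @param p_mon array `[n_rows, n_cols, 12]` of monthly precipitation
#'   (mm/month, >= 0).
#' @param meta a `grid_meta` (row latitudes decide the winter half-year).
#' @param days_per_month month lengths summing to 365.
#' @return An object of class `climate_normals`.
#' @export
climate_normals <- function(t_mon, p_mon, meta, days_per_month = MONTH_DAYS) {
  stopifnot(length(dim(t_mon)) == 3, dim(t_mon)[3] == 12,
            identical(dim(t_mon), dim(p_mon)),
            dim(t_mon)[1] == meta$n_rows, dim(t_mon)[2] == meta$n_cols,
            sum(days_per_month) == 365)
  if (any(p_mon < 0, na.rm = TRUE)) stop("monthly precipitation must be >= 0")
  structure(list(t_mon = t_mon, p_mon = p_mon, meta = meta,
                 days_per_month = as.integer(days_per_month)),
            class = "climate_normals")
}

#' @export
print.climate_normals <- function(x, ...) {
  cat(sprintf("<climate_normals> %d x %d x 12 months\n",
              x$meta$n_rows, x$meta$n_cols))
  invisible(x)
}

#' Annual growing-degree days from monthly means
#'
#' The monthly approximation of the annual degree-day sum over a 5 degree C
#' base: each month contributes `max(T_mon - 5, 0)` times its length in
#' days.
#'
#' @param t_mon numeric vector of 12 monthly mean temperatures (degrees C).
#' @param days month lengths (default the 365-day year).
#' @return GDD in degree C days.
#' @export
monthly_gdd <- function(t_mon, days = MONTH_DAYS) {
  if (length(t_mon) != 12 || length(days) != 12)
    stop("monthly_gdd needs 12 monthly values")
  sum(pmax(t_mon - GDD_BASE, 0) * days)
}

#' Derive bioclimatic indicator rasters
#'
#' Per cell: coldest/warmest monthly mean (`t_c`, `t_w`), annual
#' growing-degree days (`gdd`, base 5 degrees C, month-length weighted),
#' annual precipitation (`p_ann`), winter-half-year precipitation (`p_win`:
#' November-April where the cell-centre latitude is >= 0, May-October
#' otherwise), driest-month precipitation (`p_driest`), and the number of
#' months that are simultaneously dry (<= 25 mm) and hot (> 22 degrees C)
#' (`n_dry_hot`).
#'
#' @param climate a `climate_normals`.
#' @return An object of class `bioclim_indicators`: a list of matrices plus
#'   the `grid_meta`.
#' @export
derive_indicators <- function(climate) {
  tm <- climate$t_mon; pm <- climate$p_mon
  nr <- dim(tm)[1]; nc <- dim(tm)[2]
  t_c <- apply(tm, c(1, 2), min)
  t_w <- apply(tm, c(1, 2), max)
  days <- climate$days_per_month
  gdd <- matrix(0, nr, nc)
  for (m in 1:12) gdd <- gdd + pmax(tm[, , m] - GDD_BASE, 0) * days[m]
  p_ann <- apply(pm, c(1, 2), sum)
  p_driest <- apply(pm, c(1, 2), min)
  north <- row_latitudes(climate$meta) >= 0
  win_n <- c(11, 12, 1, 2, 3, 4); win_s <- 5:10
  p_win_n <- matrix(0, nr, nc); p_win_s <- matrix(0, nr, nc)
  for (m in win_n) p_win_n <- p_win_n + pm[, , m]
  for (m in win_s) p_win_s <- p_win_s + pm[, , m]
  p_win <- p_win_s
  p_win[north, ] <- p_win_n[north, ]
  n_dry_hot <- matrix(0L, nr, nc)
  for (m in 1:12)
    n_dry_hot <- n_dry_hot + (pm[, , m] <= 25 & tm[, , m] > 22)
  structure(list(t_c = t_c, t_w = t_w, gdd = gdd, p_ann = p_ann,
                 p_win = p_win, p_driest = p_driest, n_dry_hot = n_dry_hot,
                 meta = climate$meta),
            class = "bioclim_indicators")
}

#' Transfer preliminary forest labels to a future map
#'
#' A future forest cell that carries a baseline label keeps it; any other
#' future forest cell takes the label of the nearest baseline-labelled cell
#' (Euclidean distance between cell centres), ties broken by row-major scan
#' order of the candidate sources.
#'
#' @param future a `land_grid` whose forest cells need labels.
#' @param baseline_prelim integer matrix of [FOREST_PRELIM] labels (`NA`
#'   off the baseline forest).
#' @return Integer matrix of labels on the future forest cells, `NA`
#'   elsewhere.
#' @export
assign_preliminary_forest <- function(future, baseline_prelim) {
  stopifnot(identical(dim(future$codes), dim(baseline_prelim)))
  src <- which(!is.na(baseline_prelim))
  if (!length(src)) stop("baseline preliminary-forest label set is empty")
  nr <- nrow(baseline_prelim)
  out <- matrix(NA_integer_, nr, ncol(baseline_prelim))
  fut <- which(!is.na(future$codes) & future$codes == LAND_CLASSES[["forest"]])
  keep <- fut[!is.na(baseline_prelim[fut])]
  out[keep] <- baseline_prelim[keep]
  todo <- fut[is.na(baseline_prelim[fut])]
  if (!length(todo)) return(out)
  # sources in row-major order so the first minimum realises the tie-break
  sr <- (src - 1L) %% nr; sc <- (src - 1L) %/% nr
  rm_order <- order(sr, sc)
  src <- src[rm_order]; sr <- sr[rm_order]; sc <- sc[rm_order]
  lab <- baseline_prelim[src]
  tr <- (todo - 1L) %% nr; tc <- (todo - 1L) %/% nr
  chunk <- max(1L, 2e6 %/% length(src))
  for (start in seq(1, length(todo), by = chunk)) {
    ii <- start:min(start + chunk - 1, length(todo))
    d2 <- outer(sr, tr[ii], function(a, b) (a - b)^2) +
      outer(sc, tc[ii], function(a, b) (a - b)^2)
    out[todo[ii]] <- lab[apply(d2, 2, which.min)]
  }
  out
}

#' Subdivide preliminary forest types by climate
#'
#' Climate rules per preliminary type, evaluated top-down; the last row of
#' each preliminary type absorbs cells that match no printed rule (the
#' literal broadleaf-deciduous rules leave part of the indicator space
#' unassigned), keeping the classifier total. Needleleaf deciduous has no
#' climate split.
#'
#' @param prelim integer [FOREST_PRELIM] labels (vectorised).
#' @param t_c,gdd,p_ann,p_win bioclimatic indicators at the same cells.
#' @return Integer PFT codes 1-11.
#' @export
classify_forest <- function(prelim, t_c, gdd, p_ann, p_win) {
  if (any(!prelim %in% FOREST_PRELIM))
    stop("unknown preliminary forest label")
  n <- length(prelim)
  t_c <- rep_len(t_c, n); gdd <- rep_len(gdd, n)
  p_ann <- rep_len(p_ann, n); p_win <- rep_len(p_win, n)
  out <- integer(n)
  bet <- prelim == FOREST_PRELIM[["broadleaf_evergreen"]]
  out[bet] <- ifelse(t_c[bet] > 15.5, PFT_CODES[["bet_tropical"]],
                     PFT_CODES[["bet_temperate"]])
  bdt <- prelim == FOREST_PRELIM[["broadleaf_deciduous"]]
  out[bdt] <- ifelse(t_c[bdt] > 15.5, PFT_CODES[["bdt_tropical"]],
                     ifelse(t_c[bdt] > -15 & gdd[bdt] > 1200,
                            PFT_CODES[["bdt_temperate"]],
                            PFT_CODES[["bdt_boreal"]]))
  net <- prelim == FOREST_PRELIM[["needleleaf_evergreen"]]
  out[net] <- ifelse(t_c[net] > -19 & gdd[net] > 600,
                     PFT_CODES[["net_temperate"]], PFT_CODES[["net_boreal"]])
  out[prelim == FOREST_PRELIM[["needleleaf_deciduous"]]] <- PFT_CODES[["ndt"]]
  shr <- prelim == FOREST_PRELIM[["shrub"]]
  temperate <- t_c > -19 & gdd > 600
  evergreen <- p_ann > 520 & p_win > 2 / 3 * p_ann
  out[shr] <- ifelse(temperate[shr],
                     ifelse(evergreen[shr], PFT_CODES[["bes_temperate"]],
                            PFT_CODES[["bds_temperate"]]),
                     PFT_CODES[["bds_boreal"]])
  out
}

#' Subdivide grassland by climate
#'
#' First match in table order: arctic C3 (`GDD < 400`); C3 (`GDD >= 400` and
#' warmest month <= 22 C, or at least six months simultaneously dry
#' (<= 25 mm) and hot (> 22 C)); C4 (`GDD >= 400`, coldest month >= 22 C and
#' driest month > 25 mm); otherwise mixed C3/C4 (one code carrying the 50/50
#' semantic).
#'
#' @param t_c,t_w,gdd,p_driest,n_dry_hot bioclimatic indicators
#'   (vectorised).
#' @param c4_on_warmest evaluate the C4 temperature clause on the warmest
#'   rather than the printed coldest month (non-normative switch; default
#'   `FALSE`).
#' @return Integer PFT codes 12-15.
#' @export
classify_grass <- function(t_c, t_w, gdd, p_driest, n_dry_hot,
                           c4_on_warmest = FALSE) {
  n <- max(length(t_c), length(t_w), length(gdd), length(p_driest),
           length(n_dry_hot))
  t_c <- rep_len(t_c, n); t_w <- rep_len(t_w, n); gdd <- rep_len(gdd, n)
  p_driest <- rep_len(p_driest, n); n_dry_hot <- rep_len(n_dry_hot, n)
  t_c4 <- if (c4_on_warmest) t_w else t_c
  out <- rep(PFT_CODES[["c3c4_mixed"]], n)
  c4 <- gdd >= 400 & t_c4 >= 22 & p_driest > 25
  out[c4] <- PFT_CODES[["c4_grass"]]
  c3 <- gdd >= 400 & (t_w <= 22 | n_dry_hot >= 6)
  out[c3] <- PFT_CODES[["c3_grass"]]
  out[gdd < 400] <- PFT_CODES[["c3_arctic"]]
  unname(out)
}

#' Subdivide a broad land map into the 20-class PFT scheme
#'
#' Forest cells are labelled by [assign_preliminary_forest()] then split by
#' [classify_forest()]; grassland by [classify_grass()]; barren, cropland,
#' urban, water and snow/ice map 1-1 to codes 16-20. Every classified cell
#' receives exactly one code.
#'
#' @param broad a `land_grid`.
#' @param baseline_prelim preliminary forest label matrix (baseline).
#' @param ind a `bioclim_indicators` (co-registered).
#' @param c4_on_warmest passed to [classify_grass()].
#' @return A `pft_grid`.
#' @export
subdivide <- function(broad, baseline_prelim, ind, c4_on_warmest = FALSE) {
  stopifnot(identical(dim(broad$codes), dim(ind$t_c)))
  codes <- broad$codes
  out <- matrix(NA_integer_, nrow(codes), ncol(codes))
  fmask <- !is.na(codes) & codes == LAND_CLASSES[["forest"]]
  if (any(fmask)) {
    prelim <- assign_preliminary_forest(broad, baseline_prelim)
    fi <- which(fmask)
    out[fi] <- classify_forest(prelim[fi], ind$t_c[fi], ind$gdd[fi],
                               ind$p_ann[fi], ind$p_win[fi])
  }
  gmask <- !is.na(codes) & codes == LAND_CLASSES[["grassland"]]
  if (any(gmask)) {
    gi <- which(gmask)
    out[gi] <- classify_grass(ind$t_c[gi], ind$t_w[gi], ind$gdd[gi],
                              ind$p_driest[gi], ind$n_dry_hot[gi],
                              c4_on_warmest)
  }
  retain <- c(barren = 16L, cropland = 17L, urban = 18L, water = 19L,
              snow_ice = 20L)
  for (nm in names(retain))
    out[!is.na(codes) & codes == LAND_CLASSES[[nm]]] <- retain[[nm]]
  pft_grid(out, broad$meta)
}

#' Collapse a PFT map back to the broad scheme
#'
#' Codes 1-11 collapse to forest, 12-15 to grassland, 16-20 to their broad
#' classes; the inverse of the refinement.
#'
#' @param pft a `pft_grid`.
#' @return A `land_grid`.
#' @export
collapse_pft <- function(pft) {
  lut <- c(rep(LAND_CLASSES[["forest"]], 11),
           rep(LAND_CLASSES[["grassland"]], 4),
           LAND_CLASSES[["barren"]], LAND_CLASSES[["cropland"]],
           LAND_CLASSES[["urban"]], LAND_CLASSES[["water"]],
           LAND_CLASSES[["snow_ice"]])
  codes <- pft$codes
  out <- matrix(NA_integer_, nrow(codes), ncol(codes))
  ok <- !is.na(codes)
  out[ok] <- lut[codes[ok]]
  land_grid(out, pft$meta)
}
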