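#' @useDynLib pftsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm fft predict
#' @importFrom utils read.csv write.csv
NULL

# Broad land-class scheme. Water and permanent snow/ice are frozen: they take
# no part in demand, suitability learning, or allocation.
#' Broad land-class codes
#'
#' The seven-class scheme used throughout the simulation: 1 forest,
#' 2 grassland, 3 barren, 4 cropland, 5 urban, 6 water, 7 permanent snow/ice.
#' Classes 1-5 are "active" (simulated); 6-7 are frozen.
#'
#' @format Named integer vector of length 7.
#' @export
LAND_CLASSES <- c(
  forest = 1L, grassland = 2L, barren = 3L, cropland = 4L,
  urban = 5L, water = 6L, snow_ice = 7L
)

#' @rdname LAND_CLASSES
#' @export
ACTIVE_CLASSES <- LAND_CLASSES[1:5]

#' @rdname LAND_CLASSES
#' @export
FROZEN_CLASSES <- LAND_CLASSES[6:7]

# nodata sentinel used on disk (uint8 payload); in memory nodata is NA
NODATA_CODE <- 255L
KM_PER_DEGREE <- 111.32

#' Grid georeference metadata
#'
#' Describes a regular raster grid: dimensions, cell size in km, and the
#' geographic coordinate of the top-left corner. Row 1 is the northernmost
#' row; cell latitude is evaluated at the cell centre.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_km cell edge length in km (default 1).
#' @param origin numeric length-2 `(x, y)` of the top-left corner; `y` is the
#'   latitude of the grid's northern edge in degrees.
#' @return An object of class `grid_meta`.
#' @export
grid_meta <- function(n_rows, n_cols, cell_km = 1, origin = c(0, 60)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_km > 0, length(origin) == 2)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_km = as.numeric(cell_km), origin = as.numeric(origin)),
    class = "grid_meta"
  )
}

#' Latitude of each row's cell centres
#'
#' @param meta a `grid_meta`.
#' @return Numeric vector of length `n_rows`, northernmost row first.
#' @export
row_latitudes <- function(meta) {
  meta$origin[2] - (seq_len(meta$n_rows) - 0.5) * meta$cell_km / KM_PER_DEGREE
}

same_meta <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_km, b$cell_km)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Categorical land-class raster
#'
#' @param codes integer matrix of broad class codes (1-7) with `NA` as nodata.
#' @param meta a `grid_meta` matching `dim(codes)`; built from the matrix
#'   shape if omitted.
#' @return An object of class `land_grid`.
#' @export
land_grid <- function(codes, meta = NULL) {
  codes <- as_code_matrix(codes)
  if (is.null(meta)) meta <- grid_meta(nrow(codes), ncol(codes))
  stopifnot(inherits(meta, "grid_meta"),
            nrow(codes) == meta$n_rows, ncol(codes) == meta$n_cols)
  bad <- codes[!is.na(codes)]
  bad <- bad[bad < 1L | bad > 7L]
  if (length(bad)) {
    stop("land_grid codes outside the 7-class scheme: ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(meta = meta, codes = codes), class = "land_grid")
}

#' 20-class plant-functional-type raster
#'
#' Codes: 1 BET tropical, 2 BET temperate, 3 BDT tropical, 4 BDT temperate,
#' 5 BDT boreal, 6 NET temperate, 7 NET boreal, 8 NDT, 9 BES temperate,
#' 10 BDS temperate, 11 BDS boreal, 12 arctic C3 grass, 13 C3 grass,
#' 14 C4 grass, 15 mixed C3/C4 grass, 16 barren, 17 cropland, 18 urban,
#' 19 water, 20 permanent snow/ice.
#'
#' @param codes integer matrix of PFT codes (1-20) with `NA` as nodata.
#' @param meta a `grid_meta`; built from the matrix shape if omitted.
#' @return An object of class `pft_grid`.
#' @export
pft_grid <- function(codes, meta = NULL) {
  codes <- as_code_matrix(codes)
  if (is.null(meta)) meta <- grid_meta(nrow(codes), ncol(codes))
  stopifnot(inherits(meta, "grid_meta"),
            nrow(codes) == meta$n_rows, ncol(codes) == meta$n_cols)
  bad <- codes[!is.na(codes)]
  bad <- bad[bad < 1L | bad > 20L]
  if (length(bad)) {
    stop("pft_grid codes outside the 20-class scheme: ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(meta = meta, codes = codes), class = "pft_grid")
}

#' Region-id raster
#'
#' @param region_id integer matrix of region ids `1..n_regions`, `NA` nodata.
#' @param meta a `grid_meta`; built from the matrix shape if omitted.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(region_id, meta = NULL) {
  region_id <- as_code_matrix(region_id)
  if (is.null(meta)) meta <- grid_meta(nrow(region_id), ncol(region_id))
  stopifnot(nrow(region_id) == meta$n_rows, ncol(region_id) == meta$n_cols)
  ids <- region_id[!is.na(region_id)]
  if (length(ids) && any(ids < 1L)) stop("region ids must be >= 1")
  structure(list(meta = meta, region_id = region_id,
                 n_regions = if (length(ids)) max(ids) else 0L),
            class = "region_mask")
}

as_code_matrix <- function(x) {
  if (!is.matrix(x)) stop("expected a matrix")
  storage.mode(x) <- "integer"
  x
}

#' Per-class cell census of a land grid
#'
#' @param grid a `land_grid` (or `pft_grid`).
#' @param classes codes to count (default the 7 broad classes).
#' @return Named integer vector of cell counts.
#' @export
census <- function(grid, classes = LAND_CLASSES) {
  tab <- tabulate(grid$codes[!is.na(grid$codes)], nbins = max(classes))
  structure(tab[classes], names = names(classes))
}

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("<land_grid> %d x %d cells (%.3g km), %d classified\n",
              x$meta$n_rows, x$meta$n_cols, x$meta$cell_km,
              sum(!is.na(x$codes))))
  cs <- census(x)
  cat("  census:", paste(sprintf("%s=%d", names(cs), cs), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.pft_grid <- function(x, ...) {
  cat(sprintf("<pft_grid> %d x %d cells, %d classified, %d distinct codes\n",
              x$meta$n_rows, x$meta$n_cols, sum(!is.na(x$codes)),
              length(unique(x$codes[!is.na(x$codes)]))))
  invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d cells, %d regions\n",
              x$meta$n_rows, x$meta$n_cols, x$n_regions))
  invisible(x)
}

#' Simulation run configuration
#'
#' @param seed integer seed governing all stochastic stages.
#' @param horizon_years simulation years (default 2015-2100 step 5).
#' @param tolerance_cells demand tolerance in cells; `NULL` means the default
#'   `max(1, 0.1%)` of each class demand.
#' @param max_iterations CA macro-iteration cap per step.
#' @param neighborhood_window odd window width for the neighbourhood effect.
#' @param neighborhood_floor floor applied to the neighbourhood factor so a
#'   class with no neighbours can still nucleate; 0 gives the literal product.
#' @param sample_fraction training/evaluation sampling fraction.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       horizon_years = seq(2015L, 2100L, by = 5L),
                       tolerance_cells = NULL,
                       max_iterations = 300L,
                       neighborhood_window = 3L,
                       neighborhood_floor = 1e-4,
                       sample_fraction = 0.10) {
  stopifnot(neighborhood_window %% 2 == 1, neighborhood_window >= 3,
            sample_fraction > 0, sample_fraction <= 1,
            is.null(tolerance_cells) || tolerance_cells >= 0,
            max_iterations >= 1, neighborhood_floor >= 0)
  structure(list(seed = as.integer(seed),
                 horizon_years = as.integer(horizon_years),
                 tolerance_cells = tolerance_cells,
                 max_iterations = as.integer(max_iterations),
                 neighborhood_window = as.integer(neighborhood_window),
                 neighborhood_floor = neighborhood_floor,
                 sample_fraction = sample_fraction),
            class = "run_config")
}
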