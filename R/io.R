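# Raster payloads are single-band TIFF (uint8 for class rasters, float32 for
# continuous layers); the georeference travels in a plain-text .hdr sidecar
# (key = value, doubles printed with 17 significant digits so the
# geotransform round-trips bit-exactly). Nodata is 255 in uint8 payloads and
# NaN in float32 payloads.

hdr_path <- function(path) paste0(path, ".hdr")

write_hdr <- function(meta, path, nodata, scale = NULL, offset = NULL) {
  lines <- c(
    sprintf("nrows = %d", meta$n_rows),
    sprintf("ncols = %d", meta$n_cols),
    sprintf("cell_km = %.17g", meta$cell_km),
    sprintf("origin_x = %.17g", meta$origin[1]),
    sprintf("origin_y = %.17g", meta$origin[2]),
    sprintf("nodata = %s", nodata)
  )
  if (!is.null(scale))
    lines <- c(lines, sprintf("scale = %.17g", scale),
               sprintf("offset = %.17g", offset))
  writeLines(lines, hdr_path(path))
}

read_hdr <- function(path) {
  hp <- hdr_path(path)
  if (!file.exists(hp)) stop("missing sidecar header: ", hp)
  kv <- read.table(hp, sep = "=", strip.white = TRUE,
                   col.names = c("key", "value"), colClasses = "character")
  val <- function(k) kv$value[match(k, kv$key)]
  sc <- val("scale")
  list(meta = grid_meta(as.integer(val("nrows")), as.integer(val("ncols")),
                        cell_km = as.numeric(val("cell_km")),
                        origin = c(as.numeric(val("origin_x")),
                                   as.numeric(val("origin_y")))),
       nodata = as.numeric(val("nodata")),
       scale = if (is.na(sc)) 1 else as.numeric(sc),
       offset = if (is.na(sc)) 0 else as.numeric(val("offset")))
}

#' Write a categorical class raster
#'
#' Writes a `land_grid`, `pft_grid` or `region_mask` as a single-band uint8
#' TIFF (nodata 255) plus a text sidecar carrying the georeference.
#'
#' @param grid the raster object.
#' @param path output path (conventionally `.tif`).
#' @return `path`, invisibly.
#' @export
write_class_raster <- function(grid, path) {
  codes <- if (inherits(grid, "region_mask")) grid$region_id else grid$codes
  pay <- codes
  pay[is.na(pay)] <- NODATA_CODE
  if (any(pay < 0L | pay > 255L)) stop("codes do not fit a uint8 payload")
  tiff::writeTIFF(matrix(pay / 255, nrow(pay), ncol(pay)), path,
                  bits.per.sample = 8L, compression = "none")
  write_hdr(grid$meta, path, NODATA_CODE)
  invisible(path)
}

read_code_payload <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 3L) stop("multi-band raster not supported: ", path)
  hdr <- read_hdr(path)
  codes <- matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
  codes[codes == hdr$nodata] <- NA_integer_
  list(codes = codes, meta = hdr$meta)
}

#' Read a categorical class raster
#'
#' @param path raster path written by [write_class_raster()].
#' @param scheme one of `"land"` (7 broad classes), `"pft"` (20 classes) or
#'   `"region"`; values outside the scheme are rejected with a schema error.
#' @return A `land_grid`, `pft_grid` or `region_mask`.
#' @export
read_class_raster <- function(path, scheme = c("land", "pft", "region")) {
  scheme <- match.arg(scheme)
  p <- read_code_payload(path)
  switch(scheme,
         land = land_grid(p$codes, p$meta),
         pft = pft_grid(p$codes, p$meta),
         region = region_mask(p$codes, p$meta))
}

#' Write / read a continuous float32 raster layer
#'
#' Continuous layers (drivers, climate normals, suitability surfaces) are
#' float32 single-band TIFFs with NaN as nodata.
#'
#' @param values numeric matrix.
#' @param meta a `grid_meta`.
#' @param path file path.
#' @return `path` invisibly (write); a list with `values` and `meta` (read).
#' @export
write_float_raster <- function(values, meta, path) {
  stopifnot(is.matrix(values), nrow(values) == meta$n_rows,
            ncol(values) == meta$n_cols)
  # the TIFF writer expects [0, 1]: data are stored scaled to [0, 0.9] with
  # 1.0 as the in-payload nodata sentinel; the linear scale/offset travels
  # in the sidecar (the usual raster scale/offset convention)
  fin <- values[is.finite(values)]
  offset <- if (length(fin)) min(fin) else 0
  spread <- if (length(fin) && max(fin) > offset) max(fin) - offset else 1
  scale <- spread / 0.9
  v <- (values - offset) / scale
  v[!is.finite(v)] <- 1
  tiff::writeTIFF(v, path, bits.per.sample = 32L, compression = "none")
  write_hdr(meta, path, 1, scale = scale, offset = offset)
  invisible(path)
}

#' @rdname write_float_raster
#' @export
read_float_raster <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 3L) stop("multi-band raster not supported: ", path)
  hdr <- read_hdr(path)
  raw <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
  # 32-bit payloads are integer-quantised at ~2.3e-10, so the sentinel (1.0,
  # vs data in [0, 0.9]) is detected with a midpoint threshold, not equality
  nodata <- raw > (0.9 + hdr$nodata) / 2
  vals <- raw * hdr$scale + hdr$offset
  vals[nodata] <- NA_real_
  list(values = vals, meta = hdr$meta)
}

#' Coarse per-region per-class area series
#'
#' Container for the coarse demand trajectories (the top-down constraint the
#' calibration ingests): an area in km^2 for every (region, class, year).
#'
#' @param area 3-d array `[region, class, year]`, km^2, with dimnames
#'   `region` = "1".."R", `class` = class names, `year` = years.
#' @param years integer years, strictly increasing, uniform step.
#' @return An object of class `coarse_series`.
#' @export
coarse_series <- function(area, years) {
  stopifnot(length(dim(area)) == 3, dim(area)[3] == length(years))
  if (any(area < 0)) stop("coarse areas must be >= 0")
  years <- as.integer(years)
  if (length(years) > 1) {
    d <- diff(years)
    if (any(d <= 0) || length(unique(d)) > 1)
      stop("years must be strictly increasing with a uniform step")
  }
  dimnames(area)[[3]] <- as.character(years)
  structure(list(area = area, years = years), class = "coarse_series")
}

#' @export
print.coarse_series <- function(x, ...) {
  d <- dim(x$area)
  cat(sprintf("<coarse_series> %d regions x %d classes x %d years (%d-%d)\n",
              d[1], d[2], d[3], min(x$years), max(x$years)))
  invisible(x)
}

#' Read a coarse area series from CSV
#'
#' Expects columns `region, class, year, area_km2` where `class` holds source
#' class names. `class_map` maps each source name onto a broad class name;
#' source classes sharing a target are summed.
#'
#' @param path CSV path.
#' @param class_map named character vector: source name -> broad class name
#'   (one of `names(LAND_CLASSES)`).
#' @return A `coarse_series` whose class dimension uses broad class names.
#' @export
read_coarse_series <- function(path, class_map) {
  if (length(class_map) == 0) stop("empty class_map")
  if (!all(class_map %in% names(LAND_CLASSES)))
    stop("class_map targets must be broad class names")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "class", "year", "area_km2")
  if (!all(need %in% names(df))) stop("coarse series CSV needs columns: ",
                                      paste(need, collapse = ", "))
  unmapped <- setdiff(unique(df$class), names(class_map))
  if (length(unmapped))
    stop("unmapped source classes: ", paste(unmapped, collapse = ", "))
  df$target <- unname(class_map[df$class])
  regions <- sort(unique(df$region))
  years <- sort(unique(df$year))
  targets <- intersect(names(LAND_CLASSES), unique(df$target))
  area <- array(0, dim = c(length(regions), length(targets), length(years)),
                dimnames = list(region = as.character(regions),
                                class = targets, year = as.character(years)))
  for (i in seq_len(nrow(df))) {
    area[as.character(df$region[i]), df$target[i], as.character(df$year[i])] <-
      area[as.character(df$region[i]), df$target[i], as.character(df$year[i])] +
      df$area_km2[i]
  }
  coarse_series(area, years)
}

#' Write a coarse area series to CSV
#'
#' @param series a `coarse_series`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_coarse_series <- function(series, path) {
  dn <- dimnames(series$area)
  df <- expand.grid(region = dn$region, class = dn$class, year = dn$year,
                    stringsAsFactors = FALSE)
  df$area_km2 <- as.vector(series$area)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
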