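# Demand calibration: per-region per-class change trajectories are extracted
# from the coarse series and applied to the fine baseline census, then the
# per-region totals are harmonised back to the actual active land area.
# Rates are handled as gross ratios g = area_t / area_{t-1} with net rate
# n = g - 1: branch 1 of the calibration uses n, every other branch uses g,
# the only reading under which no-change (g = 1) is a fixed point everywhere.

#' Gross and net change rate of a coarse series entry
#'
#' @param series a `coarse_series`.
#' @param r region id (or index into the region dimension).
#' @param j class name or index.
#' @param t timestep index (>= 2).
#' @return List with `gross` (ratio, >= 0) and `net` (`gross - 1`). A zero
#'   area at `t-1` yields `gross = 1, net = 0` (hold constant).
#' @export
change_rate <- function(series, r, j, t) {
  if (t < 2) stop("change rate needs t >= 2")
  a_prev <- series$area[r, j, t - 1]
  a_curr <- series$area[r, j, t]
  if (is.na(a_prev) || is.na(a_curr)) stop("unknown (r, j, t)")
  g <- if (a_prev == 0) 1 else a_curr / a_prev
  list(gross = g, net = g - 1)
}

#' One calibration step for one class
#'
#' Applies the coarse trend to a fine-scale area. Non-urban classes: when the
#' coarse area undershoots the fine area (`luh2_prev / prev < 1`) the net
#' rate is damped by that ratio, `prev * (net * ratio + 1)`; otherwise the
#' gross ratio applies directly. Urban never shrinks: the gross ratio applies
#' only when >= 1.
#'
#' @param prev calibrated fine area at `t-1` (km^2, >= 0).
#' @param luh2_prev,luh2_curr coarse areas at `t-1`, `t` (km^2).
#' @param is_urban logical.
#' @return Calibrated area at `t` (km^2).
#' @export
calibrate_step <- function(prev, luh2_prev, luh2_curr, is_urban = FALSE) {
  if (prev < 0 || luh2_prev < 0 || luh2_curr < 0) stop("negative areas")
  gross <- if (luh2_prev == 0) 1 else luh2_curr / luh2_prev
  net <- gross - 1
  if (is_urban) return(if (gross >= 1) prev * gross else prev)
  if (prev == 0) return(0)
  ratio <- luh2_prev / prev
  if (ratio < 1) prev * (net * ratio + 1) else prev * gross
}

#' Harmonise per-class areas to the actual active total
#'
#' Rescales the non-urban active classes proportionally so the active total
#' (including urban, which is left untouched) equals `total_active`.
#'
#' @param areas named numeric vector of non-urban active areas (km^2).
#' @param urban urban area (km^2), not rescaled.
#' @param total_active actual active (non-frozen) land area of the region.
#' @return Named vector of rescaled non-urban areas; together with `urban`
#'   they sum exactly to `total_active`.
#' @export
harmonize <- function(areas, urban, total_active) {
  if (total_active <= urban) stop("total_active must exceed urban area")
  s <- sum(areas)
  if (s <= 0) stop("all non-urban areas zero: shares undefined")
  (total_active - urban) * areas / s
}

#' Build the calibrated, harmonised demand table
#'
#' Year-0 demand is the baseline per-region census (cell counts times cell
#' area). Each later step applies [calibrate_step()] per class and then
#' [harmonize()] per region. Water and snow/ice are frozen: held at their
#' baseline areas and excluded from harmonisation.
#'
#' @param baseline a `land_grid` (year-0 map).
#' @param regions a co-registered `region_mask`.
#' @param series a `coarse_series` covering the five active classes and all
#'   regions; its years define the demand years.
#' @return An object of class `demand_table`: `area` array
#'   `[region, class(7), year]` (km^2), `region_total_active`, `frozen_area`,
#'   `years`.
#' @export
build_demand <- function(baseline, regions, series) {
  stopifnot(same_meta(baseline$meta, regions$meta))
  years <- series$years
  R <- regions$n_regions
  sr <- dimnames(series$area)$region
  if (!all(as.character(seq_len(R)) %in% sr))
    stop("region present in mask but absent from series: ",
         paste(setdiff(as.character(seq_len(R)), sr), collapse = ", "))
  acts <- names(ACTIVE_CLASSES)
  if (!all(acts %in% dimnames(series$area)$class))
    stop("series must cover all active classes")
  cell_area <- baseline$meta$cell_km^2
  area <- array(0, dim = c(R, 7, length(years)),
                dimnames = list(region = as.character(seq_len(R)),
                                class = names(LAND_CLASSES),
                                year = as.character(years)))
  frozen_area <- matrix(0, R, 2,
                        dimnames = list(NULL, names(FROZEN_CLASSES)))
  total_active <- numeric(R)
  for (r in seq_len(R)) {
    inr <- regions$region_id == r & !is.na(baseline$codes)
    cs <- tabulate(baseline$codes[inr], 7) * cell_area
    area[r, , 1] <- cs
    frozen_area[r, ] <- cs[FROZEN_CLASSES]
    total_active[r] <- sum(cs[ACTIVE_CLASSES])
  }
  for (t in seq_along(years)[-1]) {
    for (r in seq_len(R)) {
      rr <- as.character(r)
      prelim <- vapply(acts, function(j) {
        calibrate_step(area[r, j, t - 1],
                       series$area[rr, j, t - 1], series$area[rr, j, t],
                       is_urban = (j == "urban"))
      }, numeric(1))
      urban <- prelim[["urban"]]
      non_urban <- prelim[setdiff(acts, "urban")]
      area[r, setdiff(acts, "urban"), t] <-
        harmonize(non_urban, urban, total_active[r])
      area[r, "urban", t] <- urban
      area[r, names(FROZEN_CLASSES), t] <- frozen_area[r, ]
    }
  }
  structure(list(area = area, region_total_active = total_active,
                 frozen_area = frozen_area, years = years),
            class = "demand_table")
}

#' @export
print.demand_table <- function(x, ...) {
  d <- dim(x$area)
  cat(sprintf("<demand_table> %d regions x %d classes x %d years\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Convert a demand table to integer cell counts
#'
#' Largest-remainder rounding of the active-class demands per (region, year)
#' so the rounded counts sum exactly to the region's active cell count.
#'
#' @param demand a `demand_table`.
#' @param baseline the baseline `land_grid` (supplies cell area).
#' @param regions the `region_mask` (supplies active cell counts).
#' @return Array `[region, active class, year]` of integer cell counts.
#' @export
demand_to_cells <- function(demand, baseline, regions) {
  acts <- names(ACTIVE_CLASSES)
  R <- dim(demand$area)[1]
  years <- demand$years
  cell_area <- baseline$meta$cell_km^2
  out <- array(0L, dim = c(R, length(acts), length(years)),
               dimnames = list(region = as.character(seq_len(R)),
                               class = acts, year = as.character(years)))
  for (r in seq_len(R)) {
    inr <- regions$region_id == r & !is.na(baseline$codes)
    n_active <- sum(baseline$codes[inr] %in% ACTIVE_CLASSES)
    for (t in seq_along(years)) {
      raw <- demand$area[r, acts, t] / cell_area
      out[r, , t] <- largest_remainder(raw, n_active)
    }
  }
  out
}

# round non-negative shares to integers summing to `total`
largest_remainder <- function(x, total) {
  x <- pmax(x, 0)
  if (sum(x) == 0) {
    out <- integer(length(x))
    if (total > 0) out[1] <- as.integer(total)
    return(out)
  }
  scaled <- x / sum(x) * total
  fl <- floor(scaled)
  left <- as.integer(round(total - sum(fl)))
  ord <- order(scaled - fl, decreasing = TRUE)
  fl[ord[seq_len(left)]] <- fl[ord[seq_len(left)]] + 1
  as.integer(fl)
}

#' Write / read a demand table as CSV
#'
#' Long format with columns `region, class, year, area_km2`.
#'
#' @param demand a `demand_table`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `demand_table` (read).
#' @export
write_demand_table <- function(demand, path) {
  dn <- dimnames(demand$area)
  df <- expand.grid(region = dn$region, class = dn$class, year = dn$year,
                    stringsAsFactors = FALSE)
  df$area_km2 <- as.vector(demand$area)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_demand_table
#' @export
read_demand_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  regions <- sort(unique(as.integer(df$region)))
  years <- sort(unique(df$year))
  area <- array(0, dim = c(length(regions), 7, length(years)),
                dimnames = list(region = as.character(regions),
                                class = names(LAND_CLASSES),
                                year = as.character(years)))
  for (i in seq_len(nrow(df)))
    area[as.character(df$region[i]), df$class[i], as.character(df$year[i])] <-
      df$area_km2[i]
  frozen_area <- area[, names(FROZEN_CLASSES), 1, drop = FALSE]
  dim(frozen_area) <- c(length(regions), 2)
  colnames(frozen_area) <- names(FROZEN_CLASSES)
  structure(list(area = area,
                 region_total_active =
                   rowSums(area[, names(ACTIVE_CLASSES), 1, drop = FALSE]),
                 frozen_area = frozen_area, years = as.integer(years)),
            class = "demand_table")
}
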