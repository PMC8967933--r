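# Cellular-automata allocation engine. A cell's total conversion probability
# is the product of its learned suitability, the neighbourhood effect of the
# destination class, the destination's adaptive inertia, and a hard 0/1
# conversion constraint; the next state is drawn by roulette selection.
# Macro-iterations sweep all active cells in a fresh seeded random order
# until every class is within tolerance of its demand.

#' Default conversion-constraint matrix
#'
#' 7 x 7 indicator `cons[k, j]` of whether class k may convert to class j.
#' Diagonal 1 everywhere; water and snow/ice are frozen (no conversions in
#' or out); urban never converts away.
#'
#' @return Integer matrix with class-name dimnames.
#' @export
default_conversion_matrix <- function() {
  cons <- matrix(1L, 7, 7, dimnames = list(names(LAND_CLASSES),
                                           names(LAND_CLASSES)))
  for (f in names(FROZEN_CLASSES)) {
    cons[f, ] <- 0L
    cons[, f] <- 0L
    cons[f, f] <- 1L
  }
  cons["urban", ] <- 0L
  cons["urban", "urban"] <- 1L
  cons
}

validate_cons <- function(cons) {
  stopifnot(is.matrix(cons), nrow(cons) == 7, ncol(cons) == 7,
            all(cons %in% c(0L, 1L)), all(diag(cons) == 1L))
  storage.mode(cons) <- "integer"
  cons
}

#' Neighbourhood effect of one class
#'
#' Per cell, the share of class-`j` cells in the `window` x `window`
#' neighbourhood excluding the centre; edge cells use the truncated window's
#' in-grid neighbours as denominator.
#'
#' @param grid a `land_grid`.
#' @param j class code.
#' @param window odd window width >= 3.
#' @return Numeric matrix in [0, 1].
#' @export
neighborhood <- function(grid, j, window = 3L) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  codes <- grid$codes
  nr <- nrow(codes); nc <- ncol(codes)
  half <- window %/% 2
  isj <- !is.na(codes) & codes == j
  cnt <- matrix(0, nr, nc)
  avail <- matrix(0, nr, nc)
  ones <- matrix(1, nr, nc)
  for (dr in -half:half) for (dc in -half:half) {
    if (dr == 0 && dc == 0) next
    sr <- intersect(seq_len(nr), seq_len(nr) - dr)
    sc <- intersect(seq_len(nc), seq_len(nc) - dc)
    cnt[sr, sc] <- cnt[sr, sc] + isj[sr + dr, sc + dc]
    avail[sr, sc] <- avail[sr, sc] + ones[sr + dr, sc + dc]
  }
  out <- cnt / pmax(avail, 1)
  out
}

#' Total conversion probability of one cell-class pair
#'
#' The product `pg * max(neigh, floor) * inertia * cons`: a forbidden
#' conversion is exactly 0; the neighbourhood floor lets a class with no
#' neighbours nucleate (0 reproduces the literal product).
#'
#' @param pg suitability probability in [0, 1].
#' @param neigh neighbourhood effect in [0, 1].
#' @param inertia adaptive inertia coefficient (> 0).
#' @param cons 0/1 conversion indicator.
#' @param floor neighbourhood floor (>= 0).
#' @return Non-negative score.
#' @export
total_probability <- function(pg, neigh, inertia, cons, floor = 1e-4) {
  stopifnot(all(pg >= 0 & pg <= 1), all(neigh >= 0 & neigh <= 1),
            all(inertia > 0))
  ifelse(cons == 0, 0, pg * pmax(neigh, floor) * inertia)
}

#' Adaptive inertia update
#'
#' Adjusts a class's inertia from its last two demand gaps
#' (`d = demand - allocated`, in cells): unchanged while the gap is not
#' worsening; scaled down by `d2/d1` when over-allocation worsens
#' (`d1 < d2 < 0`); scaled up by `d1/d2` when under-allocation worsens
#' (`0 < d2 < d1`).
#'
#' @param prev current inertia (> 0).
#' @param d1 most recent gap (cells).
#' @param d2 gap of the iteration before (cells).
#' @return Updated inertia.
#' @export
update_inertia <- function(prev, d1, d2) {
  stopifnot(prev > 0)
  if (abs(d1) <= abs(d2)) return(prev)
  if (d1 < d2 && d2 < 0) return(prev * d2 / d1)
  if (0 < d2 && d2 < d1) return(prev * d1 / d2)
  prev
}

#' Roulette selection over class scores
#'
#' Draws a class with probability proportional to its score, using the
#' current R random-number stream; an all-zero vector yields no change
#' (`NA`).
#'
#' @param tp non-negative score vector.
#' @return Selected index, or `NA_integer_` for an all-zero vector.
#' @export
roulette <- function(tp) {
  if (any(tp < 0)) stop("roulette scores must be >= 0")
  total <- sum(tp)
  if (total <= 0) return(NA_integer_)
  u <- runif(1) * total
  which(cumsum(tp) >= u)[1]
}

demand_tolerance <- function(demand, cfg) {
  if (!is.null(cfg$tolerance_cells)) rep(cfg$tolerance_cells, length(demand))
  else pmax(1, 0.001 * demand)
}

#' Allocate one region's demand onto the grid
#'
#' Runs macro-iterations over the region's active cells: each sweep visits
#' the cells in a fresh random order, computes total conversion
#' probabilities over candidate classes (conversion allowed, demand not yet
#' over-filled) and roulette-selects the next state; per-class inertia is
#' updated between sweeps from the demand-gap history. Stops when every
#' class is within tolerance of its demand or `max_iterations` is reached.
#' Frozen cells are never visited. Uses the current R random stream.
#'
#' @param grid a `land_grid` (whole raster; only this region's cells change).
#' @param regions `region_mask`.
#' @param r region id to allocate.
#' @param suit a `suitability_maps` for this region.
#' @param demand_cells named integer vector of target cell counts for the
#'   five active classes; must sum to the region's active cell count.
#' @param cons 7 x 7 conversion matrix (default [default_conversion_matrix()]).
#' @param cfg a [run_config()].
#' @param log optional function called once per macro-iteration with a
#'   one-line status string (iteration, per-class gap, inertia).
#' @return The updated `land_grid`, with attributes `iterations` and
#'   `converged`.
#' @export
allocate_step <- function(grid, regions, r, suit, demand_cells,
                          cons = default_conversion_matrix(),
                          cfg = run_config(), log = NULL) {
  cons <- validate_cons(cons)
  # ca_sweep updates the matrix in place; duplicate so the input grid (and
  # anything sharing its memory) is never mutated
  codes <- grid$codes + 0L
  active_idx <- which(regions$region_id == r & !is.na(codes) &
                        codes %in% ACTIVE_CLASSES)
  demand <- as.integer(demand_cells[names(ACTIVE_CLASSES)])
  if (anyNA(demand)) stop("demand_cells must cover the five active classes")
  if (sum(demand) != length(active_idx))
    stop(sprintf("infeasible demand: %d cells demanded, %d active cells",
                 sum(demand), length(active_idx)))
  pg <- vapply(names(ACTIVE_CLASSES), function(nm) as.vector(suit[[nm]]),
               numeric(length(codes)))
  allocated <- vapply(ACTIVE_CLASSES, function(k)
    sum(codes[active_idx] == k), integer(1))
  inertia <- rep(1, 5)
  tol <- demand_tolerance(demand, cfg)
  gap_prev <- NULL
  it <- 0L
  converged <- all(abs(demand - allocated) <= tol)
  while (!converged && it < cfg$max_iterations) {
    it <- it + 1L
    visit <- sample(active_idx)
    alloc_io <- as.integer(allocated)
    ca_sweep(codes, as.integer(visit - 1L), pg, inertia, cons,
             demand, alloc_io, cfg$neighborhood_window,
             cfg$neighborhood_floor)
    allocated <- alloc_io
    gap <- demand - allocated
    if (!is.null(log))
      log(sprintf("region %d iter %d gap [%s] inertia [%s]", r, it,
                  paste(gap, collapse = " "),
                  paste(sprintf("%.3g", inertia), collapse = " ")))
    if (!is.null(gap_prev))
      inertia <- vapply(1:5, function(j)
        update_inertia(inertia[j], gap[j], gap_prev[j]), numeric(1))
    gap_prev <- gap
    converged <- all(abs(gap) <= tol)
  }
  out <- land_grid(codes, grid$meta)
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}

#' Run a multi-step land-change simulation
#'
#' One [allocate_step()] per region per timestep, each initialised from the
#' previous output. Fully reproducible in `cfg$seed`.
#'
#' @param initial baseline `land_grid`.
#' @param regions `region_mask`.
#' @param suit a single `suitability_maps` used for every region, or a named
#'   list of them (`"1"`, `"2"`, ...) per region.
#' @param demand a `demand_table` covering `cfg$horizon_years` (its own
#'   years are used if `cfg$horizon_years` is not a subset).
#' @param cons 7 x 7 conversion matrix.
#' @param cfg a [run_config()].
#' @param log optional per-iteration logging function.
#' @return Named list of `land_grid`s, one per year (first = initial).
#' @export
run_simulation <- function(initial, regions, suit, demand,
                           cons = default_conversion_matrix(),
                           cfg = run_config(), log = NULL) {
  years <- demand$years
  cells <- demand_to_cells(demand, initial, regions)
  set.seed(cfg$seed)
  out <- list()
  out[[as.character(years[1])]] <- initial
  grid <- initial
  per_region <- !inherits(suit, "suitability_maps")
  for (t in seq_along(years)[-1]) {
    for (r in seq_len(regions$n_regions)) {
      sm <- if (per_region) suit[[as.character(r)]] else suit
      grid <- allocate_step(grid, regions, r, sm,
                            structure(cells[r, , t],
                                      names = dimnames(cells)$class),
                            cons, cfg, log)
    }
    out[[as.character(years[t])]] <- grid
  }
  out
}
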