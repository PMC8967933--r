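# Map-comparison validation: confusion matrix, overall accuracy, Cohen's
# kappa, figure of merit with its four change components, block-aggregated
# net change, and class proportions.

#' Confusion matrix of two co-registered class maps
#'
#' @param observed,simulated `land_grid`s (or `pft_grid`s) on the same
#'   scheme; cells nodata in either map are excluded.
#' @param n_classes number of classes in the scheme (default 7).
#' @return Integer matrix `counts[observed, simulated]`.
#' @export
confusion <- function(observed, simulated, n_classes = 7L) {
  if (!identical(dim(observed$codes), dim(simulated$codes)))
    stop("maps have different shapes")
  ok <- !is.na(observed$codes) & !is.na(simulated$codes)
  o <- observed$codes[ok]; s <- simulated$codes[ok]
  m <- matrix(0L, n_classes, n_classes)
  tab <- table(factor(o, levels = seq_len(n_classes)),
               factor(s, levels = seq_len(n_classes)))
  m[] <- as.integer(tab)
  m
}

#' Overall accuracy from a confusion matrix
#'
#' @param m confusion matrix.
#' @return `trace / total`, a proportion in [0, 1].
#' @export
overall_accuracy <- function(m) {
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(m)) / total
}

#' Cohen's kappa from a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` from the
#' marginals.
#'
#' @param m confusion matrix.
#' @return Kappa coefficient; errors when `p_e = 1` (degenerate marginals).
#' @export
kappa_coefficient <- function(m) {
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (p_e >= 1) stop("kappa undefined: chance agreement is 1")
  (p_o - p_e) / (1 - p_e)
}

#' Figure of merit of a simulated change map
#'
#' Decomposes the cells into misses `A` (observed change, simulated
#' persistence), hits `B` (observed change simulated as the correct new
#' class), wrong-class `C` (observed change simulated as change to another
#' class) and false alarms `D` (observed persistence, simulated change);
#' `FoM = B / (A + B + C + D)`. With no observed or simulated change
#' anywhere the FoM is 0 with all components 0.
#'
#' @param obs_t0,obs_t1 observed maps at the start and end of the interval.
#' @param sim_t1 simulated end map.
#' @return List: `fom`, `components` (named counts A, B, C, D).
#' @export
figure_of_merit <- function(obs_t0, obs_t1, sim_t1) {
  if (!identical(dim(obs_t0$codes), dim(obs_t1$codes)) ||
      !identical(dim(obs_t0$codes), dim(sim_t1$codes)))
    stop("maps have different shapes")
  ok <- !is.na(obs_t0$codes) & !is.na(obs_t1$codes) & !is.na(sim_t1$codes)
  o0 <- obs_t0$codes[ok]; o1 <- obs_t1$codes[ok]; s1 <- sim_t1$codes[ok]
  obs_chg <- o0 != o1
  sim_chg <- o0 != s1
  A <- sum(obs_chg & !sim_chg)
  B <- sum(obs_chg & sim_chg & s1 == o1)
  C <- sum(obs_chg & sim_chg & s1 != o1)
  D <- sum(!obs_chg & sim_chg)
  denom <- A + B + C + D
  list(fom = if (denom == 0) 0 else B / denom,
       components = c(A = A, B = B, C = C, D = D))
}

#' Block-aggregated net change of one class
#'
#' Net change in class-`j` area (km^2) per `block` x `block` cell block;
#' partial edge blocks aggregate their available cells as-is.
#'
#' @param grid_t0,grid_t1 co-registered `land_grid`s.
#' @param j class code.
#' @param block block edge length in cells (>= 1).
#' @return Numeric matrix of net change (km^2), one entry per block.
#' @export
block_change <- function(grid_t0, grid_t1, j, block = 10L) {
  if (block < 1) stop("block must be >= 1")
  if (!identical(dim(grid_t0$codes), dim(grid_t1$codes)))
    stop("maps have different shapes")
  delta <- (!is.na(grid_t1$codes) & grid_t1$codes == j) -
    (!is.na(grid_t0$codes) & grid_t0$codes == j)
  nr <- nrow(delta); nc <- ncol(delta)
  br <- (seq_len(nr) - 1L) %/% block + 1L
  bc <- (seq_len(nc) - 1L) %/% block + 1L
  tmp <- rowsum(delta, br)
  out <- t(rowsum(t(tmp), bc))
  dimnames(out) <- NULL
  out * grid_t0$meta$cell_km^2
}

#' Class proportions of a map
#'
#' @param grid a `land_grid` or `pft_grid`.
#' @param classes codes to report (default: the grid's scheme).
#' @return Named numeric vector of proportions over classified cells,
#'   summing to 1.
#' @export
class_proportions <- function(grid, classes = NULL) {
  if (is.null(classes))
    classes <- if (inherits(grid, "pft_grid")) PFT_CODES else LAND_CLASSES
  v <- grid$codes[!is.na(grid$codes)]
  if (!length(v)) stop("empty grid")
  tab <- tabulate(v, nbins = max(classes))
  structure(tab[classes] / length(v), names = names(classes))
}

#' Full validation report for a simulated map
#'
#' @param obs_t0,obs_t1,sim_t1 co-registered `land_grid`s.
#' @param mask_frozen exclude cells frozen at `obs_t0` (water, snow/ice)
#'   from the agreement metrics.
#' @return data.frame with kappa, overall accuracy, FoM and the four change
#'   components.
#' @export
validation_report <- function(obs_t0, obs_t1, sim_t1, mask_frozen = FALSE) {
  o1 <- obs_t1; s1 <- sim_t1
  if (mask_frozen) {
    frozen <- !is.na(obs_t0$codes) & obs_t0$codes %in% FROZEN_CLASSES
    o1$codes[frozen] <- NA_integer_
    s1$codes[frozen] <- NA_integer_
  }
  m <- confusion(o1, s1)
  f <- figure_of_merit(obs_t0, obs_t1, sim_t1)
  data.frame(kappa = kappa_coefficient(m), oa = overall_accuracy(m),
             fom = f$fom, A = f$components[["A"]], B = f$components[["B"]],
             C = f$components[["C"]], D = f$components[["D"]])
}
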