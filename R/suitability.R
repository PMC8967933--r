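# Suitability-probability surfaces: a single-hidden-layer neural network
# (logistic hidden units, softmax outputs) maps min-max normalised driver
# vectors to per-class probability-of-occurrence. Training cells come from a
# per-class (or uniform) 10% random draw; accuracy is scored by ROC AUC
# computed as the rank statistic on a sampled subset.

#' Min-max normalise a driver stack
#'
#' Each layer is scaled to [0, 1] using its min/max over the cells in `mask`
#' (or all finite cells). The recorded ranges are reused at prediction time.
#'
#' @param drivers named list of numeric matrices, co-registered.
#' @param mask optional logical matrix restricting the cells used for the
#'   ranges.
#' @return List: `layers` (normalised matrices), `norm` (2 x n matrix of
#'   mins/maxs).
#' @export
normalize_drivers <- function(drivers, mask = NULL) {
  stopifnot(length(drivers) >= 1, !is.null(names(drivers)))
  norm <- vapply(drivers, function(d) {
    v <- if (is.null(mask)) d else d[mask]
    v <- v[is.finite(v)]
    r <- range(v)
    if (r[1] == r[2]) r[2] <- r[1] + 1   # constant layer maps to 0
    r
  }, numeric(2))
  layers <- Map(function(d, i) {
    pmin(pmax((d - norm[1, i]) / (norm[2, i] - norm[1, i]), 0), 1)
  }, drivers, seq_along(drivers))
  names(layers) <- names(drivers)
  list(layers = layers, norm = norm)
}

apply_norm <- function(drivers, norm) {
  if (!identical(sort(names(drivers)), sort(colnames(norm))))
    stop("driver layer names do not match the training normalisation")
  layers <- lapply(colnames(norm), function(nm) {
    pmin(pmax((drivers[[nm]] - norm[1, nm]) / (norm[2, nm] - norm[1, nm]), 0), 1)
  })
  names(layers) <- colnames(norm)
  layers
}

#' Draw a training/evaluation sample of cells
#'
#' Random draw without replacement over the classified active cells of each
#' region: per class (`stratified = TRUE`, the default, each class sampled at
#' `fraction` of its cell count, at least 1 cell) or uniform over the region.
#' Nodata and frozen-class cells are excluded.
#'
#' @param grid a `land_grid`.
#' @param regions a co-registered `region_mask`.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @param stratified per-class (default) or uniform-over-region sampling.
#' @return A data.frame of class `training_sample` with columns `cell`
#'   (linear index), `region`, `class`.
#' @export
sample_cells <- function(grid, regions, fraction, seed, stratified = TRUE) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  set.seed(seed)
  ok <- !is.na(grid$codes) & grid$codes %in% ACTIVE_CLASSES &
    !is.na(regions$region_id)
  idx <- which(ok)
  if (!length(idx)) stop("no active classified cells to sample")
  reg <- regions$region_id[idx]
  cls <- grid$codes[idx]
  rows <- integer(0)
  for (r in sort(unique(reg))) {
    in_r <- idx[reg == r]
    if (stratified) {
      for (k in sort(unique(grid$codes[in_r]))) {
        pool <- in_r[grid$codes[in_r] == k]
        n <- max(1L, round(fraction * length(pool)))
        rows <- c(rows, if (n >= length(pool)) pool else sample(pool, n))
      }
    } else {
      n <- max(1L, round(fraction * length(in_r)))
      rows <- c(rows, if (n >= length(in_r)) in_r else sample(in_r, n))
    }
  }
  if (!length(rows)) stop("sampling fraction yields zero rows")
  out <- data.frame(cell = rows, region = regions$region_id[rows],
                    class = grid$codes[rows])
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- seed
  class(out) <- c("training_sample", "data.frame")
  out
}

#' Fit a suitability model
#'
#' Trains a single-hidden-layer neural network (12 logistic hidden units,
#' softmax output over the classes present in the sample) on normalised
#' driver vectors. Deterministic given `seed`.
#'
#' @param sample a `training_sample` from [sample_cells()].
#' @param drivers named list of driver matrices (raw; normalisation is fitted
#'   here and stored in the model).
#' @param seed integer seed (weight initialisation).
#' @param size hidden-layer width.
#' @param maxit optimiser iteration cap.
#' @param decay weight decay.
#' @return An object of class `suitability_model`.
#' @export
fit_suitability <- function(sample, drivers, seed, size = 12L, maxit = 200L,
                            decay = 1e-4) {
  classes <- sort(unique(sample$class))
  if (length(classes) < 2) stop("need at least 2 classes in the sample")
  nd <- normalize_drivers(drivers)
  X <- vapply(nd$layers, function(l) l[sample$cell], numeric(nrow(sample)))
  y <- factor(sample$class, levels = classes)
  set.seed(seed)
  net <- nnet::nnet(x = X, y = nnet::class.ind(y), size = size,
                    softmax = TRUE, maxit = maxit, decay = decay,
                    trace = FALSE, MaxNWts = 5000)
  structure(list(net = net, classes = classes, norm = nd$norm,
                 layer_names = names(drivers), seed = as.integer(seed)),
            class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf("<suitability_model> %d drivers -> %d classes, %d hidden units\n",
              length(x$layer_names), length(x$classes), x$net$n[2]))
  invisible(x)
}

#' Predict per-class suitability surfaces
#'
#' @param object a `suitability_model`.
#' @param drivers named list of driver matrices (same layer names as
#'   training; normalised with the training ranges).
#' @param ... unused.
#' @return An object of class `suitability_maps`: a named list (over the
#'   five active classes) of probability matrices in [0, 1]; classes absent
#'   from training get an all-zero surface.
#' @export
predict.suitability_model <- function(object, drivers, ...) {
  layers <- apply_norm(drivers, object$norm)
  dims <- dim(layers[[1]])
  X <- vapply(layers, as.vector, numeric(prod(dims)))
  colnames(X) <- names(layers)
  p <- predict(object$net, X, type = "raw")
  maps <- lapply(names(ACTIVE_CLASSES), function(nm) {
    k <- ACTIVE_CLASSES[[nm]]
    i <- match(k, object$classes)
    if (is.na(i)) matrix(0, dims[1], dims[2])
    else matrix(pmin(pmax(p[, i], 0), 1), dims[1], dims[2])
  })
  names(maps) <- names(ACTIVE_CLASSES)
  structure(maps, class = "suitability_maps")
}

#' @export
print.suitability_maps <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<suitability_maps> %d classes, %d x %d\n", length(x), d[1], d[2]))
  invisible(x)
}

#' Fit one suitability model per region
#'
#' @param grid baseline `land_grid`.
#' @param regions `region_mask`.
#' @param drivers named list of driver matrices.
#' @param fraction training sampling fraction.
#' @param seed integer seed; region r uses `seed + r`.
#' @param ... passed to [fit_suitability()].
#' @return Named list of `suitability_model`s, one per region id.
#' @export
fit_region_models <- function(grid, regions, drivers, fraction = 0.1, seed = 1,
                              ...) {
  models <- list()
  for (r in seq_len(regions$n_regions)) {
    sub <- grid
    sub$codes[regions$region_id != r | is.na(regions$region_id)] <- NA_integer_
    smp <- sample_cells(sub, regions, fraction, seed + r)
    models[[as.character(r)]] <- fit_suitability(smp, drivers, seed + r, ...)
  }
  models
}

#' ROC AUC of a score surface against binary labels
#'
#' The rank statistic: the probability that a random positive cell outscores
#' a random negative one, ties counting one half, computed on a sampled
#' subset of cells.
#'
#' @param scores numeric matrix (or vector) of scores.
#' @param labels binary (0/1 or logical) matrix/vector, co-registered; `NA`
#'   cells are excluded.
#' @param fraction sampling fraction in (0, 1] (default 1: all cells).
#' @param seed integer seed for the sampling draw.
#' @return AUC in [0, 1].
#' @export
evaluate_auc <- function(scores, labels, fraction = 1, seed = 1) {
  s <- as.vector(scores)
  l <- as.vector(labels)
  keep <- !is.na(s) & !is.na(l)
  s <- s[keep]; l <- as.integer(l[keep])
  if (fraction < 1) {
    set.seed(seed)
    n <- max(2L, round(fraction * length(s)))
    pick <- sample.int(length(s), n)
    s <- s[pick]; l <- l[pick]
  }
  n_pos <- sum(l == 1); n_neg <- sum(l == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: evaluation sample contains a single class")
  r <- rank(s, ties.method = "average")
  (sum(r[l == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-class AUC table for a set of suitability maps
#'
#' Scores each active class's surface against the one-vs-rest observed
#' labels, per region, on a sampled subset (the shape of a per-region
#' accuracy table).
#'
#' @param maps a `suitability_maps`.
#' @param grid observed `land_grid`.
#' @param regions `region_mask`.
#' @param fraction evaluation sampling fraction.
#' @param seed integer seed.
#' @return data.frame with columns `region`, `class`, `auc` (NA where a
#'   class is absent from a region).
#' @export
auc_table <- function(maps, grid, regions, fraction = 0.1, seed = 1) {
  out <- expand.grid(region = seq_len(regions$n_regions),
                     class = names(ACTIVE_CLASSES), stringsAsFactors = FALSE)
  out$auc <- NA_real_
  for (i in seq_len(nrow(out))) {
    r <- out$region[i]; nm <- out$class[i]
    in_r <- regions$region_id == r & !is.na(grid$codes) &
      grid$codes %in% ACTIVE_CLASSES
    lab <- grid$codes[in_r] == ACTIVE_CLASSES[[nm]]
    if (length(unique(lab)) < 2) next
    out$auc[i] <- evaluate_auc(maps[[nm]][in_r], lab, fraction,
                               seed + 31 * r + ACTIVE_CLASSES[[nm]])
  }
  out
}
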