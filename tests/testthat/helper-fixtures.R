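# Shared fixtures and independent brute-force oracles. Worlds are cached per
# (seed, size) so expensive generation runs once per test session.

.fixture_cache <- new.env(parent = emptyenv())

world_fixture <- function(seed = 1, n_rows = 120, n_cols = 120,
                          n_regions = 2) {
  key <- paste(seed, n_rows, n_cols, n_regions, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_world(seed, n_rows, n_cols, n_regions)
  .fixture_cache[[key]]
}

# random co-registered land maps for metric oracle checks
random_map_pair <- function(seed, n = 64, n_classes = 7, p_nodata = 0.05) {
  set.seed(seed)
  mk <- function() {
    m <- matrix(sample.int(n_classes, n * n, replace = TRUE), n, n)
    m[runif(n * n) < p_nodata] <- NA_integer_
    m
  }
  list(a = land_grid(mk()), b = land_grid(mk()), c = land_grid(mk()))
}

# AUC by exhaustive positive-negative pair counting (ties one half)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# per-cell confusion tally
brute_confusion <- function(a, b, n_classes = 7) {
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(a$codes)) {
    o <- a$codes[i]; s <- b$codes[i]
    if (!is.na(o) && !is.na(s)) m[o, s] <- m[o, s] + 1L
  }
  m
}

brute_kappa <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

# four-component change decomposition by per-cell scan
brute_fom <- function(o0, o1, s1) {
  A <- B <- C <- D <- 0L
  for (i in seq_along(o0$codes)) {
    x0 <- o0$codes[i]; x1 <- o1$codes[i]; y1 <- s1$codes[i]
    if (is.na(x0) || is.na(x1) || is.na(y1)) next
    if (x0 != x1) {
      if (y1 == x0) A <- A + 1L
      else if (y1 == x1) B <- B + 1L
      else C <- C + 1L
    } else if (y1 != x0) D <- D + 1L
  }
  denom <- A + B + C + D
  list(fom = if (denom == 0) 0 else B / denom, A = A, B = B, C = C, D = D)
}

brute_block <- function(g0, g1, j, block) {
  nr <- nrow(g0$codes); nc <- ncol(g0$codes)
  out <- matrix(0, ceiling(nr / block), ceiling(nc / block))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- (isTRUE(g1$codes[r, c] == j)) - (isTRUE(g0$codes[r, c] == j))
    if (d != 0) {
      br <- (r - 1) %/% block + 1; bc <- (c - 1) %/% block + 1
      out[br, bc] <- out[br, bc] + d
    }
  }
  out * g0$meta$cell_km^2
}

# locate a decision boundary of a labelling function f(x) by bisection
bisect_boundary <- function(f, lo, hi, tol = 1e-9) {
  f_lo <- f(lo)
  if (identical(f(hi), f_lo)) stop("no label change over the bracket")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(f(mid), f_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# flat suitability surfaces (every class equally suitable everywhere)
constant_suitability <- function(w) {
  d <- dim(w$baseline$codes)
  maps <- lapply(names(ACTIVE_CLASSES), function(nm) matrix(0.5, d[1], d[2]))
  names(maps) <- names(ACTIVE_CLASSES)
  structure(maps, class = "suitability_maps")
}

region_census <- function(w, r) {
  region_census_of(w$baseline, w$regions, r)
}

region_census_of <- function(grid, regions, r) {
  inr <- regions$region_id == r & !is.na(grid$codes)
  structure(tabulate(grid$codes[inr], 7)[1:5], names = names(ACTIVE_CLASSES))
}
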