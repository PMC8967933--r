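#include <Rcpp.h>
using namespace Rcpp;

// Neighbourhood effect of class j at cell (r, c): share of class-j cells in
// the window excluding the centre; edge cells use the truncated window's
// in-grid neighbours as denominator.
static inline double neigh_share(const IntegerMatrix& codes, int r, int c,
                                 int j, int half) {
  int nr = codes.nrow(), nc = codes.ncol();
  int cnt = 0, avail = 0;
  for (int dr = -half; dr <= half; ++dr) {
    int rr = r + dr;
    if (rr < 0 || rr >= nr) continue;
    for (int dc = -half; dc <= half; ++dc) {
      if (dr == 0 && dc == 0) continue;
      int cc = c + dc;
      if (cc < 0 || cc >= nc) continue;
      ++avail;
      int v = codes(rr, cc);
      if (v != NA_INTEGER && v == j) ++cnt;
    }
  }
  return avail > 0 ? (double)cnt / avail : 0.0;
}

// One macro-iteration sweep: visit the given cells in order; for each,
// compute the total conversion probability over candidate active classes
// (conversion allowed, demand not over-filled) and roulette-select the next
// state. `codes` and `allocated` are updated in place. Uses R's RNG.
// [[Rcpp::export]]
void ca_sweep(IntegerMatrix codes, IntegerVector visit_order,
              NumericMatrix pg, NumericVector inertia, IntegerMatrix cons,
              IntegerVector demand, IntegerVector allocated,
              int window, double floor_val) {
  const int n_active = 5;  // active classes are codes 1..5
  int half = window / 2;
  int nr = codes.nrow();
  double tp[n_active];
  for (R_xlen_t v = 0; v < visit_order.size(); ++v) {
    int idx = visit_order[v];           // 0-based linear (column-major) index
    int r = idx % nr, c = idx / nr;
    int k = codes(r, c);
    if (k == NA_INTEGER || k < 1 || k > n_active) continue;
    double total = 0.0;
    for (int j = 1; j <= n_active; ++j) {
      double t = 0.0;
      if (cons(k - 1, j - 1) != 0) {
        bool blocked = (j != k && allocated[j - 1] >= demand[j - 1]) ||
                       (j == k && allocated[k - 1] > demand[k - 1]);
        if (!blocked) {
          double nb = neigh_share(codes, r, c, j, half);
          if (nb < floor_val) nb = floor_val;
          t = pg(idx, j - 1) * nb * inertia[j - 1];
        }
      }
      tp[j - 1] = t;
      total += t;
    }
    if (total <= 0.0) continue;         // all-zero vector: no change
    double u = unif_rand() * total, acc = 0.0;
    int pick = k;
    for (int j = 1; j <= n_active; ++j) {
      acc += tp[j - 1];
      if (u <= acc) { pick = j; break; }
    }
    if (pick != k) {
      codes(r, c) = pick;
      --allocated[k - 1];
      ++allocated[pick - 1];
    }
  }
}
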