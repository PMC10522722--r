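#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// logistic time weight: 1 / (1 + exp(-alpha * (dt - beta)))
static inline double tweight(double dt, double alpha, double beta) {
  return 1.0 / (1.0 + std::exp(-alpha * (dt - beta)));
}

// [[Rcpp::export]]
NumericMatrix cpp_base_cost(NumericVector x, NumericVector tx,
                            NumericVector y, NumericVector ty,
                            double alpha, double beta, bool weighted,
                            bool circular, double period) {
  const int n = x.size(), m = y.size();
  NumericMatrix d(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double cost = std::fabs(x[i] - y[j]);
      if (weighted) {
        double dt = std::fabs(tx[i] - ty[j]);
        if (circular) dt = std::min(dt, period - dt);
        cost += tweight(dt, alpha, beta);
      }
      d(i, j) = cost;
    }
  }
  return d;
}

// cumulative cost: d[i,j] = base[i,j] + min(d[i-1,j], d[i-1,j-1], d[i,j-1])
// [[Rcpp::export]]
NumericMatrix cpp_accumulate(NumericMatrix base) {
  const int n = base.nrow(), m = base.ncol();
  NumericMatrix d(n, m);
  d(0, 0) = base(0, 0);
  for (int i = 1; i < n; ++i) d(i, 0) = base(i, 0) + d(i - 1, 0);
  for (int j = 1; j < m; ++j) d(0, j) = base(0, j) + d(0, j - 1);
  for (int i = 1; i < n; ++i)
    for (int j = 1; j < m; ++j)
      d(i, j) = base(i, j) +
        std::min(d(i - 1, j), std::min(d(i - 1, j - 1), d(i, j - 1)));
  return d;
}

// backtrack the optimal warping path from (n,m) to (1,1); tie-break prefers
// the diagonal predecessor, then up (i-1,j), then left (i,j-1)
// [[Rcpp::export]]
IntegerMatrix cpp_backtrack(NumericMatrix cum) {
  const int n = cum.nrow(), m = cum.ncol();
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double diag = cum(i - 1, j - 1), up = cum(i - 1, j), left = cum(i, j - 1);
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {          // reverse to start at (1,1)
    path(k, 0) = pi[L - 1 - k] + 1;
    path(k, 1) = pj[L - 1 - k] + 1;
  }
  return path;
}

// batch TWDTW distances: one row of `series` per pixel, columns = timesteps.
// NA observations in a pixel's series are dropped (with their timestamps)
// before alignment; a pixel with < 2 finite observations gets NA.
// [[Rcpp::export]]
NumericVector cpp_twdtw_batch(NumericMatrix series, NumericVector tx,
                              NumericVector y, NumericVector ty,
                              double alpha, double beta, bool weighted,
                              bool circular, double period) {
  const int npix = series.nrow(), nt = series.ncol(), m = y.size();
  NumericVector out(npix);
  std::vector<double> xs(nt), txs(nt);
  std::vector<double> prev(m), cur(m);
  for (int p = 0; p < npix; ++p) {
    int n = 0;
    for (int t = 0; t < nt; ++t) {
      double v = series(p, t);
      if (R_finite(v)) { xs[n] = v; txs[n] = tx[t]; ++n; }
    }
    if (n < 2) { out[p] = NA_REAL; continue; }
    // rolling two-row DP
    for (int j = 0; j < m; ++j) {
      double cost = std::fabs(xs[0] - y[j]);
      if (weighted) {
        double dt = std::fabs(txs[0] - ty[j]);
        if (circular) dt = std::min(dt, period - dt);
        cost += tweight(dt, alpha, beta);
      }
      prev[j] = cost + (j > 0 ? prev[j - 1] : 0.0);
    }
    for (int i = 1; i < n; ++i) {
      for (int j = 0; j < m; ++j) {
        double cost = std::fabs(xs[i] - y[j]);
        if (weighted) {
          double dt = std::fabs(txs[i] - ty[j]);
          if (circular) dt = std::min(dt, period - dt);
          cost += tweight(dt, alpha, beta);
        }
        double best;
        if (j == 0) best = prev[0];
        else best = std::min(cur[j - 1], std::min(prev[j], prev[j - 1]));
        cur[j] = cost + best;
      }
      std::swap(prev, cur);
    }
    out[p] = prev[m - 1];
  }
  return out;
}

// connected-component labeling of a binary matrix by BFS flood fill;
// connectivity 4 or 8. Returns an integer label matrix (0 = background).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix map, int connectivity) {
  const int nr = map.nrow(), nc = map.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 0, 0, 1};
  const int dc4[] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (map(r, c) != 1 || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> rc = q.front(); q.pop();
        for (int k = 0; k < nd; ++k) {
          int rr = rc.first + dr[k], cc = rc.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (map(rr, cc) == 1 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// seeded region growing: carve the grid into contiguous patches whose sizes
// follow `sizes` (consumed in order; the last patches may come up short when
// the unassigned area runs out). Randomness uses R's RNG so set.seed()
// governs the mosaic. Returns a patch-id matrix (ids 1..k, no zeros).
// [[Rcpp::export]]
IntegerMatrix cpp_grow_patches(int nrow, int ncol, NumericVector sizes) {
  IntegerMatrix patch(nrow, ncol);
  std::fill(patch.begin(), patch.end(), 0);
  const int ncell = nrow * ncol;
  // row-major free-cell bookkeeping
  std::vector<int> free_cells(ncell);
  std::vector<int> pos(ncell);            // cell -> index in free_cells
  for (int i = 0; i < ncell; ++i) { free_cells[i] = i; pos[i] = i; }
  int nfree = ncell;
  const int dr4[] = {-1, 0, 0, 1};
  const int dc4[] = {0, -1, 1, 0};
  GetRNGstate();
  int id = 0, sidx = 0;
  while (nfree > 0) {
    ++id;
    int target = (sidx < sizes.size()) ? (int)sizes[sidx++] : 1;
    if (target < 1) target = 1;
    // random free seed
    int k = (int)(unif_rand() * nfree); if (k >= nfree) k = nfree - 1;
    int seed = free_cells[k];
    std::vector<int> frontier;
    frontier.push_back(seed);
    int grown = 0;
    while (grown < target && !frontier.empty()) {
      int fk = (int)(unif_rand() * frontier.size());
      if (fk >= (int)frontier.size()) fk = frontier.size() - 1;
      int cell = frontier[fk];
      frontier[fk] = frontier.back(); frontier.pop_back();
      int r = cell % nrow, c = cell / nrow;   // column-major cell ids
      if (patch(r, c) != 0) continue;
      patch(r, c) = id; ++grown;
      // remove from free set
      int p = pos[cell], last = free_cells[nfree - 1];
      free_cells[p] = last; pos[last] = p; --nfree;
      for (int d = 0; d < 4; ++d) {
        int rr = r + dr4[d], cc = c + dc4[d];
        if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
        if (patch(rr, cc) == 0) frontier.push_back(rr + cc * nrow);
      }
    }
  }
  PutRNGstate();
  return patch;
}
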