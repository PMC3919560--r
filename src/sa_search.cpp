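#include <Rcpp.h>
using namespace Rcpp;

// Simulated-annealing search for a fixed-size submatrix with minimal mean
// value. Moves replace one selected row (or column, 50/50) with a uniformly
// chosen outside row/column; acceptance follows the Metropolis criterion on
// the change in mean. Uses R's RNG so results are reproducible under
// set.seed(). Returns 1-based row/col indices of the best submatrix seen.
// [[Rcpp::export]]
List sa_seed_search_cpp(NumericMatrix a, int seed_rows, int seed_cols,
                        double t0, double cooling, int moves_per_temp,
                        double t_stop) {
  const int nr = a.nrow(), nc = a.ncol();
  const double area = (double)seed_rows * (double)seed_cols;

  // membership flags and index lists
  std::vector<int> rows(seed_rows), cols(seed_cols);
  std::vector<char> in_row(nr, 0), in_col(nc, 0);
  {
    // random initial placement (sample without replacement)
    IntegerVector r0 = Rcpp::sample(nr, seed_rows, false);
    IntegerVector c0 = Rcpp::sample(nc, seed_cols, false);
    for (int i = 0; i < seed_rows; ++i) { rows[i] = r0[i] - 1; in_row[rows[i]] = 1; }
    for (int j = 0; j < seed_cols; ++j) { cols[j] = c0[j] - 1; in_col[cols[j]] = 1; }
  }

  double total = 0.0;
  for (int i = 0; i < seed_rows; ++i)
    for (int j = 0; j < seed_cols; ++j)
      total += a(rows[i], cols[j]);

  double best = total;
  std::vector<int> best_rows(rows), best_cols(cols);

  const int n_out_rows = nr - seed_rows, n_out_cols = nc - seed_cols;
  double temp = t0;
  while (temp > t_stop) {
    for (int mv = 0; mv < moves_per_temp; ++mv) {
      bool row_move = (n_out_rows > 0) &&
        (n_out_cols == 0 || unif_rand() < 0.5);
      if (!row_move && n_out_cols == 0) continue;
      double delta = 0.0;
      if (row_move) {
        int pos = (int)(unif_rand() * seed_rows); if (pos == seed_rows) --pos;
        int k = (int)(unif_rand() * n_out_rows); if (k == n_out_rows) --k;
        int cand = -1;
        for (int r = 0, seen = 0; r < nr; ++r)
          if (!in_row[r] && seen++ == k) { cand = r; break; }
        int old = rows[pos];
        for (int j = 0; j < seed_cols; ++j)
          delta += a(cand, cols[j]) - a(old, cols[j]);
        if (delta <= 0.0 || unif_rand() < std::exp(-delta / (area * temp))) {
          in_row[old] = 0; in_row[cand] = 1; rows[pos] = cand; total += delta;
        }
      } else {
        int pos = (int)(unif_rand() * seed_cols); if (pos == seed_cols) --pos;
        int k = (int)(unif_rand() * n_out_cols); if (k == n_out_cols) --k;
        int cand = -1;
        for (int c = 0, seen = 0; c < nc; ++c)
          if (!in_col[c] && seen++ == k) { cand = c; break; }
        int old = cols[pos];
        for (int i = 0; i < seed_rows; ++i)
          delta += a(rows[i], cand) - a(rows[i], old);
        if (delta <= 0.0 || unif_rand() < std::exp(-delta / (area * temp))) {
          in_col[old] = 0; in_col[cand] = 1; cols[pos] = cand; total += delta;
        }
      }
      if (total < best - 1e-12) {
        best = total; best_rows = rows; best_cols = cols;
      }
    }
    temp *= cooling;
  }

  // deterministic greedy polish: best-improvement single swaps until no
  // move lowers the score, so the returned seed is a local optimum
  rows = best_rows; cols = best_cols; total = best;
  std::fill(in_row.begin(), in_row.end(), 0);
  std::fill(in_col.begin(), in_col.end(), 0);
  for (int i = 0; i < seed_rows; ++i) in_row[rows[i]] = 1;
  for (int j = 0; j < seed_cols; ++j) in_col[cols[j]] = 1;
  bool improved = true;
  while (improved) {
    improved = false;
    for (int pos = 0; pos < seed_rows; ++pos) {
      double old_sum = 0.0;
      for (int j = 0; j < seed_cols; ++j) old_sum += a(rows[pos], cols[j]);
      double best_delta = -1e-12; int best_cand = -1;
      for (int r = 0; r < nr; ++r) {
        if (in_row[r]) continue;
        double s = 0.0;
        for (int j = 0; j < seed_cols; ++j) s += a(r, cols[j]);
        if (s - old_sum < best_delta) { best_delta = s - old_sum; best_cand = r; }
      }
      if (best_cand >= 0) {
        in_row[rows[pos]] = 0; in_row[best_cand] = 1;
        rows[pos] = best_cand; total += best_delta; improved = true;
      }
    }
    for (int pos = 0; pos < seed_cols; ++pos) {
      double old_sum = 0.0;
      for (int i = 0; i < seed_rows; ++i) old_sum += a(rows[i], cols[pos]);
      double best_delta = -1e-12; int best_cand = -1;
      for (int c = 0; c < nc; ++c) {
        if (in_col[c]) continue;
        double s = 0.0;
        for (int i = 0; i < seed_rows; ++i) s += a(rows[i], c);
        if (s - old_sum < best_delta) { best_delta = s - old_sum; best_cand = c; }
      }
      if (best_cand >= 0) {
        in_col[cols[pos]] = 0; in_col[best_cand] = 1;
        cols[pos] = best_cand; total += best_delta; improved = true;
      }
    }
  }
  best = total; best_rows = rows; best_cols = cols;

  IntegerVector out_rows(seed_rows), out_cols(seed_cols);
  for (int i = 0; i < seed_rows; ++i) out_rows[i] = best_rows[i] + 1;
  for (int j = 0; j < seed_cols; ++j) out_cols[j] = best_cols[j] + 1;
  return List::create(_["rows"] = out_rows, _["cols"] = out_cols,
                      _["score"] = best / area);
}
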