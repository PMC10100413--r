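// Simplex-projection kernel shared by univariate forecasting and convergent
// cross mapping.  For each prediction row the nearest library neighbours
// (Euclidean distance in the delay-embedding space, with a temporal
// exclusion radius around the prediction time) forecast the target with
// exponential weights exp(-d/dmin); ties at distance zero fall back to
// uniform weights over the tied set.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_simplex_predict(const NumericMatrix& coords,
                                  const IntegerVector& times,
                                  const NumericVector& target,
                                  const IntegerVector& lib,
                                  const IntegerVector& pred,
                                  const int n_neighbors,
                                  const int exclusion) {
  const int e_dim = coords.ncol();
  const int n_lib = lib.size();
  const int n_pred = pred.size();
  NumericVector out(n_pred, NA_REAL);

  std::vector<std::pair<double, int>> cand;
  cand.reserve(n_lib);

  for (int ip = 0; ip < n_pred; ++ip) {
    const int p = pred[ip] - 1;  // 1-based from R
    const int tp_time = times[p];
    cand.clear();
    for (int il = 0; il < n_lib; ++il) {
      const int l = lib[il] - 1;
      if (std::abs(times[l] - tp_time) <= exclusion) continue;
      if (!R_finite(target[l])) continue;
      double d2 = 0.0;
      for (int j = 0; j < e_dim; ++j) {
        const double diff = coords(p, j) - coords(l, j);
        d2 += diff * diff;
      }
      cand.push_back(std::make_pair(d2, l));
    }
    if (cand.empty()) continue;
    const int k = std::min<int>(n_neighbors, cand.size());
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());

    const double dmin = std::sqrt(cand[0].first);
    double wsum = 0.0, psum = 0.0;
    if (dmin <= 0.0) {
      // uniform over the tied (distance zero) set only
      for (int j = 0; j < k; ++j) {
        if (cand[j].first > 0.0) break;
        psum += target[cand[j].second];
        wsum += 1.0;
      }
    } else {
      for (int j = 0; j < k; ++j) {
        const double w = std::exp(-std::sqrt(cand[j].first) / dmin);
        psum += w * target[cand[j].second];
        wsum += w;
      }
    }
    if (wsum > 0.0) out[ip] = psum / wsum;
  }
  return out;
}

// Neighbour sets and weights for every row at once (library = all rows,
// temporal exclusion fixed), so a caller can re-use them across many
// prediction offsets.  Returns k neighbour indices (1-based, 0 = none)
// and their simplex weights per row.
// [[Rcpp::export]]
List cpp_simplex_neighbors(const NumericMatrix& coords,
                           const IntegerVector& times,
                           const int n_neighbors,
                           const int exclusion) {
  const int n = coords.nrow();
  const int e_dim = coords.ncol();
  IntegerMatrix idx(n, n_neighbors);
  NumericMatrix wgt(n, n_neighbors);

  std::vector<double> d2(n);
  std::vector<int> ord(n);
  const double inf = std::numeric_limits<double>::infinity();

  for (int p = 0; p < n; ++p) {
    std::fill(d2.begin(), d2.end(), 0.0);
    // column-major accumulation keeps memory access sequential
    for (int j = 0; j < e_dim; ++j) {
      const double* col = &coords(0, j);
      const double vp = col[p];
      for (int l = 0; l < n; ++l) {
        const double diff = vp - col[l];
        d2[l] += diff * diff;
      }
    }
    for (int l = 0; l < n; ++l) {
      if (std::abs(times[l] - times[p]) <= exclusion) d2[l] = inf;
      ord[l] = l;
    }
    const int k = std::min(n_neighbors, n);
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) { return d2[a] < d2[b]; });
    if (!std::isfinite(d2[ord[0]])) continue;
    const double dmin = std::sqrt(d2[ord[0]]);
    for (int j = 0; j < k; ++j) {
      const int l = ord[j];
      if (!std::isfinite(d2[l])) break;
      idx(p, j) = l + 1;
      wgt(p, j) = dmin <= 0.0 ? (d2[l] <= 0.0 ? 1.0 : 0.0)
                              : std::exp(-std::sqrt(d2[l]) / dmin);
    }
  }
  return List::create(Named("idx") = idx, Named("weight") = wgt);
}

// Maximum cross-map skill over a grid of prediction offsets, reusing one
// neighbour set (idx 1-based rows into `times`, 0 = absent).  Pearson
// correlation between weighted-neighbour predictions and observations,
// maximised over offsets; used for the selection-corrected surrogate null.
// [[Rcpp::export]]
double cpp_max_skill_over_tps(const IntegerMatrix& idx,
                              const NumericMatrix& wgt,
                              const IntegerVector& times,
                              const NumericVector& b,
                              const IntegerVector& tp_range) {
  const int n = idx.nrow();
  const int k = idx.ncol();
  const int t_len = b.size();
  double best = NA_REAL;

  for (int g = 0; g < tp_range.size(); ++g) {
    const int tp = tp_range[g];
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    int m = 0;
    for (int p = 0; p < n; ++p) {
      const int oi = times[p] + tp;
      if (oi < 1 || oi > t_len) continue;
      const double obs = b[oi - 1];
      if (!R_finite(obs)) continue;
      double wsum = 0, psum = 0;
      for (int j = 0; j < k; ++j) {
        const int l = idx(p, j);
        if (l == 0) break;
        const int ti = times[l - 1] + tp;
        if (ti < 1 || ti > t_len) continue;
        const double tv = b[ti - 1];
        if (!R_finite(tv)) continue;
        psum += wgt(p, j) * tv;
        wsum += wgt(p, j);
      }
      if (wsum <= 0) continue;
      const double pr = psum / wsum;
      sx += pr; sy += obs; sxx += pr * pr; syy += obs * obs;
      sxy += pr * obs;
      ++m;
    }
    if (m < 5) continue;
    const double vx = sxx - sx * sx / m;
    const double vy = syy - sy * sy / m;
    if (vx <= 0 || vy <= 0) continue;
    const double rho = (sxy - sx * sy / m) / std::sqrt(vx * vy);
    if (!R_finite(rho)) continue;
    if (ISNA(best) || rho > best) best = rho;
  }
  return best;
}
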