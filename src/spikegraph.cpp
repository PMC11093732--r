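#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact k-nearest landmarks per query point (Euclidean), brute force.
// X: n x d query points, L: m x d landmarks. Returns n x k index matrix
// (1-based, ties broken by landmark index).
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix X, NumericMatrix L, int k) {
  const int n = X.nrow(), m = L.nrow(), d = X.ncol();
  if (k > m) stop("k exceeds number of landmarks");
  IntegerMatrix out(n, k);
  // store points contiguously (one point per stretch of d doubles)
  std::vector<double> xt((size_t)n * d), lt((size_t)m * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) xt[(size_t)i * d + c] = X(i, c);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < d; ++c) lt[(size_t)j * d + c] = L(j, c);
  std::vector<std::pair<double, int> > dist(m);
  for (int i = 0; i < n; ++i) {
    const double *xi = xt.data() + (size_t)i * d;
    for (int j = 0; j < m; ++j) {
      const double *lj = lt.data() + (size_t)j * d;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double v = xi[c] - lj[c];
        s += v * v;
      }
      dist[j] = std::make_pair(s, j);
    }
    std::partial_sort(dist.begin(), dist.begin() + k, dist.end());
    for (int j = 0; j < k; ++j) out(i, j) = dist[j].second + 1;
  }
  return out;
}

// Running maximum of x over a centered window of half-width w.
// [[Rcpp::export]]
NumericVector cpp_running_max(NumericVector x, int w) {
  const int n = x.size();
  NumericVector out(n);
  // monotonic deque of indices
  std::vector<int> dq;
  dq.reserve(n);
  int head = 0;
  for (int i = 0; i < n + w; ++i) {
    if (i < n) {
      while ((int)dq.size() > head && x[dq.back()] <= x[i]) dq.pop_back();
      dq.push_back(i);
    }
    int t = i - w; // output position whose window [t-w, t+w] is complete
    if (t >= 0) {
      while (dq[head] < t - w) ++head;
      out[t] = x[dq[head]];
    }
  }
  return out;
}

// Row-wise running max over time (columns) of matrix V (rows = positions).
// [[Rcpp::export]]
NumericMatrix cpp_running_max_rows(NumericMatrix V, int w) {
  const int p = V.nrow(), t = V.ncol();
  NumericMatrix out(p, t);
  NumericVector row(t);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < t; ++j) row[j] = V(i, j);
    NumericVector rm = cpp_running_max(row, w);
    for (int j = 0; j < t; ++j) out(i, j) = rm[j];
  }
  return out;
}

// For each row i, max over rows listed in nb (1-based, p x kn) of M.
// [[Rcpp::export]]
NumericMatrix cpp_neighbor_max(NumericMatrix M, IntegerMatrix nb) {
  const int p = M.nrow(), t = M.ncol(), kn = nb.ncol();
  NumericMatrix out(p, t);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < t; ++j) {
      double best = R_NegInf;
      for (int q = 0; q < kn; ++q) {
        double v = M(nb(i, q) - 1, j);
        if (v > best) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Pair-difference histogram between two sorted spike-time vectors (seconds).
// Bins are centered: bin j covers ((j - 0.5) * bin_s, (j + 0.5) * bin_s]
// for j = -nb..nb. When acg is true, zero-lag self pairs are excluded
// (the inputs are then the same train).
// [[Rcpp::export]]
NumericVector cpp_correlogram(NumericVector a, NumericVector b, double bin_s,
                              int nb, bool acg) {
  const int na = a.size(), nbn = b.size();
  NumericVector counts(2 * nb + 1);
  const double win = (nb + 0.5) * bin_s;
  int lo = 0;
  for (int i = 0; i < na; ++i) {
    while (lo < nbn && b[lo] < a[i] - win) ++lo;
    for (int j = lo; j < nbn && b[j] <= a[i] + win; ++j) {
      if (acg && i == j) continue;
      double dt = a[i] - b[j];
      int bin = (int)std::lround(dt / bin_s);
      if (bin >= -nb && bin <= nb) counts[bin + nb] += 1.0;
    }
  }
  return counts;
}

// Greedy one-to-one nearest-in-time matching of two sorted spike trains
// within tolerance tol (same units as the times). Returns the number of
// matched pairs.
// [[Rcpp::export]]
int cpp_match_count(NumericVector truth, NumericVector det, double tol) {
  const int nt = truth.size(), nd = det.size();
  int i = 0, j = 0, matched = 0;
  while (i < nt && j < nd) {
    double dt = det[j] - truth[i];
    if (dt < -tol) {
      ++j;
    } else if (dt > tol) {
      ++i;
    } else {
      ++matched;
      ++i;
      ++j;
    }
  }
  return matched;
}

// Column-wise median of a matrix (used by the common average reference).
// [[Rcpp::export]]
NumericVector cpp_col_median(NumericMatrix X) {
  const int nr = X.nrow(), nc = X.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = X(i, j);
    int mid = nr / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (nr % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + mid - 1,
                       buf.begin() + mid);
      m = 0.5 * (m + buf[mid - 1]);
    }
    out[j] = m;
  }
  return out;
}

// Cross-correlation of every row of d (C x L) with kernel k (length n_t,
// 0-based center c0): out[ch, t] = sum_tau k[tau] d[ch, t + tau - c0],
// out-of-range samples treated as zero.
// [[Rcpp::export]]
NumericMatrix cpp_xcorr_rows(NumericMatrix d, NumericVector k, int c0) {
  const int C = d.nrow(), L = d.ncol(), n_t = k.size();
  NumericMatrix out(C, L);
  std::vector<double> row(L), acc(L);
  for (int ch = 0; ch < C; ++ch) {
    for (int t = 0; t < L; ++t) row[t] = d(ch, t);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int tau = 0; tau < n_t; ++tau) {
      const double kv = k[tau];
      if (kv == 0.0) continue;
      const int off = tau - c0; // out[t] += kv * row[t + off]
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      const double *src = row.data() + t0 + off;
      double *dst = acc.data() + t0;
      for (int t = t0; t < t1; ++t) *dst++ += kv * *src++;
    }
    for (int t = 0; t < L; ++t) out(ch, t) = acc[t];
  }
  return out;
}

// Sum over r of cross-correlation of row r of P (R x L) with column r of
// V (n_t x R); same alignment as cpp_xcorr_rows.
// [[Rcpp::export]]
NumericVector cpp_xcorr_sum(NumericMatrix P, NumericMatrix V, int c0) {
  const int R = P.nrow(), L = P.ncol(), n_t = V.nrow();
  NumericVector out(L);
  std::vector<double> row(L);
  for (int r = 0; r < R; ++r) {
    for (int t = 0; t < L; ++t) row[t] = P(r, t);
    for (int tau = 0; tau < n_t; ++tau) {
      const double kv = V(tau, r);
      if (kv == 0.0) continue;
      const int off = tau - c0;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      const double *src = row.data() + t0 + off;
      double *dst = out.begin() + t0;
      for (int t = t0; t < t1; ++t) *dst++ += kv * *src++;
    }
  }
  return out;
}

// In-place update: where A*A > V, set V = A*A and id = newid. V and id are
// modified directly (callers own freshly allocated matrices).
// [[Rcpp::export]]
void cpp_sq_max_update(NumericMatrix V, IntegerMatrix id, NumericMatrix A,
                       int newid) {
  const int n = V.nrow() * V.ncol();
  for (int i = 0; i < n; ++i) {
    double a2 = A[i] * A[i];
    if (a2 > V[i]) { V[i] = a2; id[i] = newid; }
  }
}

// In-place update for matching pursuit: where v > V, set V = v, id = newid,
// corr = c.
// [[Rcpp::export]]
void cpp_v_max_update(NumericVector V, IntegerVector id, NumericVector corr,
                      NumericVector v, NumericVector cc, int newid) {
  const int n = V.size();
  for (int i = 0; i < n; ++i) {
    if (v[i] > V[i]) { V[i] = v[i]; id[i] = newid; corr[i] = cc[i]; }
  }
}

// Column-wise maximum of a matrix, broadcast back to all rows.
// [[Rcpp::export]]
NumericMatrix cpp_col_max_broadcast(NumericMatrix X) {
  const int nr = X.nrow(), nc = X.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double m = R_NegInf;
    for (int i = 0; i < nr; ++i) if (X(i, j) > m) m = X(i, j);
    for (int i = 0; i < nr; ++i) out(i, j) = m;
  }
  return out;
}

// Best template per time point for matching pursuit: given corr (K x L)
// and template norms xw (K), returns V_best, k_best (1-based), corr_best.
// [[Rcpp::export]]
List cpp_mp_best(NumericMatrix corr, NumericVector xw) {
  const int K = corr.nrow(), L = corr.ncol();
  NumericVector V(L), cb(L);
  IntegerVector kb(L);
  for (int t = 0; t < L; ++t) {
    double best = R_NegInf, bc = 0.0;
    int bk = 0;
    for (int k = 0; k < K; ++k) {
      double v = 2.0 * xw[k] * corr(k, t) - xw[k] * xw[k];
      if (v > best) { best = v; bk = k + 1; bc = corr(k, t); }
    }
    V[t] = best; kb[t] = bk; cb[t] = bc;
  }
  return List::create(Named("V") = V, Named("k") = kb, Named("corr") = cb);
}

// Local update of template correlations after subtracting amplitude a of
// template k0 (1-based) at time t0 (1-based): for every template j,
// corr[j, t0 + lag] -= a * lp[j, k0, lag + n_t] for lag in -(n_t-1)..(n_t-1),
// where lp is the K x K x (2 n_t - 1) lagged-product array.
// [[Rcpp::export]]
void cpp_mp_update(NumericMatrix corr, NumericVector lp_flat, int K,
                   int n_t, int k0, int t0, double a) {
  const int L = corr.ncol();
  const int nl = 2 * n_t - 1;
  for (int j = 0; j < K; ++j) {
    for (int l = 0; l < nl; ++l) {
      int t = t0 - 1 + (l - (n_t - 1));
      if (t < 0 || t >= L) continue;
      // lp[k0-1, j, l] in column-major: (k0-1) + K*j + K*K*l
      corr(j, t) -= a * lp_flat[(k0 - 1) + K * j + K * K * l];
    }
  }
}

// Grouped in-place square-max update for stacked footprint blocks:
// A is (nZ * P) x L (size z occupies rows (z-1)P..zP-1); for each position
// p and time t, V[p,t] / best[p,t] are updated with the best A^2 over the
// nZ blocks; ids are (s0 + z) for z = 1..nZ.
// [[Rcpp::export]]
void cpp_sq_max_update_grouped(NumericMatrix V, IntegerMatrix best,
                               NumericMatrix A, int P, int nZ, int s0) {
  const int L = V.ncol();
  for (int t = 0; t < L; ++t) {
    const double *acol = &A(0, t);
    double *vcol = &V(0, t);
    int *bcol = &best(0, t);
    for (int z = 0; z < nZ; ++z) {
      const double *ablk = acol + z * P;
      for (int p = 0; p < P; ++p) {
        double a2 = ablk[p] * ablk[p];
        if (a2 > vcol[p]) { vcol[p] = a2; bcol[p] = s0 + z + 1; }
      }
    }
  }
}

// Fused footprint product + square-max update for one shape:
// for every time t, computes a = Fall %*% corr[, t] (Fall is (nZ*P) x C,
// column-major) and updates V/best with a^2 per position over the nZ
// blocks. Avoids materializing the product and stays single-threaded.
// [[Rcpp::export]]
void cpp_detect_accumulate(NumericMatrix V, IntegerMatrix best,
                           NumericMatrix Fall, NumericMatrix corr,
                           int P, int nZ, int s0) {
  const int rows = Fall.nrow(), C = Fall.ncol(), L = corr.ncol();
  // four time points per sweep so each loaded footprint value feeds four
  // accumulations (the footprint block exceeds L1)
  std::vector<double> acc((size_t)rows * 4);
  int t = 0;
  for (; t + 3 < L; t += 4) {
    std::fill(acc.begin(), acc.end(), 0.0);
    const double *x0 = &corr(0, t), *x1 = &corr(0, t + 1),
                 *x2 = &corr(0, t + 2), *x3 = &corr(0, t + 3);
    double *a0 = acc.data(), *a1 = a0 + rows, *a2 = a1 + rows,
           *a3 = a2 + rows;
    for (int c = 0; c < C; ++c) {
      const double xc0 = x0[c], xc1 = x1[c], xc2 = x2[c], xc3 = x3[c];
      const double *fc = &Fall(0, c);
      for (int r = 0; r < rows; ++r) {
        const double f = fc[r];
        a0[r] += xc0 * f; a1[r] += xc1 * f;
        a2[r] += xc2 * f; a3[r] += xc3 * f;
      }
    }
    for (int q = 0; q < 4; ++q) {
      const double *aq = acc.data() + (size_t)q * rows;
      double *vcol = &V(0, t + q);
      int *bcol = &best(0, t + q);
      for (int z = 0; z < nZ; ++z) {
        const double *ablk = aq + z * P;
        for (int p = 0; p < P; ++p) {
          double a2v = ablk[p] * ablk[p];
          if (a2v > vcol[p]) { vcol[p] = a2v; bcol[p] = s0 + z + 1; }
        }
      }
    }
  }
  for (; t < L; ++t) {
    std::fill(acc.begin(), acc.begin() + rows, 0.0);
    const double *x = &corr(0, t);
    for (int c = 0; c < C; ++c) {
      const double xc = x[c];
      const double *fc = &Fall(0, c);
      double *a = acc.data();
      for (int r = 0; r < rows; ++r) a[r] += xc * fc[r];
    }
    double *vcol = &V(0, t);
    int *bcol = &best(0, t);
    for (int z = 0; z < nZ; ++z) {
      const double *ablk = acc.data() + z * P;
      for (int p = 0; p < P; ++p) {
        double a2v = ablk[p] * ablk[p];
        if (a2v > vcol[p]) { vcol[p] = a2v; bcol[p] = s0 + z + 1; }
      }
    }
  }
}

// Peak extraction: positions/times where V equals the neighborhood max,
// exceeds thr2, and the (1-based) time lies in [lo, hi]. Returns a 2-col
// matrix of (row, col) 1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_find_peaks(NumericMatrix V, NumericMatrix Vnb,
                             double thr2, int lo, int hi) {
  const int P = V.nrow();
  std::vector<int> rr, cc;
  for (int t = lo - 1; t < hi; ++t) {
    for (int p = 0; p < P; ++p) {
      double v = V(p, t);
      if (v > thr2 && v >= Vnb(p, t)) { rr.push_back(p + 1); cc.push_back(t + 1); }
    }
  }
  IntegerMatrix out(rr.size(), 2);
  for (size_t i = 0; i < rr.size(); ++i) { out(i, 0) = rr[i]; out(i, 1) = cc[i]; }
  return out;
}
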