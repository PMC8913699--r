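#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact Debye double sum: I(Q) = sum_i sum_j b_i b_j sinc(Q d_ij).
// O(n^2 nQ); intended for n up to a few thousand.
// [[Rcpp::export(name = ".debye_direct")]]
NumericVector debye_direct(NumericMatrix xyz, NumericVector b, NumericVector Q) {
  const int n = xyz.nrow();
  const int nq = Q.size();
  NumericVector I(nq);
  double sumb2 = 0.0;
  for (int i = 0; i < n; ++i) sumb2 += b[i] * b[i];
  for (int q = 0; q < nq; ++q) I[q] = sumb2;
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0);
      const double dy = yi - xyz(j, 1);
      const double dz = zi - xyz(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double bb = 2.0 * b[i] * b[j];
      for (int q = 0; q < nq; ++q) {
        const double x = Q[q] * d;
        I[q] += (x < 1e-12) ? bb : bb * std::sin(x) / x;
      }
    }
  }
  return I;
}

// Contrast-weighted pair-distance histogram.  Off-diagonal weight
// 2 b_i b_j accumulated at the bin of d_ij; the self term sum(b_i^2) is
// returned separately so I(Q) = self + sum_k w_k sinc(Q d_k) with d_k the
// bin centres.  Bin width trades speed for phase accuracy (error ~ Q*bin/2).
// [[Rcpp::export(name = ".pair_hist")]]
List pair_hist(NumericMatrix xyz, NumericVector b, double bin) {
  const int n = xyz.nrow();
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += b[i] * b[i];
  // bounding-box diagonal bounds every pair distance
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      if (xyz(i, k) < lo[k]) lo[k] = xyz(i, k);
      if (xyz(i, k) > hi[k]) hi[k] = xyz(i, k);
    }
  double diag2 = 0.0;
  for (int k = 0; k < 3; ++k) diag2 += (hi[k] - lo[k]) * (hi[k] - lo[k]);
  const double dmax = std::sqrt(diag2) + bin;
  const int nbin = std::max(1, (int)std::ceil(dmax / bin));
  std::vector<double> w(nbin, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    const double bi2 = 2.0 * b[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0);
      const double dy = yi - xyz(j, 1);
      const double dz = zi - xyz(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int k = (int)(d / bin);
      if (k >= nbin) k = nbin - 1;
      w[k] += bi2 * b[j];
    }
  }
  NumericVector centres(nbin), weights(nbin);
  for (int k = 0; k < nbin; ++k) {
    centres[k] = (k + 0.5) * bin;
    weights[k] = w[k];
  }
  return List::create(_["self"] = self, _["d"] = centres, _["w"] = weights);
}

// Count inter-body bead pairs closer than cutoff, using a uniform cell
// grid (cell edge = cutoff) so the cost is near-linear in bead count.
// Pairs within the same body are ignored.  Stops early once `stop_at`
// violations are found (stop_at <= 0 means count all).
// [[Rcpp::export(name = ".clash_count")]]
int clash_count(NumericMatrix xyz, IntegerVector body, double cutoff,
                int stop_at) {
  const int n = xyz.nrow();
  if (n < 2) return 0;
  const double c2 = cutoff * cutoff;
  double lo[3];
  for (int k = 0; k < 3; ++k) lo[k] = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      if (xyz(i, k) < lo[k]) lo[k] = xyz(i, k);
  int dim[3];
  for (int k = 0; k < 3; ++k) dim[k] = 1;
  std::vector<int> cell(n);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      c[k] = (int)((xyz(i, k) - lo[k]) / cutoff);
      if (c[k] + 1 > dim[k]) dim[k] = c[k] + 1;
    }
  }
  std::vector<std::vector<int> > buckets((size_t)dim[0] * dim[1] * dim[2]);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)((xyz(i, 0) - lo[0]) / cutoff);
    cy[i] = (int)((xyz(i, 1) - lo[1]) / cutoff);
    cz[i] = (int)((xyz(i, 2) - lo[2]) / cutoff);
    buckets[(size_t)(cx[i] * dim[1] + cy[i]) * dim[2] + cz[i]].push_back(i);
  }
  int count = 0;
  for (int i = 0; i < n; ++i) {
    for (int ax = cx[i] - 1; ax <= cx[i] + 1; ++ax) {
      if (ax < 0 || ax >= dim[0]) continue;
      for (int ay = cy[i] - 1; ay <= cy[i] + 1; ++ay) {
        if (ay < 0 || ay >= dim[1]) continue;
        for (int az = cz[i] - 1; az <= cz[i] + 1; ++az) {
          if (az < 0 || az >= dim[2]) continue;
          const std::vector<int> &bk =
              buckets[(size_t)(ax * dim[1] + ay) * dim[2] + az];
          for (size_t m = 0; m < bk.size(); ++m) {
            const int j = bk[m];
            if (j <= i || body[i] == body[j]) continue;
            const double dx = xyz(i, 0) - xyz(j, 0);
            const double dy = xyz(i, 1) - xyz(j, 1);
            const double dz = xyz(i, 2) - xyz(j, 2);
            if (dx * dx + dy * dy + dz * dz < c2) {
              ++count;
              if (stop_at > 0 && count >= stop_at) return count;
            }
          }
        }
      }
    }
  }
  return count;
}
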