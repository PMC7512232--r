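// Pairwise loops behind the nonlinear estimators. Everything here has an
// exact-by-enumeration contract: results must equal the naive all-pairs
// computation on the same inputs (tested against R oracles).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Theiler-windowed correlation sums for several embedding dimensions at once.
// x: scalar series; tau: delay; ms: embedding dimensions (increasing);
// w: Theiler window; radii: increasing radius grid.
// Returns C[mi, r] = (# pairs i<j, j >= i+1+w, both < M_m, dist_m <= r)
//                    / ((M_m - w) * (M_m - w - 1) / 2),
// with M_m = N - (m-1)*tau. Distances accumulate incrementally over the
// delay coordinates so all m share one pass over the pairs.
// [[Rcpp::export]]
NumericMatrix corr_sum_multi_cpp(NumericVector x, int tau, IntegerVector ms,
                                 int w, NumericVector radii) {
  const int N = x.size();
  const int nr = radii.size();
  const int nm = ms.size();
  const int mmax = ms[nm - 1];

  // m -> row index in the output, or -1
  std::vector<int> mrow(mmax + 1, -1);
  for (int mi = 0; mi < nm; ++mi) mrow[ms[mi]] = mi;

  // compare squared distances against squared radii (monotone, sqrt-free);
  // counts laid out flat as [mi * (nr+1) + bin], bin nr = "beyond rmax"
  std::vector<double> rad2(nr);
  for (int r = 0; r < nr; ++r) rad2[r] = radii[r] * radii[r];
  std::vector<double> counts((size_t)nm * (nr + 1), 0.0);
  const double *xp = REAL(x);

  for (int i = 0; i < N - 1 - w; ++i) {
    for (int j = i + 1 + w; j < N; ++j) {
      double d2 = 0.0;
      int bin = 0;  // squared distance grows with m, so the bin only advances
      // after adding coordinate k (0-based) this is the m = k+1 distance;
      // the pair is admissible for m iff j + (m-1)*tau < N, which is
      // exactly the loop guard below
      for (int k = 0; k < mmax && j + k * tau < N; ++k) {
        const double diff = xp[i + k * tau] - xp[j + k * tau];
        d2 += diff * diff;
        const int mi = mrow[k + 1];
        if (mi >= 0) {
          while (bin < nr && rad2[bin] < d2) ++bin;  // first radius >= dist
          counts[(size_t)mi * (nr + 1) + bin] += 1.0;
        }
      }
    }
  }

  NumericMatrix C(nm, nr);
  for (int mi = 0; mi < nm; ++mi) {
    const int m = ms[mi];
    const long long M = (long long)N - (long long)(m - 1) * tau;
    const double denom = (double)(M - w) * (double)(M - w - 1) / 2.0;
    double acc = 0.0;
    for (int r = 0; r < nr; ++r) {
      acc += counts[(size_t)mi * (nr + 1) + r];
      C(mi, r) = (denom > 0) ? acc / denom : NA_REAL;
    }
  }
  return C;
}

// False-nearest-neighbour fractions per embedding dimension (Kennel method).
// For each m in ms: embed at m using only vectors whose (m+1)-th coordinate
// exists (i <= N - m*tau - 1, 0-based), find each vector's Euclidean nearest
// neighbour (self and |i-j| <= w excluded; ties -> smallest index), and mark
// it FALSE when |x[i+m*tau] - x[j+m*tau]| / dist_m(i,j) > R. Duplicate
// neighbours (distance <= dup_eps, covering exact duplicates and
// floating-point revisits of periodic signals) are excluded and counted.
// [[Rcpp::export]]
List fnn_profile_cpp(NumericVector x, int tau, IntegerVector ms, double R,
                     int w, double dup_eps) {
  const int N = x.size();
  const int nm = ms.size();
  const double eps2 = dup_eps * dup_eps;
  NumericVector frac(nm), nfalse(nm), nvalid(nm), nzero(nm);

  for (int mi = 0; mi < nm; ++mi) {
    const int m = ms[mi];
    const int Mp = N - m * tau;  // vectors with the extra coordinate
    long long nf = 0, nv = 0, nz = 0;
    for (int i = 0; i < Mp; ++i) {
      double best = R_PosInf;
      int bestj = -1;
      for (int j = 0; j < Mp; ++j) {
        if (std::abs(i - j) <= w) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          const double diff = x[i + k * tau] - x[j + k * tau];
          d2 += diff * diff;
          if (d2 >= best) break;
        }
        if (d2 <= eps2) { ++nz; continue; }  // duplicate: not a usable NN
        if (d2 < best) { best = d2; bestj = j; }
      }
      if (bestj < 0 || !R_FINITE(best)) continue;
      const double d = std::sqrt(best);
      const double extra = std::abs(x[i + m * tau] - x[bestj + m * tau]);
      if (extra / d > R) ++nf;
      ++nv;
    }
    nfalse[mi] = (double)nf;
    nvalid[mi] = (double)nv;
    nzero[mi] = (double)nz;
    frac[mi] = nv > 0 ? (double)nf / (double)nv : NA_REAL;
  }
  return List::create(_["fnn_fraction"] = frac, _["n_false"] = nfalse,
                      _["n_valid"] = nvalid, _["n_zero_excluded"] = nzero);
}

// Rosenstein mean log-divergence curve. For each embedded vector, find its
// nearest neighbour under Theiler exclusion (|i-j| > w), then track the log
// of the pair distance over nsteps forward steps; return the mean of log d
// per step over all pairs still inside the embedding. Initial separations
// at or below dup_eps (exact duplicates and floating-point revisits) are
// excluded from seeding, never divided by; zero step distances are skipped
// so no log(0) enters the mean.
// [[Rcpp::export]]
List lle_divergence_cpp(NumericVector x, int tau, int m, int w, int nsteps,
                        double dup_eps) {
  const int N = x.size();
  const int M = N - (m - 1) * tau;
  const double eps2 = dup_eps * dup_eps;
  std::vector<double> sumlog(nsteps + 1, 0.0);
  std::vector<long long> cnt(nsteps + 1, 0);
  long long npairs = 0, nzero0 = 0;

  for (int i = 0; i < M; ++i) {
    double best = R_PosInf;
    int bestj = -1;
    bool saw_dup = false;
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= w) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = x[i + k * tau] - x[j + k * tau];
        d2 += diff * diff;
        if (d2 >= best) break;
      }
      if (d2 <= eps2) { saw_dup = true; continue; }
      if (d2 < best) { best = d2; bestj = j; }
    }
    if (saw_dup) ++nzero0;
    if (bestj < 0 || !R_FINITE(best)) continue;
    ++npairs;
    for (int s = 0; s <= nsteps && i + s < M && bestj + s < M; ++s) {
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = x[i + s + k * tau] - x[bestj + s + k * tau];
        d2 += diff * diff;
      }
      if (d2 > 0.0) {
        sumlog[s] += 0.5 * std::log(d2);
        cnt[s] += 1;
      }
    }
  }

  NumericVector curve(nsteps + 1);
  for (int s = 0; s <= nsteps; ++s) {
    curve[s] = cnt[s] > 0 ? sumlog[s] / (double)cnt[s] : NA_REAL;
  }
  return List::create(_["mean_log_divergence"] = curve,
                      _["n_pairs"] = (double)npairs,
                      _["n_zero_excluded"] = (double)nzero0);
}
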