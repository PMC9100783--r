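#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <queue>
#include <vector>
using namespace Rcpp;

// Streaming chi-square scoring of the augmented feature universe.
//
// Base features are enumerated as b = 1..p (stage-1 singletons) followed by
// the choose(p, 2) unordered products (i < j, lexicographic). Universe ids
// interleave raw and log twins: raw id = 2b - 1, log id = 2b.
//
// The continuous chi-square statistic needs only per-class sums, the
// feature minimum/maximum (for min-max calibration to [0, 1], whose class
// sums follow in closed form from the raw sums) and per-element logs for
// the calibrated log twin log(1 + (x - min)/(max - min)). Per-class sums
// for all label columns at once are a matrix product, computed with BLAS
// over fixed-width chunks of the universe, so scoring P label
// permutations shares one product/min-max/log pass.

static inline double chi2_from_sums(double s1, double s0, double n1,
                                    double n0, double mn, double mx,
                                    bool calibrate) {
  if (mx <= mn) return 0.0;           // constant feature: no evidence
  if (calibrate) {                    // min-max rescale to [0, 1]
    double range = mx - mn;
    s1 = (s1 - n1 * mn) / range;
    s0 = (s0 - n0 * mn) / range;
  }
  double tot = s0 + s1;
  if (tot <= 0.0) return 0.0;
  double p1 = n1 / (n1 + n0);
  double e1 = tot * p1;
  double e0 = tot - e1;
  double d1 = s1 - e1, d0 = s0 - e0;
  return d1 * d1 / e1 + d0 * d0 / e0;
}

struct Scored {
  double chi2;
  double id;  // universe id (may exceed 2^31 at full scale)
};
// "better" = higher chi2, ties broken toward the earlier stream position
static inline bool better(const Scored &a, const Scored &b) {
  if (a.chi2 != b.chi2) return a.chi2 > b.chi2;
  return a.id < b.id;
}
struct BetterCmp {
  bool operator()(const Scored &a, const Scored &b) const {
    return better(a, b);  // priority_queue top = worst retained element
  }
};
typedef std::priority_queue<Scored, std::vector<Scored>, BetterCmp> TopKHeap;

static inline void heap_offer(TopKHeap &h, size_t k, double chi2, double id) {
  Scored cand{chi2, id};
  if (h.size() < k) { h.push(cand); return; }
  if (better(cand, h.top())) { h.pop(); h.push(cand); }
}

// One pass over the universe scoring every feature against every column of
// Y (n x P, entries 0/1; each column must contain both classes).
//
// k >= 1:       per column, keep the exact top-k (chi2 desc, earlier
//               stream position wins ties).
// return_full:  additionally return the full chi2 vectors per base feature
//               (raw and log twins) plus base min/max; only sensible for
//               small P (used with P = 1).
// calibrate_all: if true, min-max calibrate every raw feature before
//               scoring (scale-fair ranking); if false, only features
//               containing a negative value are calibrated.
// [[Rcpp::export]]
List chisq_scan_cpp(NumericMatrix X, NumericMatrix Y, int k,
                    bool calibrate_all, bool return_full) {
  const int n = X.nrow(), p = X.ncol(), P = Y.ncol();
  if (Y.nrow() != n) stop("label matrix row mismatch");
  std::vector<double> n1(P, 0.0);
  for (int q = 0; q < P; ++q) {
    for (int s = 0; s < n; ++s) {
      double v = Y(s, q);
      if (v != 0.0 && v != 1.0) stop("labels must be 0/1");
      n1[q] += v;
    }
    if (n1[q] == 0 || n1[q] == n) stop("single-class label column");
  }

  const R_xlen_t nbase = (R_xlen_t)p + (R_xlen_t)p * (p - 1) / 2;
  const int B = 2048;                     // chunk width (base features)
  std::vector<double> U((size_t)n * B), L((size_t)n * B);
  std::vector<double> mnv(B), mxv(B), totr(B), totl(B);
  std::vector<double> S1r((size_t)B * P), S1l((size_t)B * P);

  std::vector<TopKHeap> heaps(k >= 1 ? P : 0);
  NumericVector full_raw, full_log, full_min, full_max;
  if (return_full) {
    full_raw = NumericVector(nbase);
    full_log = NumericVector(nbase);
    full_min = NumericVector(nbase);
    full_max = NumericVector(nbase);
  }

  int i = 0, j = -1;                       // j == -1: singleton i
  R_xlen_t b = 0;
  const double one = 1.0, zero = 0.0;
  while (b < nbase) {
    const int width = (int)std::min((R_xlen_t)B, nbase - b);
    for (int c = 0; c < width; ++c) {
      double *u = &U[(size_t)n * c];
      if (j < 0) {
        const double *xi = &X(0, i);
        std::copy(xi, xi + n, u);
      } else {
        const double *xi = &X(0, i), *xj = &X(0, j);
        for (int s = 0; s < n; ++s) u[s] = xi[s] * xj[s];
      }
      double mn = u[0], mx = u[0], tot = 0.0;
      for (int s = 0; s < n; ++s) {
        if (u[s] < mn) mn = u[s];
        if (u[s] > mx) mx = u[s];
        tot += u[s];
      }
      mnv[c] = mn; mxv[c] = mx; totr[c] = tot;
      double *lg = &L[(size_t)n * c];
      double tl = 0.0;
      if (mx > mn) {
        const double inv = 1.0 / (mx - mn);
        for (int s = 0; s < n; ++s) {
          lg[s] = log1p((u[s] - mn) * inv);
          tl += lg[s];
        }
      } else std::fill(lg, lg + n, 0.0);
      totl[c] = tl;
      // advance (i, j)
      if (j < 0) { if (i + 1 < p) ++i; else { i = 0; j = 1; } }
      else { if (j + 1 < p) ++j; else { ++i; j = i + 1; } }
    }
    // class-1 sums for all label columns: S1 = U' Y and L' Y
    F77_CALL(dgemm)("T", "N", &width, &P, &n, &one, U.data(), &n,
                    REAL(Y), &n, &zero, S1r.data(), &width
                    FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &width, &P, &n, &one, L.data(), &n,
                    REAL(Y), &n, &zero, S1l.data(), &width
                    FCONE FCONE);
    for (int q = 0; q < P; ++q) {
      const double nn1 = n1[q], nn0 = n - n1[q];
      const double *s1r = &S1r[(size_t)width * q];
      const double *s1l = &S1l[(size_t)width * q];
      for (int c = 0; c < width; ++c) {
        const bool cal = calibrate_all || mnv[c] < 0.0;
        const double craw = chi2_from_sums(
          s1r[c], totr[c] - s1r[c], nn1, nn0, mnv[c], mxv[c], cal);
        // log twins span [0, log 2] exactly; under scale-fair scoring they
        // are min-max calibrated like every other feature
        const double clog = chi2_from_sums(
          s1l[c], totl[c] - s1l[c], nn1, nn0, 0.0,
          mxv[c] > mnv[c] ? M_LN2 : 0.0, calibrate_all);
        const double raw_id = 2.0 * (double)(b + c + 1) - 1.0;
        if (k >= 1) {
          heap_offer(heaps[q], (size_t)k, craw, raw_id);
          heap_offer(heaps[q], (size_t)k, clog, raw_id + 1.0);
        }
        if (return_full && q == 0) {
          full_raw[b + c] = craw;
          full_log[b + c] = clog;
          full_min[b + c] = mnv[c];
          full_max[b + c] = mxv[c];
        }
      }
    }
    b += width;
  }

  List out;
  if (k >= 1) {
    List topk(P);
    for (int q = 0; q < P; ++q) {
      size_t m = heaps[q].size();
      NumericVector ids(m), chi2(m);
      for (size_t t = m; t > 0; --t) {   // pops worst-first
        const Scored &s = heaps[q].top();
        ids[t - 1] = s.id;
        chi2[t - 1] = s.chi2;
        heaps[q].pop();
      }
      topk[q] = List::create(_["ids"] = ids, _["chi2"] = chi2);
    }
    out["topk"] = topk;
  }
  if (return_full) {
    out["raw"] = full_raw;
    out["log"] = full_log;
    out["min"] = full_min;
    out["max"] = full_max;
  }
  return out;
}
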