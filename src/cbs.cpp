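#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <algorithm>

// Circular binary segmentation of one chromosome's bin-level log2 values.
//
// The change statistic for an arc (i, j] of length k within a region of n
// bins is the two-sample t-like statistic comparing the mean inside the arc
// with the mean outside, with a region-level variance estimate (permutation
// invariant, so it cancels in permutation comparisons):
//
//   Z(i,j) = (D - k*mu) * sqrt(n / (k*(n-k))) / s,   D = S_j - S_i
//
// For fixed k, |Z| is maximised by the extreme values of D, so the full
// O(n^2) arc scan reduces to one max/min pass over lagged prefix-sum
// differences per k. Significance of the best arc is assessed by permuting
// the bin values; p = (1 + #exceedances) / (1 + n_perm). Early stopping is
// applied only on the non-significant side (once p >= alpha is inevitable),
// which leaves accepted splits exact.

namespace {

struct BestArc {
  int i = 0, j = 0;        // arc (i, j], 0-based offsets into the region
  double z2 = -1.0;        // squared standardised statistic numerator
};

// Scan all admissible arcs; returns best arc by |D - k*mu| * sqrt(n/(k(n-k))).
// min_width constrains the arc (k >= mw, n-k >= mw) and forbids leftover
// outer pieces shorter than mw (i in {0} U [mw, n-k-mw] U {n-k}).
// For fixed k the statistic is monotone in |D - k*mu|, so only the extreme
// lagged differences D = S[i+k] - S[i] matter: one tight min/max pass per k.
// If early_stop > 0, returns as soon as z2 > early_stop (used in
// permutations, where only exceedance matters, not the arg max).
BestArc scan_arcs(const std::vector<double>& S, int n, double mu, int mw,
                  double early_stop) {
  BestArc best;
  for (int k = mw; k <= n - mw; ++k) {
    double w = static_cast<double>(n) / (static_cast<double>(k) * (n - k));
    double target = k * mu;
    double dmax = S[k] - S[0];          // i = 0 always admissible
    double dmin = dmax;
    {
      double d = S[n] - S[n - k];       // i = n-k always admissible
      if (d > dmax) dmax = d; else if (d < dmin) dmin = d;
    }
    const double* lo = S.data();
    const double* hi = S.data() + k;
    int i0 = mw, i1 = n - k - mw;       // interior admissible range
    for (int i = i0; i <= i1; ++i) {    // plain min/max reductions: SIMD
      double d = hi[i] - lo[i];
      dmax = d > dmax ? d : dmax;
      dmin = d < dmin ? d : dmin;
    }
    double devmax = dmax - target;
    double devmin = target - dmin;
    double dev = devmax > devmin ? devmax : devmin;
    double z2 = dev * dev * w;
    if (z2 > best.z2) {
      best.z2 = z2;
      if (early_stop > 0) {             // arg max not needed
        if (z2 > early_stop) return best;
        continue;
      }
      // recover the arg max i for this k (rare; O(n) when improved)
      double want = devmax > devmin ? dmax : dmin;
      int ibest = 0;
      if (S[k] - S[0] == want) ibest = 0;
      else if (S[n] - S[n - k] == want) ibest = n - k;
      else {
        for (int i = i0; i <= i1; ++i)
          if (S[i + k] - S[i] == want) { ibest = i; break; }
      }
      best.i = ibest;
      best.j = ibest + k;
    }
  }
  return best;
}

void prefix_sums(const std::vector<double>& x, std::vector<double>& S) {
  S[0] = 0.0;
  for (size_t t = 0; t < x.size(); ++t) S[t + 1] = S[t] + x[t];
}

// Recursive CBS on x[lo..hi] (inclusive); appends accepted internal
// breakpoints (global 0-based index of first bin of the right piece).
void segment_rec(const std::vector<double>& x, int lo, int hi,
                 double alpha, int n_perm, int min_width,
                 unsigned int seed, std::vector<int>& breaks) {
  int n = hi - lo + 1;
  if (n < 2 * min_width) return;

  std::vector<double> xs(x.begin() + lo, x.begin() + hi + 1);
  std::vector<double> S(n + 1);
  prefix_sums(xs, S);
  double mu = S[n] / n;

  // region variance (ddof 1); degenerate (constant) regions cannot split
  double ss = 0.0;
  for (int t = 0; t < n; ++t) ss += (xs[t] - mu) * (xs[t] - mu);
  double s2 = ss / (n - 1);

  BestArc obs = scan_arcs(S, n, mu, min_width, -1.0);
  if (obs.z2 <= 0) return;

  bool significant;
  if (s2 < 1e-24) {
    // noiseless: any non-zero mean difference is a certain split
    significant = obs.z2 > 1e-18;
  } else {
    // permutation test with early stop on the non-significant side
    int max_exceed = static_cast<int>(std::floor(alpha * (n_perm + 1))) - 1;
    // need exceed <= max_exceed for (1+exceed)/(1+n_perm) < alpha
    std::mt19937 rng(seed ^ (static_cast<unsigned int>(lo) * 2654435761u)
                          ^ (static_cast<unsigned int>(n) * 40503u));
    std::vector<double> xp(xs);
    std::vector<double> Sp(n + 1);
    // M = max |x - mu| is permutation invariant; with R the range of the
    // centred prefix walk T[i] = Sp[i] - i*mu, every arc satisfies
    // |D - k*mu| <= min(R, k*M, (n-k)*M), an O(n) upper bound on the
    // permuted max statistic: when it falls below the observed value the
    // permutation certainly contributes no exceedance and the O(n^2) scan
    // is skipped. The envelope is unimodal in k (peak near R/M), so a few
    // candidate k cover its discrete max.
    double M = 0.0;
    for (int t = 0; t < n; ++t) M = std::max(M, std::fabs(xs[t] - mu));
    int exceed = 0;
    for (int p = 0; p < n_perm; ++p) {
      // Fisher-Yates shuffle
      for (int t = n - 1; t > 0; --t) {
        std::uniform_int_distribution<int> u(0, t);
        std::swap(xp[t], xp[u(rng)]);
      }
      prefix_sums(xp, Sp);
      if (M > 0.0) {
        double tmin = 0.0, tmax = 0.0;
        for (int t = 1; t <= n; ++t) {
          double tv = Sp[t] - t * mu;
          if (tv > tmax) tmax = tv; else if (tv < tmin) tmin = tv;
        }
        double R = tmax - tmin;
        double kstar = R / M;
        int kf = static_cast<int>(std::floor(kstar));
        int cand[6] = {min_width, n - min_width, kf, kf + 1, n - kf, n - kf - 1};
        double bound = 0.0;
        for (int c = 0; c < 6; ++c) {
          int k = cand[c];
          if (k < min_width || k > n - min_width) continue;
          double dev = std::min(R, std::min(k * M, (n - k) * M));
          double z2 = dev * dev * static_cast<double>(n) /
                      (static_cast<double>(k) * (n - k));
          if (z2 > bound) bound = z2;
        }
        if (bound < obs.z2) continue;  // exceedance impossible
      }
      BestArc pb = scan_arcs(Sp, n, mu, min_width, obs.z2);
      if (pb.z2 >= obs.z2) {
        if (++exceed > max_exceed) break;  // cannot reach significance
      }
    }
    significant = exceed <= max_exceed;
  }
  if (!significant) return;

  // accepted: internal breakpoints at obs.i and obs.j (skip region edges)
  int bi = obs.i, bj = obs.j;
  if (bi > 0) breaks.push_back(lo + bi);
  if (bj < n) breaks.push_back(lo + bj);

  if (bi > 0) segment_rec(x, lo, lo + bi - 1, alpha, n_perm, min_width, seed, breaks);
  segment_rec(x, lo + bi, lo + bj - 1, alpha, n_perm, min_width, seed, breaks);
  if (bj < n) segment_rec(x, lo + bj, hi, alpha, n_perm, min_width, seed, breaks);
}

}  // namespace

// [[Rcpp::export(name = ".cbs_chrom")]]
Rcpp::IntegerVector cbs_chrom(Rcpp::NumericVector x, double alpha, int n_perm,
                              int min_width, int seed, double merge_tol) {
  int n = x.size();
  if (n == 0) return Rcpp::IntegerVector(0);
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> breaks;
  segment_rec(xv, 0, n - 1, alpha, n_perm, min_width,
              static_cast<unsigned int>(seed), breaks);
  std::sort(breaks.begin(), breaks.end());
  breaks.erase(std::unique(breaks.begin(), breaks.end()), breaks.end());

  // segment boundaries -> per-segment means; merge adjacent segments whose
  // means differ by less than merge_tol (left-to-right, repeat to fixpoint)
  std::vector<int> starts;
  starts.push_back(0);
  for (int b : breaks) starts.push_back(b);
  std::vector<double> S(n + 1);
  prefix_sums(xv, S);

  bool changed = true;
  while (changed && starts.size() > 1) {
    changed = false;
    std::vector<int> out;
    out.push_back(starts[0]);
    for (size_t t = 1; t < starts.size(); ++t) {
      int a0 = out.back();
      int a1 = starts[t];
      int b1 = (t + 1 < starts.size()) ? starts[t + 1] : n;
      double m1 = (S[a1] - S[a0]) / (a1 - a0);
      double m2 = (S[b1] - S[a1]) / (b1 - a1);
      if (std::fabs(m1 - m2) < merge_tol) {
        changed = true;  // drop this boundary
      } else {
        out.push_back(a1);
      }
    }
    starts = out;
  }

  // return 1-based segment end indices
  Rcpp::IntegerVector ends(starts.size());
  for (size_t t = 0; t < starts.size(); ++t)
    ends[t] = (t + 1 < starts.size()) ? starts[t + 1] : n;
  return ends;
}
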