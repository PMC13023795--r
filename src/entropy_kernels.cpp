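#include <Rcpp.h>
using namespace Rcpp;

// Pairwise template-matching kernels for the quadratic-cost entropy
// measures.  All distances are Chebyshev (max-norm) over delay-embedded
// templates; matches use d <= r.  Raw pointers keep the O(n^2) loops
// tight; callers in R validate lengths and parameters.

// Template counts for sample entropy: B = matching m-templates,
// A = matching (m+1)-templates, both over the first n-m template
// start points so every counted template has an (m+1)-th element.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const double* p = x.begin();
  int n = x.size();
  int N = n - m;  // template start points
  double A = 0.0, B = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      int k = 0;
      for (; k < m; ++k) {
        double t = std::fabs(p[i + k] - p[j + k]);
        if (t > d) { d = t; if (d > r) break; }
      }
      if (k < m) continue;  // early exit: no m-match
      B += 1.0;
      // (m+1)-distance = max(d, last-element distance), d <= r already
      if (std::fabs(p[i + m] - p[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(_["B"] = B, _["A"] = A);
}

// Mean exponential memberships for fuzzy entropy.  Templates are
// baseline-removed (their own mean subtracted); membership
// mu = exp(-d^2 / (2 r^2)).
// [[Rcpp::export]]
NumericVector fuzzy_phi_cpp(NumericVector x, int m, double r) {
  const double* p = x.begin();
  int n = x.size();
  int N = n - m;
  double denom = 2.0 * r * r;
  std::vector<double> mean_m(N), mean_m1(N);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += p[i + k];
    mean_m[i] = s / m;
    mean_m1[i] = (s + p[i + m]) / (m + 1);
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  long cnt = 0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dm = 0.0, dm1 = 0.0;
      double om = mean_m[i] - mean_m[j], om1 = mean_m1[i] - mean_m1[j];
      for (int k = 0; k < m; ++k) {
        double diff = p[i + k] - p[j + k];
        double t = std::fabs(diff - om);
        if (t > dm) dm = t;
        double t1 = std::fabs(diff - om1);
        if (t1 > dm1) dm1 = t1;
      }
      double t1 = std::fabs(p[i + m] - p[j + m] - om1);
      if (t1 > dm1) dm1 = t1;
      phi_m += std::exp(-dm * dm / denom);
      phi_m1 += std::exp(-dm1 * dm1 / denom);
      ++cnt;
    }
  }
  return NumericVector::create(_["phi_m"] = phi_m / cnt,
                               _["phi_m1"] = phi_m1 / cnt);
}

// Correlation sums C_m and C_{m+1} for the K2 (correlation-entropy)
// estimate; each C uses all templates of its own length, so the two
// sums have different normalizations (unlike sample entropy).
// [[Rcpp::export]]
NumericVector corr_sums_cpp(NumericVector x, int m, double r) {
  const double* p = x.begin();
  int n = x.size();
  double out[2];
  for (int step = 0; step < 2; ++step) {
    int mm = m + step;
    int N = n - mm + 1;
    double c = 0.0;
    long cnt = 0;
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        int k = 0;
        for (; k < mm; ++k)
          if (std::fabs(p[i + k] - p[j + k]) > r) break;
        if (k == mm) c += 1.0;
        ++cnt;
      }
    }
    out[step] = c / cnt;
  }
  return NumericVector::create(_["C_m"] = out[0], _["C_m1"] = out[1]);
}

// Histogram (probability vector) of pairwise Chebyshev distances
// between m-embedded templates, on [0, max distance] with `bins`
// equal-width bins; used by distribution entropy.
// [[Rcpp::export]]
NumericVector cheb_dist_probs_cpp(NumericVector x, int m, int bins) {
  const double* p = x.begin();
  int n = x.size();
  int N = n - m + 1;
  long npair = (long)N * (N - 1) / 2;
  std::vector<double> d(npair);
  long idx = 0;
  double dmax = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dd = 0.0;
      for (int k = 0; k < m; ++k) {
        double t = std::fabs(p[i + k] - p[j + k]);
        if (t > dd) dd = t;
      }
      d[idx++] = dd;
      if (dd > dmax) dmax = dd;
    }
  }
  NumericVector probs(bins);
  if (dmax <= 0.0) { probs[0] = 1.0; return probs; }
  for (long t = 0; t < npair; ++t) {
    int b = (int)std::floor(d[t] / dmax * bins);
    if (b >= bins) b = bins - 1;
    probs[b] += 1.0;
  }
  for (int b = 0; b < bins; ++b) probs[b] /= (double)npair;
  return probs;
}

// Fraction of embedded-template pairs whose angular distance
// acos(cosine similarity)/pi is below r; used by cosine-similarity
// entropy (caller removes the series median first).
// [[Rcpp::export]]
double cosine_match_p_cpp(NumericVector x, int m, int tau, double r) {
  const double* p = x.begin();
  int n = x.size();
  int N = n - (m - 1) * tau;
  double cnt = 0.0;
  long npair = 0;
  double cos_thr = std::cos(r * M_PI);  // ang < r  <=>  cos > cos(r*pi)
  std::vector<double> norm2(N);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) { double a = p[i + k * tau]; s += a * a; }
    norm2[i] = s;
  }
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      bool match;
      if (norm2[i] <= 0.0 || norm2[j] <= 0.0) {
        match = true;  // zero-norm template: treat as aligned (angle 0)
      } else {
        double dot = 0.0;
        for (int k = 0; k < m; ++k) dot += p[i + k * tau] * p[j + k * tau];
        match = dot > cos_thr * std::sqrt(norm2[i] * norm2[j]);
      }
      if (match) cnt += 1.0;
      ++npair;
    }
  }
  return cnt / npair;
}
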