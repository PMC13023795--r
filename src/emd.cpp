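#include <Rcpp.h>
using namespace Rcpp;

// Sifting core for empirical mode decomposition.  Envelopes are natural
// cubic splines through the local extrema, mirror-extended by up to two
// extrema beyond each boundary; one sift subtracts the mean envelope.  A
// candidate is accepted when the Cauchy SD criterion falls below threshold
// AND the IMF count condition (|#zero-crossings - #extrema| <= 1) holds,
// or when the iteration cap is reached.

static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& mx, std::vector<int>& mn) {
  mx.clear(); mn.clear();
  int n = x.size();
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) mx.push_back(i);
    else if (x[i] < x[i - 1] && x[i] < x[i + 1]) mn.push_back(i);
  }
}

static int zero_crossings(const std::vector<double>& x) {
  int zc = 0, prev = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    int s = (x[i] > 0) - (x[i] < 0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++zc;
    prev = s;
  }
  return zc;
}

// Natural cubic spline through (t, v), evaluated at 1..n (1-based sample
// positions); t strictly increasing.
static void spline_envelope(const std::vector<double>& t,
                            const std::vector<double>& v,
                            int n, std::vector<double>& out) {
  int K = t.size();
  out.assign(n, 0.0);
  if (K == 2) {  // straight line
    double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = v[0] + slope * ((i + 1) - t[0]);
    return;
  }
  // second derivatives via Thomas algorithm (natural BC: M[0]=M[K-1]=0)
  std::vector<double> h(K - 1), alpha(K), l(K), mu(K), z(K), M(K);
  for (int i = 0; i < K - 1; ++i) h[i] = t[i + 1] - t[i];
  alpha[0] = 0.0;
  for (int i = 1; i < K - 1; ++i)
    alpha[i] = 3.0 * ((v[i + 1] - v[i]) / h[i] - (v[i] - v[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < K - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[K - 1] = 0.0;
  for (int i = K - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // evaluate; positions 1..n, walk the knot intervals
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double xx = i + 1;
    while (seg < K - 2 && xx > t[seg + 1]) ++seg;
    double hh = h[seg];
    double A = (t[seg + 1] - xx) / hh, B = (xx - t[seg]) / hh;
    out[i] = A * v[seg] + B * v[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) *
        (hh * hh) / 6.0;
  }
}

// Mirror-extend extrema (1-based positions p, values from x) by up to two
// beyond each end, then fit the envelope.
static bool build_envelope(const std::vector<double>& x,
                           const std::vector<int>& p, int n,
                           std::vector<double>& env) {
  int K = p.size();
  if (K < 2) return false;
  int k = std::min(2, K);
  std::vector<double> t, v;
  t.reserve(K + 2 * k); v.reserve(K + 2 * k);
  for (int i = k - 1; i >= 0; --i) {
    double tp = 2.0 - (p[i] + 1);  // mirror about sample 1
    t.push_back(tp); v.push_back(x[p[i]]);
  }
  for (int i = 0; i < K; ++i) { t.push_back(p[i] + 1); v.push_back(x[p[i]]); }
  for (int i = 0; i < k; ++i) {
    double tp = 2.0 * n - (p[K - 1 - i] + 1);  // mirror about sample n
    t.push_back(tp); v.push_back(x[p[K - 1 - i]]);
  }
  // drop non-increasing knots introduced by mirroring end extrema
  std::vector<double> tt, vv;
  for (size_t i = 0; i < t.size(); ++i) {
    if (tt.empty() || t[i] > tt.back() + 1e-9) { tt.push_back(t[i]); vv.push_back(v[i]); }
  }
  if (tt.size() < 2) return false;
  spline_envelope(tt, vv, n, env);
  return true;
}

// [[Rcpp::export]]
List emd_decompose_cpp(NumericVector x_in, int max_imfs, double sd_thresh,
                       int max_iters) {
  int n = x_in.size();
  std::vector<double> residue(x_in.begin(), x_in.end());
  std::vector<double> h(n), upper(n), lower(n);
  std::vector<int> mx, mn;
  double e0 = 0.0;
  for (int i = 0; i < n; ++i) e0 += residue[i] * residue[i];
  List imfs(max_imfs);
  int n_imfs = 0;
  for (int k = 0; k < max_imfs; ++k) {
    double rm = 0.0;
    for (int i = 0; i < n; ++i) rm += residue[i];
    rm /= n;
    double er = 0.0;
    for (int i = 0; i < n; ++i) er += (residue[i] - rm) * (residue[i] - rm);
    // oscillatory part of the residue negligible: decomposition done
    if (er <= 1e-10 * e0) break;
    find_extrema(residue, mx, mn);
    if ((int)mx.size() < 2 || (int)mn.size() < 2) break;
    h = residue;
    for (int iter = 0; iter < max_iters; ++iter) {
      find_extrema(h, mx, mn);
      if ((int)mx.size() < 2 || (int)mn.size() < 2) break;
      if (!build_envelope(h, mx, n, upper)) break;
      if (!build_envelope(h, mn, n, lower)) break;
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = 0.5 * (upper[i] + lower[i]);
        num += m * m; den += h[i] * h[i];
        h[i] -= m;
      }
      double sd_crit = den > 0 ? num / den : 0.0;
      find_extrema(h, mx, mn);
      int n_ext = mx.size() + mn.size();
      int zc = zero_crossings(h);
      if (sd_crit < sd_thresh && std::abs(zc - n_ext) <= 1) break;
    }
    imfs[n_imfs] = NumericVector(h.begin(), h.end());
    ++n_imfs;
    for (int i = 0; i < n; ++i) residue[i] -= h[i];
  }
  List out_imfs(n_imfs);
  for (int i = 0; i < n_imfs; ++i) out_imfs[i] = imfs[i];
  return List::create(_["imfs"] = out_imfs,
                      _["residue"] = NumericVector(residue.begin(), residue.end()),
                      _["n_imfs"] = n_imfs);
}
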