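// Compiled inner loops: fractional-noise spectral synthesis, sample-entropy
// pair counting, and zero-phase IIR filtering.  These are the hot paths when
// a full 42-subject cohort (19 channels x 180,000 samples) is processed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

// Assemble the Hermitian-symmetric spectrum of the circulant embedding from
// pre-drawn standard normals and invert it.  `ev` are the m circulant
// eigenvalues, `z` are m iid N(0,1) draws taken from R's RNG (so the result
// is reproducible under set.seed), `n` is the number of samples wanted.
// Returns one exact fractional-Gaussian-noise realization of length n.
// [[Rcpp::export(name = ".fgn_from_normals")]]
NumericVector fgn_from_normals(const arma::vec& ev, const arma::vec& z, int n) {
  const int m = ev.n_elem;
  const int half = m / 2;
  arma::cx_vec a(m);
  a[0]    = std::sqrt(std::max(ev[0], 0.0)) * z[0];
  a[half] = std::sqrt(std::max(ev[half], 0.0)) * z[1];
  for (int k = 1; k < half; ++k) {
    double s = std::sqrt(std::max(ev[k], 0.0) / 2.0);
    a[k] = std::complex<double>(s * z[2 * k], s * z[2 * k + 1]);
    a[m - k] = std::conj(a[k]);
  }
  arma::cx_vec f = arma::fft(a);
  const double sc = 1.0 / std::sqrt(static_cast<double>(m));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = f[i].real() * sc;
  return out;
}

// Sample-entropy template-match counts (Richman & Moorman convention):
// over the N-m template start positions, B = #{i<j : max_{k<m}|x[i+k]-x[j+k]| <= r},
// A = same with the (m+1)-th point included.  Sorting template heads and
// sweeping a two-pointer window over the first coordinate avoids the full
// O(N^2) scan while returning exactly the same counts.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(const NumericVector& x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double A = 0.0, B = 0.0;
  int lo = 0;
  for (int jj = 0; jj < nt; ++jj) {
    const int j = ord[jj];
    while (x[ord[jj]] - x[ord[lo]] > r) ++lo;
    for (int ii = lo; ii < jj; ++ii) {
      const int i = ord[ii];
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& x) {
  // direct-form II transposed, a[0] assumed 1
  const size_t n = x.size(), ord = b.size() - 1;
  std::vector<double> w(ord, 0.0);
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (ord ? w[0] : 0.0);
    for (size_t k = 0; k + 1 < ord; ++k)
      w[k] = b[k + 1] * xi + w[k + 1] - a[k + 1] * yi;
    if (ord) w[ord - 1] = b[ord] * xi - a[ord] * yi;
    x[i] = yi;
  }
}

// Zero-phase filtering: odd-reflection padding at both ends, filter forward,
// reverse, filter again, reverse, trim.  Equivalent in the signal interior to
// signal::filtfilt but without its per-call R overhead.
// [[Rcpp::export(name = ".filtfilt_cpp")]]
NumericVector filtfilt_cpp(const NumericVector& b_, const NumericVector& a_,
                           const NumericVector& x_, int pad) {
  const int n = x_.size();
  pad = std::min(pad, n - 1);
  std::vector<double> b(b_.begin(), b_.end()), a(a_.begin(), a_.end());
  // normalize so a[0] == 1
  for (size_t k = 0; k < b.size(); ++k) b[k] /= a_[0];
  for (size_t k = 0; k < a.size(); ++k) a[k] /= a_[0];
  std::vector<double> y(n + 2 * pad);
  for (int i = 0; i < pad; ++i)                       // odd reflection, left
    y[i] = 2.0 * x_[0] - x_[pad - i];
  for (int i = 0; i < n; ++i) y[pad + i] = x_[i];
  for (int i = 0; i < pad; ++i)                       // odd reflection, right
    y[pad + n + i] = 2.0 * x_[n - 1] - x_[n - 2 - i];
  iir_pass(b, a, y);
  std::reverse(y.begin(), y.end());
  iir_pass(b, a, y);
  std::reverse(y.begin(), y.end());
  return NumericVector(y.begin() + pad, y.begin() + pad + n);
}

// Higuchi normalized curve lengths L(k), k = 1..k_max, averaged over the k
// start offsets.  Kept in C++ because it runs once per epoch over the whole
// cohort.  Returns the vector of L(k).
// [[Rcpp::export(name = ".higuchi_lengths_cpp")]]
NumericVector higuchi_lengths_cpp(const NumericVector& x, int k_max) {
  const int N = x.size();
  NumericVector L(k_max);
  for (int k = 1; k <= k_max; ++k) {
    double acc = 0.0;
    for (int m = 1; m <= k; ++m) {
      const int nmax = (N - m) / k;
      double s = 0.0;
      for (int i = 1; i <= nmax; ++i)
        s += std::abs(x[m - 1 + i * k] - x[m - 1 + (i - 1) * k]);
      acc += s * (N - 1.0) / (static_cast<double>(nmax) * k) / k;
    }
    L[k - 1] = acc / k;
  }
  return L;
}
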