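#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Rolling window primitives along the m/z axis (rows); columns are pixel
// spectra and are processed independently.  Windows shrink at the edges.

// [[Rcpp::export(name = ".cpp_roll_extreme")]]
NumericMatrix cpp_roll_extreme(NumericMatrix x, int w, bool maximum) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  if (w < 1) { std::copy(x.begin(), x.end(), out.begin()); return out; }
  // monotonic index deque per column: O(n) per column
  std::vector<int> dq(n);
  for (int j = 0; j < p; ++j) {
    const double *col = &x(0, j);
    double *o = &out(0, j);
    int head = 0, tail = 0;  // dq[head..tail) holds candidate indices
    for (int i = 0; i < n + w; ++i) {
      if (i < n) {
        const double v = col[i];
        while (tail > head &&
               (maximum ? col[dq[tail - 1]] <= v : col[dq[tail - 1]] >= v))
          --tail;
        dq[tail++] = i;
      }
      const int center = i - w;  // window [center - w, center + w]
      if (center >= 0) {
        while (dq[head] < center - w) ++head;
        o[center] = col[dq[head]];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_roll_mean")]]
NumericMatrix cpp_roll_mean(NumericMatrix x, int w) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  if (w < 1) { std::copy(x.begin(), x.end(), out.begin()); return out; }
  std::vector<double> cs(n + 1);
  for (int j = 0; j < p; ++j) {
    const double *col = &x(0, j);
    double *o = &out(0, j);
    cs[0] = 0.0;
    for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + col[i];
    for (int i = 0; i < n; ++i) {
      const int lo = std::max(0, i - w);
      const int hi = std::min(n - 1, i + w);
      o[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
    }
  }
  return out;
}

// full baseline correction in one pass per column: morphological opening
// (running min then max over +/- w), running-mean smoothing, optional
// clip-and-resmooth refinements, subtraction, clipping at zero
// [[Rcpp::export(name = ".cpp_baseline_correct")]]
NumericMatrix cpp_baseline_correct(NumericMatrix x, int w, int iterations) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  std::vector<int> dq(n);
  std::vector<double> buf1(n), buf2(n), cs(n + 1);

  auto roll_extreme = [&](const double *in, double *o, bool maximum) {
    int head = 0, tail = 0;
    for (int i = 0; i < n + w; ++i) {
      if (i < n) {
        const double v = in[i];
        while (tail > head &&
               (maximum ? in[dq[tail - 1]] <= v : in[dq[tail - 1]] >= v))
          --tail;
        dq[tail++] = i;
      }
      const int center = i - w;
      if (center >= 0) {
        while (dq[head] < center - w) ++head;
        o[center] = in[dq[head]];
      }
    }
  };
  auto roll_mean = [&](const double *in, double *o) {
    cs[0] = 0.0;
    for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + in[i];
    for (int i = 0; i < n; ++i) {
      const int lo = std::max(0, i - w);
      const int hi = std::min(n - 1, i + w);
      o[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
    }
  };

  for (int j = 0; j < p; ++j) {
    const double *col = &x(0, j);
    double *o = &out(0, j);
    roll_extreme(col, buf1.data(), false);          // erosion
    roll_extreme(buf1.data(), buf2.data(), true);   // dilation
    roll_mean(buf2.data(), buf1.data());            // smoothed estimate
    for (int it = 1; it < iterations; ++it) {
      for (int i = 0; i < n; ++i) buf2[i] = std::min(buf1[i], col[i]);
      roll_mean(buf2.data(), buf1.data());
    }
    for (int i = 0; i < n; ++i) o[i] = std::max(col[i] - buf1[i], 0.0);
  }
  return out;
}

// convolution with a normalized kernel, reflected edges
// [[Rcpp::export(name = ".cpp_convolve")]]
NumericMatrix cpp_convolve(NumericMatrix x, NumericVector kernel) {
  const int n = x.nrow(), p = x.ncol(), m = kernel.size();
  const int half = m / 2;
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double *col = &x(0, j);
    double *o = &out(0, j);
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < m; ++k) {
        int idx = i + k - half;
        if (idx < 0) idx = -idx;                 // reflect
        if (idx >= n) idx = 2 * (n - 1) - idx;
        acc += col[idx] * kernel[k];
      }
      o[i] = acc;
    }
  }
  return out;
}
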