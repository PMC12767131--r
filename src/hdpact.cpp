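// Compute kernels: im2col convolution (+ gradients), selective state-space
// scan (+ gradients), band-limited wavelet scatter for the array simulator,
// and the delay-and-sum inner loop. All single-threaded and deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Column layout used by conv kernels: feature index f = c*kh*kw + kj*kh + ki
// (ki fastest), matching weight matrices of shape (kh*kw*Cin) x Cout.
// Valid output-index range [i0, i1) such that i*stride + k - pad lies in
// [0, n): hoists the bounds check out of the inner copy loops.
static inline void valid_range(int n, int stride, int k, int pad,
                               int nout, int& i0, int& i1) {
  i0 = (pad - k + stride - 1) / stride;
  if (i0 < 0) i0 = 0;
  i1 = (n - 1 - k + pad) / stride + 1;
  if (i1 > nout) i1 = nout;
  if (i1 < i0) i1 = i0;
}

static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(Ho * (long)Wo, (long)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.memptr() + (long)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      int j0, j1;
      valid_range(W, stride, kj, pad, Wo, j0, j1);
      for (int ki = 0; ki < kh; ++ki) {
        const int f = c * kh * kw + kj * kh + ki;
        double* cf = col.colptr(f);
        int i0, i1;
        valid_range(H, stride, ki, pad, Ho, i0, i1);
        for (int j = j0; j < j1; ++j) {
          const int xj = j * stride + kj - pad;
          const double* src = xc + (long)H * xj;
          double* dst = cf + (long)Ho * j;
          if (stride == 1) {
            std::memcpy(dst + i0, src + i0 + ki - pad,
                        (i1 - i0) * sizeof(double));
          } else {
            for (int i = i0; i < i1; ++i)
              dst[i] = src[i * stride + ki - pad];
          }
        }
      }
    }
  }
  return col;
}

static void col2im_acc(arma::cube& dx, const arma::mat& dcol, int kh, int kw,
                       int stride, int pad, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    double* xc = dx.memptr() + (long)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      int j0, j1;
      valid_range(W, stride, kj, pad, Wo, j0, j1);
      for (int ki = 0; ki < kh; ++ki) {
        const int f = c * kh * kw + kj * kh + ki;
        const double* cf = dcol.colptr(f);
        int i0, i1;
        valid_range(H, stride, ki, pad, Ho, i0, i1);
        for (int j = j0; j < j1; ++j) {
          const int xj = j * stride + kj - pad;
          double* dst = xc + (long)H * xj + (ki - pad);
          const double* src = cf + (long)Ho * j;
          if (stride == 1) {
            for (int i = i0; i < i1; ++i) dst[i] += src[i];
          } else {
            for (int i = i0; i < i1; ++i) dst[i * stride] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int kh, int kw,
                      int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout = w.n_cols;
  arma::mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat out = col * w;
  out.each_row() += b.t();
  arma::cube y(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = arma::reshape(out.col(c), Ho, Wo);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                const arma::cube& dy, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  arma::mat dout(Ho * (long)Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    dout.col(c) = arma::vectorise(dy.slice(c));
  arma::mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat dw = col.t() * dout;
  arma::vec db = arma::sum(dout, 0).t();
  arma::mat dcol = dout * w.t();
  arma::cube dx(H, W, x.n_slices, arma::fill::zeros);
  col2im_acc(dx, dcol, kh, kw, stride, pad, Ho, Wo);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Selective scan with diagonal state dynamics:
//   h_t(c,n) = exp(delta(t,c) * A(c,n)) * h_{t-1}(c,n)
//              + delta(t,c) * B(t,n) * u(t,c)
//   y(t,c)   = sum_n Cc(t,n) * h_t(c,n) + D(c) * u(t,c)
// [[Rcpp::export(name = ".sscan_fwd")]]
List sscan_fwd(const arma::mat& u, const arma::mat& delta, const arma::mat& A,
               const arma::mat& B, const arma::mat& Cc, const arma::vec& D) {
  const int L = u.n_rows, C = u.n_cols, N = A.n_cols;
  arma::mat y(L, C);
  arma::cube h(C, N, L);
  arma::mat hprev(C, N, arma::fill::zeros);
  for (int t = 0; t < L; ++t) {
    for (int c = 0; c < C; ++c) {
      const double dt = delta(t, c), ut = u(t, c);
      double acc = 0.0;
      for (int n = 0; n < N; ++n) {
        const double ht = std::exp(dt * A(c, n)) * hprev(c, n)
                          + dt * B(t, n) * ut;
        h(c, n, t) = ht;
        acc += Cc(t, n) * ht;
      }
      y(t, c) = acc + D(c) * ut;
    }
    hprev = h.slice(t);
  }
  return List::create(_["y"] = y, _["h"] = h);
}

// [[Rcpp::export(name = ".sscan_bwd")]]
List sscan_bwd(const arma::mat& u, const arma::mat& delta, const arma::mat& A,
               const arma::mat& B, const arma::mat& Cc, const arma::vec& D,
               const arma::cube& h, const arma::mat& dy) {
  const int L = u.n_rows, C = u.n_cols, N = A.n_cols;
  arma::mat du(L, C, arma::fill::zeros), ddelta(L, C, arma::fill::zeros);
  arma::mat dA(C, N, arma::fill::zeros), dB(L, N, arma::fill::zeros);
  arma::mat dC(L, N, arma::fill::zeros);
  arma::vec dD(C, arma::fill::zeros);
  arma::mat dh(C, N, arma::fill::zeros);   // gradient w.r.t. h_t
  for (int t = L - 1; t >= 0; --t) {
    for (int c = 0; c < C; ++c) {
      const double dyt = dy(t, c), dt = delta(t, c), ut = u(t, c);
      dD(c) += dyt * ut;
      double du_acc = D(c) * dyt, ddel_acc = 0.0;
      for (int n = 0; n < N; ++n) {
        const double ht = h(c, n, t);
        double g = dh(c, n) + Cc(t, n) * dyt;     // total dL/dh_t(c,n)
        dC(t, n) += dyt * ht;
        const double hp = (t > 0) ? h(c, n, t - 1) : 0.0;
        const double ab = std::exp(dt * A(c, n));
        // input branch
        dB(t, n) += g * dt * ut;
        du_acc   += g * dt * B(t, n);
        ddel_acc += g * B(t, n) * ut;
        // decay branch
        const double dab = g * hp;
        ddel_acc += dab * A(c, n) * ab;
        dA(c, n) += dab * dt * ab;
        dh(c, n) = g * ab;                        // pass to h_{t-1}
      }
      du(t, c) += du_acc;
      ddelta(t, c) += ddel_acc;
    }
  }
  return List::create(_["du"] = du, _["ddelta"] = ddelta, _["dA"] = dA,
                      _["dB"] = dB, _["dC"] = dC, _["dD"] = dD);
}

// Superpose Gaussian-modulated sinusoid wavelets, one per (element, source)
// pair, delayed by time-of-flight and scaled by 1/distance.
// Units: positions mm, speed mm/us, fs/f0 MHz, t0 us.
// [[Rcpp::export(name = ".rf_scatter")]]
arma::mat rf_scatter(const arma::mat& elem_pos, const arma::mat& src_pos,
                     const arma::vec& src_amp, double fs, double f0,
                     double frac_bw, double sos, double t0, int nt) {
  const int M = elem_pos.n_rows, S = src_pos.n_rows;
  arma::mat out(M, nt, arma::fill::zeros);
  const double sigma_f = (frac_bw * f0) / 2.35482004503;   // FWHM -> sd
  const double sigma_t = 1.0 / (2.0 * M_PI * sigma_f);
  const double half_w = 4.0 * sigma_t;
  const double twopif0 = 2.0 * M_PI * f0;
  for (int m = 0; m < M; ++m) {
    for (int s = 0; s < S; ++s) {
      const double dx = elem_pos(m, 0) - src_pos(s, 0);
      const double dy = elem_pos(m, 1) - src_pos(s, 1);
      const double dz = elem_pos(m, 2) - src_pos(s, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double tof = d / sos;
      const double a = src_amp(s) / std::max(d, 1e-6);
      int k0 = (int)std::ceil((tof - half_w - t0) * fs);
      int k1 = (int)std::floor((tof + half_w - t0) * fs);
      if (k0 < 0) k0 = 0;
      if (k1 > nt - 1) k1 = nt - 1;
      for (int k = k0; k <= k1; ++k) {
        const double dtc = t0 + k / fs - tof;
        out(m, k) += a * std::exp(-dtc * dtc / (2.0 * sigma_t * sigma_t))
                       * std::sin(twopif0 * dtc);
      }
    }
  }
  return out;
}

// Delay-and-sum: voxel value = sum over channels of the linearly
// interpolated sample at the one-way time of flight.
// [[Rcpp::export(name = ".das_core")]]
List das_core(const arma::mat& samples, const arma::mat& elem_pos,
              const arma::mat& vox_pos, double sos, double fs, double t0) {
  const int M = samples.n_rows, nt = samples.n_cols, V = vox_pos.n_rows;
  arma::vec out(V, arma::fill::zeros);
  long n_outside = 0;
  for (int m = 0; m < M; ++m) {
    const double ex = elem_pos(m, 0), ey = elem_pos(m, 1), ez = elem_pos(m, 2);
    for (int v = 0; v < V; ++v) {
      const double dx = ex - vox_pos(v, 0);
      const double dy = ey - vox_pos(v, 1);
      const double dz = ez - vox_pos(v, 2);
      const double tau = std::sqrt(dx * dx + dy * dy + dz * dz) / sos;
      const double fk = (tau - t0) * fs;
      const int k = (int)std::floor(fk);
      if (k < 0 || k >= nt - 1) { ++n_outside; continue; }
      const double w = fk - k;
      out(v) += (1.0 - w) * samples(m, k) + w * samples(m, k + 1);
    }
  }
  return List::create(_["values"] = out, _["n_outside"] = (double)n_outside);
}
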