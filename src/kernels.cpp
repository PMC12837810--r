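// Numerical kernels for the network and losses. Feature maps are arma::cube
// (H, W, C); all layouts match R's column-major array convention so cubes can
// be passed to/from R without copies beyond what Rcpp requires.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- conv2d ---

static inline int conv_out(int H, int k, int pad, int stride, int dil) {
  return (H + 2 * pad - ((k - 1) * dil + 1)) / stride + 1;
}

// im2col: col is (k*k*Cin) x (outH*outW); q = ki + k*kj + k*k*ci,
// n = oy + outH*ox. Replicate padding (clamped indices), so constant inputs
// stay constant through every convolution.
static inline int clampi(int v, int hi) {
  return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
}

static arma::mat im2col(const arma::cube& x, int k, int pad, int stride,
                        int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oH = conv_out(H, k, pad, stride, dil);
  const int oW = conv_out(W, k, pad, stride, dil);
  arma::mat col(k * k * C, oH * oW);
  for (int ci = 0; ci < C; ++ci)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * ci;
        for (int ox = 0; ox < oW; ++ox) {
          const int c0 = clampi(ox * stride - pad + kj * dil, W);
          for (int oy = 0; oy < oH; ++oy) {
            const int r0 = clampi(oy * stride - pad + ki * dil, H);
            col(q, oy + oH * ox) = x(r0, c0, ci);
          }
        }
      }
  return col;
}

// [[Rcpp::export(name = "cpp_conv2d_fw")]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int k, int pad, int stride,
                         int dil) {
  const int oH = conv_out(x.n_rows, k, pad, stride, dil);
  const int oW = conv_out(x.n_cols, k, pad, stride, dil);
  const int Cout = w.n_cols;
  arma::mat col = im2col(x, k, pad, stride, dil);
  arma::mat y = w.t() * col;           // Cout x N
  y.each_col() += b;
  arma::cube out(oH, oW, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(y.row(co).t(), oH, oW);
  return out;
}

// [[Rcpp::export(name = "cpp_conv2d_bw")]]
List cpp_conv2d_bw(const arma::cube& x, const arma::mat& w,
                   const arma::cube& dy, int k, int pad, int stride, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oH = dy.n_rows, oW = dy.n_cols, Cout = dy.n_slices;
  arma::mat dyM(Cout, oH * oW);
  for (int co = 0; co < Cout; ++co)
    dyM.row(co) = arma::vectorise(dy.slice(co)).t();
  arma::mat col = im2col(x, k, pad, stride, dil);
  arma::mat dw = col * dyM.t();
  arma::vec db = arma::sum(dyM, 1);
  arma::mat dcol = w * dyM;            // (k*k*C) x N
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * ci;
        for (int ox = 0; ox < oW; ++ox) {
          const int c0 = clampi(ox * stride - pad + kj * dil, W);
          for (int oy = 0; oy < oH; ++oy) {
            const int r0 = clampi(oy * stride - pad + ki * dil, H);
            dx(r0, c0, ci) += dcol(q, oy + oH * ox);
          }
        }
      }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ------------------------------------------------- depthwise 3x3, stride 1 --

// [[Rcpp::export(name = "cpp_dwconv_fw")]]
arma::cube cpp_dwconv_fw(const arma::cube& x, const arma::cube& w,
                         const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const double wv = w(ki, kj, ci);
        if (wv == 0.0) continue;
        for (int c0 = 0; c0 < W; ++c0) {
          const int cs = clampi(c0 + kj - 1, W);
          for (int r0 = 0; r0 < H; ++r0) {
            const int rs = clampi(r0 + ki - 1, H);
            y(r0, c0, ci) += wv * x(rs, cs, ci);
          }
        }
      }
    y.slice(ci) += b(ci);
  }
  return y;
}

// [[Rcpp::export(name = "cpp_dwconv_bw")]]
List cpp_dwconv_bw(const arma::cube& x, const arma::cube& w,
                   const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  arma::cube dw(3, 3, C, arma::fill::zeros);
  arma::vec db(C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    db(ci) = arma::accu(dy.slice(ci));
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        double acc = 0.0;
        const double wv = w(ki, kj, ci);
        for (int c0 = 0; c0 < W; ++c0) {
          const int cs = clampi(c0 + kj - 1, W);
          for (int r0 = 0; r0 < H; ++r0) {
            const int rs = clampi(r0 + ki - 1, H);
            const double g = dy(r0, c0, ci);
            acc += g * x(rs, cs, ci);
            dx(rs, cs, ci) += g * wv;
          }
        }
        dw(ki, kj, ci) = acc;
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ------------------------------------------- min/max pool, stride 1, s odd --
// Replicate padding: window coordinates are clamped to the image, which is
// exactly the flat-structuring-element erosion/dilation with border replication
// used by the slim-region top-hat.

// [[Rcpp::export(name = "cpp_pool_fw")]]
List cpp_pool_fw(const arma::cube& x, int s, bool want_max) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int r = (s - 1) / 2;
  arma::cube y(H, W, C);
  IntegerVector idx(H * W * C);   // 0-based linear index of chosen source px
  for (int ci = 0; ci < C; ++ci)
    for (int c0 = 0; c0 < W; ++c0)
      for (int r0 = 0; r0 < H; ++r0) {
        double best = want_max ? -INFINITY : INFINITY;
        int bi = 0;
        for (int dj = -r; dj <= r; ++dj) {
          int cs = c0 + dj; cs = cs < 0 ? 0 : (cs >= W ? W - 1 : cs);
          for (int di = -r; di <= r; ++di) {
            int rs = r0 + di; rs = rs < 0 ? 0 : (rs >= H ? H - 1 : rs);
            const double v = x(rs, cs, ci);
            if (want_max ? (v > best) : (v < best)) {
              best = v; bi = rs + H * cs + H * W * ci;
            }
          }
        }
        y(r0, c0, ci) = best;
        idx[r0 + H * c0 + H * W * ci] = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_pool_bw")]]
arma::cube cpp_pool_bw(const IntegerVector& idx, const arma::cube& dy) {
  arma::cube dx(dy.n_rows, dy.n_cols, dy.n_slices, arma::fill::zeros);
  const int n = idx.size();
  for (int i = 0; i < n; ++i) dx(idx[i]) += dy(i);
  return dx;
}

// -------------------------------------------------- nearest 2x upsampling --

// [[Rcpp::export(name = "cpp_upnn_fw")]]
arma::cube cpp_upnn_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c0 = 0; c0 < W; ++c0)
      for (int r0 = 0; r0 < H; ++r0) {
        const double v = x(r0, c0, ci);
        y(2 * r0, 2 * c0, ci) = v;
        y(2 * r0 + 1, 2 * c0, ci) = v;
        y(2 * r0, 2 * c0 + 1, ci) = v;
        y(2 * r0 + 1, 2 * c0 + 1, ci) = v;
      }
  return y;
}

// [[Rcpp::export(name = "cpp_upnn_bw")]]
arma::cube cpp_upnn_bw(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c0 = 0; c0 < W; ++c0)
      for (int r0 = 0; r0 < H; ++r0)
        dx(r0, c0, ci) = dy(2 * r0, 2 * c0, ci) + dy(2 * r0 + 1, 2 * c0, ci) +
                         dy(2 * r0, 2 * c0 + 1, ci) +
                         dy(2 * r0 + 1, 2 * c0 + 1, ci);
  return dx;
}

// ------------------------------------------------------------- SQ-Shift ---
// Channel quarters shifted one pixel up / down / left / right, zero filled.
// dir = +1 forward, -1 transpose (used for the backward pass).

// [[Rcpp::export(name = "cpp_sqshift")]]
arma::cube cpp_sqshift(const arma::cube& x, int dir) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(H, W, C, arma::fill::zeros);
  const int q = C / 4;
  for (int ci = 0; ci < C; ++ci) {
    int grp = ci / q; if (grp > 3) grp = 3;
    int dr = 0, dc = 0;
    if (grp == 0) dr = -1;            // up: y(r,c) = x(r+1,c)
    else if (grp == 1) dr = 1;        // down
    else if (grp == 2) dc = -1;       // left
    else dc = 1;                      // right
    dr *= dir; dc *= dir;
    for (int c0 = 0; c0 < W; ++c0) {
      const int cs = c0 - dc;
      if (cs < 0 || cs >= W) continue;
      for (int r0 = 0; r0 < H; ++r0) {
        const int rs = r0 - dr;
        if (rs < 0 || rs >= H) continue;
        y(r0, c0, ci) = x(rs, cs, ci);
      }
    }
  }
  return y;
}

// --------------------------------------------------------------- Bi-WKV ---
// out_t = (sum_{i != t} e^{-(|t-i|-1)/T * w + k_i} v_i + e^{u + k_t} v_t) /
//         (sum_{i != t} e^{-(|t-i|-1)/T * w + k_i}     + e^{u + k_t})
// per channel, computed by a stabilized O(T) two-pass scan.

// [[Rcpp::export(name = "cpp_biwkv_fw")]]
arma::mat cpp_biwkv_fw(const arma::mat& k, const arma::mat& v,
                       const arma::vec& w, const arma::vec& u) {
  const int T = k.n_rows, C = k.n_cols;
  arma::mat out(T, C);
  arma::vec mL(T), aL(T), bL(T), mR(T), aR(T), bR(T);
  for (int c = 0; c < C; ++c) {
    const double dlt = w(c) / (double)T;   // decay per step
    // left scan: state at t covers i < t with exponent -(t-1-i)*dlt + k_i
    double m = -INFINITY, a = 0.0, bnum = 0.0;
    for (int t = 0; t < T; ++t) {
      mL(t) = m; aL(t) = a; bL(t) = bnum;
      // absorb i = t for position t+1
      const double mNew = std::max(m - dlt, k(t, c));
      if (std::isfinite(m)) {
        const double e1 = std::exp(m - dlt - mNew);
        a = a * e1; bnum = bnum * e1;
      } else { a = 0.0; bnum = 0.0; }
      const double e2 = std::exp(k(t, c) - mNew);
      a += e2; bnum += e2 * v(t, c);
      m = mNew;
    }
    // right scan
    m = -INFINITY; a = 0.0; bnum = 0.0;
    for (int t = T - 1; t >= 0; --t) {
      mR(t) = m; aR(t) = a; bR(t) = bnum;
      const double mNew = std::max(m - dlt, k(t, c));
      if (std::isfinite(m)) {
        const double e1 = std::exp(m - dlt - mNew);
        a = a * e1; bnum = bnum * e1;
      } else { a = 0.0; bnum = 0.0; }
      const double e2 = std::exp(k(t, c) - mNew);
      a += e2; bnum += e2 * v(t, c);
      m = mNew;
    }
    for (int t = 0; t < T; ++t) {
      const double ms = u(c) + k(t, c);
      double M = ms;
      if (std::isfinite(mL(t)) && mL(t) > M) M = mL(t);
      if (std::isfinite(mR(t)) && mR(t) > M) M = mR(t);
      double num = std::exp(ms - M) * v(t, c);
      double den = std::exp(ms - M);
      if (std::isfinite(mL(t))) {
        const double e = std::exp(mL(t) - M);
        num += e * bL(t); den += e * aL(t);
      }
      if (std::isfinite(mR(t))) {
        const double e = std::exp(mR(t) - M);
        num += e * bR(t); den += e * aR(t);
      }
      out(t, c) = num / den;
    }
  }
  return out;
}

// Exact analytic backward via per-channel O(T^2) accumulation of the
// normalized weights; used only at training token counts.
// [[Rcpp::export(name = "cpp_biwkv_bw")]]
List cpp_biwkv_bw(const arma::mat& k, const arma::mat& v, const arma::vec& w,
                  const arma::vec& u, const arma::mat& out,
                  const arma::mat& dout) {
  const int T = k.n_rows, C = k.n_cols;
  arma::mat dk(T, C, arma::fill::zeros), dv(T, C, arma::fill::zeros);
  arma::vec dw(C, arma::fill::zeros), du(C, arma::fill::zeros);
  arma::vec lw(T);
  for (int c = 0; c < C; ++c) {
    const double dlt = w(c) / (double)T;
    for (int t = 0; t < T; ++t) {
      const double g = dout(t, c);
      if (g == 0.0) continue;
      double M = u(c) + k(t, c);
      for (int i = 0; i < T; ++i) {
        lw(i) = (i == t) ? (u(c) + k(t, c))
                         : (-(std::abs(t - i) - 1.0) * dlt + k(i, c));
        if (lw(i) > M) M = lw(i);
      }
      double den = 0.0;
      for (int i = 0; i < T; ++i) { lw(i) = std::exp(lw(i) - M); den += lw(i); }
      const double ot = out(t, c);
      for (int i = 0; i < T; ++i) {
        const double Wti = lw(i) / den;
        dv(i, c) += g * Wti;
        const double dlogw = g * Wti * (v(i, c) - ot);
        dk(i, c) += dlogw;
        if (i == t) du(c) += dlogw;
        else dw(c) += dlogw * (-(std::abs(t - i) - 1.0) / (double)T);
      }
    }
  }
  return List::create(_["dk"] = dk, _["dv"] = dv, _["dw"] = dw, _["du"] = du);
}

// -------------------------------------------------- connected components --
// BFS labelling, connectivity 4 or 8; labels 1..N in scan order.

// [[Rcpp::export(name = "cpp_label_components")]]
IntegerMatrix cpp_label_components(const IntegerMatrix& m, int connectivity) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = connectivity == 8 ? 8 : 4;
  std::queue<std::pair<int, int> > q;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (m(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      lab(r0, c0) = ++next;
      q.push(std::make_pair(r0, c0));
      while (!q.empty()) {
        const int rr = q.front().first, cc = q.front().second;
        q.pop();
        for (int d = 0; d < nn; ++d) {
          const int r2 = rr + dr8[d], c2 = cc + dc8[d];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (m(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
    }
  return lab;
}

// backward of 2x2 mean pooling: spread gradient equally over each 2x2 block
// [[Rcpp::export(name = "cpp_upnn_bw_mean")]]
arma::cube cpp_upnn_bw_mean(const arma::cube& dy) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  arma::cube dx(2 * H, 2 * W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c0 = 0; c0 < W; ++c0)
      for (int r0 = 0; r0 < H; ++r0) {
        const double v = dy(r0, c0, ci) / 4.0;
        dx(2 * r0, 2 * c0, ci) = v;
        dx(2 * r0 + 1, 2 * c0, ci) = v;
        dx(2 * r0, 2 * c0 + 1, ci) = v;
        dx(2 * r0 + 1, 2 * c0 + 1, ci) = v;
      }
  return dx;
}
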