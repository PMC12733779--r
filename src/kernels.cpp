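// Low-level numeric kernels for the segmentation network.
//
// Array conventions (column-major, matching R):
//   feature maps  : arma::cube (H, W, C)       -- channels-last
//   conv weights  : R array dim (k, k, Cin/g, Cout), flattened column-major
//   token batches : arma::mat  (E, L)          -- one column per token
//
// All kernels are plain forward/backward pairs; the tape that strings them
// together lives in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat weight_as_mat(const arma::vec& w, int k, int cing, int coutg,
                                      int gidx) {
  // view of group gidx: rows = k*k*cing, cols = coutg
  const int per_out = k * k * cing;
  arma::mat wm(per_out, coutg);
  const double* src = w.memptr() + (std::size_t)gidx * coutg * per_out;
  std::copy(src, src + (std::size_t)per_out * coutg, wm.memptr());
  return wm;
}

static void im2col_group(const arma::cube& x, int g, int cing, int k, int stride,
                         int pad, int Ho, int Wo, arma::mat& col) {
  const int H = x.n_rows, W = x.n_cols;
  // col: (k*k*cing) x (Ho*Wo); row index = kh + kw*k + c*k*k
  for (int c = 0; c < cing; ++c) {
    const arma::mat& xc = x.slice(g * cing + c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + kw * k + c * k * k;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          double* dst = col.colptr(wo * Ho) + r;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[(std::size_t)ho * col.n_rows] = 0.0;
            continue;
          }
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            dst[(std::size_t)ho * col.n_rows] =
              (hi < 0 || hi >= H) ? 0.0 : xc(hi, wi);
          }
        }
      }
    }
  }
}

// fast path: 1x1 convolution, groups == 1 -> single GEMM on (L x C) view
static arma::cube pointwise_fw(const arma::cube& x, const arma::vec& w,
                               const arma::vec& b, int cout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const std::size_t L = (std::size_t)H * W;
  const arma::mat xm(const_cast<double*>(x.memptr()), L, C, false, true);
  const arma::mat wm(const_cast<double*>(w.memptr()), C, cout, false, true);
  arma::cube out(H, W, cout);
  arma::mat om(out.memptr(), L, cout, false, true);
  om = xm * wm;
  om.each_row() += b.t();
  return out;
}

// fast path: depthwise convolution (groups == C == cout), stride 1,
// computed as shifted-block accumulations
static arma::cube depthwise_fw(const arma::cube& x, const arma::vec& w,
                               const arma::vec& b, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(H, W, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    arma::mat& oc = out.slice(c);
    oc.fill(b(c));
    const double* wc = w.memptr() + (std::size_t)c * k * k;
    for (int kw = 0; kw < k; ++kw) {
      const int dw = kw - pad;
      const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
      if (w0 >= w1) continue;
      for (int kh = 0; kh < k; ++kh) {
        const int dh = kh - pad;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        if (h0 >= h1) continue;
        const double wv = wc[kh + kw * k];
        if (wv == 0.0) continue;
        oc.submat(h0, w0, h1 - 1, w1 - 1) +=
          wv * xc.submat(h0 + dh, w0 + dw, h1 - 1 + dh, w1 - 1 + dw);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::vec& w, const arma::vec& b,
                         int k, int stride, int pad, int groups, int cout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (k == 1 && groups == 1 && stride == 1)
    return pointwise_fw(x, w, b, cout);
  if (groups == C && cout == C && stride == 1 && 2 * pad == k - 1)
    return depthwise_fw(x, w, b, k, pad);
  const int cing = C / groups, coutg = cout / groups;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::cube out(Ho, Wo, cout);
  arma::mat col(k * k * cing, (std::size_t)Ho * Wo);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x, g, cing, k, stride, pad, Ho, Wo, col);
    arma::mat wm = weight_as_mat(w, k, cing, coutg, g);
    arma::mat o = wm.t() * col;  // coutg x (Ho*Wo)
    for (int co = 0; co < coutg; ++co) {
      arma::rowvec row = o.row(co);
      arma::mat m(row.memptr(), Ho, Wo);
      out.slice(g * coutg + co) = m + b(g * coutg + co);
    }
  }
  return out;
}

static List pointwise_bw(const arma::cube& x, const arma::vec& w,
                         const arma::cube& gy, int cout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const std::size_t L = (std::size_t)H * W;
  const arma::mat xm(const_cast<double*>(x.memptr()), L, C, false, true);
  const arma::mat wm(const_cast<double*>(w.memptr()), C, cout, false, true);
  const arma::mat gym(const_cast<double*>(gy.memptr()), L, cout, false, true);
  arma::cube gx(H, W, C);
  arma::mat gxm(gx.memptr(), L, C, false, true);
  gxm = gym * wm.t();
  arma::vec gw(arma::vectorise(xm.t() * gym));
  arma::vec gb(arma::sum(gym, 0).t());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

static List depthwise_bw(const arma::cube& x, const arma::vec& w,
                         const arma::cube& gy, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  arma::vec gw((std::size_t)k * k * C, arma::fill::zeros);
  arma::vec gb(C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    const arma::mat& gc = gy.slice(c);
    arma::mat& gxc = gx.slice(c);
    gb(c) = arma::accu(gc);
    double* gwc = gw.memptr() + (std::size_t)c * k * k;
    const double* wc = w.memptr() + (std::size_t)c * k * k;
    for (int kw = 0; kw < k; ++kw) {
      const int dw = kw - pad;
      const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
      if (w0 >= w1) continue;
      for (int kh = 0; kh < k; ++kh) {
        const int dh = kh - pad;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        if (h0 >= h1) continue;
        const arma::subview<double> xs =
          xc.submat(h0 + dh, w0 + dw, h1 - 1 + dh, w1 - 1 + dw);
        const arma::subview<double> gs = gc.submat(h0, w0, h1 - 1, w1 - 1);
        gwc[kh + kw * k] = arma::accu(xs % gs);
        gxc.submat(h0 + dh, w0 + dw, h1 - 1 + dh, w1 - 1 + dw) +=
          wc[kh + kw * k] * gs;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const arma::vec& w, const arma::cube& gy,
                   int k, int stride, int pad, int groups, int cout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (k == 1 && groups == 1 && stride == 1)
    return pointwise_bw(x, w, gy, cout);
  if (groups == C && cout == C && stride == 1 && 2 * pad == k - 1)
    return depthwise_bw(x, w, gy, k, pad);
  const int cing = C / groups, coutg = cout / groups;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  arma::vec gw((std::size_t)k * k * cing * cout, arma::fill::zeros);
  arma::vec gb(cout, arma::fill::zeros);
  arma::mat col(k * k * cing, (std::size_t)Ho * Wo);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x, g, cing, k, stride, pad, Ho, Wo, col);
    arma::mat gyg(coutg, (std::size_t)Ho * Wo);
    for (int co = 0; co < coutg; ++co) {
      const arma::mat& sl = gy.slice(g * coutg + co);
      gyg.row(co) = arma::rowvec(const_cast<double*>(sl.memptr()),
                                 (std::size_t)Ho * Wo, false);
      gb(g * coutg + co) = arma::accu(sl);
    }
    arma::mat gwm = col * gyg.t();  // (k*k*cing) x coutg
    std::copy(gwm.memptr(), gwm.memptr() + gwm.n_elem,
              gw.memptr() + (std::size_t)g * coutg * k * k * cing);
    arma::mat wm = weight_as_mat(w, k, cing, coutg, g);
    arma::mat gcol = wm * gyg;  // (k*k*cing) x (Ho*Wo)
    // col2im scatter
    for (int c = 0; c < cing; ++c) {
      arma::mat& gxc = gx.slice(g * cing + c);
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          const int r = kh + kw * k + c * k * k;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              gxc(hi, wi) += gcol(r, (std::size_t)wo * Ho + ho);
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 3x3 average pooling, stride 1, zero padding, fixed divisor 9 (size-preserving)
// [[Rcpp::export]]
arma::cube cpp_avgpool3_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    arma::mat& oc = out.slice(c);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double s = 0.0;
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            const int hh = h + dh, ww = w + dw;
            if (hh >= 0 && hh < H && ww >= 0 && ww < W) s += xc(hh, ww);
          }
        oc(h, w) = s / 9.0;
      }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool3_bw(const arma::cube& gy) {
  const int H = gy.n_rows, W = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& gc = gy.slice(c);
    arma::mat& xc = gx.slice(c);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double g = gc(h, w) / 9.0;
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            const int hh = h + dh, ww = w + dw;
            if (hh >= 0 && hh < H && ww >= 0 && ww < W) xc(hh, ww) += g;
          }
      }
  }
  return gx;
}

struct BilinWeights {
  std::vector<int> i0, i1;
  std::vector<double> w0, w1;
};

static BilinWeights bilin_axis(int nin, int nout) {
  BilinWeights bw;
  bw.i0.resize(nout); bw.i1.resize(nout); bw.w0.resize(nout); bw.w1.resize(nout);
  const double scale = (double)nin / nout;
  for (int o = 0; o < nout; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > nin - 1) s = nin - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, nin - 1);
    double w1 = s - i0;
    bw.i0[o] = i0; bw.i1[o] = i1; bw.w0[o] = 1.0 - w1; bw.w1[o] = w1;
  }
  return bw;
}

// [[Rcpp::export]]
arma::cube cpp_bilinear_fw(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  BilinWeights bh = bilin_axis(H, Ho), bwt = bilin_axis(W, Wo);
  arma::cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    arma::mat& oc = out.slice(c);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        oc(ho, wo) = bh.w0[ho] * (bwt.w0[wo] * xc(bh.i0[ho], bwt.i0[wo]) +
                                  bwt.w1[wo] * xc(bh.i0[ho], bwt.i1[wo])) +
                     bh.w1[ho] * (bwt.w0[wo] * xc(bh.i1[ho], bwt.i0[wo]) +
                                  bwt.w1[wo] * xc(bh.i1[ho], bwt.i1[wo]));
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_bilinear_bw(const arma::cube& gy, int Hi, int Wi) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  BilinWeights bh = bilin_axis(Hi, Ho), bwt = bilin_axis(Wi, Wo);
  arma::cube gx(Hi, Wi, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& gc = gy.slice(c);
    arma::mat& xc = gx.slice(c);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = gc(ho, wo);
        xc(bh.i0[ho], bwt.i0[wo]) += g * bh.w0[ho] * bwt.w0[wo];
        xc(bh.i0[ho], bwt.i1[wo]) += g * bh.w0[ho] * bwt.w1[wo];
        xc(bh.i1[ho], bwt.i0[wo]) += g * bh.w1[ho] * bwt.w0[wo];
        xc(bh.i1[ho], bwt.i1[wo]) += g * bh.w1[ho] * bwt.w1[wo];
      }
  }
  return gx;
}

// Selective scan (S6) with exact zero-order-hold discretization:
//   h_t = exp(delta_t A) (*) h_{t-1} + ((exp(delta_t A) - 1) / A) B_t x_t
//   y_t = h_t . C_t + D (*) x_t
// x, delta: (E x L); A: (E x d, A < 0); B, Cm: (d x L); D: (E)
// [[Rcpp::export]]
List cpp_selscan_fw(const arma::mat& x, const arma::mat& delta, const arma::mat& A,
                    const arma::mat& B, const arma::mat& Cm, const arma::vec& D,
                    bool keep_h) {
  const int E = x.n_rows, L = x.n_cols, d = A.n_cols;
  arma::mat y(E, L);
  arma::mat h(E, d, arma::fill::zeros);
  arma::cube hs;
  if (keep_h) hs.set_size(E, d, L);
  double* hp = h.memptr();
  const double* Ap = A.memptr();
  for (int t = 0; t < L; ++t) {
    const double* xt = x.colptr(t);
    const double* dt = delta.colptr(t);
    const double* Bt = B.colptr(t);
    const double* Ct = Cm.colptr(t);
    double* yt = y.colptr(t);
    for (int e = 0; e < E; ++e) yt[e] = D(e) * xt[e];
    for (int j = 0; j < d; ++j) {
      const double bj = Bt[j], cj = Ct[j];
      double* hj = hp + (std::size_t)j * E;
      const double* aj = Ap + (std::size_t)j * E;
      for (int e = 0; e < E; ++e) {
        const double z = dt[e] * aj[e];
        // flush to an exact zero well before the subnormal range
        const double edA = (z < -60.0) ? 0.0 : std::exp(z);
        hj[e] = edA * hj[e] + ((edA - 1.0) / aj[e]) * xt[e] * bj;
        yt[e] += hj[e] * cj;
      }
    }
    if (keep_h) std::copy(hp, hp + (std::size_t)E * d, hs.slice_memptr(t));
  }
  if (keep_h) return List::create(_["y"] = y, _["h"] = hs);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List cpp_selscan_bw(const arma::mat& x, const arma::mat& delta, const arma::mat& A,
                    const arma::mat& B, const arma::mat& Cm, const arma::vec& D,
                    const arma::cube& hs, const arma::mat& gy) {
  const int E = x.n_rows, L = x.n_cols, d = A.n_cols;
  arma::mat gx(E, L, arma::fill::zeros), gdelta(E, L, arma::fill::zeros);
  arma::mat gA(E, d, arma::fill::zeros), gB(d, L, arma::fill::zeros),
            gC(d, L, arma::fill::zeros);
  arma::vec gD(E, arma::fill::zeros);
  arma::mat dh(E, d, arma::fill::zeros);
  double* dhp = dh.memptr();
  const double* Ap = A.memptr();
  double* gAp = gA.memptr();
  for (int t = L - 1; t >= 0; --t) {
    const double* ht = hs.slice_memptr(t);
    const double* hprev = (t > 0) ? hs.slice_memptr(t - 1) : nullptr;
    const double* xt = x.colptr(t);
    const double* dt = delta.colptr(t);
    const double* Bt = B.colptr(t);
    const double* Ct = Cm.colptr(t);
    const double* gyt = gy.colptr(t);
    double* gxt = gx.colptr(t);
    double* gdt = gdelta.colptr(t);
    double* gBt = gB.colptr(t);
    double* gCt = gC.colptr(t);
    for (int e = 0; e < E; ++e) {
      gD(e) += gyt[e] * xt[e];
      gxt[e] += gyt[e] * D(e);
    }
    for (int j = 0; j < d; ++j) {
      double* dhj = dhp + (std::size_t)j * E;
      const double* hj = ht + (std::size_t)j * E;
      const double* aj = Ap + (std::size_t)j * E;
      double* gaj = gAp + (std::size_t)j * E;
      const double cj = Ct[j], bj = Bt[j];
      double gcj = 0.0, gbj = 0.0;
      for (int e = 0; e < E; ++e) {
        // y_t = sum_j h_t C_t + D x_t
        gcj += hj[e] * gyt[e];
        const double dhe = dhj[e] + gyt[e] * cj;
        // h_t = edA h_{t-1} + u B x, edA = exp(dt a), u = (edA - 1) / a
        const double a = aj[e];
        const double z = dt[e] * a;
        const double edA = (z < -60.0) ? 0.0 : std::exp(z);
        const double u = (edA - 1.0) / a;
        const double du_da = (dt[e] * a * edA - (edA - 1.0)) / (a * a);
        const double hp_ = (t > 0) ? hprev[(std::size_t)j * E + e] : 0.0;
        gbj += dhe * u * xt[e];
        gxt[e] += dhe * u * bj;
        gdt[e] += dhe * (a * edA * hp_ + edA * xt[e] * bj);
        gaj[e] += dhe * (dt[e] * edA * hp_ + xt[e] * bj * du_da);
        dhj[e] = (t > 0) ? dhe * edA : 0.0;
      }
      gCt[j] = gcj;
      gBt[j] = gbj;
    }
  }
  return List::create(_["gx"] = gx, _["gdelta"] = gdelta, _["gA"] = gA,
                      _["gB"] = gB, _["gC"] = gC, _["gD"] = gD);
}

// Directed nearest-neighbour distances between two 2-D point sets
// (rows of a and b are (row, col) coordinates). Returns, for each point of a,
// the Euclidean distance to the closest point of b.
// [[Rcpp::export]]
arma::vec cpp_directed_dists(const arma::mat& a, const arma::mat& b) {
  const int na = a.n_rows, nb = b.n_rows;
  arma::vec out(na);
  for (int i = 0; i < na; ++i) {
    double best = std::numeric_limits<double>::infinity();
    const double ar = a(i, 0), ac = a(i, 1);
    for (int j = 0; j < nb; ++j) {
      const double dr = ar - b(j, 0), dc = ac - b(j, 1);
      const double dd = dr * dr + dc * dc;
      if (dd < best) best = dd;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
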