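// Minimal dense conv-net kernels used by the U-Net variants, the multi-scale
// head and the saliency backward pass.
//
// Memory layout (shared with the R side):
//   * feature map  : R array dim (H, W, C), column-major => arma::mat (H*W) x C,
//                    pixel (i, j) zero-based sits in row i + j*H.
//   * conv weight  : R array dim (k, k, Cin, Cout) => arma::mat (k*k*Cin) x Cout,
//                    entry (di, dj, c) sits in row di + k*dj + k*k*c.
//   * tconv weight : R array dim (2, 2, Cin, Cout) => arma::mat Cin x (4*Cout),
//                    column (di, dj, co) = di + 2*dj + 4*co.
// All convolutions are stride 1 with "same" zero padding and odd kernels;
// pooling and transposed convolution use fixed 2x2 / stride 2 geometry.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::mat& x, int H, int W, int Cin, int k) {
  const int p = (k - 1) / 2;
  arma::mat cols(H * W, k * k * Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di);
          const int i1 = std::min(H, H + p - di);
          if (i0 >= i1) continue;
          // rows i0..i1-1 of output column j pull input rows (i+di-p, sj)
          cols.submat(i0 + j * H, q, i1 - 1 + j * H, q) =
            x.submat(i0 + di - p + sj * H, c, i1 - 1 + di - p + sj * H, c);
        }
      }
    }
  }
  return cols;
}

static arma::mat col2im(const arma::mat& gcols, int H, int W, int Cin, int k) {
  const int p = (k - 1) / 2;
  arma::mat gx(H * W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di);
          const int i1 = std::min(H, H + p - di);
          if (i0 >= i1) continue;
          gx.submat(i0 + di - p + sj * H, c, i1 - 1 + di - p + sj * H, c) +=
            gcols.submat(i0 + j * H, q, i1 - 1 + j * H, q);
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::mat nn_conv_fw(const arma::mat& x, int H, int W, int Cin,
                     const arma::mat& Wm, const arma::rowvec& b, int k) {
  arma::mat y = im2col(x, H, W, Cin, k) * Wm;
  y.each_row() += b;
  return y;
}

// [[Rcpp::export]]
List nn_conv_bw(const arma::mat& x, const arma::mat& gy, int H, int W, int Cin,
                const arma::mat& Wm, int k) {
  arma::mat cols = im2col(x, H, W, Cin, k);
  arma::mat gW = cols.t() * gy;
  arma::rowvec gb = arma::sum(gy, 0);
  arma::mat gx = col2im(gy * Wm.t(), H, W, Cin, k);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
List nn_pool_fw(const arma::mat& x, int H, int W, int C) {
  const int H2 = H / 2, W2 = W / 2;
  arma::mat y(H2 * W2, C);
  arma::umat amax(H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        const int r00 = 2 * i + 2 * j * H;
        const int rows[4] = {r00, r00 + 1, r00 + H, r00 + H + 1};
        double best = x(rows[0], c);
        int bi = rows[0];
        for (int t = 1; t < 4; ++t) {
          if (x(rows[t], c) > best) { best = x(rows[t], c); bi = rows[t]; }
        }
        y(i + j * H2, c) = best;
        amax(i + j * H2, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["amax"] = amax);
}

// [[Rcpp::export]]
arma::mat nn_pool_bw(const arma::mat& gy, const arma::umat& amax,
                     int H, int W, int C) {
  arma::mat gx(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (arma::uword r = 0; r < gy.n_rows; ++r)
      gx(amax(r, c), c) += gy(r, c);
  return gx;
}

// transposed convolution, kernel 2x2, stride 2 (doubles H and W)
// [[Rcpp::export]]
arma::mat nn_tconv_fw(const arma::mat& x, int H, int W, int Cin,
                      const arma::mat& Wm, const arma::rowvec& b, int Cout) {
  arma::mat cols = x * Wm;  // (HW) x (4*Cout)
  const int H2 = 2 * H;
  arma::mat y(4 * H * W, Cout);
  y.each_row() = b;
  for (int co = 0; co < Cout; ++co) {
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        const int q = di + 2 * dj + 4 * co;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            y((2 * i + di) + (2 * j + dj) * H2, co) += cols(i + j * H, q);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_tconv_bw(const arma::mat& x, const arma::mat& gy, int H, int W,
                 int Cin, const arma::mat& Wm, int Cout) {
  const int H2 = 2 * H;
  arma::mat gcols(H * W, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const int q = di + 2 * dj + 4 * co;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            gcols(i + j * H, q) = gy((2 * i + di) + (2 * j + dj) * H2, co);
      }
  arma::mat gW = x.t() * gcols;
  arma::mat gx = gcols * Wm.t();
  arma::rowvec gb = arma::sum(gy, 0);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Whole-network U-Net forward/backward in one call. Activations and GEMMs run
// in single precision with im2col buffers cached between the passes; weights
// arrive as a flat list in the order produced by unet_flatten() on the R side:
//   enc i: W1 b1 W2 b2 | bottleneck: W1 b1 W2 b2 |
//   dec i (shallow..deep index, executed deep-first): Wt bt W1 b1 W2 b2 |
//   out: W b
// ---------------------------------------------------------------------------

typedef arma::fmat FM;
typedef arma::frowvec FRV;

static FM im2col_f(const FM& x, int H, int W, int Cin, int k) {
  const int p = (k - 1) / 2;
  FM cols(H * W, k * k * Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di);
          const int i1 = std::min(H, H + p - di);
          if (i0 >= i1) continue;
          cols.submat(i0 + j * H, q, i1 - 1 + j * H, q) =
            x.submat(i0 + di - p + sj * H, c, i1 - 1 + di - p + sj * H, c);
        }
      }
  return cols;
}

static FM col2im_f(const FM& gcols, int H, int W, int Cin, int k) {
  const int p = (k - 1) / 2;
  FM gx(H * W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di);
          const int i1 = std::min(H, H + p - di);
          if (i0 >= i1) continue;
          gx.submat(i0 + di - p + sj * H, c, i1 - 1 + di - p + sj * H, c) +=
            gcols.submat(i0 + j * H, q, i1 - 1 + j * H, q);
        }
      }
  return gx;
}

struct ConvCache { FM cols, z, a; };

static FM conv_relu_f(const FM& x, int H, int W, int Cin, const FM& Wm,
                      const FRV& b, int k, ConvCache& cc, bool relu = true) {
  cc.cols = im2col_f(x, H, W, Cin, k);
  cc.z = cc.cols * Wm;
  cc.z.each_row() += b;
  cc.a = relu ? arma::clamp(cc.z, 0.0f, arma::datum::inf) : cc.z;
  return cc.a;
}

// backward through conv (+ optional relu); fills gW/gb, returns gx
static FM conv_relu_bw_f(const ConvCache& cc, FM gy, const FM& Wm, int H,
                         int W, int Cin, int k, FM& gW, FRV& gb,
                         bool relu = true, bool need_gx = true) {
  if (relu) gy %= arma::conv_to<FM>::from(cc.z > 0.0f);
  gW = cc.cols.t() * gy;
  gb = arma::sum(gy, 0);
  if (!need_gx) return FM();
  return col2im_f(gy * Wm.t(), H, W, Cin, k);
}

struct PoolCache { arma::umat amax; };

static FM pool_f(const FM& x, int H, int W, int C, PoolCache& pc) {
  const int H2 = H / 2, W2 = W / 2;
  FM y(H2 * W2, C);
  pc.amax.set_size(H2 * W2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const int r00 = 2 * i + 2 * j * H;
        const int rows[4] = {r00, r00 + 1, r00 + H, r00 + H + 1};
        float best = x(rows[0], c); int bi = rows[0];
        for (int t = 1; t < 4; ++t)
          if (x(rows[t], c) > best) { best = x(rows[t], c); bi = rows[t]; }
        y(i + j * H2, c) = best;
        pc.amax(i + j * H2, c) = bi;
      }
  return y;
}

static FM pool_bw_f(const FM& gy, const PoolCache& pc, int H, int W, int C) {
  FM gx(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (arma::uword r = 0; r < gy.n_rows; ++r)
      gx(pc.amax(r, c), c) += gy(r, c);
  return gx;
}

static FM tconv_f(const FM& x, int H, int W, const FM& Wm, const FRV& b,
                  int Cout) {
  FM cols = x * Wm;
  const int H2 = 2 * H;
  FM y(4 * H * W, Cout);
  y.each_row() = b;
  for (int co = 0; co < Cout; ++co)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const int q = di + 2 * dj + 4 * co;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            y((2 * i + di) + (2 * j + dj) * H2, co) += cols(i + j * H, q);
      }
  return y;
}

static FM tconv_bw_f(const FM& x, const FM& gy, int H, int W, const FM& Wm,
                     int Cout, FM& gW, FRV& gb) {
  const int H2 = 2 * H;
  FM gcols(H * W, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const int q = di + 2 * dj + 4 * co;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            gcols(i + j * H, q) = gy((2 * i + di) + (2 * j + dj) * H2, co);
      }
  gW = x.t() * gcols;
  gb = arma::sum(gy, 0);
  return gcols * Wm.t();
}

static FM as_fm(SEXP s) { return arma::conv_to<FM>::from(as<arma::mat>(s)); }
static FRV as_frv(SEXP s) {
  return arma::conv_to<FRV>::from(as<arma::rowvec>(s));
}

// [[Rcpp::export]]
List unet_fw_bw(List flat, IntegerVector filters, int bottleneck,
                int input_size, const arma::mat& image,
                Nullable<NumericMatrix> y_mask, std::string loss, double beta,
                bool backward) {
  const int d = filters.size();
  const int H0 = input_size;
  int pi = 0;
  std::vector<FM> Wts; std::vector<FRV> bs;
  const int n_mats = 4 * d + 4 + 6 * d + 2;
  Wts.reserve(n_mats); bs.reserve(n_mats);
  for (int t = 0; t < (int)flat.size(); t += 2) {
    Wts.push_back(as_fm(flat[t]));
    bs.push_back(as_frv(flat[t + 1]));
  }
  FM cur = arma::conv_to<FM>::from(
    arma::reshape(as<arma::mat>(wrap(image)), H0 * H0, 1));
  std::vector<ConvCache> ec1(d), ec2(d), dc1(d), dc2(d);
  ConvCache bc1, bc2, oc;
  std::vector<PoolCache> pc(d);
  std::vector<FM> enc_in(d), skip(d), dec_in(d), up_cat(d);
  std::vector<int> hs(d);
  int h = H0;
  int ci = 1;
  pi = 0;
  for (int i = 0; i < d; ++i) {
    enc_in[i] = cur; hs[i] = h;
    FM a1 = conv_relu_f(cur, h, h, ci, Wts[pi], bs[pi], 3, ec1[i]); pi++;
    FM a2 = conv_relu_f(a1, h, h, filters[i], Wts[pi], bs[pi], 3, ec2[i]); pi++;
    skip[i] = a2;
    cur = pool_f(a2, h, h, filters[i], pc[i]);
    ci = filters[i];
    h /= 2;
  }
  FM bx = cur;
  FM b1 = conv_relu_f(cur, h, h, filters[d - 1], Wts[pi], bs[pi], 3, bc1); pi++;
  FM b2 = conv_relu_f(b1, h, h, bottleneck, Wts[pi], bs[pi], 3, bc2); pi++;
  cur = b2;
  // decoder params are stored shallow-first: index level i uses slots
  // base + 3*i .. base + 3*i + 2 (tconv, conv1, conv2)
  const int dec_base = pi;
  std::vector<int> dh(d);
  for (int i = d - 1; i >= 0; --i) {
    const int s = dec_base + 3 * i;
    dec_in[i] = cur; dh[i] = h;
    FM up = tconv_f(cur, h, h, Wts[s], bs[s], filters[i]);
    h *= 2;
    up_cat[i] = arma::join_rows(up, skip[i]);
    FM a1 = conv_relu_f(up_cat[i], h, h, 2 * filters[i], Wts[s + 1],
                        bs[s + 1], 3, dc1[i]);
    FM a2 = conv_relu_f(a1, h, h, filters[i], Wts[s + 2], bs[s + 2], 3,
                        dc2[i]);
    cur = a2;
  }
  const int out_slot = dec_base + 3 * d;
  FM logits_f = conv_relu_f(cur, H0, H0, filters[0], Wts[out_slot],
                            bs[out_slot], 1, oc, false);
  arma::mat logits = arma::conv_to<arma::mat>::from(
    arma::reshape(logits_f, H0, H0));
  if (!backward)
    return List::create(_["logits"] = logits);

  arma::mat y = as<arma::mat>(y_mask.get());
  arma::mat p = 1.0 / (1.0 + arma::exp(-logits));
  const double eps = 1e-7;
  arma::mat pc_ = arma::clamp(p, eps, 1 - eps);
  const double N = H0 * (double)H0;
  double loss_val; arma::mat dz;
  if (loss == "balanced_bce") {
    loss_val = arma::accu(-beta * y % arma::log(pc_) -
                          (1 - beta) * (1 - y) % arma::log(1 - pc_)) / N;
    dz = (-beta * y % (1 - p) + (1 - beta) * (1 - y) % p) / N;
  } else {
    const double smooth = 1.0;
    const double den = arma::accu(p) + arma::accu(y) + smooth;
    const double num = 2.0 * arma::accu(p % y) + smooth;
    loss_val = 1.0 - num / den;
    arma::mat dp = -(2.0 * y * den - num) / (den * den);
    dz = dp % p % (1 - p);
  }
  FM gcur = arma::conv_to<FM>::from(
    arma::reshape(dz, H0 * H0, 1));
  std::vector<FM> gW(n_mats); std::vector<FRV> gb(n_mats);
  gcur = conv_relu_bw_f(oc, gcur, Wts[out_slot], H0, H0, filters[0], 1,
                        gW[out_slot], gb[out_slot], false);
  h = H0;
  for (int i = 0; i < d; ++i) {
    const int s = dec_base + 3 * i;
    FM g2 = conv_relu_bw_f(dc2[i], gcur, Wts[s + 2], h, h, filters[i], 3,
                           gW[s + 2], gb[s + 2]);
    FM g1 = conv_relu_bw_f(dc1[i], g2, Wts[s + 1], h, h, 2 * filters[i], 3,
                           gW[s + 1], gb[s + 1]);
    FM gup = g1.cols(0, filters[i] - 1);
    skip[i] = g1.cols(filters[i], 2 * filters[i] - 1);  // reuse as gskip
    gcur = tconv_bw_f(dec_in[i], gup, dh[i], dh[i], Wts[s], filters[i],
                      gW[s], gb[s]);
    h = dh[i];
  }
  const int bslot = 4 * d / 2;  // = 2*d (pairs); bottleneck W1 at index 2*d
  FM g2 = conv_relu_bw_f(bc2, gcur, Wts[2 * d + 1], h, h, bottleneck, 3,
                         gW[2 * d + 1], gb[2 * d + 1]);
  gcur = conv_relu_bw_f(bc1, g2, Wts[2 * d], h, h, filters[d - 1], 3,
                        gW[2 * d], gb[2 * d]);
  for (int i = d - 1; i >= 0; --i) {
    h = hs[i];
    FM ga2 = pool_bw_f(gcur, pc[i], h, h, filters[i]) + skip[i];
    FM gz2 = conv_relu_bw_f(ec2[i], ga2, Wts[2 * i + 1], h, h, filters[i], 3,
                            gW[2 * i + 1], gb[2 * i + 1]);
    const int cin_i = (i == 0) ? 1 : filters[i - 1];
    gcur = conv_relu_bw_f(ec1[i], gz2, Wts[2 * i], h, h, cin_i, 3,
                          gW[2 * i], gb[2 * i], true, i > 0);
  }
  List grads(2 * n_mats);
  for (int t = 0; t < n_mats; ++t) {
    grads[2 * t] = wrap(arma::conv_to<arma::mat>::from(gW[t]));
    grads[2 * t + 1] = wrap(arma::conv_to<arma::rowvec>::from(gb[t]));
  }
  return List::create(_["logits"] = logits, _["loss"] = loss_val,
                      _["grads"] = grads);
}
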