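// Dense 2-D conv-net kernels on (H, W, C) column-major arrays (R layout).
// Convolution is im2col + BLAS matmul via Armadillo; pooling, bilinear
// resampling and 2x2-stride-2 transposed convolution are direct loops.
// All kernels are deterministic; gradients recompute im2col rather than
// caching it, trading a little CPU for a flat memory profile.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d (H, W, C) array");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

static NumericVector cube_to_r(const arma::cube& c) {
  NumericVector out(c.memptr(), c.memptr() + c.n_elem);
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

static void im2col(const arma::cube& x, int c0, int cin_g,
                   int k, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& cols) {
  const int H = x.n_rows, W = x.n_cols;
  for (int n = 0; n < Ho * Wo; ++n) {
    const int ho = n % Ho, wo = n / Ho;
    const int ih0 = ho * stride - pad, iw0 = wo * stride - pad;
    double* col = cols.colptr(n);
    int r = 0;
    for (int ci = 0; ci < cin_g; ++ci) {
      const arma::mat& sl = x.slice(c0 + ci);
      for (int dx = 0; dx < k; ++dx) {
        const int iw = iw0 + dx * dil;
        const bool wok = (iw >= 0 && iw < W);
        for (int dy = 0; dy < k; ++dy, ++r) {
          const int ih = ih0 + dy * dil;
          col[r] = (wok && ih >= 0 && ih < H) ? sl(ih, iw) : 0.0;
        }
      }
    }
  }
}

static void col2im_add(arma::cube& gx, int c0, int cin_g,
                       int k, int stride, int pad, int dil,
                       int Ho, int Wo, const arma::mat& gcols) {
  const int H = gx.n_rows, W = gx.n_cols;
  for (int n = 0; n < Ho * Wo; ++n) {
    const int ho = n % Ho, wo = n / Ho;
    const int ih0 = ho * stride - pad, iw0 = wo * stride - pad;
    const double* col = gcols.colptr(n);
    int r = 0;
    for (int ci = 0; ci < cin_g; ++ci) {
      arma::mat& sl = gx.slice(c0 + ci);
      for (int dx = 0; dx < k; ++dx) {
        const int iw = iw0 + dx * dil;
        const bool wok = (iw >= 0 && iw < W);
        for (int dy = 0; dy < k; ++dy, ++r) {
          const int ih = ih0 + dy * dil;
          if (wok && ih >= 0 && ih < H) sl(ih, iw) += col[r];
        }
      }
    }
  }
}

static int conv_out_dim(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - ((k - 1) * dil + 1)) / stride + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x_, NumericVector w_, NumericVector b_,
                            int stride, int pad, int dil, int groups) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");           // (k, k, Cin/groups, Cout)
  const int k = wd[0], cin_g = wd[2], cout = wd[3];
  const int cout_g = cout / groups;
  const int Ho = conv_out_dim(x.n_rows, k, stride, pad, dil);
  const int Wo = conv_out_dim(x.n_cols, k, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv output would be empty");
  if ((int)x.n_slices != cin_g * groups) stop("channel count mismatch in conv");

  arma::mat Wall(const_cast<double*>(w_.begin()), k * k * cin_g, cout, false, true);
  arma::cube y(Ho, Wo, cout);
  arma::mat cols(k * k * cin_g, Ho * Wo);
  for (int g = 0; g < groups; ++g) {
    im2col(x, g * cin_g, cin_g, k, stride, pad, dil, Ho, Wo, cols);
    arma::mat out = cols.t() * Wall.cols(g * cout_g, (g + 1) * cout_g - 1);
    std::memcpy(y.slice(g * cout_g).memptr(), out.memptr(),
                sizeof(double) * out.n_elem);
  }
  for (int co = 0; co < cout; ++co) y.slice(co) += b_[co];
  return cube_to_r(y);
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x_, NumericVector w_, NumericVector gout_,
                   int stride, int pad, int dil, int groups) {
  arma::cube x = as_cube(x_);
  arma::cube gout = as_cube(gout_);
  IntegerVector wd = w_.attr("dim");
  const int k = wd[0], cin_g = wd[2], cout = wd[3];
  const int cout_g = cout / groups;
  const int Ho = gout.n_rows, Wo = gout.n_cols;

  arma::mat Wall(const_cast<double*>(w_.begin()), k * k * cin_g, cout, false, true);
  arma::cube gx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  NumericVector gw_(w_.size());
  gw_.attr("dim") = wd;
  arma::mat GW(gw_.begin(), k * k * cin_g, cout, false, true);
  NumericVector gb_(cout);
  arma::mat cols(k * k * cin_g, Ho * Wo);

  for (int g = 0; g < groups; ++g) {
    // gout slab for this group's output channels, as (Npix, cout_g)
    arma::mat G(gout.slice_memptr(g * cout_g), Ho * Wo, cout_g, false, true);
    im2col(x, g * cin_g, cin_g, k, stride, pad, dil, Ho, Wo, cols);
    GW.cols(g * cout_g, (g + 1) * cout_g - 1) = cols * G;
    arma::mat gcols = Wall.cols(g * cout_g, (g + 1) * cout_g - 1) * G.t();
    col2im_add(gx, g * cin_g, cin_g, k, stride, pad, dil, Ho, Wo, gcols);
  }
  for (int co = 0; co < cout; ++co) gb_[co] = arma::accu(gout.slice(co));
  return List::create(_["gx"] = cube_to_r(gx), _["gw"] = gw_, _["gb"] = gb_);
}

// 2x2-kernel stride-2 transposed convolution (non-overlapping output tiles)
// [[Rcpp::export]]
NumericVector cpp_tconv2_fw(NumericVector x_, NumericVector w_, NumericVector b_) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");           // (2, 2, Cin, Cout)
  const int cin = wd[2], cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  if ((int)x.n_slices != cin) stop("channel count mismatch in transposed conv");
  arma::mat X(const_cast<double*>(x.memptr()), H * W, cin, false, true);
  arma::cube y(2 * H, 2 * W, cout);
  for (int co = 0; co < cout; ++co) y.slice(co).fill(b_[co]);
  arma::mat Wsub(cin, cout);
  for (int dx = 0; dx < 2; ++dx) {
    for (int dy = 0; dy < 2; ++dy) {
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wsub(ci, co) = w_[dy + 2 * dx + 4 * ci + 4 * cin * co];
      arma::mat out = X * Wsub;               // (H*W, cout)
      for (int co = 0; co < cout; ++co) {
        const double* o = out.colptr(co);
        arma::mat& sl = y.slice(co);
        for (int w2 = 0; w2 < W; ++w2)
          for (int h2 = 0; h2 < H; ++h2)
            sl(2 * h2 + dy, 2 * w2 + dx) += o[h2 + H * w2];
      }
    }
  }
  return cube_to_r(y);
}

// [[Rcpp::export]]
List cpp_tconv2_bw(NumericVector x_, NumericVector w_, NumericVector gout_) {
  arma::cube x = as_cube(x_);
  arma::cube gout = as_cube(gout_);
  IntegerVector wd = w_.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  arma::mat X(const_cast<double*>(x.memptr()), H * W, cin, false, true);
  arma::cube gx(H, W, cin, arma::fill::zeros);
  arma::mat GX(gx.memptr(), H * W, cin, false, true);
  NumericVector gw_(w_.size());
  gw_.attr("dim") = wd;
  NumericVector gb_(cout);
  arma::mat Gsub(H * W, cout);
  for (int dx = 0; dx < 2; ++dx) {
    for (int dy = 0; dy < 2; ++dy) {
      for (int co = 0; co < cout; ++co) {
        double* gp = Gsub.colptr(co);
        const arma::mat& sl = gout.slice(co);
        for (int w2 = 0; w2 < W; ++w2)
          for (int h2 = 0; h2 < H; ++h2)
            gp[h2 + H * w2] = sl(2 * h2 + dy, 2 * w2 + dx);
      }
      arma::mat gWsub = X.t() * Gsub;         // (cin, cout)
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          gw_[dy + 2 * dx + 4 * ci + 4 * cin * co] = gWsub(ci, co);
      // accumulate input grad: gx += Gsub * Wsub^T
      arma::mat Wsub(cin, cout);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wsub(ci, co) = w_[dy + 2 * dx + 4 * ci + 4 * cin * co];
      GX += Gsub * Wsub.t();
    }
  }
  for (int co = 0; co < cout; ++co) gb_[co] = arma::accu(gout.slice(co));
  return List::create(_["gx"] = cube_to_r(gx), _["gw"] = gw_, _["gb"] = gb_);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x_, int k, int stride, int pad) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = conv_out_dim(H, k, stride, pad, 1);
  const int Wo = conv_out_dim(W, k, stride, pad, 1);
  if (Ho <= 0 || Wo <= 0) stop("pool output would be empty");
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);              // linear index into x
  int n = 0;
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho, ++n) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = -1;
        for (int dx = 0; dx < k; ++dx) {
          const int iw = wo * stride - pad + dx;
          if (iw < 0 || iw >= W) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int ih = ho * stride - pad + dy;
            if (ih < 0 || ih >= H) continue;
            const double v = sl(ih, iw);
            if (v > best) { best = v; bi = ih + H * iw + H * W * c; }
          }
        }
        y(ho, wo, c) = best;
        idx[n] = bi;
      }
    }
  }
  return List::create(_["y"] = cube_to_r(y), _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector gout_,
                             int H, int W, int C) {
  NumericVector gx_(H * W * C);
  gx_.attr("dim") = IntegerVector::create(H, W, C);
  for (int n = 0; n < gout_.size(); ++n)
    if (idx[n] >= 0) gx_[idx[n]] += gout_[n];
  return gx_;
}

// Bilinear resampling by an integer factor, half-pixel-centre convention.
static void bilin_coef(int out_n, int in_n, int f,
                       std::vector<int>& i0, std::vector<int>& i1,
                       std::vector<double>& t) {
  i0.resize(out_n); i1.resize(out_n); t.resize(out_n);
  for (int o = 0; o < out_n; ++o) {
    double s = (o + 0.5) / f - 0.5;
    int lo = (int)std::floor(s);
    double tt = s - lo;
    int hi = lo + 1;
    if (lo < 0) { lo = 0; hi = 0; tt = 0.0; }
    if (hi >= in_n) { hi = in_n - 1; lo = in_n - 1; tt = 0.0; }
    i0[o] = lo; i1[o] = hi; t[o] = tt;
  }
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_up_fw(NumericVector x_, int f) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H * f, Wo = W * f;
  std::vector<int> r0, r1, c0, c1; std::vector<double> rt, ct;
  bilin_coef(Ho, H, f, r0, r1, rt);
  bilin_coef(Wo, W, f, c0, c1, ct);
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    arma::mat& out = y.slice(c);
    for (int wo = 0; wo < Wo; ++wo) {
      const int a = c0[wo], b = c1[wo]; const double u = ct[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double v = rt[ho];
        out(ho, wo) =
          (1 - v) * ((1 - u) * sl(r0[ho], a) + u * sl(r0[ho], b)) +
          v       * ((1 - u) * sl(r1[ho], a) + u * sl(r1[ho], b));
      }
    }
  }
  return cube_to_r(y);
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_up_bw(NumericVector gout_, int H, int W, int f) {
  arma::cube gout = as_cube(gout_);
  const int C = gout.n_slices, Ho = gout.n_rows, Wo = gout.n_cols;
  std::vector<int> r0, r1, c0, c1; std::vector<double> rt, ct;
  bilin_coef(Ho, H, f, r0, r1, rt);
  bilin_coef(Wo, W, f, c0, c1, ct);
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& g = gout.slice(c);
    arma::mat& out = gx.slice(c);
    for (int wo = 0; wo < Wo; ++wo) {
      const int a = c0[wo], b = c1[wo]; const double u = ct[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double v = rt[ho], gv = g(ho, wo);
        out(r0[ho], a) += (1 - v) * (1 - u) * gv;
        out(r0[ho], b) += (1 - v) * u * gv;
        out(r1[ho], a) += v * (1 - u) * gv;
        out(r1[ho], b) += v * u * gv;
      }
    }
  }
  return cube_to_r(gx);
}
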