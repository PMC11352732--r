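// 3x3 same-padding convolution kernels used by the U-net estimator.
// Tensor layout everywhere: column-major R arrays (H, W, C, B).
// Weights: (9*Cin) x Cout matrix; im2col column index k = kh + 3*(kw + 3*c),
// kh/kw in {0,1,2} for offsets {-1,0,+1}.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col3(const double* x, int H, int W, int C, arma::mat& col) {
  // col: (H*W) x (9*C), zero-padded borders
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (std::size_t)c * H * W;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        int k = kh + 3 * (kw + 3 * c);
        double* dst = col.colptr(k);
        int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          double* dcol = dst + (std::size_t)w * H;
          if (sw < 0 || sw >= W) {
            std::fill(dcol, dcol + H, 0.0);
          } else {
            const double* src = plane + (std::size_t)sw * H;
            for (int h = 0; h < H; ++h) {
              int sh = h + dh;
              dcol[h] = (sh >= 0 && sh < H) ? src[sh] : 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im3_add(const arma::mat& col, int H, int W, int C, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* plane = dx + (std::size_t)c * H * W;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        int k = kh + 3 * (kw + 3 * c);
        const double* src = col.colptr(k);
        int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          double* dplane = plane + (std::size_t)sw * H;
          const double* scol = src + (std::size_t)w * H;
          for (int h = 0; h < H; ++h) {
            int sh = h + dh;
            if (sh >= 0 && sh < H) dplane[sh] += scol[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv3x3_fwd")]]
NumericVector cpp_conv3x3_fwd(NumericVector x, IntegerVector dims,
                              const arma::mat& w, const arma::vec& b) {
  int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  int Cout = w.n_cols;
  if ((int)w.n_rows != 9 * C) stop("weight rows must equal 9*Cin");
  NumericVector y((std::size_t)H * W * Cout * B);
  arma::mat col(H * W, 9 * C);
  arma::rowvec br = b.t();
  for (int bi = 0; bi < B; ++bi) {
    im2col3(x.begin() + (std::size_t)bi * H * W * C, H, W, C, col);
    arma::mat yb = col * w;
    yb.each_row() += br;
    std::copy(yb.memptr(), yb.memptr() + (std::size_t)H * W * Cout,
              y.begin() + (std::size_t)bi * H * W * Cout);
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv3x3_bwd")]]
List cpp_conv3x3_bwd(NumericVector x, IntegerVector dims,
                     const arma::mat& w, NumericVector dy) {
  int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  int Cout = w.n_cols;
  NumericVector dx((std::size_t)H * W * C * B);
  arma::mat dw(9 * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(H * W, 9 * C);
  for (int bi = 0; bi < B; ++bi) {
    const double* xb = x.begin() + (std::size_t)bi * H * W * C;
    arma::mat dyb(dy.begin() + (std::size_t)bi * H * W * Cout, H * W, Cout,
                  false, true);
    im2col3(xb, H, W, C, col);
    dw += col.t() * dyb;
    db += arma::sum(dyb, 0).t();
    arma::mat dcol = dyb * w.t();
    col2im3_add(dcol, H, W, C, dx.begin() + (std::size_t)bi * H * W * C);
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}
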