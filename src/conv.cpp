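// Convolution kernels for the autodiff engine. Tensors are dense R arrays
// in column-major layout: feature maps (H, W, C, B), convolution weights
// (k, k, Cin, Cout). im2col patches for the whole batch are assembled into
// one matrix (rows grouped by batch element) so each convolution is a
// single GEMM plus a gather/scatter.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// fill rows [Ho*Wo*b, Ho*Wo*(b+1)) of P with patches of batch element b
static void im2col_fill(const double* x, int H, int W, int Ci, int b,
                        int k, int stride, int pad, int Ho, int Wo,
                        arma::mat& P) {
  const size_t row0 = (size_t)Ho * Wo * b;
  const double* xb = x + (size_t)H * W * Ci * b;
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = xb + (size_t)H * W * ci;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * ci;
        double* Pc = P.colptr(col) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int cc = wo * stride + kj - pad;
          double* Pp = Pc + (size_t)Ho * wo;
          if (cc < 0 || cc >= W) continue;
          const double* xcol = xc + (size_t)H * cc;
          for (int ho = 0; ho < Ho; ++ho) {
            const int rr = ho * stride + ki - pad;
            if (rr < 0 || rr >= H) continue;
            Pp[ho] = xcol[rr];
          }
        }
      }
    }
  }
}

static arma::mat im2col_all(const double* x, int H, int W, int Ci, int B,
                            int k, int stride, int pad, int Ho, int Wo) {
  arma::mat P((size_t)Ho * Wo * B, (size_t)k * k * Ci, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    im2col_fill(x, H, W, Ci, b, k, stride, pad, Ho, Wo, P);
  }
  return P;
}

// [[Rcpp::export]]
List cpp_conv2d_fwd(NumericVector x, NumericVector w,
                    Nullable<NumericVector> bias,
                    int stride, int pad, bool keep_p = false) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3];
  const int k = dw[0], Co = dw[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const size_t npos = (size_t)Ho * Wo;
  arma::mat Wm(w.begin(), k * k * Ci, Co, false, true);
  arma::mat P = im2col_all(x.begin(), H, W, Ci, B, k, stride, pad, Ho, Wo);
  arma::mat Y = P * Wm;                       // (npos*B) x Co, rows: (pos, b)
  if (bias.isNotNull()) Y.each_row() += as<arma::vec>(bias.get()).t();
  NumericVector y(no_init(npos * Co * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, B);
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Co; ++co) {
      const double* Yc = Y.colptr(co) + npos * b;
      double* yc = y.begin() + npos * (co + (size_t)Co * b);
      std::copy(Yc, Yc + npos, yc);
    }
  }
  if (!keep_p) return List::create(_["y"] = y, _["P"] = R_NilValue);
  NumericMatrix Pr(P.n_rows, P.n_cols);
  std::copy(P.begin(), P.end(), Pr.begin());
  return List::create(_["y"] = y, _["P"] = Pr);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool need_gx,
                    Nullable<NumericMatrix> P_saved = R_NilValue) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3];
  const int k = dw[0], Co = dw[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const size_t npos = (size_t)Ho * Wo;
  arma::mat Wm(w.begin(), k * k * Ci, Co, false, true);
  NumericMatrix Pr;                 // keeps a saved P alive if supplied
  arma::mat P_built;
  double* pmem;
  if (P_saved.isNotNull()) {
    Pr = P_saved.get();
    pmem = Pr.begin();
  } else {
    P_built = im2col_all(x.begin(), H, W, Ci, B, k, stride, pad, Ho, Wo);
    pmem = P_built.memptr();
  }
  const arma::mat P(pmem, npos * B, (size_t)k * k * Ci, false, true);
  // gather gy (Ho,Wo,Co,B) into (npos*B) x Co with rows (pos, b)
  arma::mat gY(npos * B, Co);
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Co; ++co) {
      const double* gc = gy.begin() + npos * (co + (size_t)Co * b);
      std::copy(gc, gc + npos, gY.colptr(co) + npos * b);
    }
  }
  arma::mat gW = P.t() * gY;
  arma::rowvec gb = arma::sum(gY, 0);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * Ci * B);
    gx.attr("dim") = dx;
    arma::mat gP = gY * Wm.t();
    for (int b = 0; b < B; ++b) {
      double* gxb = gx.begin() + (size_t)H * W * Ci * b;
      const size_t row0 = npos * b;
      for (int ci = 0; ci < Ci; ++ci) {
        double* gxc = gxb + (size_t)H * W * ci;
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const int col = ki + k * kj + k * k * ci;
            const double* Pc = gP.colptr(col) + row0;
            for (int wo = 0; wo < Wo; ++wo) {
              const int cc = wo * stride + kj - pad;
              if (cc < 0 || cc >= W) continue;
              double* gxcol = gxc + (size_t)H * cc;
              const double* Pp = Pc + (size_t)Ho * wo;
              for (int ho = 0; ho < Ho; ++ho) {
                const int rr = ho * stride + ki - pad;
                if (rr < 0 || rr >= H) continue;
                gxcol[rr] += Pp[ho];
              }
            }
          }
        }
      }
    }
  }
  NumericVector gWr(gW.begin(), gW.end());
  gWr.attr("dim") = dw;
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gWr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// transposed convolution, kernel 2, stride 2: y(2i+a, 2j+c) += x(i,j) w(a,c).
// realized as one GEMM X (HWB x Ci) * W(a,c) (Ci x Co) per kernel offset.
// [[Rcpp::export]]
NumericVector cpp_convt2d_fwd(NumericVector x, NumericVector w,
                              Nullable<NumericVector> bias) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3];
  const int Co = dw[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t hw = (size_t)H * W;
  // X: rows (pos, b), cols ci
  arma::mat X(hw * B, Ci);
  for (int b = 0; b < B; ++b) {
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = x.begin() + hw * (ci + (size_t)Ci * b);
      std::copy(xc, xc + hw, X.colptr(ci) + hw * b);
    }
  }
  NumericVector y((size_t)Ho * Wo * Co * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, B);
  arma::vec bv;
  const bool has_b = bias.isNotNull();
  if (has_b) bv = as<arma::vec>(bias.get());
  for (int a = 0; a < 2; ++a) {
    for (int c2 = 0; c2 < 2; ++c2) {
      arma::mat Wac(Ci, Co);
      for (int ci = 0; ci < Ci; ++ci) {
        for (int co = 0; co < Co; ++co) {
          Wac(ci, co) = w[a + 2 * c2 + 4 * (ci + (size_t)Ci * co)];
        }
      }
      arma::mat Y = X * Wac;
      for (int b = 0; b < B; ++b) {
        for (int co = 0; co < Co; ++co) {
          const double* Yc = Y.colptr(co) + hw * b;
          double* yc = y.begin() + (size_t)Ho * Wo * (co + (size_t)Co * b);
          for (int j = 0; j < W; ++j) {
            double* ycol = yc + (size_t)Ho * (2 * j + c2);
            const double* Yp = Yc + (size_t)H * j;
            for (int i = 0; i < H; ++i) ycol[2 * i + a] = Yp[i];
          }
        }
      }
    }
  }
  if (has_b) {
    for (int b = 0; b < B; ++b) {
      for (int co = 0; co < Co; ++co) {
        double* yc = y.begin() + (size_t)Ho * Wo * (co + (size_t)Co * b);
        const double bc = bv[co];
        for (size_t t = 0; t < (size_t)Ho * Wo; ++t) yc[t] += bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                     bool need_gx, bool has_bias) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3];
  const int Co = dw[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t hw = (size_t)H * W;
  arma::mat X(hw * B, Ci);
  for (int b = 0; b < B; ++b) {
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = x.begin() + hw * (ci + (size_t)Ci * b);
      std::copy(xc, xc + hw, X.colptr(ci) + hw * b);
    }
  }
  NumericVector gw((size_t)4 * Ci * Co);
  gw.attr("dim") = dw;
  NumericVector gb(Co);
  arma::mat gX(hw * B, Ci, arma::fill::zeros);
  for (int a = 0; a < 2; ++a) {
    for (int c2 = 0; c2 < 2; ++c2) {
      // gather strided slice of gy into G: rows (pos, b), cols co
      arma::mat G(hw * B, Co);
      for (int b = 0; b < B; ++b) {
        for (int co = 0; co < Co; ++co) {
          const double* gc = gy.begin() + (size_t)Ho * Wo * (co + (size_t)Co * b);
          double* Gc = G.colptr(co) + hw * b;
          for (int j = 0; j < W; ++j) {
            const double* gcol = gc + (size_t)Ho * (2 * j + c2);
            double* Gp = Gc + (size_t)H * j;
            for (int i = 0; i < H; ++i) Gp[i] = gcol[2 * i + a];
          }
        }
      }
      arma::mat gWac = X.t() * G;             // Ci x Co
      for (int ci = 0; ci < Ci; ++ci) {
        for (int co = 0; co < Co; ++co) {
          gw[a + 2 * c2 + 4 * (ci + (size_t)Ci * co)] += gWac(ci, co);
        }
      }
      if (need_gx) {
        arma::mat Wac(Ci, Co);
        for (int ci = 0; ci < Ci; ++ci) {
          for (int co = 0; co < Co; ++co) {
            Wac(ci, co) = w[a + 2 * c2 + 4 * (ci + (size_t)Ci * co)];
          }
        }
        gX += G * Wac.t();
      }
      if (has_bias) {
        arma::rowvec s = arma::sum(G, 0);
        for (int co = 0; co < Co; ++co) gb[co] += s[co];
      }
    }
  }
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * Ci * B);
    gx.attr("dim") = dx;
    for (int b = 0; b < B; ++b) {
      for (int ci = 0; ci < Ci; ++ci) {
        const double* Gc = gX.colptr(ci) + hw * b;
        double* xc = gx.begin() + hw * (ci + (size_t)Ci * b);
        std::copy(Gc, Gc + hw, xc);
      }
    }
  }
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw, _["gb"] = gb);
}
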