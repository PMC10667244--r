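// Volumetric convolution primitives used by the DCAE layers.
//
// Tensor layout (per sample, flattened column vector):
//   index = ((c*W + w)*H + h)*D + d          (depth fastest, channel slowest)
// which is exactly an R array of dim c(D, H, W, C) flattened column-major.
// A batch is a matrix (features x N). 2D images are depth-1 volumes.
//
// A convolution maps (Ci, D, H, W) -> (Co, Do, Ho, Wo) with
//   Do = (D + 2*pd - kd)/sd + 1  (floor), etc.
// The weight matrix is Co x (Ci*kd*kh*kw) with patch-row index
//   krow = ((ci*kw + wi)*kh + hi)*kd + di.
// Transposed convolutions are expressed in R through bwd_data/fwd/bwd_param
// of the mirrored geometry, so these three kernels are the whole engine.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvGeom {
  int Ci, D, H, W;
  int kd, kh, kw;
  int sd, sh, sw;
  int pd, ph, pw;
  int Do, Ho, Wo;
  int K, P;
  ConvGeom(IntegerVector inDim, IntegerVector kDim, IntegerVector stride,
           IntegerVector pad) {
    Ci = inDim[0]; D = inDim[1]; H = inDim[2]; W = inDim[3];
    kd = kDim[0]; kh = kDim[1]; kw = kDim[2];
    sd = stride[0]; sh = stride[1]; sw = stride[2];
    pd = pad[0]; ph = pad[1]; pw = pad[2];
    Do = (D + 2 * pd - kd) / sd + 1;
    Ho = (H + 2 * ph - kh) / sh + 1;
    Wo = (W + 2 * pw - kw) / sw + 1;
    K = Ci * kd * kh * kw;
    P = Do * Ho * Wo;
  }
};

// Gather patches of one sample into cols (K x P).
void im2col(const double* x, const ConvGeom& g, arma::mat& cols) {
  const int DHW = g.D * g.H * g.W;
  for (int wo = 0; wo < g.Wo; ++wo) {
    for (int ho = 0; ho < g.Ho; ++ho) {
      for (int dd = 0; dd < g.Do; ++dd) {
        const int p = (wo * g.Ho + ho) * g.Do + dd;
        double* cp = cols.colptr(p);
        for (int ci = 0; ci < g.Ci; ++ci) {
          const double* xc = x + (std::size_t)ci * DHW;
          for (int wi = 0; wi < g.kw; ++wi) {
            const int w = wo * g.sw - g.pw + wi;
            const bool wok = (w >= 0 && w < g.W);
            for (int hi = 0; hi < g.kh; ++hi) {
              const int h = ho * g.sh - g.ph + hi;
              const bool hok = (h >= 0 && h < g.H);
              const int base = ((ci * g.kw + wi) * g.kh + hi) * g.kd;
              for (int di = 0; di < g.kd; ++di) {
                const int d = dd * g.sd - g.pd + di;
                double v = 0.0;
                if (wok && hok && d >= 0 && d < g.D)
                  v = xc[(w * g.H + h) * g.D + d];
                cp[base + di] = v;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add cols (K x P) back onto one sample gradient.
void col2im(const arma::mat& cols, const ConvGeom& g, double* dx) {
  const int DHW = g.D * g.H * g.W;
  for (int wo = 0; wo < g.Wo; ++wo) {
    for (int ho = 0; ho < g.Ho; ++ho) {
      for (int dd = 0; dd < g.Do; ++dd) {
        const int p = (wo * g.Ho + ho) * g.Do + dd;
        const double* cp = cols.colptr(p);
        for (int ci = 0; ci < g.Ci; ++ci) {
          double* xc = dx + (std::size_t)ci * DHW;
          for (int wi = 0; wi < g.kw; ++wi) {
            const int w = wo * g.sw - g.pw + wi;
            if (w < 0 || w >= g.W) continue;
            for (int hi = 0; hi < g.kh; ++hi) {
              const int h = ho * g.sh - g.ph + hi;
              if (h < 0 || h >= g.H) continue;
              const int base = ((ci * g.kw + wi) * g.kh + hi) * g.kd;
              for (int di = 0; di < g.kd; ++di) {
                const int d = dd * g.sd - g.pd + di;
                if (d < 0 || d >= g.D) continue;
                xc[(w * g.H + h) * g.D + d] += cp[base + di];
              }
            }
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const arma::mat& Wm,
                       const arma::vec& b, IntegerVector inDim,
                       IntegerVector kDim, IntegerVector stride,
                       IntegerVector pad, bool useBias) {
  ConvGeom g(inDim, kDim, stride, pad);
  const int Co = Wm.n_rows;
  const int N = X.n_cols;
  arma::mat out((std::size_t)Co * g.P, N);
  arma::mat cols(g.K, g.P);
  for (int j = 0; j < N; ++j) {
    im2col(X.colptr(j), g, cols);
    arma::mat Y = Wm * cols;  // Co x P
    if (useBias) Y.each_col() += b;
    // layout wants p fastest within each output channel
    out.col(j) = arma::vectorise(Y.t());
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_conv_bwd_data(const arma::mat& G, const arma::mat& Wm,
                            IntegerVector inDim, IntegerVector kDim,
                            IntegerVector stride, IntegerVector pad) {
  ConvGeom g(inDim, kDim, stride, pad);
  const int Co = Wm.n_rows;
  const int N = G.n_cols;
  arma::mat dX((std::size_t)g.Ci * g.D * g.H * g.W, N, arma::fill::zeros);
  for (int j = 0; j < N; ++j) {
    const arma::mat gm(const_cast<double*>(G.colptr(j)), g.P, Co, false, true);
    arma::mat dcol = Wm.t() * gm.t();  // K x P
    col2im(dcol, g, dX.colptr(j));
  }
  return dX;
}

// [[Rcpp::export]]
List cpp_conv_bwd_param(const arma::mat& X, const arma::mat& G,
                        int Co, IntegerVector inDim, IntegerVector kDim,
                        IntegerVector stride, IntegerVector pad) {
  ConvGeom g(inDim, kDim, stride, pad);
  const int N = X.n_cols;
  arma::mat dW(Co, g.K, arma::fill::zeros);
  arma::vec db(Co, arma::fill::zeros);
  arma::mat cols(g.K, g.P);
  for (int j = 0; j < N; ++j) {
    im2col(X.colptr(j), g, cols);
    const arma::mat gm(const_cast<double*>(G.colptr(j)), g.P, Co, false, true);
    dW += gm.t() * cols.t();
    db += arma::sum(gm, 0).t();
  }
  return List::create(Named("dW") = dW, Named("db") = db);
}
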