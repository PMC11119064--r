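// Fused numeric kernels for the discriminator training hot path.
// No RNG here: all stochastic draws stay on the R side so seed control is
// unaffected. Layouts mirror the R implementation exactly:
//   edge maps Ec: (f1) x (n*n*B), column index c = j + i*n + b*n*n
//   ECN input Emat: rows (j + f*n), cols (i + b*n)

#include <Rcpp.h>
using namespace Rcpp;

// Ec[f, (j,i,b)] = A1t[f, i + b*n] + A2t[f, j + b*n] + b1[f]
// [[Rcpp::export(name = ".c_eceExpand")]]
NumericMatrix c_eceExpand(NumericMatrix A1t, NumericMatrix A2t,
                          NumericVector b1, int n, int B) {
  const int f1 = A1t.nrow();
  NumericMatrix out(no_init(f1, n * n * B));
  const double* a1 = A1t.begin();
  const double* a2 = A2t.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      const double* col1 = a1 + (size_t)(i + b * n) * f1;
      for (int j = 0; j < n; ++j) {
        const double* col2 = a2 + (size_t)(j + b * n) * f1;
        double* oc = o + (size_t)(j + i * n + (size_t)b * n * n) * f1;
        for (int f = 0; f < f1; ++f) oc[f] = col1[f] + col2[f] + b1[f];
      }
    }
  }
  return out;
}

// (f1, n*n*B) channel-major edge maps -> ECN input (n*f1, n*B)
// [[Rcpp::export(name = ".c_ematPack")]]
NumericMatrix c_ematPack(NumericMatrix E, int n, int B) {
  const int f1 = E.nrow();
  NumericMatrix out(no_init(n * f1, n * B));
  const double* e = E.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < n; ++i) {
      double* oc = o + (size_t)(i + b * n) * (n * f1);
      for (int j = 0; j < n; ++j) {
        const double* ec = e + (size_t)(j + i * n + (size_t)b * n * n) * f1;
        for (int f = 0; f < f1; ++f) oc[j + f * n] = ec[f];
      }
    }
  return out;
}

// inverse of c_ematPack (gradient routing)
// [[Rcpp::export(name = ".c_ematUnpack")]]
NumericMatrix c_ematUnpack(NumericMatrix dEmat, int n, int B) {
  const int f1 = dEmat.nrow() / n;
  NumericMatrix out(no_init(f1, n * n * B));
  const double* e = dEmat.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < n; ++i) {
      const double* ec = e + (size_t)(i + b * n) * (n * f1);
      for (int j = 0; j < n; ++j) {
        double* oc = o + (size_t)(j + i * n + (size_t)b * n * n) * f1;
        for (int f = 0; f < f1; ++f) oc[f] = ec[j + f * n];
      }
    }
  return out;
}

// row/column reductions of the edge-map gradient:
// dA1[i + b*n, f] = sum_j dEpre[f, (j,i,b)];
// dA2[j + b*n, f] = sum_i dEpre[f, (j,i,b)]; db1[f] = total sum
// [[Rcpp::export(name = ".c_eceReduce")]]
List c_eceReduce(NumericMatrix dEpre, int n, int B) {
  const int f1 = dEpre.nrow();
  NumericMatrix dA1(n * B, f1), dA2(n * B, f1);
  NumericVector db1(f1);
  const double* e = dEpre.begin();
  double* a1 = dA1.begin();
  double* a2 = dA2.begin();
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        const double* ec = e + (size_t)(j + i * n + (size_t)b * n * n) * f1;
        for (int f = 0; f < f1; ++f) {
          const double v = ec[f];
          a1[(size_t)f * (n * B) + i + b * n] += v;
          a2[(size_t)f * (n * B) + j + b * n] += v;
          db1[f] += v;
        }
      }
  return List::create(_["dA1"] = dA1, _["dA2"] = dA2, _["db1"] = db1);
}

// training-mode batch norm over channel-major (C x M) input
// [[Rcpp::export(name = ".c_bnFwdTrain")]]
List c_bnFwdTrain(NumericMatrix x, NumericVector gamma, NumericVector beta,
                  double eps) {
  const int C = x.nrow(), M = x.ncol();
  NumericVector mu(C), va(C), invstd(no_init(C));
  double* mup = mu.begin(); double* vap = va.begin();
  double* isp = invstd.begin();
  const double* gp = gamma.begin(); const double* bp = beta.begin();
  NumericMatrix xhat(no_init(C, M)), y(no_init(C, M));
  const double* xp = x.begin();
  for (int m = 0; m < M; ++m) {
    const double* xc = xp + (size_t)m * C;
    for (int c = 0; c < C; ++c) mup[c] += xc[c];
  }
  for (int c = 0; c < C; ++c) mup[c] /= M;
  for (int m = 0; m < M; ++m) {
    const double* xc = xp + (size_t)m * C;
    for (int c = 0; c < C; ++c) {
      const double d = xc[c] - mup[c];
      vap[c] += d * d;
    }
  }
  for (int c = 0; c < C; ++c) {
    vap[c] /= M;
    isp[c] = 1.0 / std::sqrt(vap[c] + eps);
  }
  double* xh = xhat.begin();
  double* yp = y.begin();
  for (int m = 0; m < M; ++m) {
    const double* xc = xp + (size_t)m * C;
    double* xhc = xh + (size_t)m * C;
    double* yc = yp + (size_t)m * C;
    for (int c = 0; c < C; ++c) {
      xhc[c] = (xc[c] - mup[c]) * isp[c];
      yc[c] = gp[c] * xhc[c] + bp[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mu"] = mu, _["va"] = va);
}

// batch-norm backward; dy may already include activation/dropout factors
// [[Rcpp::export(name = ".c_bnBwd")]]
List c_bnBwd(NumericMatrix dy, NumericMatrix xhat, NumericVector invstd,
             NumericVector gamma) {
  const int C = dy.nrow(), M = dy.ncol();
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C);
  NumericMatrix dx(no_init(C, M));
  const double* dyp = dy.begin();
  const double* xh = xhat.begin();
  for (int m = 0; m < M; ++m) {
    const double* dc = dyp + (size_t)m * C;
    const double* xc = xh + (size_t)m * C;
    for (int c = 0; c < C; ++c) {
      dgamma[c] += dc[c] * xc[c];
      dbeta[c] += dc[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    s1[c] = dbeta[c] * gamma[c];          // sum of dxhat
    s2[c] = dgamma[c] * gamma[c];         // sum of dxhat * xhat
  }
  double* dxp = dx.begin();
  for (int m = 0; m < M; ++m) {
    const double* dc = dyp + (size_t)m * C;
    const double* xc = xh + (size_t)m * C;
    double* dxc = dxp + (size_t)m * C;
    for (int c = 0; c < C; ++c) {
      const double dxhat = dc[c] * gamma[c];
      dxc[c] = (invstd[c] / M) * (M * dxhat - s1[c] - xc[c] * s2[c]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// one fused Adam update; returns new (param, m, v) without touching inputs
// [[Rcpp::export(name = ".c_adamUpdate")]]
List c_adamUpdate(NumericVector p, NumericVector g, NumericVector m,
                  NumericVector v, double lr, double beta1, double beta2,
                  double eps, double c1, double c2) {
  const R_xlen_t nn = p.size();
  NumericVector p2(no_init(nn)), m2(no_init(nn)), v2(no_init(nn));
  for (R_xlen_t i = 0; i < nn; ++i) {
    const double mi = beta1 * m[i] + (1 - beta1) * g[i];
    const double vi = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    m2[i] = mi;
    v2[i] = vi;
    p2[i] = p[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}

// fused LeakyReLU + inverted dropout. u: uniform draws (length 0 = no
// dropout, evaluation mode). keep = 1 - dropout rate.
// [[Rcpp::export(name = ".c_lreluDrop")]]
NumericMatrix c_lreluDrop(NumericMatrix x, NumericVector u, double keep,
                          double slope) {
  const R_xlen_t nn = x.size();
  NumericMatrix y(no_init(x.nrow(), x.ncol()));
  const double* xp = x.begin();
  double* yp = y.begin();
  if (u.size() == 0) {
    for (R_xlen_t i = 0; i < nn; ++i)
      yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  } else {
    const double* up = u.begin();
    const double inv = 1.0 / keep;
    for (R_xlen_t i = 0; i < nn; ++i) {
      const double a = xp[i] > 0 ? xp[i] : slope * xp[i];
      yp[i] = up[i] < keep ? a * inv : 0.0;
    }
  }
  return y;
}

// backward of c_lreluDrop: dy routed through the same mask and slope,
// with x the pre-activation input
// [[Rcpp::export(name = ".c_lreluDropBwd")]]
NumericMatrix c_lreluDropBwd(NumericMatrix dy, NumericMatrix x,
                             NumericVector u, double keep, double slope) {
  const R_xlen_t nn = dy.size();
  NumericMatrix dx(no_init(dy.nrow(), dy.ncol()));
  const double* dp = dy.begin();
  const double* xp = x.begin();
  double* op = dx.begin();
  if (u.size() == 0) {
    for (R_xlen_t i = 0; i < nn; ++i)
      op[i] = xp[i] > 0 ? dp[i] : slope * dp[i];
  } else {
    const double* up = u.begin();
    const double inv = 1.0 / keep;
    for (R_xlen_t i = 0; i < nn; ++i) {
      const double g = xp[i] > 0 ? inv : slope * inv;
      op[i] = up[i] < keep ? dp[i] * g : 0.0;
    }
  }
  return dx;
}
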