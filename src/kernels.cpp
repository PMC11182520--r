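// Numerical kernels for the segmentation and refinement networks.
//
// Feature maps cross the R boundary as double arma::cube with layout
// (H, W, C) — channels last, matching R's array(dim = c(H, W, C)).
// Convolutions are stride-1, "same" padding, implemented as im2col +
// BLAS gemm.  Internally the convolution pipeline runs in single
// precision: weights are O(1)-scaled and gradients are consumed by a
// stochastic optimizer, so float precision is ample, and it halves both
// memory traffic and gemm time on one CPU core.  The im2col patch
// matrix and the batch-norm intermediates are cached between forward
// and backward as external pointers, so the backward pass needs no
// recomputation and no extra copies through R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// Patch matrix P: (H*W) x (k*k*C), column (c*k*k + dj*k + di) holds the
// channel-c pixel offset by (di-p, dj-p).  Weight matrices use the same
// ordering, so Y = P * K is the convolution.  Cast to float on the fly.
static fmat im2col_f(const cube& X, const int k) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int p = k / 2;
  fmat P(static_cast<uword>(H) * W, static_cast<uword>(k) * k * C,
         fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        const int oi = di - p, oj = dj - p;
        const int r0 = std::max(0, -oi), r1 = std::min(H - 1, H - 1 - oi);
        const int c0 = std::max(0, -oj), c1 = std::min(W - 1, W - 1 - oj);
        if (r1 < r0 || c1 < c0) continue;
        float* pcol = P.colptr(col);
        for (int j = c0; j <= c1; ++j) {
          const double* src = X.slice(c).memptr() +
                              static_cast<uword>(j + oj) * H + r0 + oi;
          float* dst = pcol + static_cast<uword>(j) * H + r0;
          for (int i = r0; i <= r1; ++i) *dst++ = static_cast<float>(*src++);
        }
      }
    }
  }
  return P;
}

static cube col2im_f(const fmat& dP, const int H, const int W, const int C,
                     const int k) {
  const int p = k / 2;
  fcube dXf(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        const int oi = di - p, oj = dj - p;
        const int r0 = std::max(0, -oi), r1 = std::min(H - 1, H - 1 - oi);
        const int c0 = std::max(0, -oj), c1 = std::min(W - 1, W - 1 - oj);
        if (r1 < r0 || c1 < c0) continue;
        const float* pcol = dP.colptr(col);
        for (int j = c0; j <= c1; ++j) {
          float* dst = dXf.slice(c).memptr() +
                       static_cast<uword>(j + oj) * H + r0 + oi;
          const float* src = pcol + static_cast<uword>(j) * H + r0;
          for (int i = r0; i <= r1; ++i) *dst++ += *src++;
        }
      }
    }
  }
  cube dX(H, W, C);
  const float* src = dXf.memptr();
  double* dst = dX.memptr();
  for (uword i = 0; i < dXf.n_elem; ++i) dst[i] = src[i];
  return dX;
}

static cube fmat_to_cube(const fmat& Y, const int H, const int W) {
  cube out(H, W, Y.n_cols);
  const uword n = Y.n_elem;
  const float* src = Y.memptr();
  double* dst = out.memptr();
  for (uword i = 0; i < n; ++i) dst[i] = src[i];
  return out;
}

static XPtr<fmat> cache_ptr(fmat&& M) {
  return XPtr<fmat>(new fmat(std::move(M)), true);
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
List cpp_conv_fwd(const arma::cube& X, const arma::mat& K,
                  const arma::vec& b, const int k,
                  const bool want_cache = false) {
  fmat P = im2col_f(X, k);
  fmat Y = P * conv_to<fmat>::from(K);
  Y.each_row() += conv_to<frowvec>::from(b.t());
  List out = List::create(_["Y"] = fmat_to_cube(Y, X.n_rows, X.n_cols));
  if (want_cache) out["P"] = cache_ptr(std::move(P));
  return out;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(SEXP Pcache, const arma::mat& K, const arma::cube& dY,
                  const int k, const int Cin) {
  XPtr<fmat> P(Pcache);
  const int H = dY.n_rows, W = dY.n_cols;
  const mat dYd(const_cast<double*>(dY.memptr()),
                static_cast<uword>(H) * W, dY.n_slices, false, true);
  const fmat dYm = conv_to<fmat>::from(dYd);
  fmat dK = P->t() * dYm;
  fvec db = sum(dYm, 0).t();
  fmat dP = dYm * conv_to<fmat>::from(K).t();
  return List::create(_["dX"] = col2im_f(dP, H, W, Cin, k),
                      _["dK"] = conv_to<mat>::from(dK),
                      _["db"] = conv_to<vec>::from(db));
}

// Phi block: 3x3 conv -> spatial batch norm (statistics over H*W of the
// single slice in the batch) -> ReLU.
// [[Rcpp::export(name = ".cpp_phi_fwd")]]
List cpp_phi_fwd(const arma::cube& X, const arma::mat& K, const arma::vec& b,
                 const arma::vec& gamma, const arma::vec& beta,
                 const arma::vec& rmean, const arma::vec& rvar,
                 const double eps, const double momentum, const bool train,
                 const int k, const bool want_cache = false) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cout = K.n_cols;
  const double n = static_cast<double>(H) * W;
  fmat P = im2col_f(X, k);
  fmat Z = P * conv_to<fmat>::from(K);
  Z.each_row() += conv_to<frowvec>::from(b.t());
  vec mu(Cout), var(Cout), sinv(Cout);
  vec new_rmean = rmean, new_rvar = rvar;
  if (train) {
    for (int c = 0; c < Cout; ++c) {
      // double accumulators for the channel statistics
      double s = 0.0, s2 = 0.0;
      const float* z = Z.colptr(c);
      for (uword i = 0; i < Z.n_rows; ++i) { s += z[i]; s2 += z[i] * z[i]; }
      mu[c] = s / n;
      var[c] = std::max(0.0, s2 / n - mu[c] * mu[c]);
      new_rmean[c] = (1.0 - momentum) * rmean[c] + momentum * mu[c];
      new_rvar[c] = (1.0 - momentum) * rvar[c] + momentum * var[c];
    }
  } else {
    mu = rmean;
    var = rvar;
  }
  fmat Xhat(Z.n_rows, Cout), Y(Z.n_rows, Cout);
  for (int c = 0; c < Cout; ++c) {
    sinv[c] = 1.0 / std::sqrt(var[c] + eps);
    Xhat.col(c) = (Z.col(c) - static_cast<float>(mu[c])) *
                  static_cast<float>(sinv[c]);
    Y.col(c) = clamp(Xhat.col(c) * static_cast<float>(gamma[c]) +
                         static_cast<float>(beta[c]),
                     0.0f, std::numeric_limits<float>::max());
  }
  List out = List::create(_["Y"] = fmat_to_cube(Y, H, W),
                          _["sinv"] = sinv, _["rmean"] = new_rmean,
                          _["rvar"] = new_rvar);
  if (want_cache) {
    out["P"] = cache_ptr(std::move(P));
    out["xhat"] = cache_ptr(std::move(Xhat));
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_phi_bwd")]]
List cpp_phi_bwd(const arma::cube& dY, SEXP xhat_cache,
                 const arma::vec& sinv, const arma::vec& gamma,
                 const arma::vec& beta, SEXP Pcache, const arma::mat& K,
                 const bool train, const int k, const int Cin) {
  XPtr<fmat> P(Pcache);
  XPtr<fmat> Xh(xhat_cache);
  const int H = dY.n_rows, W = dY.n_cols;
  const int Cout = K.n_cols;
  const double n = static_cast<double>(H) * W;
  const mat dYd(const_cast<double*>(dY.memptr()),
                static_cast<uword>(H) * W, Cout, false, true);
  vec dgamma(Cout), dbeta(Cout);
  fmat dZ(static_cast<uword>(H) * W, Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* dy = dYd.colptr(c);
    const float* xh = Xh->colptr(c);
    float* dz = dZ.colptr(c);
    // the ReLU was active where gamma * xhat + beta > 0
    const float gc = static_cast<float>(gamma[c]);
    const float bc = static_cast<float>(beta[c]);
    double sdA = 0.0, sdAx = 0.0;
    for (uword i = 0; i < dZ.n_rows; ++i) {
      const double dA = (gc * xh[i] + bc) > 0.0f ? dy[i] : 0.0;
      dz[i] = static_cast<float>(dA);
      sdA += dA;
      sdAx += dA * xh[i];
    }
    dgamma[c] = sdAx;
    dbeta[c] = sdA;
    const float g = static_cast<float>(gamma[c]);
    const float si = static_cast<float>(sinv[c]);
    if (train) {
      // batch statistics participated in the normalization
      const float mdA = static_cast<float>(g * sdA / n);
      const float mdAx = static_cast<float>(g * sdAx / n);
      for (uword i = 0; i < dZ.n_rows; ++i) {
        dz[i] = si * (g * dz[i] - mdA - xh[i] * mdAx);
      }
    } else {
      for (uword i = 0; i < dZ.n_rows; ++i) dz[i] = si * g * dz[i];
    }
  }
  fmat dK = P->t() * dZ;
  fvec db = sum(dZ, 0).t();
  fmat dP = dZ * conv_to<fmat>::from(K).t();
  return List::create(_["dX"] = col2im_f(dP, H, W, Cin, k),
                      _["dK"] = conv_to<mat>::from(dK),
                      _["db"] = conv_to<vec>::from(db),
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 2x2 max pooling, stride 2.  idx codes the argmax position within each
// window as di + 2*dj (ties to the first scanned, i.e. lowest code).
// [[Rcpp::export(name = ".cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube Y(Ho, Wo, C), idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = X(2 * i, 2 * j, c);
        int code = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = X(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; code = di + 2 * dj; }
          }
        }
        Y(i, j, c) = best;
        idx(i, j, c) = code;
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
arma::cube cpp_maxpool_bwd(const arma::cube& dY, const arma::cube& idx,
                           const int H, const int W) {
  const int C = dY.n_slices, Ho = dY.n_rows, Wo = dY.n_cols;
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int code = static_cast<int>(idx(i, j, c));
        dX(2 * i + code % 2, 2 * j + code / 2, c) += dY(i, j, c);
      }
    }
  }
  return dX;
}

struct BilinearAxis {
  std::vector<int> i0, i1;
  std::vector<double> w1;  // weight on i1; weight on i0 is 1 - w1
};

// Half-pixel-centre convention: src = (dst + 0.5) * n_in / n_out - 0.5,
// clamped to the valid range, so resizing to the input size is identity.
static BilinearAxis bilinear_axis(const int n_in, const int n_out) {
  BilinearAxis ax;
  ax.i0.resize(n_out); ax.i1.resize(n_out); ax.w1.resize(n_out);
  const double scale = static_cast<double>(n_in) / n_out;
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    const int lo = static_cast<int>(std::floor(s));
    ax.i0[i] = lo;
    ax.i1[i] = std::min(lo + 1, n_in - 1);
    ax.w1[i] = s - lo;
  }
  return ax;
}

// [[Rcpp::export(name = ".cpp_resize_bl_fwd")]]
arma::cube cpp_resize_bl_fwd(const arma::cube& X, const int Ho, const int Wo) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const BilinearAxis ai = bilinear_axis(H, Ho), aj = bilinear_axis(W, Wo);
  cube Y(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      const int j0 = aj.i0[j], j1 = aj.i1[j];
      const double wj = aj.w1[j];
      for (int i = 0; i < Ho; ++i) {
        const int i0 = ai.i0[i], i1 = ai.i1[i];
        const double wi = ai.w1[i];
        Y(i, j, c) =
            (1 - wi) * (1 - wj) * X(i0, j0, c) + wi * (1 - wj) * X(i1, j0, c) +
            (1 - wi) * wj * X(i0, j1, c) + wi * wj * X(i1, j1, c);
      }
    }
  }
  return Y;
}

// Adjoint of cpp_resize_bl_fwd (scatter the interpolation weights).
// [[Rcpp::export(name = ".cpp_resize_bl_bwd")]]
arma::cube cpp_resize_bl_bwd(const arma::cube& dY, const int Hi, const int Wi) {
  const int Ho = dY.n_rows, Wo = dY.n_cols, C = dY.n_slices;
  const BilinearAxis ai = bilinear_axis(Hi, Ho), aj = bilinear_axis(Wi, Wo);
  cube dX(Hi, Wi, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      const int j0 = aj.i0[j], j1 = aj.i1[j];
      const double wj = aj.w1[j];
      for (int i = 0; i < Ho; ++i) {
        const int i0 = ai.i0[i], i1 = ai.i1[i];
        const double wi = ai.w1[i];
        const double g = dY(i, j, c);
        dX(i0, j0, c) += (1 - wi) * (1 - wj) * g;
        dX(i1, j0, c) += wi * (1 - wj) * g;
        dX(i0, j1, c) += (1 - wi) * wj * g;
        dX(i1, j1, c) += wi * wj * g;
      }
    }
  }
  return dX;
}

// Symmetric Hausdorff distance between two boundary-voxel coordinate sets
// (rows are voxel indices), scaled per-axis by `spacing`.
// [[Rcpp::export(name = ".cpp_hausdorff_pairs")]]
double cpp_hausdorff_pairs(const arma::mat& A, const arma::mat& B,
                           const arma::vec& spacing) {
  const uword nA = A.n_rows, nB = B.n_rows, d = A.n_cols;
  double worst = 0.0;
  for (int dir = 0; dir < 2; ++dir) {
    const mat& P = dir == 0 ? A : B;
    const mat& Q = dir == 0 ? B : A;
    const uword nP = dir == 0 ? nA : nB;
    const uword nQ = dir == 0 ? nB : nA;
    for (uword i = 0; i < nP; ++i) {
      double best = datum::inf;
      for (uword j = 0; j < nQ; ++j) {
        double s = 0.0;
        for (uword k = 0; k < d; ++k) {
          const double diff = (P(i, k) - Q(j, k)) * spacing[k];
          s += diff * diff;
        }
        if (s < best) best = s;
      }
      if (best > worst) worst = best;
    }
  }
  return std::sqrt(worst);
}

// For each query pixel, is any boundary pixel within `radius` (Euclidean)?
// [[Rcpp::export(name = ".cpp_near_boundary")]]
LogicalVector cpp_near_boundary(const NumericVector& qi, const NumericVector& qj,
                                const NumericVector& bi, const NumericVector& bj,
                                const double radius) {
  const int nq = qi.size(), nb = bi.size();
  const double r2 = radius * radius;
  LogicalVector out(nq);
  for (int i = 0; i < nq; ++i) {
    bool hit = false;
    for (int j = 0; j < nb; ++j) {
      const double di = qi[i] - bi[j], dj = qj[i] - bj[j];
      if (di * di + dj * dj <= r2) { hit = true; break; }
    }
    out[i] = hit;
  }
  return out;
}
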