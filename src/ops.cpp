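// Numerical kernels: batched matrix multiply for windowed self-attention and
// a bilinear affine warp used by the training-time augmentation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Batched matrix multiply over the third dimension of two cubes.
// a: (ra x ca x S), b: (rb x cb x S); optional transposes per slice.
// [[Rcpp::export]]
arma::cube bmm_cube(const arma::cube& a, const arma::cube& b,
                    const bool ta = false, const bool tb = false) {
  const arma::uword S = a.n_slices;
  if (b.n_slices != S) stop("bmm_cube: slice counts differ");
  const arma::uword r = ta ? a.n_cols : a.n_rows;
  const arma::uword c = tb ? b.n_rows : b.n_cols;
  arma::cube out(r, c, S);
  for (arma::uword s = 0; s < S; ++s) {
    if (!ta && !tb)      out.slice(s) = a.slice(s) * b.slice(s);
    else if (ta && !tb)  out.slice(s) = a.slice(s).t() * b.slice(s);
    else if (!ta && tb)  out.slice(s) = a.slice(s) * b.slice(s).t();
    else                 out.slice(s) = a.slice(s).t() * b.slice(s).t();
  }
  return out;
}

// Inverse-mapped bilinear warp. For each output pixel (x, y) (0-based,
// x = column), samples the input at (m11*x + m12*y + m13, m21*x + m22*y +
// m23). Out-of-bounds samples take `background`.
// [[Rcpp::export]]
NumericMatrix warp_affine(const NumericMatrix& img, const NumericVector& m,
                          const int h_out, const int w_out,
                          const double background = 0.0) {
  if (m.size() != 6) stop("warp_affine: m must have 6 elements");
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(h_out, w_out);
  for (int x = 0; x < w_out; ++x) {
    for (int y = 0; y < h_out; ++y) {
      const double sx = m[0] * x + m[1] * y + m[2];
      const double sy = m[3] * x + m[4] * y + m[5];
      if (sx < 0 || sy < 0 || sx > W - 1 || sy > H - 1) {
        out(y, x) = background;
        continue;
      }
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double fx = sx - x0, fy = sy - y0;
      out(y, x) = (1 - fx) * ((1 - fy) * img(y0, x0) + fy * img(y1, x0)) +
                  fx * ((1 - fy) * img(y0, x1) + fy * img(y1, x1));
    }
  }
  return out;
}

// Row gather with zero rows for idx == 0 (1-based indices otherwise).
// [[Rcpp::export]]
NumericMatrix gather_rows0(const NumericMatrix& x, const IntegerVector& idx) {
  const int n = idx.size(), p = x.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* col = &x(0, j);
    double* oc = &out(0, j);
    for (int i = 0; i < n; ++i) {
      const int s = idx[i];
      oc[i] = s > 0 ? col[s - 1] : 0.0;
    }
  }
  return out;
}

// Transpose of gather_rows0: scatter-add gradient rows back onto n rows.
// [[Rcpp::export]]
NumericMatrix scatter_rows0(const NumericMatrix& g, const IntegerVector& idx,
                            const int n) {
  const int m = idx.size(), p = g.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* gc = &g(0, j);
    double* oc = &out(0, j);
    for (int i = 0; i < m; ++i) {
      const int s = idx[i];
      if (s > 0) oc[s - 1] += gc[i];
    }
  }
  return out;
}

// Split multi-head projections out of a windowed token matrix.
// x: (wsq*nW x >=c0+dh*nh); returns cube (wsq x dh x nh*nW) with head
// fastest in the slice index; c0 is the first column of the projection.
// [[Rcpp::export]]
arma::cube split_heads_cpp(const arma::mat& x, const int wsq, const int nW,
                           const int dh, const int nh, const int c0) {
  arma::cube out(wsq, dh, (arma::uword)nh * nW);
  for (int w = 0; w < nW; ++w)
    for (int h = 0; h < nh; ++h)
      out.slice((arma::uword)w * nh + h) =
        x.submat(w * wsq, c0 + h * dh, (w + 1) * wsq - 1,
                 c0 + (h + 1) * dh - 1);
  return out;
}

// Inverse of split_heads_cpp into a (wsq*nW x ncol) zero matrix.
// [[Rcpp::export]]
arma::mat merge_heads_cpp(const arma::cube& y, const int wsq, const int nW,
                          const int dh, const int nh, const int c0,
                          const int ncol) {
  arma::mat out(arma::uword(wsq) * nW, ncol, arma::fill::zeros);
  for (int w = 0; w < nW; ++w)
    for (int h = 0; h < nh; ++h)
      out.submat(w * wsq, c0 + h * dh, (w + 1) * wsq - 1,
                 c0 + (h + 1) * dh - 1) = y.slice((arma::uword)w * nh + h);
  return out;
}

// Row-wise softmax within every slice of a cube (softmax over keys).
// [[Rcpp::export]]
arma::cube softmax_rows_cpp(const arma::cube& a) {
  arma::cube out(arma::size(a));
  for (arma::uword s = 0; s < a.n_slices; ++s) {
    arma::mat mt = a.slice(s).t();          // keys contiguous per column
    for (arma::uword i = 0; i < mt.n_cols; ++i) {
      arma::vec c = mt.col(i);
      c -= c.max();
      c = arma::exp(c);
      mt.col(i) = c / arma::accu(c);
    }
    out.slice(s) = mt.t();
  }
  return out;
}

// Backward of softmax_rows_cpp: s the softmax output, g the upstream grad.
// [[Rcpp::export]]
arma::cube softmax_rows_grad_cpp(const arma::cube& s, const arma::cube& g) {
  arma::cube out(arma::size(s));
  for (arma::uword k = 0; k < s.n_slices; ++k) {
    const arma::mat st = s.slice(k).t();
    const arma::mat gt = g.slice(k).t();
    arma::mat ot(arma::size(st));
    for (arma::uword i = 0; i < st.n_cols; ++i) {
      const double dot = arma::dot(gt.col(i), st.col(i));
      ot.col(i) = st.col(i) % (gt.col(i) - dot);
    }
    out.slice(k) = ot.t();
  }
  return out;
}

// Pixel-shuffle gather: out(i, c) = m(coarse[i]-1, c*4 + off[i]-1).
// [[Rcpp::export]]
NumericMatrix gather_shuffle(const NumericMatrix& m,
                             const IntegerVector& coarse,
                             const IntegerVector& off, const int cout) {
  const int n = coarse.size();
  NumericMatrix out(n, cout);
  for (int c = 0; c < cout; ++c)
    for (int i = 0; i < n; ++i)
      out(i, c) = m(coarse[i] - 1, c * 4 + off[i] - 1);
  return out;
}

// [[Rcpp::export]]
NumericMatrix scatter_shuffle(const NumericMatrix& g,
                              const IntegerVector& coarse,
                              const IntegerVector& off, const int nc,
                              const int cout) {
  const int n = coarse.size();
  NumericMatrix out(nc, cout * 4);
  for (int c = 0; c < cout; ++c)
    for (int i = 0; i < n; ++i)
      out(coarse[i] - 1, c * 4 + off[i] - 1) += g(i, c);
  return out;
}

// Fused neighbor concatenation: idx holds k stacked index vectors (length
// k*n, 0 = zero row); output (n x k*C) with block o = rows gathered by the
// o-th index vector.
// [[Rcpp::export]]
NumericMatrix im2col0(const NumericMatrix& x, const IntegerVector& idx,
                      const int k) {
  const int n = idx.size() / k, p = x.ncol();
  NumericMatrix out(n, k * p);
  for (int o = 0; o < k; ++o) {
    const int* iv = &idx[o * n];
    for (int j = 0; j < p; ++j) {
      const double* col = &x(0, j);
      double* oc = &out(0, o * p + j);
      for (int i = 0; i < n; ++i) {
        const int s = iv[i];
        oc[i] = s > 0 ? col[s - 1] : 0.0;
      }
    }
  }
  return out;
}

// Transpose of im2col0: scatter-add (n x k*C) gradient back onto nr rows.
// [[Rcpp::export]]
NumericMatrix col2im0(const NumericMatrix& g, const IntegerVector& idx,
                      const int k, const int nr) {
  const int n = idx.size() / k, p = g.ncol() / k;
  NumericMatrix out(nr, p);
  for (int o = 0; o < k; ++o) {
    const int* iv = &idx[o * n];
    for (int j = 0; j < p; ++j) {
      const double* gc = &g(0, o * p + j);
      double* oc = &out(0, j);
      for (int i = 0; i < n; ++i) {
        const int s = iv[i];
        if (s > 0) oc[s - 1] += gc[i];
      }
    }
  }
  return out;
}

// 8-connected component labelling of a binary mask (column-major scan
// order; labels start at 1 in scan order).
// [[Rcpp::export]]
IntegerMatrix label_components(const LogicalMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int cur = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      ++cur;
      lab(i, j) = cur;
      stack.push_back(i + j * H);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ni = pi + di, nj = pj + dj;
            if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
            if (m(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = cur;
              stack.push_back(ni + nj * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Separable Gaussian blur with mirrored edges (kernel radius 3 sigma).
// [[Rcpp::export]]
NumericMatrix gauss_blur(const NumericMatrix& img, const double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii - 1;
        if (ii >= H) ii = 2 * H - ii - 1;
        acc += k[t + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj - 1;
        if (jj >= W) jj = 2 * W - jj - 1;
        acc += k[t + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}
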