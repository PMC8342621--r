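// Low-level numerical kernels: dilated 2-D convolution (im2col + gemm) with its
// gradients, greedy non-maximum suppression, and the repel proximity encoding.
// Feature maps are arma::cube with dimensions (H, W, C); weights are
// (Cin*k*k) x Cout matrices with column layout c*(k*k) + ki*k + kj, where
// (ki, kj) index the kernel row/column offsets.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int stride, int dil,
                        int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(Ho * (long)Wo, (long)C * k * k, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& plane = x.slice(c);
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int col = c * k * k + ki * k + kj;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride - pad + kj * dil;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride - pad + ki * dil;
            if (ii < 0 || ii >= H) continue;
            cols(i + (long)j * Ho, col) = plane(ii, jj);
          }
        }
      }
    }
  }
  return cols;
}

static void out_dims(int H, int W, int k, int stride, int dil, int pad,
                     int& Ho, int& Wo) {
  Ho = (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  Wo = (W + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int stride, int dil, int pad) {
  int Ho, Wo;
  out_dims(x.n_rows, x.n_cols, k, stride, dil, pad, Ho, Wo);
  const int Cout = w.n_cols;
  arma::mat cols = im2col(x, k, stride, dil, pad, Ho, Wo);
  arma::mat out = cols * w;
  out.each_row() += b.t();
  arma::cube y(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = arma::reshape(out.col(c), Ho, Wo);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& dy,
                int k, int stride, int dil, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  arma::mat cols = im2col(x, k, stride, dil, pad, Ho, Wo);
  arma::mat dy_mat(Ho * (long)Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    dy_mat.col(c) = arma::vectorise(dy.slice(c));
  arma::mat dw = cols.t() * dy_mat;
  arma::vec db = arma::sum(dy_mat, 0).t();
  arma::mat dcols = dy_mat * w.t();
  // col2im: scatter-add the column gradients back onto the input raster
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& plane = dx.slice(c);
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int col = c * k * k + ki * k + kj;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride - pad + kj * dil;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride - pad + ki * dil;
            if (ii < 0 || ii >= H) continue;
            plane(ii, jj) += dcols(i + (long)j * Ho, col);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Greedy NMS over a score raster. Candidates are all pixels with
// score >= threshold, processed by descending score with ties broken in
// row-major (y, then x) order; a candidate is kept iff its Euclidean distance
// to every already-kept point is >= min_distance. Coordinates are 0-based,
// x = column, y = row.
// [[Rcpp::export]]
DataFrame nms_greedy(const arma::mat& score, double min_distance,
                     double threshold) {
  const int H = score.n_rows, W = score.n_cols;
  std::vector<int> cx, cy;
  std::vector<double> cs;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (score(y, x) >= threshold) {
        cx.push_back(x); cy.push_back(y); cs.push_back(score(y, x));
      }
  std::vector<size_t> ord(cs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (cs[a] != cs[b]) return cs[a] > cs[b];
    if (cy[a] != cy[b]) return cy[a] < cy[b];
    return cx[a] < cx[b];
  });
  const double d2min = min_distance * min_distance;
  std::vector<int> kx, ky;
  std::vector<double> ks;
  for (size_t oi = 0; oi < ord.size(); ++oi) {
    const int x = cx[ord[oi]], y = cy[ord[oi]];
    bool ok = true;
    for (size_t j = 0; j < kx.size(); ++j) {
      const double dx = x - kx[j], dy = y - ky[j];
      if (dx * dx + dy * dy < d2min) { ok = false; break; }
    }
    if (ok) { kx.push_back(x); ky.push_back(y); ks.push_back(cs[ord[oi]]); }
  }
  return DataFrame::create(_["x"] = kx, _["y"] = ky, _["confidence"] = ks);
}

// Repel proximity code: for each pixel p with distances d1 <= d2 to the two
// nearest centers, R(p) = max(0, 1 - d1/r)^alpha * (1 - beta * d1 / max(d2, eps)).
// [[Rcpp::export]]
arma::mat repel_map(const arma::mat& centers, int H, int W, double r,
                    double alpha, double beta) {
  arma::mat out(H, W, arma::fill::zeros);
  const int n = centers.n_rows;
  if (n == 0) return out;
  const double eps = 1e-9;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double d1 = std::numeric_limits<double>::infinity(), d2 = d1;
      for (int i = 0; i < n; ++i) {
        const double dx = x - centers(i, 0), dy = y - centers(i, 1);
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d < d1) { d2 = d1; d1 = d; }
        else if (d < d2) { d2 = d; }
      }
      if (d1 >= r) continue;
      const double prox = std::pow(1.0 - d1 / r, alpha);
      const double denom = (n > 1) ? std::max(d2, eps) : std::numeric_limits<double>::infinity();
      double valley = 1.0;
      if (std::isfinite(denom)) valley = 1.0 - beta * d1 / denom;
      if (valley < 0.0) valley = 0.0;
      out(y, x) = prox * valley;
    }
  }
  return out;
}
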