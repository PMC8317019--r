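// Ray-driven parallel-beam Radon transform with bilinear sampling along rays,
// its exact algebraic transpose, and a pixel-driven linearly interpolated
// backprojection used by filtered backprojection.
//
// Geometry: square image, centre at ((H-1)/2, (W-1)/2); world coordinates
// x = col - cx (right), y = cy - row (up). A view at angle theta integrates
// along lines x.omega = t with omega = (cos theta, sin theta); detector
// offsets t_d = (d - (n_det-1)/2) * spacing. Integration step in pixels.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat radon_fwd_cpp(const arma::mat& img, const arma::vec& angles,
                        int n_det, double spacing, double step) {
  const int H = img.n_rows, W = img.n_cols;
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double L = 0.5 * std::sqrt((double)(H * H + W * W)) + 1.0;
  const int n_steps = (int)std::ceil(2.0 * L / step);
  mat sino(angles.n_elem, n_det, fill::zeros);
  for (uword a = 0; a < angles.n_elem; ++a) {
    const double c = std::cos(angles(a)), s = std::sin(angles(a));
    for (int d = 0; d < n_det; ++d) {
      const double t = (d - (n_det - 1) / 2.0) * spacing;
      double acc = 0.0;
      for (int k = 0; k < n_steps; ++k) {
        const double l = -L + (k + 0.5) * step;
        const double x = t * c - l * s, y = t * s + l * c;
        const double col = cx + x, row = cy - y;
        const int r0 = (int)std::floor(row), c0 = (int)std::floor(col);
        const double fr = row - r0, fc = col - c0;
        for (int dr = 0; dr <= 1; ++dr) {
          const int rr = r0 + dr;
          if (rr < 0 || rr >= H) continue;
          const double wr = dr ? fr : 1.0 - fr;
          for (int dc = 0; dc <= 1; ++dc) {
            const int cc = c0 + dc;
            if (cc < 0 || cc >= W) continue;
            const double wc = dc ? fc : 1.0 - fc;
            acc += wr * wc * img(rr, cc);
          }
        }
      }
      sino(a, d) = acc * step;
    }
  }
  return sino;
}

// [[Rcpp::export]]
arma::mat radon_adj_cpp(const arma::mat& sino, int H, int W,
                        const arma::vec& angles, int n_det, double spacing,
                        double step) {
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double L = 0.5 * std::sqrt((double)(H * H + W * W)) + 1.0;
  const int n_steps = (int)std::ceil(2.0 * L / step);
  mat img(H, W, fill::zeros);
  for (uword a = 0; a < angles.n_elem; ++a) {
    const double c = std::cos(angles(a)), s = std::sin(angles(a));
    for (int d = 0; d < n_det; ++d) {
      const double t = (d - (n_det - 1) / 2.0) * spacing;
      const double v = sino(a, d) * step;
      if (v == 0.0) continue;
      for (int k = 0; k < n_steps; ++k) {
        const double l = -L + (k + 0.5) * step;
        const double x = t * c - l * s, y = t * s + l * c;
        const double col = cx + x, row = cy - y;
        const int r0 = (int)std::floor(row), c0 = (int)std::floor(col);
        const double fr = row - r0, fc = col - c0;
        for (int dr = 0; dr <= 1; ++dr) {
          const int rr = r0 + dr;
          if (rr < 0 || rr >= H) continue;
          const double wr = dr ? fr : 1.0 - fr;
          for (int dc = 0; dc <= 1; ++dc) {
            const int cc = c0 + dc;
            if (cc < 0 || cc >= W) continue;
            const double wc = dc ? fc : 1.0 - fc;
            img(rr, cc) += wr * wc * v;
          }
        }
      }
    }
  }
  return img;
}

// [[Rcpp::export]]
arma::mat backproject_cpp(const arma::mat& sino, int H, int W,
                          const arma::vec& angles, int n_det, double spacing) {
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  mat img(H, W, fill::zeros);
  for (uword a = 0; a < angles.n_elem; ++a) {
    const double c = std::cos(angles(a)), s = std::sin(angles(a));
    for (int col = 0; col < W; ++col) {
      const double x = col - cx;
      for (int row = 0; row < H; ++row) {
        const double y = cy - row;
        const double t = x * c + y * s;
        const double d = t / spacing + (n_det - 1) / 2.0;
        const int d0 = (int)std::floor(d);
        const double fd = d - d0;
        double v = 0.0;
        if (d0 >= 0 && d0 < n_det) v += (1.0 - fd) * sino(a, d0);
        if (d0 + 1 >= 0 && d0 + 1 < n_det) v += fd * sino(a, d0 + 1);
        img(row, col) += v;
      }
    }
  }
  return img;
}
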