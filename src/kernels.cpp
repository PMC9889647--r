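// Numerical kernels: trilinear affine resampling, im2col-based (transposed)
// convolutions for the adversarial network, and the gamma-index search.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// trilinear sampling helpers (zero outside the grid)
// ---------------------------------------------------------------------------

static inline double trilin(const double* v, int nx, int ny, int nz,
                            double fx, double fy, double fz) {
  if (fx < 0.0 || fy < 0.0 || fz < 0.0 ||
      fx > nx - 1.0 || fy > ny - 1.0 || fz > nz - 1.0) return NA_REAL;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double dx = fx - x0, dy = fy - y0, dz = fz - z0;
  int x1 = std::min(x0 + 1, nx - 1);
  int y1 = std::min(y0 + 1, ny - 1);
  int z1 = std::min(z0 + 1, nz - 1);
#define V(i,j,k) v[(i) + nx * ((j) + (size_t)ny * (k))]
  double c00 = V(x0,y0,z0) * (1-dx) + V(x1,y0,z0) * dx;
  double c10 = V(x0,y1,z0) * (1-dx) + V(x1,y1,z0) * dx;
  double c01 = V(x0,y0,z1) * (1-dx) + V(x1,y0,z1) * dx;
  double c11 = V(x0,y1,z1) * (1-dx) + V(x1,y1,z1) * dx;
#undef V
  double c0 = c00 * (1-dy) + c10 * dy;
  double c1 = c01 * (1-dy) + c11 * dy;
  return c0 * (1-dz) + c1 * dz;
}

// Affine pull-back resample: out[i,j,k] = src(A %*% (i,j,k) + t), indices
// 0-based, trilinear. Outside the source grid: zero fill (edge = 0, the
// world-space semantics) or border replication (edge = 1, image resizing).
// [[Rcpp::export]]
NumericVector cpp_affine_resample3d(NumericVector src, IntegerVector src_dim,
                                    IntegerVector out_dim, NumericMatrix A,
                                    NumericVector t, int edge = 0) {
  int nx = src_dim[0], ny = src_dim[1], nz = src_dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = src.begin();
  double* o = out.begin();
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double fx = A(0,0)*i + A(0,1)*j + A(0,2)*k + t[0];
        double fy = A(1,0)*i + A(1,1)*j + A(1,2)*k + t[1];
        double fz = A(2,0)*i + A(2,1)*j + A(2,2)*k + t[2];
        if (edge == 1) {
          fx = std::min(std::max(fx, 0.0), nx - 1.0);
          fy = std::min(std::max(fy, 0.0), ny - 1.0);
          fz = std::min(std::max(fz, 0.0), nz - 1.0);
        }
        double val = trilin(v, nx, ny, nz, fx, fy, fz);
        o[i + ox * ((size_t)j + (size_t)oy * k)] = ISNAN(val) ? 0.0 : val;
      }
  out.attr("dim") = out_dim;
  return out;
}

// ---------------------------------------------------------------------------
// im2col convolutions (data layout: cube H x W x C; weights C_out x C_in*k*k
// for forward conv, C_in x C_out*k*k for transposed conv)
// ---------------------------------------------------------------------------

static arma::mat im2col(const arma::cube& x, int k, int s, int p,
                        int Ho, int Wo) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(C * k * k, (size_t)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        int row = c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          int sj = oj * s - p + kj;
          if (sj < 0 || sj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int si = oi * s - p + ki;
            if (si < 0 || si >= H) continue;
            cols(row, oi + (size_t)Ho * oj) = x(si, sj, c);
          }
        }
      }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C,
                         int k, int s, int p, int Ho, int Wo) {
  // adjoint of im2col: scatter-add columns back onto an H x W x C cube
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        int row = c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          int sj = oj * s - p + kj;
          if (sj < 0 || sj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int si = oi * s - p + ki;
            if (si < 0 || si >= H) continue;
            x(si, sj, c) += cols(row, oi + (size_t)Ho * oj);
          }
        }
      }
  return x;
}

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& Wm,
                        const arma::vec& b, int k, int s, int p) {
  int Ho = out_size(x.n_rows, k, s, p), Wo = out_size(x.n_cols, k, s, p);
  arma::mat cols = im2col(x, k, s, p, Ho, Wo);
  arma::mat y = Wm * cols;           // C_out x (Ho*Wo)
  y.each_col() += b;
  int Co = Wm.n_rows;
  arma::cube out(Ho, Wo, Co);
  for (int c = 0; c < Co; ++c)
    out.slice(c) = arma::reshape(y.row(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& Wm,
                  const arma::cube& gy, int k, int s, int p) {
  int Ho = gy.n_rows, Wo = gy.n_cols, Co = gy.n_slices;
  arma::mat cols = im2col(x, k, s, p, Ho, Wo);
  arma::mat gy_flat(Co, (size_t)Ho * Wo);
  for (int c = 0; c < Co; ++c)
    gy_flat.row(c) = arma::vectorise(gy.slice(c)).t();
  arma::mat gW = gy_flat * cols.t();
  arma::vec gb = arma::sum(gy_flat, 1);
  arma::mat gcols = Wm.t() * gy_flat;
  arma::cube gx = col2im(gcols, x.n_rows, x.n_cols, x.n_slices, k, s, p, Ho, Wo);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Transposed convolution: input (H,W,C_in) -> output (Ho,Wo,C_out) such that
// a forward conv(k,s,p) maps (Ho,Wo) back to (H,W).
// [[Rcpp::export]]
arma::cube cpp_convT_fwd(const arma::cube& x, const arma::mat& Wm,
                         const arma::vec& b, int k, int s, int p,
                         int Ho, int Wo) {
  int H = x.n_rows, W = x.n_cols, Ci = x.n_slices;
  int Co = Wm.n_cols / (k * k);
  arma::mat x_flat(Ci, (size_t)H * W);
  for (int c = 0; c < Ci; ++c)
    x_flat.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat cols = Wm.t() * x_flat;   // (C_out*k*k) x (H*W)
  arma::cube out = col2im(cols, Ho, Wo, Co, k, s, p, H, W);
  for (int c = 0; c < Co; ++c)
    out.slice(c) += b[c];
  return out;
}

// [[Rcpp::export]]
List cpp_convT_bwd(const arma::cube& x, const arma::mat& Wm,
                   const arma::cube& gy, int k, int s, int p) {
  int H = x.n_rows, W = x.n_cols, Ci = x.n_slices;
  int Co = gy.n_slices;
  arma::mat gcols = im2col(gy, k, s, p, H, W);   // (C_out*k*k) x (H*W)
  arma::mat x_flat(Ci, (size_t)H * W);
  for (int c = 0; c < Ci; ++c)
    x_flat.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat gx_flat = Wm * gcols;                // C_in x (H*W)
  arma::cube gx(H, W, Ci);
  for (int c = 0; c < Ci; ++c)
    gx.slice(c) = arma::reshape(gx_flat.row(c), H, W);
  arma::mat gW = x_flat * gcols.t();
  arma::vec gb(Co);
  for (int c = 0; c < Co; ++c)
    gb[c] = arma::accu(gy.slice(c));
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// In-place Adam update: p, m, v are modified directly (they are private to
// one layer environment, never shared).
// [[Rcpp::export]]
void cpp_adam_step(NumericVector p, NumericVector g, NumericVector m,
                   NumericVector v, double lr, double b1, double b2,
                   double b1t, double b2t, double eps) {
  size_t n = p.size();
  for (size_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / b1t) / (std::sqrt(v[i] / b2t) + eps);
  }
}

// ---------------------------------------------------------------------------
// gamma index
// ---------------------------------------------------------------------------

// Optimized search: candidate offsets sorted by distance, pruned as soon as
// the distance term alone exceeds the best gamma^2 found so far (lossless),
// optionally capped at `cap` (caps only the reported value, never promotes
// a failing voxel to passing when cap > 1).
// [[Rcpp::export]]
NumericVector cpp_gamma_search(NumericVector ref, NumericVector ev,
                               IntegerVector dim, NumericVector spacing,
                               double dose_tol_abs, double dist_tol,
                               double low_thresh, double radius,
                               NumericVector step, double cap) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);
  // build sorted offset table
  int mx = (int)std::floor(radius / step[0]);
  int my = (int)std::floor(radius / step[1]);
  int mz = nz > 1 ? (int)std::floor(radius / step[2]) : 0;
  std::vector<std::array<double,4>> offs; // r2, ox, oy, oz (mm)
  for (int a = -mx; a <= mx; ++a)
    for (int b = -my; b <= my; ++b)
      for (int c = -mz; c <= mz; ++c) {
        double ox = a * step[0], oy = b * step[1], oz = c * step[2];
        double r2 = ox*ox + oy*oy + oz*oz;
        if (r2 <= radius * radius + 1e-12)
          offs.push_back({r2, ox, oy, oz});
      }
  std::sort(offs.begin(), offs.end(),
            [](const std::array<double,4>& u, const std::array<double,4>& v) {
              return u[0] < v[0];
            });
  const double* rv = ref.begin();
  const double* evv = ev.begin();
  double dt2 = dist_tol * dist_tol;
  double cap2 = R_FINITE(cap) ? cap * cap : R_PosInf;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + nx * ((size_t)j + (size_t)ny * k);
        double r = rv[idx];
        if (r < low_thresh) continue;
        double best = cap2;
        for (size_t q = 0; q < offs.size(); ++q) {
          double dterm = offs[q][0] / dt2;
          if (dterm >= best) break;
          double fx = i + offs[q][1] / spacing[0];
          double fy = j + offs[q][2] / spacing[1];
          double fz = k + offs[q][3] / spacing[2];
          double e = trilin(evv, nx, ny, nz, fx, fy, fz);
          if (ISNAN(e)) continue;
          double dd = (r - e) / dose_tol_abs;
          double g2 = dterm + dd * dd;
          if (g2 < best) best = g2;
        }
        out[idx] = std::sqrt(best);
      }
  out.attr("dim") = dim;
  return out;
}

// Exhaustive reference search: every offset on the same lattice, no sorting,
// no pruning, no cap. Used as the correctness oracle on small grids.
// [[Rcpp::export]]
NumericVector cpp_gamma_bruteforce(NumericVector ref, NumericVector ev,
                                   IntegerVector dim, NumericVector spacing,
                                   double dose_tol_abs, double dist_tol,
                                   double low_thresh, double radius,
                                   NumericVector step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);
  int mx = (int)std::floor(radius / step[0]);
  int my = (int)std::floor(radius / step[1]);
  int mz = nz > 1 ? (int)std::floor(radius / step[2]) : 0;
  const double* rv = ref.begin();
  const double* evv = ev.begin();
  double dt2 = dist_tol * dist_tol;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + nx * ((size_t)j + (size_t)ny * k);
        double r = rv[idx];
        if (r < low_thresh) continue;
        double best = R_PosInf;
        for (int a = -mx; a <= mx; ++a)
          for (int b = -my; b <= my; ++b)
            for (int c = -mz; c <= mz; ++c) {
              double ox = a * step[0], oy = b * step[1], oz = c * step[2];
              double r2 = ox*ox + oy*oy + oz*oz;
              if (r2 > radius * radius + 1e-12) continue;
              double e = trilin(evv, nx, ny, nz,
                                i + ox / spacing[0],
                                j + oy / spacing[1],
                                k + oz / spacing[2]);
              if (ISNAN(e)) continue;
              double dd = (r - e) / dose_tol_abs;
              double g2 = r2 / dt2 + dd * dd;
              if (g2 < best) best = g2;
            }
        out[idx] = std::sqrt(best);
      }
  out.attr("dim") = dim;
  return out;
}
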