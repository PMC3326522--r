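// Numerical kernels: trilinear volume sampling, projection, Gaussian
// pseudo-atom density synthesis, Fourier-slice insertion for direct
// Fourier inversion, image rotation and exhaustive alignment search.
// Conventions: cubic N^3 grids, geometric centre at 0-based index N/2;
// rotation matrices are passed in from R (ZYZ intrinsic, degrees there).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sample_tri(const arma::cube& v, double x, double y, double z) {
  const int N0 = v.n_rows, N1 = v.n_cols, N2 = v.n_slices;
  if (x < 0 || y < 0 || z < 0 || x > N0 - 1 || y > N1 - 1 || z > N2 - 1) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, N0 - 1), y1 = std::min(y0 + 1, N1 - 1), z1 = std::min(z0 + 1, N2 - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c00 = v(x0, y0, z0) * (1 - fx) + v(x1, y0, z0) * fx;
  double c10 = v(x0, y1, z0) * (1 - fx) + v(x1, y1, z0) * fx;
  double c01 = v(x0, y0, z1) * (1 - fx) + v(x1, y0, z1) * fx;
  double c11 = v(x0, y1, z1) * (1 - fx) + v(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double sample_bil(const arma::mat& m, double x, double y) {
  const int N0 = m.n_rows, N1 = m.n_cols;
  if (x < 0 || y < 0 || x > N0 - 1 || y > N1 - 1) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, N0 - 1), y1 = std::min(y0 + 1, N1 - 1);
  double fx = x - x0, fy = y - y0;
  return (m(x0, y0) * (1 - fx) + m(x1, y0) * fx) * (1 - fy) +
         (m(x0, y1) * (1 - fx) + m(x1, y1) * fx) * fy;
}

// Line-integral projection along the rotated z axis:
// I(x, y) = sum_t V(R (x, y, t) + c), in voxel units.
// [[Rcpp::export]]
arma::mat cpp_project(const arma::cube& vol, const arma::mat& R) {
  const int N = vol.n_rows;
  const double c = N / 2;
  arma::mat out(N, N, arma::fill::zeros);
  const arma::vec d = R * arma::vec({0, 0, 1});
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < N; ++i) {
      const double x = i - c, y = j - c;
      double bx = R(0, 0) * x + R(0, 1) * y + c;
      double by = R(1, 0) * x + R(1, 1) * y + c;
      double bz = R(2, 0) * x + R(2, 1) * y + c;
      double s = 0.0;
      for (int t = -(int)c; t < (int)c; ++t)
        s += sample_tri(vol, bx + t * d(0), by + t * d(1), bz + t * d(2));
      out(i, j) = s;
    }
  }
  return out;
}

// Gaussian pseudo-atom spreading.  coords are fractional grid indices
// (0-based); each atom's discrete kernel is normalised so that
// sum(grid) = sum(mass) exactly, making the integrated density
// voxel-size independent.
// [[Rcpp::export]]
arma::cube cpp_synth_density(const arma::mat& coords, const arma::vec& mass,
                             int N, double sigma_vox) {
  arma::cube out(N, N, N, arma::fill::zeros);
  const int r = std::max(2, (int)std::ceil(4.0 * sigma_vox));
  const double inv2s2 = 1.0 / (2.0 * sigma_vox * sigma_vox);
  std::vector<double> w((2 * r + 1) * (2 * r + 1) * (2 * r + 1));
  for (arma::uword a = 0; a < coords.n_rows; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const int ix0 = (int)std::round(ax), iy0 = (int)std::round(ay), iz0 = (int)std::round(az);
    double wsum = 0.0;
    int idx = 0;
    for (int dz = -r; dz <= r; ++dz)
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx) {
          const double ddx = ix0 + dx - ax, ddy = iy0 + dy - ay, ddz = iz0 + dz - az;
          const double ww = std::exp(-(ddx * ddx + ddy * ddy + ddz * ddz) * inv2s2);
          w[idx++] = ww;
          wsum += ww;
        }
    if (wsum <= 0) continue;
    const double scale = mass(a) / wsum;
    idx = 0;
    for (int dz = -r; dz <= r; ++dz)
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx) {
          const int ix = ix0 + dx, iy = iy0 + dy, iz = iz0 + dz;
          const double ww = w[idx++];
          if (ix >= 0 && iy >= 0 && iz >= 0 && ix < N && iy < N && iz < N)
            out(ix, iy, iz) += ww * scale;
        }
  }
  return out;
}

// Boolean mask of voxels within radius_vox of any atom.
// [[Rcpp::export]]
arma::ucube cpp_atom_mask(const arma::mat& coords, int N, double radius_vox) {
  arma::ucube out(N, N, N, arma::fill::zeros);
  const int r = (int)std::ceil(radius_vox);
  const double r2 = radius_vox * radius_vox;
  for (arma::uword a = 0; a < coords.n_rows; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const int ix0 = (int)std::round(ax), iy0 = (int)std::round(ay), iz0 = (int)std::round(az);
    for (int dz = -r; dz <= r; ++dz)
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx) {
          const int ix = ix0 + dx, iy = iy0 + dy, iz = iz0 + dz;
          if (ix < 0 || iy < 0 || iz < 0 || ix >= N || iy >= N || iz >= N) continue;
          const double ddx = ix - ax, ddy = iy - ay, ddz = iz - az;
          if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) out(ix, iy, iz) = 1;
        }
  }
  return out;
}

// Rotate a volume about its z axis through the grid centre (degrees,
// counterclockwise looking down +z).
// [[Rcpp::export]]
arma::cube cpp_rotate_vol_z(const arma::cube& vol, double angle_deg) {
  const int N = vol.n_rows;
  const double c = N / 2;
  const double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  arma::cube out(N, N, N, arma::fill::zeros);
  for (int k = 0; k < N; ++k)
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) {
        const double x = i - c, y = j - c;
        // inverse rotation of output coords
        const double sx = ca * x + sa * y + c;
        const double sy = -sa * x + ca * y + c;
        out(i, j, k) = sample_tri(vol, sx, sy, k);
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_symmetrize_z(const arma::cube& vol, int nfold) {
  arma::cube acc = vol;
  for (int k = 1; k < nfold; ++k)
    acc += cpp_rotate_vol_z(vol, 360.0 * k / nfold);
  return acc / nfold;
}

// Rotate an image by angle_deg (counterclockwise, about the grid centre)
// then shift by (dx, dy) pixels: out(p) = img(Rinv (p - t) + c).
// [[Rcpp::export]]
arma::mat cpp_transform_image(const arma::mat& img, double angle_deg,
                              double dx, double dy) {
  const int N = img.n_rows;
  const double c = N / 2;
  const double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  arma::mat out(N, img.n_cols, arma::fill::zeros);
  for (arma::uword j = 0; j < img.n_cols; ++j)
    for (int i = 0; i < N; ++i) {
      const double x = i - c - dx, y = (double)j - c - dy;
      const double sx = ca * x + sa * y + c;
      const double sy = -sa * x + ca * y + c;
      out(i, j) = sample_bil(img, sx, sy);
    }
  return out;
}

// Central-slice insertion for direct Fourier inversion.
// fstack: unshifted 2D DFTs of the (shifted) particle images.
// rot: 3x3xP rotation matrices (same convention as cpp_project).
// shifts: P x 2 applied pixel shifts, removed here by phase correction.
// Returns accumulated complex numerator and real weights on the
// unshifted 3D DFT grid, with the centre-phase checkerboard applied so
// that a plain inverse FFT recovers a centred volume.
// [[Rcpp::export]]
List cpp_fourier_insert(const arma::cx_cube& fstack, const arma::cube& rot,
                        const arma::mat& shifts) {
  const int N = fstack.n_rows;
  const int P = fstack.n_slices;
  arma::cx_cube num(N, N, N, arma::fill::zeros);
  arma::cube wt(N, N, N, arma::fill::zeros);
  const double lim = N / 2.0 - 1.001;
  for (int p = 0; p < P; ++p) {
    const arma::mat& R = rot.slice(p);
    const double sx = shifts(p, 0), sy = shifts(p, 1);
    for (int jy = 0; jy < N; ++jy) {
      const int hy = (jy <= N / 2) ? jy : jy - N;
      if (std::abs(hy) > lim) continue;
      for (int jx = 0; jx < N; ++jx) {
        const int hx = (jx <= N / 2) ? jx : jx - N;
        if (std::abs(hx) > lim) continue;
        const double gx = R(0, 0) * hx + R(0, 1) * hy;
        const double gy = R(1, 0) * hx + R(1, 1) * hy;
        const double gz = R(2, 0) * hx + R(2, 1) * hy;
        if (std::abs(gx) > lim || std::abs(gy) > lim || std::abs(gz) > lim) continue;
        // undo the recorded translation, re-centre phase origin
        const double ph = 2.0 * M_PI * (hx * sx + hy * sy) / N;
        std::complex<double> val = fstack(jx, jy, p) *
          std::complex<double>(std::cos(ph), std::sin(ph));
        if ((jx + jy) % 2 == 1) val = -val;
        const int fx = (int)std::floor(gx), fy = (int)std::floor(gy), fz = (int)std::floor(gz);
        const double ax = gx - fx, ay = gy - fy, az = gz - fz;
        for (int cz = 0; cz <= 1; ++cz)
          for (int cy = 0; cy <= 1; ++cy)
            for (int cx = 0; cx <= 1; ++cx) {
              const double w = (cx ? ax : 1 - ax) * (cy ? ay : 1 - ay) * (cz ? az : 1 - az);
              if (w <= 0) continue;
              const int ix = ((fx + cx) % N + N) % N;
              const int iy = ((fy + cy) % N + N) % N;
              const int iz = ((fz + cz) % N + N) % N;
              num(ix, iy, iz) += w * val;
              wt(ix, iy, iz) += w;
            }
      }
    }
  }
  return List::create(Named("num") = num, Named("wt") = wt);
}

// Exhaustive alignment of particles against rotated references.
// parts: N x N x P stack; refs: N x N x R stack; angles in degrees.
// Every particle and every rotated reference is standardised to zero
// mean / unit norm, so scores are normalised cross-correlations.
// If max_shift > 0 the translation search runs over the FFT
// cross-correlation within a (2*max_shift+1)^2 window (circular).
// Returns P x 5 matrix: ref (1-based), angle, dx, dy, score.
// [[Rcpp::export]]
arma::mat cpp_align(const arma::cube& parts, const arma::cube& refs,
                    const arma::vec& angles, int max_shift) {
  const int N = parts.n_rows;
  const int P = parts.n_slices, R = refs.n_slices, A = angles.n_elem;
  arma::mat out(P, 5);
  out.col(4).fill(-2.0);
  // standardised particles (+ their FFTs if searching shifts)
  arma::cube pn(N, N, P);
  for (int p = 0; p < P; ++p) {
    arma::mat m = parts.slice(p);
    m -= arma::accu(m) / (N * N);
    double nrm = std::sqrt(arma::accu(m % m));
    pn.slice(p) = (nrm > 0) ? arma::mat(m / nrm) : m;
  }
  arma::cx_cube pf;
  if (max_shift > 0) {
    pf.set_size(N, N, P);
    for (int p = 0; p < P; ++p) pf.slice(p) = arma::fft2(pn.slice(p));
  }
  for (int r = 0; r < R; ++r) {
    for (int a = 0; a < A; ++a) {
      arma::mat rr = cpp_transform_image(refs.slice(r), angles(a), 0, 0);
      rr -= arma::accu(rr) / (N * N);
      double nrm = std::sqrt(arma::accu(rr % rr));
      if (nrm <= 0) continue;
      rr /= nrm;
      if (max_shift == 0) {
        for (int p = 0; p < P; ++p) {
          const double sc = arma::accu(pn.slice(p) % rr);
          if (sc > out(p, 4)) {
            out(p, 0) = r + 1; out(p, 1) = angles(a);
            out(p, 2) = 0; out(p, 3) = 0; out(p, 4) = sc;
          }
        }
      } else {
        const arma::cx_mat rf = arma::conj(arma::fft2(rr));
        for (int p = 0; p < P; ++p) {
          const arma::cx_mat cc = arma::ifft2(arma::cx_mat(pf.slice(p) % rf));
          for (int dy = -max_shift; dy <= max_shift; ++dy)
            for (int dx = -max_shift; dx <= max_shift; ++dx) {
              const int ix = ((dx % N) + N) % N, iy = ((dy % N) + N) % N;
              const double sc = cc(ix, iy).real();
              if (sc > out(p, 4)) {
                out(p, 0) = r + 1; out(p, 1) = angles(a);
                out(p, 2) = dx; out(p, 3) = dy; out(p, 4) = sc;
              }
            }
        }
      }
    }
  }
  return out;
}
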