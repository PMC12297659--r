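// Numerical core: Gaussian density splatting, 3-D FFTs (FFTW-backed), and
// the masked locally normalized cross-correlation scan used by the
// rigid-body search.
#include <RcppArmadillo.h>
#include <fftw3.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// 3-D complex FFT via FFTW (single-threaded, FFTW_ESTIMATE plans: results
// are deterministic for a given size). Armadillo cubes are column-major
// with the row index fastest, so the FFTW dimension order is reversed.
static cx_cube fft3(const cx_cube &X, const bool inverse) {
  const int n1 = (int)X.n_rows, n2 = (int)X.n_cols, n3 = (int)X.n_slices;
  cx_cube out(n1, n2, n3);
  fftw_plan p = fftw_plan_dft_3d(
      n3, n2, n1,
      reinterpret_cast<fftw_complex *>(const_cast<cx_double *>(X.memptr())),
      reinterpret_cast<fftw_complex *>(out.memptr()),
      inverse ? FFTW_BACKWARD : FFTW_FORWARD, FFTW_ESTIMATE);
  fftw_execute(p);
  fftw_destroy_plan(p);
  if (inverse) out /= (double)(X.n_elem);
  return out;
}

// [[Rcpp::export]]
arma::cx_cube cpp_fft3(const arma::cx_cube &x, const bool inverse) {
  return fft3(x, inverse);
}

// Splat atoms as isotropic Gaussians onto a grid. Grid index (i,j,k)
// (0-based) sits at world position origin + (i,j,k) * voxel. The kernel is
// separable and truncated at rcut * sigma per axis.
// [[Rcpp::export]]
arma::cube cpp_splat(const arma::mat &coords, const arma::vec &weights,
                     const arma::ivec &dim, const arma::vec &origin,
                     const double voxel, const double sigma,
                     const double rcut) {
  const int n1 = dim(0), n2 = dim(1), n3 = dim(2);
  cube M(n1, n2, n3, fill::zeros);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int r = (int)std::ceil(rcut * sigma / voxel);
  std::vector<double> gx(2 * r + 1), gy(2 * r + 1), gz(2 * r + 1);
  for (uword a = 0; a < coords.n_rows; ++a) {
    const double px = (coords(a, 0) - origin(0)) / voxel;
    const double py = (coords(a, 1) - origin(1)) / voxel;
    const double pz = (coords(a, 2) - origin(2)) / voxel;
    const int i0 = (int)std::lround(px), j0 = (int)std::lround(py),
              k0 = (int)std::lround(pz);
    const double w = weights(a);
    for (int t = -r; t <= r; ++t) {
      const double dx = (i0 + t - px) * voxel, dy = (j0 + t - py) * voxel,
                   dz = (k0 + t - pz) * voxel;
      gx[t + r] = std::exp(-dx * dx * inv2s2);
      gy[t + r] = std::exp(-dy * dy * inv2s2);
      gz[t + r] = std::exp(-dz * dz * inv2s2);
    }
    for (int k = std::max(0, k0 - r); k <= std::min(n3 - 1, k0 + r); ++k) {
      const double wz = w * gz[k - k0 + r];
      for (int j = std::max(0, j0 - r); j <= std::min(n2 - 1, j0 + r); ++j) {
        const double wyz = wz * gy[j - j0 + r];
        const int ilo = std::max(0, i0 - r), ihi = std::min(n1 - 1, i0 + r);
        double *col = M.slice_colptr(k, j);
        for (int i = ilo; i <= ihi; ++i)
          col[i] += wyz * gx[i - i0 + r];
      }
    }
  }
  return M;
}

// Precompute target spectra for repeated scans against one map:
// FB = FFT(B), FB2 = FFT(B^2).
// [[Rcpp::export]]
Rcpp::List cpp_scan_prepare(const arma::cube &target) {
  cx_cube B(target, cube(size(target), fill::zeros));
  cx_cube B2(target % target, cube(size(target), fill::zeros));
  return Rcpp::List::create(Rcpp::Named("FB") = fft3(B, false),
                            Rcpp::Named("FB2") = fft3(B2, false),
                            Rcpp::Named("mean_sq") =
                                accu(target % target) / target.n_elem);
}

// Masked sliding Pearson correlation of a moving map A (within binary mask
// M) against the target at every integer-voxel offset where the moving box
// lies fully inside the target. Packed-complex trick: one forward FFT of
// (M + i*A.M) and two inverse FFTs recover M*B, (A.M)*B and M*B^2, so the
// whole scan costs three 3-D FFTs.
// [[Rcpp::export]]
Rcpp::List cpp_cc_scan(const arma::cube &A, const arma::cube &M,
                       const arma::cx_cube &FB, const arma::cx_cube &FB2,
                       const double mean_sq) {
  const uword t1 = FB.n_rows, t2 = FB.n_cols, t3 = FB.n_slices;
  const uword m1 = A.n_rows, m2 = A.n_cols, m3 = A.n_slices;
  if (m1 > t1 || m2 > t2 || m3 > t3)
    Rcpp::stop("moving map does not fit inside target");
  const uword v1 = t1 - m1 + 1, v2 = t2 - m2 + 1, v3 = t3 - m3 + 1;

  const double n = accu(M);
  if (n < 2) Rcpp::stop("mask has fewer than 2 voxels");
  const cube AM = A % M;
  const double S_A = accu(AM), S_A2 = accu(A % AM);
  const double varA = S_A2 - S_A * S_A / n;

  cx_cube P(t1, t2, t3, fill::zeros);
  P.subcube(0, 0, 0, m1 - 1, m2 - 1, m3 - 1) =
      cx_cube(M, AM);
  const cx_cube F = fft3(P, false);
  const cx_cube C1 = fft3(conj(F) % FB, true);   // re: M*B, im: -(AM)*B
  const cx_cube C2 = fft3(conj(F) % FB2, true);  // re: M*B^2

  const double tolB = 1e-9 * n * std::max(mean_sq, 1e-300);
  cube cc(v1, v2, v3);
  for (uword k = 0; k < v3; ++k)
    for (uword j = 0; j < v2; ++j)
      for (uword i = 0; i < v1; ++i) {
        const double S_B = C1(i, j, k).real();
        const double S_AB = -C1(i, j, k).imag();
        const double S_B2 = C2(i, j, k).real();
        const double varB = S_B2 - S_B * S_B / n;
        double v = 0.0;
        if (varA > 0 && varB > tolB) {
          v = (S_AB - S_A * S_B / n) / std::sqrt(varA * varB);
          if (v > 1.0) v = 1.0;
          if (v < -1.0) v = -1.0;
        }
        cc(i, j, k) = v;
      }
  return Rcpp::List::create(Rcpp::Named("cc") = cc,
                            Rcpp::Named("n_mask") = n);
}

// Plain masked Pearson correlation between two equally sized cubes.
// [[Rcpp::export]]
double cpp_pearson(const arma::cube &A, const arma::cube &B,
                   const arma::cube &M) {
  const double n = accu(M);
  if (n < 2) return NA_REAL;
  const cube AM = A % M, BM = B % M;
  const double sa = accu(AM), sb = accu(BM);
  const double saa = accu(A % AM), sbb = accu(B % BM), sab = accu(A % BM);
  const double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return 0.0;
  double v = (sab - sa * sb / n) / std::sqrt(va * vb);
  if (v > 1.0) v = 1.0;
  if (v < -1.0) v = -1.0;
  return v;
}
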