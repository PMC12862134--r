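#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Finite-difference solver for the quasi-static potential problem
//   div( sigma grad(phi) ) = 0
// on a regular Cartesian grid (cell-centered), with Dirichlet values on
// electrode voxels and an insulating (zero normal current) outer boundary.
// Face conductivities use the harmonic mean of the two adjacent cells, which
// keeps the normal current continuous across conductivity jumps.
//
// Voxel labels: 0 = background, 1 = tumor, 2 = +V/2 electrode, 3 = -V/2.
// The linear system over the non-electrode cells is symmetric positive
// definite; it is solved with conjugate gradients preconditioned by one
// symmetric Gauss-Seidel sweep (SSOR with omega = 1).

static inline double harm(double a, double b) { return 2.0 * a * b / (a + b); }

struct Op {
  int nx, ny, nz;
  long nxy, n;
  // face weights: wx[c] couples c and c+1 (0 at the i = nx-1 layer), etc.
  std::vector<double> wx, wy, wz, diag, dinv;
  std::vector<signed char> fixed;

  Op(IntegerVector dims, const std::vector<double> &sig,
     const std::vector<signed char> &fx)
      : nx(dims[0]), ny(dims[1]), nz(dims[2]), fixed(fx) {
    nxy = (long)nx * ny;
    n = nxy * nz;
    wx.assign(n, 0.0); wy.assign(n, 0.0); wz.assign(n, 0.0);
    diag.assign(n, 0.0); dinv.assign(n, 0.0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long c = i + (long)nx * j + nxy * k;
          if (i < nx - 1) wx[c] = harm(sig[c], sig[c + 1]);
          if (j < ny - 1) wy[c] = harm(sig[c], sig[c + nx]);
          if (k < nz - 1) wz[c] = harm(sig[c], sig[c + nxy]);
        }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long c = i + (long)nx * j + nxy * k;
          if (fixed[c]) continue;
          double d = 0.0;
          if (i > 0) d += wx[c - 1];
          if (i < nx - 1) d += wx[c];
          if (j > 0) d += wy[c - nx];
          if (j < ny - 1) d += wy[c];
          if (k > 0) d += wz[c - nxy];
          if (k < nz - 1) d += wz[c];
          diag[c] = d;
          dinv[c] = d > 0 ? 1.0 / d : 0.0;
        }
  }

  // y <- A x over free cells (fixed cells of x are ignored; y there is 0)
  void apply(const std::vector<double> &x, std::vector<double> &y) const {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        long base = (long)nx * j + nxy * k;
        for (int i = 0; i < nx; ++i) {
          long c = base + i;
          if (fixed[c]) { y[c] = 0.0; continue; }
          double acc = diag[c] * x[c];
          long m;
          if (i > 0      && !fixed[m = c - 1])   acc -= wx[m] * x[m];
          if (i < nx - 1 && !fixed[m = c + 1])   acc -= wx[c] * x[m];
          if (j > 0      && !fixed[m = c - nx])  acc -= wy[m] * x[m];
          if (j < ny - 1 && !fixed[m = c + nx])  acc -= wy[c] * x[m];
          if (k > 0      && !fixed[m = c - nxy]) acc -= wz[m] * x[m];
          if (k < nz - 1 && !fixed[m = c + nxy]) acc -= wz[c] * x[m];
          y[c] = acc;
        }
      }
  }

  // z <- M^-1 r with M the SSOR(1) preconditioner:
  // forward (D+L) u = r, then v = D u, then backward (D+U) z = v
  void precondition(const std::vector<double> &r, std::vector<double> &z,
                    std::vector<double> &u) const {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        long base = (long)nx * j + nxy * k;
        for (int i = 0; i < nx; ++i) {
          long c = base + i;
          if (fixed[c]) { u[c] = 0.0; continue; }
          double acc = r[c];
          long m;
          if (i > 0 && !fixed[m = c - 1])   acc += wx[m] * u[m];
          if (j > 0 && !fixed[m = c - nx])  acc += wy[m] * u[m];
          if (k > 0 && !fixed[m = c - nxy]) acc += wz[m] * u[m];
          u[c] = acc * dinv[c];
        }
      }
    for (int k = nz - 1; k >= 0; --k)
      for (int j = ny - 1; j >= 0; --j) {
        long base = (long)nx * j + nxy * k;
        for (int i = nx - 1; i >= 0; --i) {
          long c = base + i;
          if (fixed[c]) { z[c] = 0.0; continue; }
          double acc = diag[c] * u[c];
          long m;
          if (i < nx - 1 && !fixed[m = c + 1])   acc += wx[c] * z[m];
          if (j < ny - 1 && !fixed[m = c + nx])  acc += wy[c] * z[m];
          if (k < nz - 1 && !fixed[m = c + nxy]) acc += wz[c] * z[m];
          z[c] = acc * dinv[c];
        }
      }
  }
};

// [[Rcpp::export(name = ".fd_solve_potential")]]
List fd_solve_potential(IntegerVector labels, NumericVector sigma,
                        IntegerVector dims, double voltage,
                        double tol, int max_iter) {
  long n = (long)dims[0] * dims[1] * dims[2];
  if ((long)labels.size() != n || (long)sigma.size() != n)
    stop("labels/sigma length does not match grid dims");

  std::vector<double> sig(n);
  std::vector<signed char> fixed(n, 0);
  std::vector<double> phi(n, 0.0);
  bool any_plus = false, any_minus = false;
  for (long c = 0; c < n; ++c) {
    sig[c] = sigma[c];
    if (sig[c] <= 0) stop("non-positive conductivity voxel");
    int lab = labels[c];
    if (lab == 2) { fixed[c] = 1; phi[c] = voltage / 2.0; any_plus = true; }
    else if (lab == 3) { fixed[c] = 1; phi[c] = -voltage / 2.0; any_minus = true; }
  }
  if (voltage != 0.0 && (!any_plus || !any_minus))
    stop("electrode voxel sets must be nonempty when voltage > 0");

  Op A(dims, sig, fixed);

  // b = -A_fixed * phi_fixed: Dirichlet neighbours feed the RHS
  std::vector<double> b(n, 0.0);
  const int nx = A.nx, ny = A.ny, nz = A.nz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long c = i + (long)nx * j + A.nxy * k;
        if (fixed[c]) continue;
        double acc = 0.0;
        long m;
        if (i > 0      && fixed[m = c - 1])     acc += A.wx[m] * phi[m];
        if (i < nx - 1 && fixed[m = c + 1])     acc += A.wx[c] * phi[m];
        if (j > 0      && fixed[m = c - nx])    acc += A.wy[m] * phi[m];
        if (j < ny - 1 && fixed[m = c + nx])    acc += A.wy[c] * phi[m];
        if (k > 0      && fixed[m = c - A.nxy]) acc += A.wz[m] * phi[m];
        if (k < nz - 1 && fixed[m = c + A.nxy]) acc += A.wz[c] * phi[m];
        b[c] = acc;
      }

  double bnorm = 0.0;
  for (long c = 0; c < n; ++c) bnorm += b[c] * b[c];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    NumericVector out(n);
    for (long c = 0; c < n; ++c) out[c] = phi[c];
    return List::create(_["phi"] = out, _["iterations"] = 0,
                        _["relative_residual"] = 0.0);
  }

  std::vector<double> x(n, 0.0), r(b), z(n, 0.0), u(n, 0.0), p(n), Ap(n);
  A.precondition(r, z, u);
  p = z;
  double rz = 0.0;
  for (long c = 0; c < n; ++c) rz += r[c] * z[c];
  double relres = 1.0;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    A.apply(p, Ap);
    double pAp = 0.0;
    for (long c = 0; c < n; ++c) pAp += p[c] * Ap[c];
    if (pAp <= 0) break;
    double alpha = rz / pAp;
    double rnorm = 0.0;
    for (long c = 0; c < n; ++c) {
      x[c] += alpha * p[c];
      r[c] -= alpha * Ap[c];
      rnorm += r[c] * r[c];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres <= tol) break;
    A.precondition(r, z, u);
    double rz_new = 0.0;
    for (long c = 0; c < n; ++c) rz_new += r[c] * z[c];
    double beta = rz_new / rz;
    rz = rz_new;
    for (long c = 0; c < n; ++c) p[c] = z[c] + beta * p[c];
  }

  NumericVector out(n);
  for (long c = 0; c < n; ++c) out[c] = fixed[c] ? phi[c] : x[c];
  return List::create(_["phi"] = out, _["iterations"] = it,
                      _["relative_residual"] = relres);
}

// |grad(phi)| by central differences (one-sided at the boundary), in units of
// potential per grid spacing; the R wrapper rescales to V/cm.
// [[Rcpp::export(name = ".fd_gradient_magnitude")]]
NumericVector fd_gradient_magnitude(NumericVector phi, IntegerVector dims,
                                    double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nxy = (long)nx * ny;
  long n = nxy * nz;
  NumericVector out(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long c = i + (long)nx * j + nxy * k;
        double gx, gy, gz;
        if (nx == 1) gx = 0;
        else if (i == 0) gx = (phi[c + 1] - phi[c]) / h;
        else if (i == nx - 1) gx = (phi[c] - phi[c - 1]) / h;
        else gx = (phi[c + 1] - phi[c - 1]) / (2 * h);
        if (ny == 1) gy = 0;
        else if (j == 0) gy = (phi[c + nx] - phi[c]) / h;
        else if (j == ny - 1) gy = (phi[c] - phi[c - nx]) / h;
        else gy = (phi[c + nx] - phi[c - nx]) / (2 * h);
        if (nz == 1) gz = 0;
        else if (k == 0) gz = (phi[c + nxy] - phi[c]) / h;
        else if (k == nz - 1) gz = (phi[c] - phi[c - nxy]) / h;
        else gz = (phi[c + nxy] - phi[c - nxy]) / (2 * h);
        out[c] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return out;
}

// Net current through the faces between one electrode's voxels and the
// surrounding free cells, using the same harmonic face weights as the
// solve operator. Only the +/- balance is asserted, so the common unit
// factor is irrelevant.
// [[Rcpp::export(name = ".fd_electrode_current")]]
double fd_electrode_current(NumericVector phi, IntegerVector labels,
                            NumericVector sigma, IntegerVector dims,
                            double h, int electrode_label) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nxy = (long)nx * ny;
  double total = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long c = i + (long)nx * j + nxy * k;
        if (labels[c] != electrode_label) continue;
        long nbrs[6];
        int nn = 0;
        if (i > 0) nbrs[nn++] = c - 1;
        if (i < nx - 1) nbrs[nn++] = c + 1;
        if (j > 0) nbrs[nn++] = c - nx;
        if (j < ny - 1) nbrs[nn++] = c + nx;
        if (k > 0) nbrs[nn++] = c - nxy;
        if (k < nz - 1) nbrs[nn++] = c + nxy;
        for (int q = 0; q < nn; ++q) {
          long m = nbrs[q];
          if (labels[m] == 2 || labels[m] == 3) continue;
          total += harm(sigma[c], sigma[m]) * (phi[c] - phi[m]) * h;
        }
      }
  return total;
}
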