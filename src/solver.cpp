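#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Matrix-free preconditioned conjugate gradient for the cell-centered
// finite-volume discretization of div(sigma grad(phi)) = -f on a regular
// grid. Face conductances (gx, gy, gz) are precomputed in R (harmonic-mean
// with optional contact-impedance term). Dirichlet cells are eliminated:
// their value enters the right-hand side, the remaining system is SPD.
//
// Index convention: cell (i,j,k) -> i + nx*(j + ny*k), 0-based.
// gx has extent (nx-1, ny, nz): gx[i,j,k] couples (i,j,k) and (i+1,j,k).

// [[Rcpp::export(name = ".fv_pcg")]]
List fv_pcg(IntegerVector dims,
            NumericVector gx, NumericVector gy, NumericVector gz,
            NumericVector diag_extra, NumericVector b,
            LogicalVector fixed, NumericVector fixed_val,
            double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  auto IX  = [&](int i, int j, int k) { return (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k); };
  auto IGX = [&](int i, int j, int k) { return (R_xlen_t)i + (nx - 1) * ((R_xlen_t)j + (R_xlen_t)ny * k); };
  auto IGY = [&](int i, int j, int k) { return (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)(ny - 1) * k); };
  auto IGZ = [&](int i, int j, int k) { return (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k); };

  // Diagonal and effective RHS (Dirichlet elimination).
  std::vector<double> diag(N, 0.0), beff(b.begin(), b.end());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t c = IX(i, j, k);
        diag[c] += diag_extra[c];
      }
  auto accumulate_face = [&](R_xlen_t a, R_xlen_t c, double g) {
    diag[a] += g; diag[c] += g;
    if (fixed[c] && !fixed[a]) beff[a] += g * fixed_val[c];
    if (fixed[a] && !fixed[c]) beff[c] += g * fixed_val[a];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx - 1; ++i)
        accumulate_face(IX(i, j, k), IX(i + 1, j, k), gx[IGX(i, j, k)]);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx; ++i)
        accumulate_face(IX(i, j, k), IX(i, j + 1, k), gy[IGY(i, j, k)]);
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        accumulate_face(IX(i, j, k), IX(i, j, k + 1), gz[IGZ(i, j, k)]);

  std::vector<double> x(N, 0.0);
  std::vector<char> fx(N);
  for (R_xlen_t c = 0; c < N; ++c) {
    fx[c] = fixed[c] ? 1 : 0;
    if (fx[c]) x[c] = fixed_val[c];
  }
  // Zero out face conductances touching fixed cells in private copies:
  // their effect is folded into diag/beff, so the matvec needs no branches.
  std::vector<double> cgx(gx.begin(), gx.end()), cgy(gy.begin(), gy.end()),
      cgz(gz.begin(), gz.end());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx - 1; ++i)
        if (fx[IX(i, j, k)] || fx[IX(i + 1, j, k)]) cgx[IGX(i, j, k)] = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx; ++i)
        if (fx[IX(i, j, k)] || fx[IX(i, j + 1, k)]) cgy[IGY(i, j, k)] = 0.0;
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (fx[IX(i, j, k)] || fx[IX(i, j, k + 1)]) cgz[IGZ(i, j, k)] = 0.0;

  // y = A * p over free cells (fixed rows are identity-zeroed).
  std::vector<double> p(N, 0.0), y(N, 0.0), r(N, 0.0), z(N, 0.0);
  const double *pgx = cgx.data(), *pgy = cgy.data(), *pgz = cgz.data();
  const char *pfx = fx.data();
  auto matvec = [&](const std::vector<double>& vin, std::vector<double>& out) {
    const double *v = vin.data();
    double *o = out.data();
    for (R_xlen_t c = 0; c < N; ++c) o[c] = pfx[c] ? 0.0 : diag[c] * v[c];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const R_xlen_t row = IX(0, j, k), grow = IGX(0, j, k);
        const double *g = pgx + grow;
        for (int i = 0; i < nx - 1; ++i) {
          const double f = g[i];
          o[row + i] -= f * v[row + i + 1];
          o[row + i + 1] -= f * v[row + i];
        }
      }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny - 1; ++j) {
        const R_xlen_t row = IX(0, j, k), grow = IGY(0, j, k);
        const double *g = pgy + grow;
        for (int i = 0; i < nx; ++i) {
          const double f = g[i];
          o[row + i] -= f * v[row + i + nx];
          o[row + i + nx] -= f * v[row + i];
        }
      }
    for (int k = 0; k < nz - 1; ++k)
      for (int j = 0; j < ny; ++j) {
        const R_xlen_t row = IX(0, j, k), grow = IGZ(0, j, k);
        const double *g = pgz + grow;
        for (int i = 0; i < nx; ++i) {
          const double f = g[i];
          o[row + i] -= f * v[row + i + sxy];
          o[row + i + sxy] -= f * v[row + i];
        }
      }
  };

  // r = beff - A x  (x starts at 0 on free cells)
  double bnorm = 0.0;
  for (R_xlen_t c = 0; c < N; ++c) {
    if (pfx[c]) { r[c] = 0.0; continue; }
    r[c] = beff[c];
    bnorm += beff[c] * beff[c];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;

  double rz = 0.0;
  for (R_xlen_t c = 0; c < N; ++c) {
    if (pfx[c]) continue;
    double d = diag[c] > 0 ? diag[c] : 1.0;
    z[c] = r[c] / d;
    p[c] = z[c];
    rz += r[c] * z[c];
  }

  double relres = 1.0;
  int it = 0;
  for (; it < maxit; ++it) {
    matvec(p, y);
    double pAp = 0.0;
    for (R_xlen_t c = 0; c < N; ++c) if (!pfx[c]) pAp += p[c] * y[c];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    double rnorm = 0.0;
    for (R_xlen_t c = 0; c < N; ++c) {
      if (pfx[c]) continue;
      x[c] += alpha * p[c];
      r[c] -= alpha * y[c];
      rnorm += r[c] * r[c];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres < tol) { ++it; break; }
    double rz_new = 0.0;
    for (R_xlen_t c = 0; c < N; ++c) {
      if (pfx[c]) continue;
      double d = diag[c] > 0 ? diag[c] : 1.0;
      z[c] = r[c] / d;
      rz_new += r[c] * z[c];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t c = 0; c < N; ++c)
      if (!pfx[c]) p[c] = z[c] + beta * p[c];
  }

  NumericVector phi(N);
  for (R_xlen_t c = 0; c < N; ++c) phi[c] = x[c];
  return List::create(_["phi"] = phi, _["relres"] = relres,
                      _["iterations"] = it, _["converged"] = relres < tol);
}
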