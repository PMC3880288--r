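#include <Rcpp.h>
using namespace Rcpp;

// Flat index helper: arrays are R column-major, 0-based here.
static inline R_xlen_t IDX(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// One explicit Euler sub-step of
//   d(phi)/dt = D lap(phi) - div(u phi) + src - snk
// on a unit-spacing lattice. 7-point Laplacian with reflected (zero-flux)
// missing neighbours at the domain faces; conservative first-order upwind
// fluxes on cell faces (face velocity = mean of adjacent cell-centred
// velocities, zero flux across the domain boundary). Dirichlet faces are
// reset to `bc` after the update when apply_bc is true. Negative values are
// clipped to zero when clip is true and the removed mass is returned.
// [[Rcpp::export]]
List fd_step_cpp(NumericVector phi, IntegerVector dims, double D,
                 Nullable<NumericVector> ux_, Nullable<NumericVector> uy_,
                 Nullable<NumericVector> uz_,
                 Nullable<NumericVector> src_, Nullable<NumericVector> snk_,
                 double dt, double bc, bool apply_bc, bool clip) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (phi.size() != n) stop("field length does not match dims");
  NumericVector out(n);
  const bool has_u = ux_.isNotNull();
  NumericVector ux, uy, uz;
  if (has_u) { ux = ux_.get(); uy = uy_.get(); uz = uz_.get(); }
  const bool has_src = src_.isNotNull(), has_snk = snk_.isNotNull();
  NumericVector src, snk;
  if (has_src) src = src_.get();
  if (has_snk) snk = snk_.get();

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t c = IDX(i, j, k, nx, ny);
        const double pc = phi[c];
        // reflected neighbours
        const double pxm = (i > 0)      ? phi[IDX(i - 1, j, k, nx, ny)] : pc;
        const double pxp = (i < nx - 1) ? phi[IDX(i + 1, j, k, nx, ny)] : pc;
        const double pym = (j > 0)      ? phi[IDX(i, j - 1, k, nx, ny)] : pc;
        const double pyp = (j < ny - 1) ? phi[IDX(i, j + 1, k, nx, ny)] : pc;
        const double pzm = (k > 0)      ? phi[IDX(i, j, k - 1, nx, ny)] : pc;
        const double pzp = (k < nz - 1) ? phi[IDX(i, j, k + 1, nx, ny)] : pc;
        double lap = pxm + pxp + pym + pyp + pzm + pzp - 6.0 * pc;
        double div = 0.0;
        if (has_u) {
          // x faces
          if (i < nx - 1) {
            double uf = 0.5 * (ux[c] + ux[IDX(i + 1, j, k, nx, ny)]);
            div += (uf > 0.0) ? uf * pc : uf * pxp;
          }
          if (i > 0) {
            double uf = 0.5 * (ux[IDX(i - 1, j, k, nx, ny)] + ux[c]);
            div -= (uf > 0.0) ? uf * pxm : uf * pc;
          }
          // y faces
          if (j < ny - 1) {
            double uf = 0.5 * (uy[c] + uy[IDX(i, j + 1, k, nx, ny)]);
            div += (uf > 0.0) ? uf * pc : uf * pyp;
          }
          if (j > 0) {
            double uf = 0.5 * (uy[IDX(i, j - 1, k, nx, ny)] + uy[c]);
            div -= (uf > 0.0) ? uf * pym : uf * pc;
          }
          // z faces
          if (k < nz - 1) {
            double uf = 0.5 * (uz[c] + uz[IDX(i, j, k + 1, nx, ny)]);
            div += (uf > 0.0) ? uf * pc : uf * pzp;
          }
          if (k > 0) {
            double uf = 0.5 * (uz[IDX(i, j, k - 1, nx, ny)] + uz[c]);
            div -= (uf > 0.0) ? uf * pzm : uf * pc;
          }
        }
        double rhs = D * lap - div;
        if (has_src) rhs += src[c];
        if (has_snk) rhs -= snk[c];
        out[c] = pc + dt * rhs;
      }
    }
  }
  if (apply_bc) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        out[IDX(0, j, k, nx, ny)] = bc;
        out[IDX(nx - 1, j, k, nx, ny)] = bc;
      }
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        out[IDX(i, 0, k, nx, ny)] = bc;
        out[IDX(i, ny - 1, k, nx, ny)] = bc;
      }
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        out[IDX(i, j, 0, nx, ny)] = bc;
        out[IDX(i, j, nz - 1, nx, ny)] = bc;
      }
  }
  double clipped = 0.0;
  if (clip) {
    for (R_xlen_t t = 0; t < n; ++t)
      if (out[t] < 0.0) { clipped -= out[t]; out[t] = 0.0; }
  }
  out.attr("dim") = dims;
  return List::create(_["field"] = out, _["clipped"] = clipped);
}

// Separable sliding-window sum: out(v) = sum of occ over the K-cube centred
// at v, truncated at the boundary (points outside the domain count as 0).
// [[Rcpp::export]]
NumericVector box_sum_cpp(NumericVector occ, IntegerVector dims, int K) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (occ.size() != n) stop("field length does not match dims");
  NumericVector a(clone(occ)), b(n);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        int lo = std::max(0, i - K), hi = std::min(nx - 1, i + K);
        for (int t = lo; t <= hi; ++t) s += a[IDX(t, j, k, nx, ny)];
        b[IDX(i, j, k, nx, ny)] = s;
      }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        double s = 0.0;
        int lo = std::max(0, j - K), hi = std::min(ny - 1, j + K);
        for (int t = lo; t <= hi; ++t) s += b[IDX(i, t, k, nx, ny)];
        a[IDX(i, j, k, nx, ny)] = s;
      }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      for (int k = 0; k < nz; ++k) {
        double s = 0.0;
        int lo = std::max(0, k - K), hi = std::min(nz - 1, k + K);
        for (int t = lo; t <= hi; ++t) s += a[IDX(i, j, t, nx, ny)];
        b[IDX(i, j, k, nx, ny)] = s;
      }
  b.attr("dim") = dims;
  return b;
}

// Tabulated Gaussian-like kernel accumulation. The occupancy fraction at a
// target voxel takes one of (2K+1)^3 + 1 discrete levels and the squared
// lattice distance to a source within the K-cube is at most 3K^2, so the
// kernel weight rho(theta) * exp(-d^2 / (2 lambda(theta)^2)) is fully
// described by the (levels x distances) table W. level holds the occupancy
// count at each voxel; pos holds 1-based source positions.
// [[Rcpp::export]]
NumericVector kernel_scatter_tab_cpp(IntegerMatrix pos, IntegerVector level,
                                     NumericMatrix W, int K,
                                     IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (level.size() != n) stop("level field length does not match dims");
  if (W.ncol() < 3 * K * K + 1) stop("weight table has too few distance columns");
  NumericVector out(n);
  const int m = pos.nrow();
  const int nlev = W.nrow();
  for (int s = 0; s < m; ++s) {
    const int cx = pos(s, 0) - 1, cy = pos(s, 1) - 1, cz = pos(s, 2) - 1;
    if (cx < 0 || cy < 0 || cz < 0 || cx >= nx || cy >= ny || cz >= nz)
      stop("source position out of bounds");
    for (int dz = -K; dz <= K; ++dz) {
      const int z = cz + dz;
      if (z < 0 || z >= nz) continue;
      for (int dy = -K; dy <= K; ++dy) {
        const int y = cy + dy;
        if (y < 0 || y >= ny) continue;
        const R_xlen_t base = (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
        const int d2yz = dy * dy + dz * dz;
        const int xlo = std::max(0, cx - K), xhi = std::min(nx - 1, cx + K);
        for (int x = xlo; x <= xhi; ++x) {
          const R_xlen_t t = base + x;
          const int lev = level[t];
          if (lev <= 0 || lev >= nlev) {
            if (lev >= nlev) stop("occupancy level outside weight table");
            continue;
          }
          const int dx = x - cx;
          out[t] += W(lev, d2yz + dx * dx);
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Gaussian-like pressure kernel accumulation. For every source position X_i
// (rows of pos, 1-based lattice indices) add, at every target X0 within the
// K-cube of X_i,
//   rho(X0) * exp(-d(X_i, X0)^2 / (2 lam(X0)^2))
// where rho and lam are precomputed per-target fields (functions of the local
// occupancy fraction). Summation over sources within the K-cube of X0 is the
// same set by symmetry of the Chebyshev ball.
// [[Rcpp::export]]
NumericVector kernel_scatter_cpp(IntegerMatrix pos, NumericVector rho,
                                 NumericVector lam, int K, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (rho.size() != n || lam.size() != n) stop("field length does not match dims");
  NumericVector out(n);
  const int m = pos.nrow();
  for (int s = 0; s < m; ++s) {
    const int cx = pos(s, 0) - 1, cy = pos(s, 1) - 1, cz = pos(s, 2) - 1;
    if (cx < 0 || cy < 0 || cz < 0 || cx >= nx || cy >= ny || cz >= nz)
      stop("source position out of bounds");
    for (int dz = -K; dz <= K; ++dz) {
      const int z = cz + dz;
      if (z < 0 || z >= nz) continue;
      for (int dy = -K; dy <= K; ++dy) {
        const int y = cy + dy;
        if (y < 0 || y >= ny) continue;
        for (int dx = -K; dx <= K; ++dx) {
          const int x = cx + dx;
          if (x < 0 || x >= nx) continue;
          const R_xlen_t t = IDX(x, y, z, nx, ny);
          const double l = lam[t];
          if (l <= 0.0) continue;
          const double d2 = (double)(dx * dx + dy * dy + dz * dz);
          out[t] += rho[t] * std::exp(-d2 / (2.0 * l * l));
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
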