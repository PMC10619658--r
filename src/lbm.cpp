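#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// D3Q27 velocity set. Direction a (0..26) has components
// c = (a%3-1, (a/3)%3-1, (a/9)%3-1); the opposite direction is 26-a.
static inline int cx(int a) { return a % 3 - 1; }
static inline int cy(int a) { return (a / 3) % 3 - 1; }
static inline int cz(int a) { return (a / 9) % 3 - 1; }

static double d3q27_w(int a) {
  int s = cx(a) * cx(a) + cy(a) * cy(a) + cz(a) * cz(a);
  switch (s) {
  case 0: return 8.0 / 27.0;
  case 1: return 2.0 / 27.0;
  case 2: return 1.0 / 54.0;
  default: return 1.0 / 216.0;
  }
}

// [[Rcpp::export]]
List d3q27_set() {
  IntegerMatrix K(27, 3);
  NumericVector w(27);
  for (int a = 0; a < 27; ++a) {
    K(a, 0) = cx(a); K(a, 1) = cy(a); K(a, 2) = cz(a);
    w[a] = d3q27_w(a);
  }
  return List::create(_["K"] = K, _["w"] = w, _["c_s2"] = 1.0 / 3.0);
}

static inline double feq_a(int a, double rho, double ux, double uy, double uz,
                           double usq) {
  double cu = cx(a) * ux + cy(a) * uy + cz(a) * uz;
  return d3q27_w(a) * rho * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * usq);
}

// Second-order equilibrium for each node: rho (n), u (n x 3) -> f (n x 27)
// [[Rcpp::export]]
NumericMatrix lbm_equilibrium(NumericVector rho, NumericMatrix u) {
  int n = rho.size();
  NumericMatrix f(n, 27);
  for (int i = 0; i < n; ++i) {
    if (rho[i] <= 0) stop("non-positive density at node %d", i + 1);
    double ux = u(i, 0), uy = u(i, 1), uz = u(i, 2);
    double usq = ux * ux + uy * uy + uz * uz;
    for (int a = 0; a < 27; ++a) f(i, a) = feq_a(a, rho[i], ux, uy, uz, usq);
  }
  return f;
}

// Macroscopic density and velocity; u gets the half-force correction when a
// body force is active: u = (sum f c + F/2) / rho. Column-wise sweeps keep
// the access sequential.
// [[Rcpp::export]]
List lbm_macroscopics(NumericMatrix f, Nullable<NumericMatrix> force_) {
  int n = f.nrow();
  NumericVector rho(n);
  NumericMatrix u(n, 3);
  bool hasF = force_.isNotNull();
  NumericMatrix F;
  if (hasF) F = NumericMatrix(force_);
  double *rp = REAL(rho), *ux = REAL(u), *uy = ux + n, *uz = uy + n;
  for (int a = 0; a < 27; ++a) {
    const double *fa = &f(0, a);
    double ex = cx(a), ey = cy(a), ez = cz(a);
    for (int i = 0; i < n; ++i) {
      rp[i] += fa[i];
      ux[i] += fa[i] * ex; uy[i] += fa[i] * ey; uz[i] += fa[i] * ez;
    }
  }
  for (int i = 0; i < n; ++i) {
    if (rp[i] <= 0) stop("non-positive density at node %d", i + 1);
    if (hasF) {
      ux[i] += 0.5 * F(i, 0); uy[i] += 0.5 * F(i, 1); uz[i] += 0.5 * F(i, 2);
    }
    ux[i] /= rp[i]; uy[i] /= rp[i]; uz[i] /= rp[i];
  }
  return List::create(_["rho"] = rho, _["u"] = u);
}

// BGK collision with per-node relaxation time and Guo forcing, in place.
// Direction-outer sweeps keep memory access sequential.
// [[Rcpp::export]]
void lbm_collide(NumericMatrix f, NumericVector rho, NumericMatrix u,
                 NumericVector tau, Nullable<NumericMatrix> force_) {
  int n = f.nrow();
  bool hasF = force_.isNotNull();
  NumericMatrix F;
  if (hasF) F = NumericMatrix(force_);
  const double *rp = REAL(rho), *tp = REAL(tau);
  const double *ux = REAL(u), *uy = ux + n, *uz = uy + n;
  const double *Fx = 0, *Fy = 0, *Fz = 0;
  if (hasF) { Fx = REAL(F); Fy = Fx + n; Fz = Fy + n; }
  for (int i = 0; i < n; ++i)
    if (tp[i] <= 0.5)
      stop("relaxation time tau <= 0.5 at node %d (unstable)", i + 1);
  for (int a = 0; a < 27; ++a) {
    double *fa = &f(0, a);
    double ex = cx(a), ey = cy(a), ez = cz(a);
    double w = d3q27_w(a);
    for (int i = 0; i < n; ++i) {
      double om = 1.0 / tp[i];
      double cu = ex * ux[i] + ey * uy[i] + ez * uz[i];
      double usq = ux[i] * ux[i] + uy[i] * uy[i] + uz[i] * uz[i];
      double fe = w * rp[i] * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * usq);
      double S = 0;
      if (hasF) {
        S = (1.0 - 0.5 * om) * w *
          (3.0 * ((ex - ux[i]) * Fx[i] + (ey - uy[i]) * Fy[i] +
                  (ez - uz[i]) * Fz[i]) +
           9.0 * cu * (ex * Fx[i] + ey * Fy[i] + ez * Fz[i]));
      }
      fa[i] += -om * (fa[i] - fe) + S;
    }
  }
}

// Pull-scheme streaming with periodic wrap and half-way bounce-back at wall
// (flag 3) and solid (flag 4) nodes. flags: 0 fluid, 1 inlet, 2 outflow.
// [[Rcpp::export]]
void lbm_stream(NumericMatrix fpost, NumericMatrix fnew, IntegerVector flags,
                IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (fpost.nrow() != n || fnew.nrow() != n) stop("field/dims mismatch");
  const int *fl = INTEGER(flags);
  bool anyWall = false;
  for (int i = 0; i < n; ++i)
    if (fl[i] >= 3) { anyWall = true; break; }
  for (int a = 0; a < 27; ++a) {
    const double *src = &fpost(0, a);
    const double *opp = &fpost(0, 26 - a);
    double *dst = &fnew(0, a);
    int dx = cx(a), dy = cy(a), dz = cz(a);
    for (int z = 0; z < nz; ++z) {
      int sz = (z - dz + nz) % nz;
      for (int y = 0; y < ny; ++y) {
        int sy = (y - dy + ny) % ny;
        int rowi = nx * (y + ny * z), rows = nx * (sy + ny * sz);
        if (!anyWall && dx == 0) {
          std::copy(src + rows, src + rows + nx, dst + rowi);
          continue;
        }
        for (int x = 0; x < nx; ++x) {
          int i = x + rowi;
          if (fl[i] >= 3) { dst[i] = src[i]; continue; }  // wall keeps values
          int sx = (x - dx + nx) % nx;
          int s = sx + rows;
          if (fl[s] >= 3)
            dst[i] = opp[i];                // bounce back off the wall
          else
            dst[i] = src[s];
        }
      }
    }
  }
}

// Inlet: prescribed-velocity equilibrium refill. Outflow: zero-gradient copy
// from the nearest interior neighbour (directions scanned by increasing |c|).
// [[Rcpp::export]]
void lbm_apply_bc(NumericMatrix f, IntegerVector flags, IntegerVector dims,
                  NumericVector u_inlet, double rho_inlet) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double ux = u_inlet[0], uy = u_inlet[1], uz = u_inlet[2];
  double usq = ux * ux + uy * uy + uz * uz;
  // neighbour scan order: face, edge, corner directions
  std::vector<int> order;
  for (int s = 1; s <= 3; ++s)
    for (int a = 0; a < 27; ++a)
      if (cx(a) * cx(a) + cy(a) * cy(a) + cz(a) * cz(a) == s)
        order.push_back(a);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = x + nx * (y + ny * z);
        if (flags[i] == 1) {
          for (int a = 0; a < 27; ++a)
            f(i, a) = feq_a(a, rho_inlet, ux, uy, uz, usq);
        } else if (flags[i] == 2) {
          for (size_t k = 0; k < order.size(); ++k) {
            int a = order[k];
            int sx_ = x + cx(a), sy_ = y + cy(a), sz_ = z + cz(a);
            if (sx_ < 0 || sx_ >= nx || sy_ < 0 || sy_ >= ny ||
                sz_ < 0 || sz_ >= nz) continue;
            int s = sx_ + nx * (sy_ + ny * sz_);
            if (flags[s] == 0) {
              for (int a2 = 0; a2 < 27; ++a2) f(i, a2) = f(s, a2);
              break;
            }
          }
        }
      }
}

// Velocity gradient tensor g[a][b] = d u_a / d x_b by central differences
// (one-sided at non-periodic boundaries). Output n x 9, column a + 3*b.
// [[Rcpp::export]]
NumericMatrix lbm_velocity_gradient(NumericMatrix u, IntegerVector dims,
                                    double dx, bool periodic) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (nx < 3 || ny < 3 || nz < 3) stop("grid must be at least 3 nodes per axis");
  NumericMatrix g(n, 9);
  int str[3] = {1, nx, nx * ny};
  int ext[3] = {nx, ny, nz};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = x + nx * (y + ny * z);
        int pos[3] = {x, y, z};
        for (int b = 0; b < 3; ++b) {
          int ip, im; double denom;
          if (periodic) {
            int pp = (pos[b] + 1) % ext[b], pm = (pos[b] - 1 + ext[b]) % ext[b];
            ip = i + (pp - pos[b]) * str[b];
            im = i + (pm - pos[b]) * str[b];
            denom = 2.0 * dx;
          } else if (pos[b] == 0) {
            ip = i + str[b]; im = i; denom = dx;
          } else if (pos[b] == ext[b] - 1) {
            ip = i; im = i - str[b]; denom = dx;
          } else {
            ip = i + str[b]; im = i - str[b]; denom = 2.0 * dx;
          }
          for (int a = 0; a < 3; ++a)
            g(i, a + 3 * b) = (u(ip, a) - u(im, a)) / denom;
        }
      }
  return g;
}

// WALE eddy viscosity from the velocity-gradient tensor:
//   nu_t = (Bw*Delta)^2 (Sd:Sd)^{3/2} / ((S:S)^{5/2} + (Sd:Sd)^{5/4})
// with S the symmetric gradient and Sd the traceless symmetric part of g^2.
// [[Rcpp::export]]
NumericVector wale_viscosity_cpp(NumericMatrix g, double Bw, double Delta) {
  int n = g.nrow();
  NumericVector nut(n);
  double pref = Bw * Delta * Bw * Delta;
  for (int i = 0; i < n; ++i) {
    double G[3][3], G2[3][3], S, Sd;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) G[a][b] = g(i, a + 3 * b);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = 0;
        for (int r = 0; r < 3; ++r) s += G[a][r] * G[r][b];
        G2[a][b] = s;
      }
    double tr = G2[0][0] + G2[1][1] + G2[2][2];
    S = Sd = 0;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double Sab = 0.5 * (G[a][b] + G[b][a]);
        double Sdab = 0.5 * (G2[a][b] + G2[b][a]) - (a == b ? tr / 3.0 : 0.0);
        S += Sab * Sab;
        Sd += Sdab * Sdab;
      }
    double denom = std::pow(S, 2.5) + std::pow(Sd, 1.25);
    nut[i] = denom > 0 ? pref * std::pow(Sd, 1.5) / denom : 0.0;
  }
  return nut;
}

// Strain rate from the non-equilibrium second moment (BGK):
//   S_ab = -(1/(2 rho c_s^2 tau)) * sum_a (f - feq) c_a c_b   (lattice units)
// [[Rcpp::export]]
NumericMatrix lbm_strain_noneq(NumericMatrix f, NumericVector rho,
                               NumericMatrix u, NumericVector tau) {
  int n = f.nrow();
  NumericMatrix S(n, 9);
  for (int i = 0; i < n; ++i) {
    double ux = u(i, 0), uy = u(i, 1), uz = u(i, 2);
    double usq = ux * ux + uy * uy + uz * uz;
    double P[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int a = 0; a < 27; ++a) {
      double dne = f(i, a) - feq_a(a, rho[i], ux, uy, uz, usq);
      int c[3] = {cx(a), cy(a), cz(a)};
      for (int p = 0; p < 3; ++p)
        for (int q = 0; q < 3; ++q) P[p][q] += dne * c[p] * c[q];
    }
    double pref = -1.0 / (2.0 * rho[i] * (1.0 / 3.0) * tau[i]);
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q) S(i, p + 3 * q) = pref * 0.5 * (P[p][q] + P[q][p]);
  }
  return S;
}

// Vorticity (curl of u) magnitude via the same difference stencils.
// [[Rcpp::export]]
NumericVector vorticity_cpp(NumericMatrix u, IntegerVector dims, double dx,
                            bool periodic) {
  NumericMatrix g = lbm_velocity_gradient(u, dims, dx, periodic);
  int n = g.nrow();
  NumericVector w(n);
  for (int i = 0; i < n; ++i) {
    // g(i, a + 3b) = du_a/dx_b
    double wx = g(i, 2 + 3 * 1) - g(i, 1 + 3 * 2);
    double wy = g(i, 0 + 3 * 2) - g(i, 2 + 3 * 0);
    double wz = g(i, 1 + 3 * 0) - g(i, 0 + 3 * 1);
    w[i] = std::sqrt(wx * wx + wy * wy + wz * wz);
  }
  return w;
}

// Total mass (sum of all distribution values).
// [[Rcpp::export]]
double lbm_total_mass(NumericMatrix f) {
  double s = 0;
  for (int i = 0; i < f.nrow(); ++i)
    for (int a = 0; a < 27; ++a) s += f(i, a);
  return s;
}
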