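#include <Rcpp.h>
#include <cmath>
#include <map>
using namespace Rcpp;

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double a[3]) { return std::sqrt(dot3(a, a)); }

// Rest-state precomputation for a triangle shell: per-triangle 2D material
// frame inverse (for CST membrane strain) and rest area; per-hinge rest
// dihedral angle and geometry factor. tris are 0-based here.
// [[Rcpp::export]]
List shell_precompute(NumericMatrix nodes, IntegerMatrix tris) {
  int m = tris.nrow();
  NumericMatrix dminv(m, 4);   // column-major 2x2 per triangle
  NumericVector area0(m);
  for (int t = 0; t < m; ++t) {
    int i0 = tris(t, 0), i1 = tris(t, 1), i2 = tris(t, 2);
    double u1[3], u2[3];
    for (int d = 0; d < 3; ++d) {
      u1[d] = nodes(i1, d) - nodes(i0, d);
      u2[d] = nodes(i2, d) - nodes(i0, d);
    }
    double n[3];
    cross3(u1, u2, n);
    double A = 0.5 * norm3(n);
    area0[t] = A;
    if (A <= 0) stop("degenerate rest triangle %d", t + 1);
    double l1 = norm3(u1);
    double e1[3] = {u1[0] / l1, u1[1] / l1, u1[2] / l1};
    double nn = norm3(n);
    double nz[3] = {n[0] / nn, n[1] / nn, n[2] / nn};
    double e2[3];
    cross3(nz, e1, e2);
    // material coordinates Dm = [[u1.e1, u2.e1], [0, u2.e2]]
    double a = dot3(u1, e1), b = dot3(u2, e1), d = dot3(u2, e2);
    double det = a * d;
    dminv(t, 0) = d / det;  dminv(t, 2) = -b / det;
    dminv(t, 1) = 0.0;      dminv(t, 3) = a / det;
  }
  // hinges: interior edges shared by exactly two triangles
  std::map<std::pair<int, int>, std::pair<int, int> > edge2tri; // edge -> (tri, opp node)
  std::vector<std::array<int, 4> > hing;
  for (int t = 0; t < m; ++t) {
    for (int e = 0; e < 3; ++e) {
      int a = tris(t, e), b = tris(t, (e + 1) % 3), o = tris(t, (e + 2) % 3);
      std::pair<int, int> key(std::min(a, b), std::max(a, b));
      auto it = edge2tri.find(key);
      if (it == edge2tri.end()) {
        edge2tri[key] = std::make_pair(o, (a < b) ? 1 : -1);
      } else {
        // first triangle stored opposite node; orientation fixed so that the
        // second triangle's opposite node is x3: hinge (x0, x1, x2, x3)
        int o1 = it->second.first;
        int x0, x1;
        if (it->second.second == 1) { x0 = key.first; x1 = key.second; }
        else { x0 = key.second; x1 = key.first; }
        hing.push_back({x0, x1, o1, o});
        edge2tri.erase(it);
      }
    }
  }
  int H = (int)hing.size();
  IntegerMatrix hinges(H, 4);
  NumericVector theta0(H), hcoef(H);
  for (int h = 0; h < H; ++h)
    for (int k = 0; k < 4; ++k) hinges(h, k) = hing[h][k];
  return List::create(_["dminv"] = dminv, _["area0"] = area0,
                      _["hinges"] = hinges, _["theta0"] = theta0,
                      _["hcoef"] = hcoef);
}

static double hinge_angle(const double x0[3], const double x1[3],
                          const double x2[3], const double x3[3],
                          double nA[3], double nB[3], double e[3]) {
  double u2[3], u3[3];
  for (int d = 0; d < 3; ++d) {
    e[d] = x1[d] - x0[d];
    u2[d] = x2[d] - x0[d];
    u3[d] = x3[d] - x0[d];
  }
  cross3(e, u2, nA);
  cross3(u3, e, nB);
  double el = norm3(e);
  double cx[3];
  cross3(nA, nB, cx);
  double s = dot3(cx, e) / (el * norm3(nA) * norm3(nB));
  double c = dot3(nA, nB) / (norm3(nA) * norm3(nB));
  return std::atan2(s, c);
}

// Rest dihedral angles and hinge stiffness coefficients; call once after
// shell_precompute. kb is the plate bending rigidity E t^3 / (12 (1 - nu^2)).
// [[Rcpp::export]]
void shell_rest_hinges(NumericMatrix nodes, IntegerMatrix hinges,
                       NumericVector theta0, NumericVector hcoef, double kb) {
  for (int h = 0; h < hinges.nrow(); ++h) {
    double x0[3], x1[3], x2[3], x3[3];
    for (int d = 0; d < 3; ++d) {
      x0[d] = nodes(hinges(h, 0), d); x1[d] = nodes(hinges(h, 1), d);
      x2[d] = nodes(hinges(h, 2), d); x3[d] = nodes(hinges(h, 3), d);
    }
    double nA[3], nB[3], e[3];
    theta0[h] = hinge_angle(x0, x1, x2, x3, nA, nB, e);
    double el2 = dot3(e, e);
    double A = 0.5 * (norm3(nA) + norm3(nB));   // combined area of both triangles
    // flexural hinge stiffness, calibrated so the summed hinge energy of a
    // regular criss-cross strip reproduces the continuum plate energy
    // (kb/2) kappa^2 per unit area under cylindrical bending
    hcoef[h] = kb * el2 / A;
  }
}

// Internal elastic forces: Saint Venant-Kirchhoff constant-strain-triangle
// membrane (plane stress) plus discrete-hinge bending. Returns n x 3 forces.
// [[Rcpp::export]]
NumericMatrix shell_internal_forces(NumericMatrix nodes, IntegerMatrix tris,
                                    NumericMatrix dminv, NumericVector area0,
                                    IntegerMatrix hinges, NumericVector theta0,
                                    NumericVector hcoef,
                                    double E, double nu, double thickness) {
  int n = nodes.nrow(), m = tris.nrow();
  NumericMatrix F(n, 3);
  double mu = E / (2.0 * (1.0 + nu));
  double lam = E * nu / (1.0 - nu * nu);
  for (int t = 0; t < m; ++t) {
    int i0 = tris(t, 0), i1 = tris(t, 1), i2 = tris(t, 2);
    double d1[3], d2[3];
    for (int d = 0; d < 3; ++d) {
      d1[d] = nodes(i1, d) - nodes(i0, d);
      d2[d] = nodes(i2, d) - nodes(i0, d);
    }
    // deformation gradient Fg (3x2) = Ds * Dm^-1
    double a = dminv(t, 0), b = dminv(t, 2), c = dminv(t, 1), dd = dminv(t, 3);
    double Fg[3][2];
    for (int d = 0; d < 3; ++d) {
      Fg[d][0] = d1[d] * a + d2[d] * c;
      Fg[d][1] = d1[d] * b + d2[d] * dd;
    }
    // Green strain (2x2)
    double C00 = 0, C01 = 0, C11 = 0;
    for (int d = 0; d < 3; ++d) {
      C00 += Fg[d][0] * Fg[d][0];
      C01 += Fg[d][0] * Fg[d][1];
      C11 += Fg[d][1] * Fg[d][1];
    }
    double E00 = 0.5 * (C00 - 1.0), E01 = 0.5 * C01, E11 = 0.5 * (C11 - 1.0);
    double trE = E00 + E11;
    // 2nd Piola-Kirchhoff stress
    double S00 = lam * trE + 2.0 * mu * E00;
    double S01 = 2.0 * mu * E01;
    double S11 = lam * trE + 2.0 * mu * E11;
    // P = Fg * S ; nodal forces f = -V * P * Dm^-T
    double V = area0[t] * thickness;
    for (int d = 0; d < 3; ++d) {
      double P0 = Fg[d][0] * S00 + Fg[d][1] * S01;
      double P1 = Fg[d][0] * S01 + Fg[d][1] * S11;
      double f1 = -V * (P0 * a + P1 * b);
      double f2 = -V * (P0 * c + P1 * dd);
      F(i1, d) += f1;
      F(i2, d) += f2;
      F(i0, d) -= f1 + f2;
    }
  }
  // bending
  for (int h = 0; h < hinges.nrow(); ++h) {
    int v0 = hinges(h, 0), v1 = hinges(h, 1), v2 = hinges(h, 2), v3 = hinges(h, 3);
    double x0[3], x1[3], x2[3], x3[3];
    for (int d = 0; d < 3; ++d) {
      x0[d] = nodes(v0, d); x1[d] = nodes(v1, d);
      x2[d] = nodes(v2, d); x3[d] = nodes(v3, d);
    }
    double nA[3], nB[3], e[3];
    double th = hinge_angle(x0, x1, x2, x3, nA, nB, e);
    double dth = th - theta0[h];
    if (dth == 0) continue;
    double el = norm3(e);
    double nA2 = dot3(nA, nA), nB2 = dot3(nB, nB);
    double pA[3], pB[3];
    for (int d = 0; d < 3; ++d) {
      pA[d] = el * nA[d] / nA2;
      pB[d] = el * nB[d] / nB2;
    }
    double u2[3], u3[3];
    for (int d = 0; d < 3; ++d) { u2[d] = x2[d] - x0[d]; u3[d] = x3[d] - x0[d]; }
    double tA = dot3(u2, e) / (el * el), tB = dot3(u3, e) / (el * el);
    double k = hcoef[h] * dth;           // -dE/dtheta with E = k/2 (th-th0)^2
    for (int d = 0; d < 3; ++d) {
      F(v0, d) -= k * ((1.0 - tA) * pA[d] + (1.0 - tB) * pB[d]);
      F(v1, d) -= k * (tA * pA[d] + tB * pB[d]);
      F(v2, d) -= k * (-pA[d]);
      F(v3, d) -= k * (-pB[d]);
    }
  }
  return F;
}

// One damped leapfrog (kick-damp-drift) step: symplectic, exact for rigid
// free fall, and mass-proportional damping strictly removes energy. Fixed
// nodes do not move. Gravity and the externally applied per-node force
// enter the acceleration; accel stores the latest evaluation (diagnostic).
// [[Rcpp::export]]
void shell_step(NumericMatrix nodes, NumericMatrix vel, NumericMatrix accel,
                NumericMatrix force_int, NumericMatrix force_ext,
                NumericVector mass, LogicalVector fixed,
                double dt, double damping, NumericVector gravity) {
  int n = nodes.nrow();
  double df = damping > 0 ? std::exp(-damping * dt) : 1.0;
  for (int i = 0; i < n; ++i) {
    if (fixed[i]) {
      for (int d = 0; d < 3; ++d) { vel(i, d) = 0; accel(i, d) = 0; }
      continue;
    }
    for (int d = 0; d < 3; ++d) {
      double a = (force_int(i, d) + force_ext(i, d)) / mass[i] + gravity[d];
      accel(i, d) = a;
      vel(i, d) = (vel(i, d) + dt * a) * df;
      nodes(i, d) += dt * vel(i, d);
    }
  }
}

// Lumped nodal mass: one third of each incident triangle's mass.
// [[Rcpp::export]]
NumericVector shell_lumped_mass(NumericMatrix nodes, IntegerMatrix tris,
                                double rho, double thickness) {
  int n = nodes.nrow();
  NumericVector mass(n);
  for (int t = 0; t < tris.nrow(); ++t) {
    double u1[3], u2[3], nrm[3];
    int i0 = tris(t, 0), i1 = tris(t, 1), i2 = tris(t, 2);
    for (int d = 0; d < 3; ++d) {
      u1[d] = nodes(i1, d) - nodes(i0, d);
      u2[d] = nodes(i2, d) - nodes(i0, d);
    }
    cross3(u1, u2, nrm);
    double mt = rho * thickness * 0.5 * norm3(nrm) / 3.0;
    mass[i0] += mt; mass[i1] += mt; mass[i2] += mt;
  }
  return mass;
}

// Smallest edge length (explicit stability estimate input).
// [[Rcpp::export]]
double shell_min_edge(NumericMatrix nodes, IntegerMatrix tris) {
  double mn = R_PosInf;
  for (int t = 0; t < tris.nrow(); ++t)
    for (int e = 0; e < 3; ++e) {
      int a = tris(t, e), b = tris(t, (e + 1) % 3);
      double s = 0;
      for (int d = 0; d < 3; ++d) {
        double dd = nodes(a, d) - nodes(b, d);
        s += dd * dd;
      }
      mn = std::min(mn, std::sqrt(s));
    }
  return mn;
}
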