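#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Roma-Peskin smoothed 3-point immersed-boundary kernel; partition of unity
// over the integer lattice.
static inline double phi3(double r) {
  double a = std::fabs(r);
  if (a <= 0.5) return (1.0 + std::sqrt(1.0 - 3.0 * r * r)) / 3.0;
  if (a <= 1.5) return (5.0 - 3.0 * a - std::sqrt(-2.0 + 6.0 * a - 3.0 * r * r)) / 6.0;
  return 0.0;
}

// [[Rcpp::export]]
double ib_phi3(double r) { return phi3(r); }

// Sum of kernel weights for each marker (diagnostic; 1 inside the domain).
// [[Rcpp::export]]
NumericVector ib_weight_sums(NumericMatrix markers, IntegerVector dims) {
  int m = markers.nrow();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    double s = 1.0;
    for (int d = 0; d < 3; ++d) {
      double X = markers(k, d);
      int base = (int)std::lround(X);
      double sd = 0;
      for (int o = -1; o <= 1; ++o) {
        int i = base + o;
        if (i < 0 || i >= dims[d]) continue;
        sd += phi3(X - i);
      }
      s *= sd;
    }
    out[k] = s;
  }
  return out;
}

static void check_marker(const NumericMatrix &markers, int k,
                         const IntegerVector &dims) {
  for (int d = 0; d < 3; ++d) {
    double X = markers(k, d);
    if (X < 1.0 || X > dims[d] - 2.0)
      stop("immersed-boundary marker %d at (%g, %g, %g) lattice units is "
           "outside the fluid domain interior",
           k + 1, markers(k, 0), markers(k, 1), markers(k, 2));
  }
}

// Interpolate a grid field (n x k, node-ordered x fastest) at marker
// positions given in lattice coordinates.
// [[Rcpp::export]]
NumericMatrix ib_interpolate(NumericMatrix field, IntegerVector dims,
                             NumericMatrix markers) {
  int nx = dims[0], ny = dims[1];
  int m = markers.nrow(), k = field.ncol();
  NumericMatrix out(m, k);
  for (int q = 0; q < m; ++q) {
    check_marker(markers, q, dims);
    double X = markers(q, 0), Y = markers(q, 1), Z = markers(q, 2);
    int bx = (int)std::lround(X), by = (int)std::lround(Y),
        bz = (int)std::lround(Z);
    for (int oz = -1; oz <= 1; ++oz) {
      double wz = phi3(Z - (bz + oz));
      if (wz == 0) continue;
      for (int oy = -1; oy <= 1; ++oy) {
        double wy = phi3(Y - (by + oy));
        if (wy == 0) continue;
        for (int ox = -1; ox <= 1; ++ox) {
          double w = phi3(X - (bx + ox)) * wy * wz;
          if (w == 0) continue;
          int i = (bx + ox) + nx * ((by + oy) + ny * (bz + oz));
          for (int c = 0; c < k; ++c) out(q, c) += w * field(i, c);
        }
      }
    }
  }
  return out;
}

// Spread per-marker values onto the grid: out(x) += value_q * delta_h(x - X_q).
// [[Rcpp::export]]
NumericMatrix ib_spread(NumericMatrix values, NumericMatrix markers,
                        IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int m = markers.nrow(), k = values.ncol();
  NumericMatrix out(nx * ny * nz, k);
  for (int q = 0; q < m; ++q) {
    check_marker(markers, q, dims);
    double X = markers(q, 0), Y = markers(q, 1), Z = markers(q, 2);
    int bx = (int)std::lround(X), by = (int)std::lround(Y),
        bz = (int)std::lround(Z);
    for (int oz = -1; oz <= 1; ++oz) {
      double wz = phi3(Z - (bz + oz));
      if (wz == 0) continue;
      for (int oy = -1; oy <= 1; ++oy) {
        double wy = phi3(Y - (by + oy));
        if (wy == 0) continue;
        for (int ox = -1; ox <= 1; ++ox) {
          double w = phi3(X - (bx + ox)) * wy * wz;
          if (w == 0) continue;
          int i = (bx + ox) + nx * ((by + oy) + ny * (bz + oz));
          for (int c = 0; c < k; ++c) out(i, c) += w * values(q, c);
        }
      }
    }
  }
  return out;
}

// Build surface markers in barycentric space: each shell triangle is
// subdivided (longest-edge bisection on the rest geometry) until every edge
// is at most max_edge; one marker per sub-triangle centroid. Barycentric
// coordinates and area fractions transfer exactly to the deformed state.
// [[Rcpp::export]]
List ib_build_markers(NumericMatrix nodes, IntegerMatrix tris, double max_edge) {
  std::vector<int> tri_id;
  std::vector<std::array<double, 3> > bary;
  std::vector<double> frac;
  double me2 = max_edge * max_edge;
  for (int t = 0; t < tris.nrow(); ++t) {
    double P[3][3];
    for (int v = 0; v < 3; ++v)
      for (int d = 0; d < 3; ++d) P[v][d] = nodes(tris(t, v) - 1, d);
    // work stack of sub-triangles in barycentric coordinates
    std::vector<std::array<std::array<double, 3>, 3> > work;
    work.push_back({{{1, 0, 0}, {0, 1, 0}, {0, 0, 1}}});
    while (!work.empty()) {
      auto tr = work.back();
      work.pop_back();
      // map to rest space, find longest edge
      double X[3][3];
      for (int v = 0; v < 3; ++v)
        for (int d = 0; d < 3; ++d)
          X[v][d] = tr[v][0] * P[0][d] + tr[v][1] * P[1][d] + tr[v][2] * P[2][d];
      double L2[3]; int longest = 0;
      for (int e = 0; e < 3; ++e) {
        L2[e] = 0;
        for (int d = 0; d < 3; ++d) {
          double dd = X[e][d] - X[(e + 1) % 3][d];
          L2[e] += dd * dd;
        }
        if (L2[e] > L2[longest]) longest = e;
      }
      if (L2[longest] <= me2) {
        std::array<double, 3> c;
        double f2 = 0;
        for (int b = 0; b < 3; ++b)
          c[b] = (tr[0][b] + tr[1][b] + tr[2][b]) / 3.0;
        // area fraction = twice-area in barycentric space relative to parent
        double ux = tr[1][0] - tr[0][0], uy = tr[1][1] - tr[0][1];
        double vx = tr[2][0] - tr[0][0], vy = tr[2][1] - tr[0][1];
        f2 = std::fabs(ux * vy - uy * vx);
        tri_id.push_back(t + 1);
        bary.push_back(c);
        frac.push_back(f2);
        continue;
      }
      int ia = longest, ib = (longest + 1) % 3, ic = (longest + 2) % 3;
      std::array<double, 3> mid;
      for (int b = 0; b < 3; ++b) mid[b] = 0.5 * (tr[ia][b] + tr[ib][b]);
      work.push_back({tr[ia], mid, tr[ic]});
      work.push_back({mid, tr[ib], tr[ic]});
    }
  }
  int m = (int)tri_id.size();
  IntegerVector TI(m);
  NumericMatrix B(m, 3);
  NumericVector FR(m);
  for (int q = 0; q < m; ++q) {
    TI[q] = tri_id[q];
    FR[q] = frac[q];
    for (int b = 0; b < 3; ++b) B(q, b) = bary[q][b];
  }
  return List::create(_["tri_id"] = TI, _["bary"] = B, _["area_frac"] = FR);
}

// Current marker positions, velocities and areas from the deformed shell.
// [[Rcpp::export]]
List ib_marker_state(NumericMatrix nodes, NumericMatrix vel, IntegerMatrix tris,
                     IntegerVector tri_id, NumericMatrix bary,
                     NumericVector area_frac) {
  int m = tri_id.size();
  NumericMatrix pos(m, 3), mvel(m, 3);
  NumericVector area(m);
  for (int q = 0; q < m; ++q) {
    int t = tri_id[q] - 1;
    int i0 = tris(t, 0) - 1, i1 = tris(t, 1) - 1, i2 = tris(t, 2) - 1;
    double b0 = bary(q, 0), b1 = bary(q, 1), b2 = bary(q, 2);
    for (int d = 0; d < 3; ++d) {
      pos(q, d) = b0 * nodes(i0, d) + b1 * nodes(i1, d) + b2 * nodes(i2, d);
      mvel(q, d) = b0 * vel(i0, d) + b1 * vel(i1, d) + b2 * vel(i2, d);
    }
    double u1[3], u2[3];
    for (int d = 0; d < 3; ++d) {
      u1[d] = nodes(i1, d) - nodes(i0, d);
      u2[d] = nodes(i2, d) - nodes(i0, d);
    }
    double cxv = u1[1] * u2[2] - u1[2] * u2[1];
    double cyv = u1[2] * u2[0] - u1[0] * u2[2];
    double czv = u1[0] * u2[1] - u1[1] * u2[0];
    double At = 0.5 * std::sqrt(cxv * cxv + cyv * cyv + czv * czv);
    area[q] = area_frac[q] * At;
  }
  return List::create(_["pos"] = pos, _["vel"] = mvel, _["area"] = area);
}

// Accumulate per-marker forces onto shell nodes by barycentric weights.
// [[Rcpp::export]]
NumericMatrix ib_marker_to_nodes(NumericMatrix marker_force, IntegerMatrix tris,
                                 IntegerVector tri_id, NumericMatrix bary,
                                 int n_nodes) {
  NumericMatrix out(n_nodes, 3);
  for (int q = 0; q < tri_id.size(); ++q) {
    int t = tri_id[q] - 1;
    for (int v = 0; v < 3; ++v) {
      int node = tris(t, v) - 1;
      for (int d = 0; d < 3; ++d)
        out(node, d) += bary(q, v) * marker_force(q, d);
    }
  }
  return out;
}
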