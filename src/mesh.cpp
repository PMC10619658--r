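#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum of triangle areas (half cross-product norm per face). faces 1-based.
// [[Rcpp::export]]
double mesh_area_cpp(NumericMatrix v, IntegerMatrix f) {
  double area = 0;
  for (int t = 0; t < f.nrow(); ++t) {
    int i0 = f(t, 0) - 1, i1 = f(t, 1) - 1, i2 = f(t, 2) - 1;
    double ax = v(i1, 0) - v(i0, 0), ay = v(i1, 1) - v(i0, 1),
           az = v(i1, 2) - v(i0, 2);
    double bx = v(i2, 0) - v(i0, 0), by = v(i2, 1) - v(i0, 1),
           bz = v(i2, 2) - v(i0, 2);
    double cx = ay * bz - az * by, cy = az * bx - ax * bz,
           cz = ax * by - ay * bx;
    area += 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
  }
  return area;
}

// Orthographic rasterization of projected triangles. pts: already-projected
// 2D coordinates (n x 2); faces 1-based. A pixel is foreground when its
// centre lies inside (or on the edge of) any triangle. Returns width x height
// integer matrix (1 = foreground).
// [[Rcpp::export]]
IntegerMatrix raster_triangles(NumericMatrix pts, IntegerMatrix faces,
                               NumericVector bounds, int width, int height) {
  double xmin = bounds[0], xmax = bounds[1], ymin = bounds[2], ymax = bounds[3];
  double sx = (xmax - xmin) / width, sy = (ymax - ymin) / height;
  IntegerMatrix img(width, height);
  for (int t = 0; t < faces.nrow(); ++t) {
    double x0 = pts(faces(t, 0) - 1, 0), y0 = pts(faces(t, 0) - 1, 1);
    double x1 = pts(faces(t, 1) - 1, 0), y1 = pts(faces(t, 1) - 1, 1);
    double x2 = pts(faces(t, 2) - 1, 0), y2 = pts(faces(t, 2) - 1, 1);
    double area2 = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (area2 == 0) continue;
    double lo_x = std::min(x0, std::min(x1, x2)),
           hi_x = std::max(x0, std::max(x1, x2));
    double lo_y = std::min(y0, std::min(y1, y2)),
           hi_y = std::max(y0, std::max(y1, y2));
    int i0 = std::max(0, (int)std::floor((lo_x - xmin) / sx - 0.5));
    int i1 = std::min(width - 1, (int)std::ceil((hi_x - xmin) / sx));
    int j0 = std::max(0, (int)std::floor((lo_y - ymin) / sy - 0.5));
    int j1 = std::min(height - 1, (int)std::ceil((hi_y - ymin) / sy));
    double s = area2 > 0 ? 1.0 : -1.0;
    for (int j = j0; j <= j1; ++j) {
      double py = ymin + (j + 0.5) * sy;
      for (int i = i0; i <= i1; ++i) {
        double px = xmin + (i + 0.5) * sx;
        double w0 = s * ((x1 - x0) * (py - y0) - (px - x0) * (y1 - y0));
        double w1 = s * ((x2 - x1) * (py - y1) - (px - x1) * (y2 - y1));
        double w2 = s * ((x0 - x2) * (py - y2) - (px - x2) * (y0 - y2));
        if (w0 >= 0 && w1 >= 0 && w2 >= 0) img(i, j) = 1;
      }
    }
  }
  return img;
}

// Subdivide triangles until every edge is at most max_edge long. Returns the
// refined (vertices, faces) pair; used for immersed-boundary markers.
// [[Rcpp::export]]
List subdivide_to_edge(NumericMatrix v, IntegerMatrix f, double max_edge) {
  std::vector<std::array<double, 3> > verts;
  std::vector<std::array<int, 3> > tris;
  for (int i = 0; i < v.nrow(); ++i)
    verts.push_back({v(i, 0), v(i, 1), v(i, 2)});
  std::vector<std::array<int, 3> > work;
  for (int t = 0; t < f.nrow(); ++t)
    work.push_back({f(t, 0) - 1, f(t, 1) - 1, f(t, 2) - 1});
  double me2 = max_edge * max_edge;
  while (!work.empty()) {
    std::array<int, 3> tr = work.back();
    work.pop_back();
    double L2[3]; int longest = 0;
    for (int e = 0; e < 3; ++e) {
      auto &a = verts[tr[e]], &b = verts[tr[(e + 1) % 3]];
      L2[e] = 0;
      for (int d = 0; d < 3; ++d) L2[e] += (a[d] - b[d]) * (a[d] - b[d]);
      if (L2[e] > L2[longest]) longest = e;
    }
    if (L2[longest] <= me2) {
      tris.push_back(tr);
      continue;
    }
    int ia = tr[longest], ib = tr[(longest + 1) % 3], ic = tr[(longest + 2) % 3];
    std::array<double, 3> mid;
    for (int d = 0; d < 3; ++d) mid[d] = 0.5 * (verts[ia][d] + verts[ib][d]);
    int im = (int)verts.size();
    verts.push_back(mid);
    work.push_back({ia, im, ic});
    work.push_back({im, ib, ic});
  }
  NumericMatrix V((int)verts.size(), 3);
  IntegerMatrix F((int)tris.size(), 3);
  for (size_t i = 0; i < verts.size(); ++i)
    for (int d = 0; d < 3; ++d) V(i, d) = verts[i][d];
  for (size_t t = 0; t < tris.size(); ++t)
    for (int d = 0; d < 3; ++d) F(t, d) = tris[t][d] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}
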