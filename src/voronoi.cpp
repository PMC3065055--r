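#include <Rcpp.h>
using namespace Rcpp;

// Clipped planar Voronoi diagram of a set of generator points inside a
// rectangle. Each cell is built by clipping the rectangle with the
// perpendicular-bisector half-planes of nearby generators, processed in
// order of increasing distance; a generator j can no longer affect cell i
// once |ci - cj| exceeds twice the largest center-to-vertex distance of the
// current polygon (the security-radius criterion), which bounds the work
// per cell by its local neighbourhood only.

namespace {

struct BucketGrid {
  double x0, y0, gx, gy;
  int nbx, nby;
  std::vector<std::vector<int>> cells;

  BucketGrid(const std::vector<double> &x, const std::vector<double> &y,
             double xmin, double xmax, double ymin, double ymax) {
    int n = (int)x.size();
    double area = (xmax - xmin) * (ymax - ymin);
    double g = std::sqrt(2.0 * area / std::max(1, n));
    if (!(g > 0)) g = std::max(xmax - xmin, ymax - ymin);
    nbx = std::max(1, (int)std::ceil((xmax - xmin) / g));
    nby = std::max(1, (int)std::ceil((ymax - ymin) / g));
    gx = (xmax - xmin) / nbx;
    gy = (ymax - ymin) / nby;
    x0 = xmin;
    y0 = ymin;
    cells.assign((size_t)nbx * nby, {});
    for (int i = 0; i < n; ++i) {
      int bx = std::min(nbx - 1, std::max(0, (int)((x[i] - x0) / gx)));
      int by = std::min(nby - 1, std::max(0, (int)((y[i] - y0) / gy)));
      cells[(size_t)bx + (size_t)by * nbx].push_back(i);
    }
  }

  // all point indices within radius r (in the max metric over buckets) of p
  void collect(double pxq, double pyq, double r, std::vector<int> &out) const {
    out.clear();
    int bx0 = std::max(0, (int)((pxq - r - x0) / gx));
    int bx1 = std::min(nbx - 1, (int)((pxq + r - x0) / gx));
    int by0 = std::max(0, (int)((pyq - r - y0) / gy));
    int by1 = std::min(nby - 1, (int)((pyq + r - y0) / gy));
    for (int by = by0; by <= by1; ++by)
      for (int bx = bx0; bx <= bx1; ++bx)
        for (int k : cells[(size_t)bx + (size_t)by * nbx]) out.push_back(k);
  }
};

struct Poly {
  // vertex k is followed by an edge with label lab[k] (-1: domain boundary,
  // otherwise the index of the neighbour whose bisector created the edge)
  std::vector<double> vx, vy;
  std::vector<int> lab;
};

// clip convex polygon with half-plane {p : (p - m).n <= 0}; the new edge is
// labelled `who`
void clip_halfplane(Poly &p, double mx, double my, double nx_, double ny_,
                    int who) {
  const double eps = 1e-12;
  size_t n = p.vx.size();
  if (n == 0) return;
  std::vector<double> ox, oy;
  std::vector<int> ol;
  ox.reserve(n + 2);
  oy.reserve(n + 2);
  ol.reserve(n + 2);
  std::vector<double> f(n);
  for (size_t k = 0; k < n; ++k)
    f[k] = (p.vx[k] - mx) * nx_ + (p.vy[k] - my) * ny_;
  for (size_t k = 0; k < n; ++k) {
    size_t k2 = (k + 1) % n;
    double fP = f[k], fQ = f[k2];
    bool inP = fP <= eps, inQ = fQ <= eps;
    if (inP && inQ) {
      ox.push_back(p.vx[k]);
      oy.push_back(p.vy[k]);
      ol.push_back(p.lab[k]);
    } else if (inP && !inQ) {
      ox.push_back(p.vx[k]);
      oy.push_back(p.vy[k]);
      ol.push_back(p.lab[k]);
      double t = fP / (fP - fQ);
      ox.push_back(p.vx[k] + t * (p.vx[k2] - p.vx[k]));
      oy.push_back(p.vy[k] + t * (p.vy[k2] - p.vy[k]));
      ol.push_back(who);
    } else if (!inP && inQ) {
      double t = fP / (fP - fQ);
      ox.push_back(p.vx[k] + t * (p.vx[k2] - p.vx[k]));
      oy.push_back(p.vy[k] + t * (p.vy[k2] - p.vy[k]));
      ol.push_back(p.lab[k]);
    }
  }
  p.vx.swap(ox);
  p.vy.swap(oy);
  p.lab.swap(ol);
}

double max_r2_from(const Poly &p, double cx, double cy) {
  double m = 0;
  for (size_t k = 0; k < p.vx.size(); ++k) {
    double dx = p.vx[k] - cx, dy = p.vy[k] - cy;
    m = std::max(m, dx * dx + dy * dy);
  }
  return m;
}

} // namespace

// [[Rcpp::export]]
List voronoi_cpp(NumericVector x, NumericVector y, double xmin, double xmax,
                 double ymin, double ymax) {
  int n = x.size();
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  BucketGrid grid(xs, ys, xmin, xmax, ymin, ymax);
  double diag = std::hypot(xmax - xmin, ymax - ymin);

  List polys(n), nbrs(n);
  NumericVector areas(n);
  std::vector<int> cand;
  std::vector<std::pair<double, int>> ordered;

  for (int i = 0; i < n; ++i) {
    double cx = xs[i], cy = ys[i];
    double rs = 3.0 * std::max(grid.gx, grid.gy);
    Poly poly;
    for (;;) {
      poly.vx = {xmin, xmax, xmax, xmin};
      poly.vy = {ymin, ymin, ymax, ymax};
      poly.lab = {-1, -1, -1, -1};
      grid.collect(cx, cy, rs, cand);
      ordered.clear();
      for (int j : cand) {
        if (j == i) continue;
        double dx = xs[j] - cx, dy = ys[j] - cy;
        ordered.push_back({dx * dx + dy * dy, j});
      }
      std::sort(ordered.begin(), ordered.end());
      double r2max = max_r2_from(poly, cx, cy);
      for (auto &pr : ordered) {
        if (pr.first > 4.0 * r2max) break; // security radius: |ci-cj| > 2 rmax
        int j = pr.second;
        double mx = 0.5 * (cx + xs[j]), my = 0.5 * (cy + ys[j]);
        clip_halfplane(poly, mx, my, xs[j] - cx, ys[j] - cy, j);
        r2max = max_r2_from(poly, cx, cy);
      }
      // finished if every unseen generator is provably too far away
      if (2.0 * std::sqrt(r2max) <= rs || rs >= diag) break;
      rs = std::min(diag, 2.0 * rs);
    }
    size_t nv = poly.vx.size();
    NumericMatrix pm(nv, 2);
    double a = 0;
    std::set<int> nb;
    for (size_t k = 0; k < nv; ++k) {
      pm(k, 0) = poly.vx[k];
      pm(k, 1) = poly.vy[k];
      size_t k2 = (k + 1) % nv;
      a += poly.vx[k] * poly.vy[k2] - poly.vx[k2] * poly.vy[k];
      if (poly.lab[k] >= 0) nb.insert(poly.lab[k] + 1); // 1-based
    }
    areas[i] = 0.5 * std::fabs(a);
    polys[i] = pm;
    nbrs[i] = IntegerVector(nb.begin(), nb.end());
  }
  return List::create(_["areas"] = areas, _["polygons"] = polys,
                      _["neighbors"] = nbrs);
}

// Index (1-based) of the nearest generator for each query point; with the
// generators of a Voronoi diagram this is exactly the containing cell.
// [[Rcpp::export]]
IntegerVector nearest_center_cpp(NumericVector qx, NumericVector qy,
                                 NumericVector x, NumericVector y,
                                 double xmin, double xmax, double ymin,
                                 double ymax) {
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  BucketGrid grid(xs, ys, xmin, xmax, ymin, ymax);
  double diag = std::hypot(xmax - xmin, ymax - ymin);
  int nq = qx.size();
  IntegerVector out(nq);
  std::vector<int> cand;
  for (int q = 0; q < nq; ++q) {
    double rs = 2.0 * std::max(grid.gx, grid.gy);
    int best = -1;
    double bd2 = R_PosInf;
    for (;;) {
      grid.collect(qx[q], qy[q], rs, cand);
      best = -1;
      bd2 = R_PosInf;
      for (int j : cand) {
        double dx = xs[j] - qx[q], dy = ys[j] - qy[q];
        double d2 = dx * dx + dy * dy;
        if (d2 < bd2) { bd2 = d2; best = j; }
      }
      if ((best >= 0 && std::sqrt(bd2) <= rs) || rs >= diag) break;
      rs = std::min(diag, 2.0 * rs);
    }
    out[q] = best + 1;
  }
  return out;
}
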