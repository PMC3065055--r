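#include <Rcpp.h>
using namespace Rcpp;

static inline double pt_seg_d2(double px, double py, double ax, double ay,
                               double bx, double by) {
  double vx = bx - ax, vy = by - ay;
  double L2 = vx * vx + vy * vy;
  double t = 0.0;
  if (L2 > 0) {
    t = ((px - ax) * vx + (py - ay) * vy) / L2;
    t = std::min(1.0, std::max(0.0, t));
  }
  double dx = px - (ax + t * vx), dy = py - (ay + t * vy);
  return dx * dx + dy * dy;
}

// Brute-force nearest alive segment for a batch of points. Returns the
// Euclidean distance and the (1-based) index into the supplied segment
// arrays; callers map that index back to segment ids.
// [[Rcpp::export]]
List nearest_segment_cpp(NumericVector px, NumericVector py, NumericVector ax,
                         NumericVector ay, NumericVector bx, NumericVector by) {
  int np = px.size(), ns = ax.size();
  NumericVector dist(np);
  IntegerVector idx(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    int bj = NA_INTEGER;
    for (int j = 0; j < ns; ++j) {
      double d2 = pt_seg_d2(px[i], py[i], ax[j], ay[j], bx[j], by[j]);
      if (d2 < best) { best = d2; bj = j + 1; }
    }
    dist[i] = (ns > 0) ? std::sqrt(best) : R_PosInf;
    idx[i] = bj;
  }
  return List::create(_["dist"] = dist, _["idx"] = idx);
}

// Distance from each point to one segment (vectorised over points).
// [[Rcpp::export]]
NumericVector dist_points_one_segment_cpp(NumericVector px, NumericVector py,
                                          double ax, double ay, double bx,
                                          double by) {
  int np = px.size();
  NumericVector out(np);
  for (int i = 0; i < np; ++i)
    out[i] = std::sqrt(pt_seg_d2(px[i], py[i], ax, ay, bx, by));
  return out;
}
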