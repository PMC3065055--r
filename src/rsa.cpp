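#include <Rcpp.h>
using namespace Rcpp;

// Random sequential addition of hard disks in [0,w] x [0,h].
// Points are accepted one at a time if no previously accepted point lies
// closer than `d` (the hard-disk diameter). Uses R's RNG, so results are
// reproducible under set.seed(). Stops at n_target accepted points, at
// max_attempts total proposals, or after `patience` consecutive rejections
// (the practical saturation criterion).
// [[Rcpp::export]]
NumericMatrix rsa_disks_cpp(double w, double h, double d, int n_target,
                            int max_attempts, int patience) {
  if (w <= 0 || h <= 0 || d <= 0)
    stop("rsa_disks_cpp: non-positive geometry");
  const double d2 = d * d;
  // occupancy grid with cell size >= d so any conflicting point is within
  // the 3x3 bucket neighbourhood
  int nbx = std::max(1, (int)std::floor(w / d));
  int nby = std::max(1, (int)std::floor(h / d));
  const double gx = w / nbx, gy = h / nby;
  std::vector<std::vector<int>> buckets((size_t)nbx * nby);
  std::vector<double> px, py;
  px.reserve(n_target > 0 ? n_target : 1024);
  py.reserve(n_target > 0 ? n_target : 1024);

  int attempts = 0, fails = 0;
  while ((int)px.size() < n_target && attempts < max_attempts &&
         fails < patience) {
    ++attempts;
    double x = unif_rand() * w;
    double y = unif_rand() * h;
    int bx = std::min(nbx - 1, (int)(x / gx));
    int by = std::min(nby - 1, (int)(y / gy));
    bool ok = true;
    for (int i = std::max(0, bx - 1); ok && i <= std::min(nbx - 1, bx + 1); ++i)
      for (int j = std::max(0, by - 1); ok && j <= std::min(nby - 1, by + 1); ++j)
        for (int k : buckets[(size_t)i + (size_t)j * nbx]) {
          double dx = px[k] - x, dy = py[k] - y;
          if (dx * dx + dy * dy < d2) { ok = false; break; }
        }
    if (ok) {
      buckets[(size_t)bx + (size_t)by * nbx].push_back((int)px.size());
      px.push_back(x);
      py.push_back(y);
      fails = 0;
    } else {
      ++fails;
    }
  }

  NumericMatrix out(px.size(), 2);
  for (size_t i = 0; i < px.size(); ++i) {
    out(i, 0) = px[i];
    out(i, 1) = py[i];
  }
  out.attr("attempts") = attempts;
  out.attr("saturated") = (fails >= patience);
  return out;
}
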