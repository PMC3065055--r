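#include <Rcpp.h>
using namespace Rcpp;

// Explicit finite-difference integration of the eight-species
// VEGF / Ang-1 / Ang-2 / VEGFR-2 / Tie-2 reaction-diffusion system, one
// simulated day (24 h) forward. Five-point Laplacian with zero-flux
// boundaries for the two diffusing ligands (VEGF, Ang-2); all other species
// are purely local. Jacobi (simultaneous) sub-step updates from the previous
// sub-step state; the sub-step dt satisfies both the diffusive CFL bound and
// dt * rho <= 1/2 for the largest linear reaction rate rho, which also keeps
// every field non-negative. Receptor updates are written as exactly opposite
// association/dissociation terms, so rv0 + rv and ra0 + ra1 + ra2 are
// conserved pointwise to rounding error.
// [[Rcpp::export]]
List pde_step_day_cpp(NumericMatrix v_in, NumericMatrix a1_in,
                      NumericMatrix a2_in, NumericMatrix rv0_in,
                      NumericMatrix ra0_in, NumericMatrix rv_in,
                      NumericMatrix ra1_in, NumericMatrix ra2_in,
                      NumericVector ei, NumericVector hi, NumericVector pi_,
                      NumericVector ni, double h0, List par, double dx,
                      double hours) {
  const int nx = v_in.nrow(), ny = v_in.ncol();
  const int N = nx * ny;
  if (ei.size() != N || hi.size() != N || pi_.size() != N || ni.size() != N)
    stop("indicator rasters do not match the field grid");

  const double Dv = par["D_v"], Da2 = par["D_a2"], bv = par["b_v"],
               ba1 = par["b_a1"], ba2 = par["b_a2"], bba2 = par["bbar_a2"],
               muv = par["mu_v"], mua1 = par["mu_a1"], mua2 = par["mu_a2"],
               k0 = par["k_0"], km0 = par["k_m0"], k1 = par["k_1"],
               km1 = par["k_m1"], k2 = par["k_2"], km2 = par["k_m2"],
               Kv = par["K_v"], Ka = par["K_a"], e0 = par["e_0"];

  std::vector<double> V(v_in.begin(), v_in.end()),
      A1(a1_in.begin(), a1_in.end()), A2(a2_in.begin(), a2_in.end()),
      RV0(rv0_in.begin(), rv0_in.end()), RA0(ra0_in.begin(), ra0_in.end()),
      RV(rv_in.begin(), rv_in.end()), RA1(ra1_in.begin(), ra1_in.end()),
      RA2(ra2_in.begin(), ra2_in.end());
  std::vector<double> Vn(N), A1n(N), A2n(N), RV0n(N), RA0n(N), RVn(N),
      RA1n(N), RA2n(N);

  auto vmaxof = [](const std::vector<double> &z) {
    double m = 0;
    for (double t : z) m = std::max(m, t);
    return m;
  };

  // stability bound: caps for the state-dependent linear rates; the
  // carrying-capacity equilibria bound the ligands during the day
  const double vcap = std::max(vmaxof(V), std::sqrt(Kv * std::max(h0, 0.0)));
  const double a1cap = std::max(vmaxof(A1), std::sqrt(Ka * e0));
  const double a2cap =
      std::max(vmaxof(A2), std::sqrt(Ka * std::max(h0, e0)));
  const double rcap = std::max(e0, std::max(vmaxof(RV0), vmaxof(RA0)));
  double rho = muv + k0 * rcap + 2.0 * bv * vcap / Kv;
  rho = std::max(rho, mua1 + k1 * rcap + 2.0 * ba1 * a1cap / Ka);
  rho = std::max(rho, mua2 + k2 * rcap + 2.0 * (ba2 + bba2) * a2cap / Ka);
  rho = std::max(rho, k0 * vcap);
  rho = std::max(rho, k1 * a1cap + k2 * a2cap);
  rho = std::max(rho, std::max(km0, std::max(km1, km2)));
  double dt = std::min(dx * dx / (4.0 * std::max(Dv, Da2)), 0.5 / rho);
  int nsub = std::max(1, (int)std::ceil(hours / dt));
  dt = hours / nsub;

  const double idx2 = 1.0 / (dx * dx);
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < ny; ++j) {
      const int jm = (j > 0) ? j - 1 : j, jp = (j < ny - 1) ? j + 1 : j;
      for (int i = 0; i < nx; ++i) {
        const int im = (i > 0) ? i - 1 : i, ip = (i < nx - 1) ? i + 1 : i;
        const int c = i + j * nx;
        const double e = ei[c], hh = hi[c];
        const double mi = pi_[c] + hh + ni[c]; // malignant-tissue indicator
        const double hconc = h0 * hh;

        const double lapv = (V[im + j * nx] + V[ip + j * nx] + V[i + jm * nx] +
                             V[i + jp * nx] - 4.0 * V[c]) * idx2;
        const double lapa2 = (A2[im + j * nx] + A2[ip + j * nx] +
                              A2[i + jm * nx] + A2[i + jp * nx] -
                              4.0 * A2[c]) * idx2;

        const double bindv = k0 * V[c] * RV0[c] - km0 * RV[c];
        const double bind1 = k1 * A1[c] * RA0[c] - km1 * RA1[c];
        const double bind2 = k2 * A2[c] * RA0[c] - km2 * RA2[c];

        Vn[c] = V[c] + dt * (Dv * lapv + bv * hh * (hconc - V[c] * V[c] / Kv) -
                             bindv - muv * V[c]);
        A1n[c] = A1[c] + dt * (ba1 * e * mi * (e0 - A1[c] * A1[c] / Ka) -
                               bind1 - mua1 * A1[c]);
        A2n[c] = A2[c] + dt * (Da2 * lapa2 +
                               ba2 * e * mi * (e0 - A2[c] * A2[c] / Ka) +
                               bba2 * hh * (hconc - A2[c] * A2[c] / Ka) -
                               bind2 - mua2 * A2[c]);
        RV0n[c] = RV0[c] - dt * bindv;
        RVn[c] = RV[c] + dt * bindv;
        RA0n[c] = RA0[c] - dt * (bind1 + bind2);
        RA1n[c] = RA1[c] + dt * bind1;
        RA2n[c] = RA2[c] + dt * bind2;
      }
    }
    V.swap(Vn); A1.swap(A1n); A2.swap(A2n); RV0.swap(RV0n);
    RA0.swap(RA0n); RV.swap(RVn); RA1.swap(RA1n); RA2.swap(RA2n);

    const std::vector<double> *flds[8] = {&V, &A1, &A2, &RV0,
                                          &RA0, &RV, &RA1, &RA2};
    const char *nms[8] = {"v", "a1", "a2", "rv0", "ra0", "rv", "ra1", "ra2"};
    for (int f = 0; f < 8; ++f) {
      double mn = 0;
      for (double t : *flds[f]) mn = std::min(mn, t);
      if (mn < -1e-13)
        stop("numerical instability: field '%s' reached %g at dt = %g h",
             nms[f], mn, dt);
    }
  }

  auto wrap = [&](std::vector<double> &z) {
    NumericMatrix m(nx, ny);
    std::copy(z.begin(), z.end(), m.begin());
    return m;
  };
  return List::create(_["v"] = wrap(V), _["a1"] = wrap(A1), _["a2"] = wrap(A2),
                      _["rv0"] = wrap(RV0), _["ra0"] = wrap(RA0),
                      _["rv"] = wrap(RV), _["ra1"] = wrap(RA1),
                      _["ra2"] = wrap(RA2), _["nsub"] = nsub, _["dt"] = dt);
}
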