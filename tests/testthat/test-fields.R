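make_ind <- function(mesh, h = 0, p = 0, e = 0, n = 0, h0 = 1e-2) {
  m <- function(v) matrix(v, mesh$nx, mesh$ny)
  structure(list(e = m(e), h = m(h), p = m(p), n = m(n), h0 = h0,
                 mesh = mesh, map = NULL),
            class = "indicator_raster")
}

test_that("zero fields with zero sources are a fixed point", {
  mesh <- make_mesh(c(0.5, 0.5), dx = 0.1)
  f <- init_field_state(mesh)
  f2 <- step_fields_day(f, make_ind(mesh), pde_params())
  for (nm in c("v", "a1", "a2", "rv0", "ra0", "rv", "ra1", "ra2")) {
    expect_true(all(f2[[nm]] == 0))
  }
})

test_that("homogeneous hypoxic tissue reaches the analytic VEGF level", {
  p <- pde_params()
  h0 <- 1e-2
  # positive root of b_v (h0 - v^2/K_v) = mu_v v
  a <- p$b_v / p$K_v
  vstar <- (-p$mu_v + sqrt(p$mu_v^2 + 4 * a * p$b_v * h0)) / (2 * a)
  mesh <- make_mesh(c(0.5, 0.5), dx = 0.1)
  f <- init_field_state(mesh)
  ind <- make_ind(mesh, h = 1, h0 = h0)
  for (d in 1:60) f <- step_fields_day(f, ind, p)
  expect_equal(f$v[2, 2], vstar, tolerance = 1e-3)
  # independent stiff-ODE oracle for the full homogeneous system
  y0 <- c(v = 0, a1 = 0, a2 = 0, rv0 = 0, ra0 = 0, rv = 0, ra1 = 0, ra2 = 0)
  oracle <- run_homogeneous_oracle(p, h0, ei = 0, hi = 1, pi_ind = 0, ni = 0,
                                   y0 = y0, days = 60)
  expect_equal(f$v[2, 2], unname(oracle["v"]), tolerance = 1e-3)
  expect_equal(f$a2[2, 2], unname(oracle["a2"]), tolerance = 1e-3)
})

test_that("receptor occupancy follows the binding isotherm at equilibrium", {
  p <- pde_params(b_v = 0, mu_v = 0, D_v = 0) # VEGF changes only by binding
  mesh <- make_mesh(c(0.5, 0.5), dx = 0.1)
  ind <- make_ind(mesh, e = 1)
  f <- init_field_state(mesh, ind, p)
  f$v <- matrix(5e-3, mesh$nx, mesh$ny)
  for (d in 1:30) f <- step_fields_day(f, ind, p)
  kd <- p$k_m0 / p$k_0
  occ <- f$rv[2, 2] / (f$rv0[2, 2] + f$rv[2, 2])
  expect_equal(occ, f$v[2, 2] / (f$v[2, 2] + kd), tolerance = 1e-4)
})

test_that("receptor totals are conserved pointwise and fields stay positive", {
  p <- pde_params()
  mesh <- make_mesh(c(0.8, 0.6), dx = 0.1)
  ind <- make_ind(mesh, h = 1, e = 1, h0 = 1e-2)
  f <- init_field_state(mesh, ind, p)
  set.seed(8)
  # scatter bound/unbound receptor mass and some ligand
  f$rv <- matrix(runif(mesh$nx * mesh$ny, 0, 5e-5), mesh$nx)
  f$rv0 <- matrix(runif(mesh$nx * mesh$ny, 0, 5e-5), mesh$nx)
  f$ra1 <- matrix(runif(mesh$nx * mesh$ny, 0, 3e-5), mesh$nx)
  f$ra2 <- matrix(runif(mesh$nx * mesh$ny, 0, 3e-5), mesh$nx)
  f$ra0 <- matrix(runif(mesh$nx * mesh$ny, 0, 4e-5), mesh$nx)
  f$v <- matrix(runif(mesh$nx * mesh$ny, 0, 8e-3), mesh$nx)
  tot_v <- f$rv0 + f$rv
  tot_a <- f$ra0 + f$ra1 + f$ra2
  for (d in 1:5) {
    f <- step_fields_day(f, ind, p)
    expect_lt(max(abs(f$rv0 + f$rv - tot_v)) / max(tot_v), 1e-10)
    expect_lt(max(abs(f$ra0 + f$ra1 + f$ra2 - tot_a)) / max(tot_a), 1e-10)
    for (nm in c("v", "a1", "a2", "rv0", "ra0", "rv", "ra1", "ra2")) {
      expect_gte(min(f[[nm]]), 0)
    }
  }
})

test_that("VEGF production shuts off above the carrying capacity", {
  p <- pde_params(D_v = 0, mu_v = 0) # isolate the production term
  h0 <- 1e-2
  mesh <- make_mesh(c(0.5, 0.5), dx = 0.1)
  ind <- make_ind(mesh, h = 1, h0 = h0)
  f <- init_field_state(mesh)
  f$v <- matrix(sqrt(p$K_v * h0) * 1.05, mesh$nx, mesh$ny) # above capacity
  f2 <- step_fields_day(f, ind, p, hours = 1)
  expect_true(all(f2$v <= f$v))
})

test_that("halving the mesh spacing barely moves the homogeneous steady state", {
  p <- pde_params()
  vs <- vapply(c(0.1, 0.05), function(dx) {
    mesh <- make_mesh(c(0.6, 0.6), dx = dx)
    f <- init_field_state(mesh)
    ind <- make_ind(mesh, h = 1)
    for (d in 1:40) f <- step_fields_day(f, ind, p)
    f$v[1, 1]
  }, numeric(1))
  expect_lt(abs(vs[1] - vs[2]) / vs[2], 0.01)
})

test_that("mesh construction rejects unusable resolutions", {
  expect_error(make_mesh(c(2, 2), dx = 0.005), "invalid argument")
  expect_error(make_mesh(c(2, 2), dx = 0.9), "invalid argument")
})

test_that("indicator rasterization reflects geometry and is idempotent", {
  lat <- small_lattice()
  net <- small_network()
  tum <- init_tumor_state(lat)
  tum$states[] <- 1L
  mesh <- make_mesh(lat, 0.1)
  # healthy tissue, dead vessels -> all-zero rasters except e on alive ones
  dead <- net
  dead$alive[] <- FALSE
  r0 <- rasterize_indicators(lat, tum, dead, mesh)
  expect_true(all(r0$e == 0) && all(r0$h == 0) && all(r0$p == 0) &&
                all(r0$n == 0))
  # a single hypoxic automaton cell covers about its own area
  cell <- tum$seed_cell
  tum$states[cell] <- 4L
  r1 <- rasterize_indicators(lat, tum, net, mesh)
  covered <- sum(r1$h) * mesh$dx^2
  expect_lt(abs(covered - lat$areas[cell]),
            4 * mesh$dx * sqrt(lat$areas[cell]) + mesh$dx^2)
  r2 <- rasterize_indicators(lat, tum, net, mesh)
  expect_identical(r1, r2)
  # indicators are 0/1 and mutually exclusive
  expect_true(all(r1$h + r1$p + r1$n <= 1))
})

test_that("bound-complex queries index the grid correctly", {
  mesh <- make_mesh(c(1, 1), dx = 0.1)
  f <- init_field_state(mesh)
  f$rv[3, 4] <- 1e-5
  f$ra1[3, 4] <- 2e-5
  f$ra2[3, 4] <- 3e-5
  # two points in the same pixel give identical values
  b1 <- bound_concentrations_at(f, c(0.21, 0.31))
  b2 <- bound_concentrations_at(f, c(0.29, 0.39))
  expect_identical(b1, b2)
  expect_equal(unname(b1), c(1e-5, 2e-5, 3e-5))
  # fresh state -> zeros
  expect_equal(unname(bound_concentrations_at(init_field_state(mesh),
                                              c(0.5, 0.5))), c(0, 0, 0))
  expect_error(bound_concentrations_at(f, c(2, 0.5)), "invalid argument")
})
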