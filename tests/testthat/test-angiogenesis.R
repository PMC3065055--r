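# craft a field state on the mesh of a network's domain
blank_fields <- function(domain, dx = 0.1) {
  init_field_state(make_mesh(domain, dx))
}

test_that("vessels regress only when destabilized and unrescued", {
  cn <- chain_network()
  net <- cn$network
  lat <- small_lattice()
  tum <- init_tumor_state(lat)
  tum$states[] <- 3L # everything malignant: pure ratio rule applies
  mesh <- make_mesh(lat, 0.1)
  ind <- rasterize_indicators(lat, tum, net, mesh)
  ap <- angiogenesis_params()

  # no bound Ang-2 anywhere: the ratio condition is unsatisfiable
  f <- blank_fields(c(2, 2))
  r <- regress_vessels(net, f, ind, ap)
  expect_equal(r$n_removed, 0L)

  # destabilized but rescued by bound VEGF
  f$ra2[] <- 7e-5
  f$ra1[] <- 1e-5 # ra2 = 7 ra1 > 6 ra1
  f$rv[] <- ap$rv_crit
  expect_equal(regress_vessels(net, f, ind, ap)$n_removed, 0L)

  # same fields with VEGF below threshold: everything regresses
  f$rv[] <- ap$rv_crit * 0.9
  r2 <- regress_vessels(net, f, ind, ap)
  expect_equal(r2$n_removed, sum(net$alive))

  # rescue clause disabled (no angiogenic response): VEGF cannot save them
  f$rv[] <- ap$rv_crit
  ap_off <- angiogenesis_params(vegf_rescue = FALSE)
  expect_equal(regress_vessels(net, f, ind, ap_off)$n_removed,
               sum(net$alive))
})

test_that("regression matches a per-segment rule evaluation plus closure", {
  net <- mid_network()
  lat <- mid_lattice()
  tum <- init_tumor_state(lat)
  tum$states[] <- 3L
  mesh <- make_mesh(lat, 0.1)
  ind <- rasterize_indicators(lat, tum, net, mesh)
  ap <- angiogenesis_params()
  f <- blank_fields(c(3, 3))
  set.seed(77)
  f$ra2 <- matrix(runif(length(f$ra2), 0, 1e-4), nrow(f$ra2))
  f$ra1 <- matrix(runif(length(f$ra1), 0, 2e-5), nrow(f$ra1))
  f$rv <- matrix(runif(length(f$rv), 0, 6e-5), nrow(f$rv))
  r <- regress_vessels(net, f, ind, ap)
  # independent re-evaluation
  al <- which(net$alive)
  midx <- vasctum:::mesh_index(f$mesh, (net$ax[al] + net$bx[al]) / 2,
                               (net$ay[al] + net$by[al]) / 2)
  doomed <- al[f$ra2[midx] > ap$regression_ratio * f$ra1[midx] &
                 f$rv[midx] < ap$rv_crit]
  expect_setequal(r$removed, closure_oracle(net, doomed))
})

test_that("sprouting requires bound VEGF and follows the gradient", {
  net <- small_network()
  ap <- angiogenesis_params()
  f <- blank_fields(c(2, 2))

  # no bound VEGF anywhere: no sprouts
  expect_equal(sprout_vessels(net, f, ap, day = 1)$n_new, 0L)

  # rv above threshold everywhere, linear VEGF ramp in +x
  f$rv[] <- ap$rv_crit * 2
  f$v <- matrix(rep(seq_len(f$mesh$nx) * 1e-3, f$mesh$ny), f$mesh$nx)
  r <- sprout_vessels(net, f, ap, day = 1)
  expect_gt(r$n_new, 0L)
  nn <- r$network
  dx <- nn$bx[r$new_ids] - nn$ax[r$new_ids]
  dy <- nn$by[r$new_ids] - nn$ay[r$new_ids]
  cosang <- dx / sqrt(dx^2 + dy^2)
  expect_true(all(cosang > cos(pi / 6))) # all point up-ramp
  expect_true(all(nn$type[r$new_ids] == 2L))
  expect_true(all(nn$parent[r$new_ids] %in% which(net$alive)))
  # distances can only improve with new vessels
  expect_true(all(nn$cell_dist <= net$cell_dist + 1e-12))

  # a second sprouting day extends the open tips
  r2 <- sprout_vessels(r$network, f, ap, day = 2)
  expect_gt(r2$n_new, 0L)
  expect_true(all(r2$network$creation_day[r2$new_ids] == 2))
})

test_that("uniform VEGF falls back to deterministic sprout directions", {
  net <- small_network()
  ap <- angiogenesis_params()
  f <- blank_fields(c(2, 2))
  f$rv[] <- ap$rv_crit * 2
  f$v[] <- 5e-3 # spatially uniform: zero gradient everywhere
  r <- sprout_vessels(net, f, ap, day = 1)
  expect_gt(r$n_new, 0L)
  # native initiation: perpendicular to the trunk (sprouts clipped by the
  # domain edge excluded)
  nn <- r$network
  interior <- r$new_ids[nn$bx[r$new_ids] > 0.15 & nn$bx[r$new_ids] < 1.85 &
                          nn$by[r$new_ids] > 0.15 & nn$by[r$new_ids] < 1.85]
  for (j in interior) {
    par <- nn$parent[j]
    pv <- c(net$bx[par] - net$ax[par], net$by[par] - net$ay[par])
    sv <- c(nn$bx[j] - nn$ax[j], nn$by[j] - nn$ay[j])
    dot <- abs(sum(pv * sv)) / sqrt(sum(pv^2) * sum(sv^2))
    expect_lt(dot, 1e-6)
  }
  # determinism: same inputs, same sprouts
  r2 <- sprout_vessels(net, f, ap, day = 1)
  expect_identical(r$network$bx, r2$network$bx)
})

test_that("a removed segment is never resurrected by same-day sprouting", {
  net <- small_network()
  lat <- small_lattice()
  tum <- init_tumor_state(lat)
  tum$states[] <- 3L
  mesh <- make_mesh(lat, 0.1)
  ind <- rasterize_indicators(lat, tum, net, mesh)
  ap <- angiogenesis_params()
  f <- blank_fields(c(2, 2))
  f$ra2[] <- 1e-4 # destabilize everything in malignant tissue
  f$rv[] <- 0
  r <- regress_vessels(net, f, ind, ap)
  f$rv[] <- ap$rv_crit * 2
  s <- sprout_vessels(r$network, f, ap, day = 1)
  expect_true(all(!s$network$alive[r$removed]))
  # dead segments spawn nothing
  expect_true(all(!(s$network$parent[s$new_ids] %in% r$removed)))
})

test_that("threshold calibrations reproduce the package defaults", {
  rvc <- calibrate_rv_crit()
  expect_equal(signif(rvc, 2), angiogenesis_params()$rv_crit)
  fl <- calibrate_ang2_floor()
  expect_equal(signif(fl, 2), angiogenesis_params()$ra2_floor)
})
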