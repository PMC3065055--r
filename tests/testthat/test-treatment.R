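test_that("AI modes modify exactly the targeted parameter and round-trip", {
  pde <- pde_params()
  ang <- angiogenesis_params()
  pr <- treatment_protocol(drugs = "AI", T1 = 100, ai_mode = "PRODUCTION")
  eff <- apply_ai(pde, ang, pr)
  expect_equal(eff$pde$b_v, 0.05 / 100)
  expect_identical(eff$pde[names(eff$pde) != "b_v"],
                   pde[names(pde) != "b_v"])
  expect_identical(eff$angio, ang)

  prb <- treatment_protocol(drugs = "AI", T1 = 50, ai_mode = "BINDING")
  expect_equal(apply_ai(pde, ang, prb)$pde$k_0, 46.8 / 50)
  prs <- treatment_protocol(drugs = "AI", T1 = 50, ai_mode = "SENSITIVITY")
  effs <- apply_ai(pde, ang, prs)
  expect_equal(effs$angio$rv_crit, ang$rv_crit * 50)
  expect_identical(effs$pde, pde)

  # identity dose and restoration
  pr1 <- treatment_protocol(drugs = "AI", T1 = 1)
  expect_identical(apply_ai(pde, ang, pr1)$pde, pde)
  # stopping the AI restores exact pre-treatment values by reapplying from
  # the pristine copies, which the simulation loop does every day
  expect_identical(pde$b_v, 0.05)
})

test_that("protocol validation enforces parameter domains", {
  expect_error(treatment_protocol(T1 = 0.5), "invalid argument")
  expect_error(treatment_protocol(T2 = 1.5), "invalid argument")
  expect_error(treatment_protocol(T3 = -0.1), "invalid argument")
  expect_error(treatment_protocol(ai_mode = "MAGIC"))
})

test_that("the cytotoxic agent kills dividing cells binomially", {
  lat <- mid_lattice()
  tum <- init_tumor_state(lat)
  tum$states[1:200] <- 3L
  # T2 = 0: nothing happens; T2 = 1: every proliferative cell dies
  r0 <- apply_cytotoxic(tum, treatment_protocol(drugs = "CYTOTOXIC", T2 = 0),
                        rng_stream(1))
  expect_equal(r0$n_killed, 0L)
  r1 <- apply_cytotoxic(tum, treatment_protocol(drugs = "CYTOTOXIC", T2 = 1),
                        rng_stream(1))
  expect_equal(r1$n_killed, sum(tum$states == 3L))
  expect_true(all(r1$tumor$states[tum$states == 3L] == 5L)) # necrotic
  # hypoxic and necrotic cells are untouched
  tum2 <- tum
  tum2$states[201:260] <- 4L
  r2 <- apply_cytotoxic(tum2, treatment_protocol(drugs = "CYTOTOXIC", T2 = 1),
                        rng_stream(2))
  expect_true(all(r2$tumor$states[201:260] == 4L))
  # kill counts match the binomial mean within 3 standard errors
  pr <- treatment_protocol(drugs = "CYTOTOXIC", T2 = 0.34)
  n <- sum(tum$states == 3L)
  kills <- vapply(1:60, function(s) {
    apply_cytotoxic(tum, pr, rng_stream(s))$n_killed
  }, integer(1))
  se <- sqrt(n * 0.34 * 0.66 / 60)
  expect_lt(abs(mean(kills) - n * 0.34), 3 * se)
})

test_that("the VDA hits only angiogenic vessels and cascades", {
  cn <- chain_network()
  net <- cn$network
  # T3 = 1 removes every angiogenic segment that day, natives untouched
  r <- apply_vda(net, treatment_protocol(drugs = "VDA", T3 = 1),
                 rng_stream(1))
  expect_equal(sum(r$network$alive & r$network$type == 2L), 0L)
  expect_equal(sum(r$network$alive & r$network$type == 1L),
               sum(net$alive & net$type == 1L))
  # no angiogenic segments -> nothing removed
  r2 <- apply_vda(r$network, treatment_protocol(drugs = "VDA", T3 = 1),
                  rng_stream(2))
  expect_equal(r2$n_removed, 0L)
  # T3 = 0 removes nothing
  r3 <- apply_vda(net, treatment_protocol(drugs = "VDA", T3 = 0),
                  rng_stream(3))
  expect_equal(r3$n_removed, 0L)
})

test_that("the fractional-kill inversion matches forward iteration", {
  # temozolomide-like: 0.4 log10 units over 5 days, 4-day doubling
  f <- fractional_kill_from_log_kill(0.4, 5, 4)
  expect_equal(f, 1 - 10^(-0.4 / 5) / 2^(1 / 4), tolerance = 1e-12)
  expect_equal(f, 0.3006, tolerance = 1e-3)
  # forward iteration: grow then kill daily, five doses
  pop <- 1
  for (d in 1:5) pop <- pop * 2^(1 / 4) * (1 - f)
  expect_equal(log10(pop), -0.4, tolerance = 1e-12)
  # stasis: zero log kill means the kill exactly offsets growth
  f0 <- fractional_kill_from_log_kill(0, 5, 4)
  expect_equal(2^(1 / 4) * (1 - f0), 1, tolerance = 1e-12)
  # no growth: pure decay limit
  expect_equal(fractional_kill_from_log_kill(0.4, 5, Inf),
               1 - 10^(-0.4 / 5), tolerance = 1e-12)
  expect_error(fractional_kill_from_log_kill(-1, 5, 4), "invalid argument")
})

test_that("treatment scheduling honours trigger, window and cadence", {
  ang <- angiogenesis_params()
  pr <- treatment_protocol(drugs = c("AI", "CYTOTOXIC", "VDA"), T1 = 100,
                           T2 = 0.9, T3 = 0.6, trigger_radius = 0.35)
  cfg <- simulation_config(seed = 3, domain = c(4, 4), total_days = 120,
                           protocol = pr, angio = ang)
  res <- run_simulation(cfg)
  m <- res$metrics
  td <- res$trigger_day
  expect_false(is.na(td))
  # the trigger fires on the first day the radius reaches the threshold
  expect_true(all(m$radius[m$day < td] < 0.35))
  expect_gte(m$radius[m$day == td], 0.35)
  expect_identical(m$triggered, m$day >= td)
  # cytotoxic events only inside the 42-day window
  chemo_days <- m$day[m$n_chemo_killed > 0]
  expect_true(all(chemo_days >= td & chemo_days < td + 42))
  expect_gt(length(chemo_days), 0)
  # VDA events only on the 21-day cadence
  vda_days <- m$day[m$n_vda_removed > 0]
  expect_true(all((vda_days - td) %% 21 == 0))
})
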