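# one small shared untreated run
sim_small <- function() {
  fixture("sim_small", function() {
    run_simulation(simulation_config(seed = 2, domain = c(4, 4),
                                     total_days = 60))
  })
}

test_that("identical configurations reproduce identical trajectories", {
  cfg <- simulation_config(seed = 5, domain = c(3, 3), total_days = 25)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$tumor$states, b$tumor$states)
  expect_identical(a$network$alive, b$network$alive)
  cfg2 <- cfg
  cfg2$seed <- 6L
  c <- run_simulation(cfg2)
  expect_false(identical(a$metrics$tumor_area, c$metrics$tumor_area))
})

test_that("a zero-day run reports only the initial state", {
  cfg <- simulation_config(seed = 1, domain = c(2, 2), total_days = 0)
  res <- run_simulation(cfg)
  expect_equal(nrow(res$metrics), 1L)
  expect_equal(res$metrics$day, 0)
  expect_equal(res$metrics$proliferative, 1) # the seeded cancer cell
})

test_that("the active area never exceeds the tumour area", {
  m <- sim_small()$metrics
  expect_true(all(m$active_area <= m$tumor_area + 1e-12))
  expect_true(all(m$tumor_area >= 0))
})

test_that("untreated tumour area is non-decreasing", {
  for (s in c(2, 9)) {
    res <- if (s == 2) sim_small() else {
      run_simulation(simulation_config(seed = 9, domain = c(4, 4),
                                       total_days = 60))
    }
    expect_true(all(diff(res$metrics$tumor_area) >= -1e-12))
    expect_true(all(diff(res$metrics$radius) >= -1e-12))
  }
})

test_that("replicate summaries average correctly and are seed-stable", {
  cfg <- simulation_config(seed = 11, domain = c(3, 3), total_days = 15)
  one <- run_replicates(cfg, n = 1)
  single <- run_simulation(cfg)
  expect_equal(one$mean$tumor_area, single$metrics$tumor_area)
  expect_true(all(one$sd == 0))

  three <- run_replicates(cfg, n = 3)
  manual <- rowMeans(vapply(three$runs, function(m) m$tumor_area,
                            numeric(nrow(three$runs[[1]]))))
  expect_equal(three$mean$tumor_area, manual)
  # permutation invariance of the mean over replicate order
  perm <- rowMeans(vapply(three$runs[c(3, 1, 2)], function(m) m$tumor_area,
                          numeric(nrow(three$runs[[1]]))))
  expect_equal(three$mean$tumor_area, perm)
})

test_that("a single-value sweep reduces to a replicate batch", {
  cfg <- simulation_config(seed = 4, domain = c(3, 3), total_days = 12,
                           protocol = treatment_protocol(drugs = "AI",
                                                         T1 = 100,
                                                         trigger_radius = 0.3))
  sw <- sensitivity_sweep(cfg, "T1", 100, n = 2)
  rr <- run_replicates(cfg, n = 2)
  expect_equal(sw$summaries[["100"]]$mean$active_area, rr$mean$active_area)
  expect_true(all(sw$table$parameter == "T1"))
  expect_error(sensitivity_sweep(cfg, "T9", 1), "invalid argument")
})

test_that("snapshots render with exactly the standard palette", {
  res <- sim_small()
  img <- render_snapshot(res$tumor, res$network, res$lattice, px_per_mm = 10)
  expect_equal(dim(img), c(40, 40, 3))
  cols <- unique(matrix(img, ncol = 3))
  allowed <- rbind(c(1, 1, 1), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                   c(0, 0, 0), c(1, 0, 0), c(160, 32, 240) / 255)
  for (k in seq_len(nrow(cols))) {
    expect_true(any(colSums(abs(t(allowed) - cols[k, ])) < 1e-9))
  }
  # deterministic rendering
  img2 <- render_snapshot(res$tumor, res$network, res$lattice, px_per_mm = 10)
  expect_identical(img, img2)
  # an all-healthy state renders white tissue with red vessels only
  tum0 <- init_tumor_state(res$lattice)
  tum0$states[] <- 1L
  net0 <- res$network
  net0$alive[net0$type == 2L] <- FALSE
  img3 <- render_snapshot(tum0, net0, res$lattice, px_per_mm = 10)
  cols3 <- unique(matrix(img3, ncol = 3))
  expect_lte(nrow(cols3), 2)
})

test_that("stored snapshots reconstruct past states", {
  cfg <- simulation_config(seed = 3, domain = c(3, 3), total_days = 20,
                           snapshot_days = c(10, 20))
  res <- run_simulation(cfg)
  s10 <- snapshot_state(res, 10)
  expect_lte(sum(s10$tumor$states %in% 3:5),
             sum(res$tumor$states %in% 3:5))
  expect_error(snapshot_state(res, 13), "invalid argument")
})

test_that("YAML configurations round-trip through the constructors", {
  f <- tempfile(fileext = ".yml")
  writeLines(c(
    "seed: 7",
    "domain: [3, 3]",
    "total_days: 10",
    "pde:",
    "  b_v: 0.025",
    "growth:",
    "  p_max: 0.3",
    "protocol:",
    "  drugs: AI",
    "  T1: 10",
    "  trigger_radius: 1.5"
  ), f)
  cfg <- read_config(f)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$pde$b_v, 0.025)
  expect_equal(cfg$growth$p_max, 0.3)
  expect_equal(cfg$protocol$T1, 10)
  expect_equal(cfg$pde$b_a1, 0.01) # untouched defaults remain
  unlink(f)
})

test_that("rng streams are independent and reproducible", {
  a <- rng_stream(42)
  b <- rng_stream(42)
  x1 <- rng_draw(a, function() runif(5))
  # drawing from an unrelated stream does not disturb stream b
  rng_draw(rng_stream(7), function() runif(100))
  y1 <- rng_draw(b, function() runif(5))
  expect_identical(x1, y1)
  # the global RNG state is left untouched
  set.seed(123)
  ref <- runif(3)
  set.seed(123)
  rng_draw(a, function() runif(10))
  expect_identical(runif(3), ref)
})
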