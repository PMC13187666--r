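test_that("generation is deterministic under a fixed master seed", {
  w1 <- small_world(seed = 5, n_conduits = 150, nuisance_rate_end = 3)
  w2 <- small_world(seed = 5, n_conduits = 150, nuisance_rate_end = 3)
  expect_identical(w1$pop, w2$pop)
  a1 <- gen_ae_stream(w1$pop, w1$truth, w1$cfg)
  a2 <- gen_ae_stream(w2$pop, w2$truth, w2$cfg)
  expect_identical(a1$time, a2$time)
  expect_identical(a1$amplitude, a2$amplitude)
  m1 <- gen_psi_measurements(w1$truth, w1$cfg)
  expect_identical(m1, gen_psi_measurements(w2$truth, w2$cfg))
  s1 <- gen_ov_stack(w1$pop, w1$truth, w1$cfg)
  s2 <- gen_ov_stack(w2$pop, w2$truth, w2$cfg)
  expect_identical(s1$frames[[10]], s2$frames[[10]])
  # a different seed changes the draw
  w3 <- small_world(seed = 6, n_conduits = 150)
  expect_false(identical(w1$pop$diameter, w3$pop$diameter))
})

test_that("the small-conduit class carries the configured mass fraction", {
  truth <- drydown_truth(seed = 2)
  cfg <- synthetic_config(n_conduits = 2000, small_fraction = 0.14)
  pop <- gen_conduit_population(cfg, truth)
  frac <- mean(pop$diameter >= 0.5 & pop$diameter < 1.5)
  # binomial tolerance: 3 sd of p(1-p)/n around 0.14
  expect_lt(abs(frac - 0.14), 3 * sqrt(0.14 * 0.86 / 2000))
  expect_true(all(pop$diameter > 0))
  expect_true(all(pop$threshold < 0))
})

test_that("thresholds follow the Weibull law (closed-form median oracle)", {
  truth <- drydown_truth(weibull_scale = 3.54, weibull_shape = 5.86, seed = 3)
  cfg <- synthetic_config(n_conduits = 100000, small_fraction = 0,
                          coupling = "none")
  pop <- gen_conduit_population(cfg, truth)
  med <- median(-pop$threshold)
  expect_equal(med, 3.54 * log(2)^(1 / 5.86), tolerance = 0.005)
  expect_error(gen_conduit_population(synthetic_config(n_conduits = 0),
                                      truth), "positive")
  expect_error(synthetic_config(small_fraction = 1.2), "small_fraction")
})

test_that("psi trajectories are monotone and exact at knots", {
  # linear ramp -0.1 MPa/h for 20 h from -0.2 ends at -2.2
  truth <- drydown_truth(psi_start = -0.2, psi_end = -2.2, duration = 72000)
  tl <- gen_psi_trajectory(truth)
  expect_equal(psi_at(tl, 72000), -2.2)
  expect_equal(psi_at(tl, 36000), -1.2)
  kn <- data.frame(time = c(0, 10000, 50000, 72000),
                   psi = c(-0.2, -1, -1.1, -6))
  tl2 <- gen_psi_trajectory(drydown_truth(psi_knots = kn))
  expect_equal(psi_at(tl2, kn$time), kn$psi)
  # dense-grid scan oracle for monotonicity
  grid <- psi_at(tl2, seq(0, 72000, by = 37))
  expect_true(all(diff(grid) <= 1e-12))
  expect_error(drydown_truth(psi_knots = data.frame(time = c(0, 1e4),
                                                    psi = c(-2, -1))),
               "non-increasing")
  expect_error(drydown_truth(duration = 1e6), "20 h")
})

test_that("AE hits match the threshold-counting oracle", {
  truth <- drydown_truth(seed = 8)
  cfg <- synthetic_config(n_conduits = 400, small_fraction = 0,
                          coupling = "none", nuisance_rate_end = 0)
  pop <- gen_conduit_population(cfg, truth)
  ae <- gen_ae_stream(pop, truth, cfg)
  tl <- gen_psi_trajectory(truth)
  for (t in c(10000, 30000, 50000, 71999)) {
    expect_equal(sum(ae$time <= t), sum(pop$threshold >= psi_at(tl, t)))
  }
  expect_equal(length(ae$time), attr(ae, "n_embolism"))
  expect_true(!is.unsorted(ae$time))
  expect_true(all(ae$amplitude >= 35))
})

test_that("unreachable thresholds emit no embolism hits", {
  truth <- drydown_truth(weibull_scale = 30, weibull_shape = 40, seed = 9,
                         psi_end = -5)  # thresholds ~ -30, never crossed
  cfg <- synthetic_config(n_conduits = 50, small_fraction = 0,
                          coupling = "none")
  pop <- gen_conduit_population(cfg, truth)
  ae <- gen_ae_stream(pop, truth, cfg)
  expect_equal(length(ae$time), 0L)
  expect_warning(gen_ae_stream(pop[0, ], truth, cfg), "empty")
})

test_that("the nuisance process keeps late-drydown activity alive", {
  truth <- drydown_truth(seed = 10)
  cfg <- synthetic_config(n_conduits = 200, nuisance_rate_end = 6,
                          nuisance_onset = 0.6)
  pop <- gen_conduit_population(cfg, truth)
  ae <- gen_ae_stream(pop, truth, cfg)
  last_hour <- sum(ae$time > truth$duration - 3600)
  expect_gt(last_hour, 0)
  # embolism alone dies out before the end (thresholds mostly crossed early)
  cfg0 <- synthetic_config(n_conduits = 200, nuisance_rate_end = 0)
  ae0 <- gen_ae_stream(pop, truth, cfg0)
  expect_lt(sum(ae0$time > truth$duration - 3600), last_hour)
})

test_that("frames are spaced at the configured 150 s interval", {
  w <- small_world(seed = 11, n_conduits = 40)
  stack <- gen_ov_stack(w$pop, w$truth, w$cfg)
  expect_true(all(diff(stack$times) == 150))
  expect_equal(stack$times[1], 0)
})

test_that("an out-of-frame conduit is refused by name", {
  w <- small_world(seed = 12, n_conduits = 30)
  pop <- w$pop
  pop$x[7] <- attr(pop, "region_um") + 50
  expect_error(gen_ov_stack(pop, w$truth, w$cfg), "conduit\\(s\\) outside frame: 7")
})

test_that("psi measurements reproduce the trajectory", {
  truth <- drydown_truth(seed = 13)
  cfg0 <- synthetic_config(psi_noise_sd = 0)
  m0 <- gen_psi_measurements(truth, cfg0)
  tl <- gen_psi_trajectory(truth)
  expect_equal(m0$psi, psi_at(tl, m0$time))   # noise 0 -> exact
  counts <- table(m0$time)
  expect_true(all(counts %in% 2:3))            # 2-3 plants per timepoint
  # Monte-Carlo: replicate means approach the trajectory
  cfg1 <- synthetic_config(psi_noise_sd = 0.05)
  reps <- sapply(1:60, function(s) {
    m <- gen_psi_measurements(drydown_truth(seed = s), cfg1)
    mean(m$psi[m$time == 36000])
  })
  expect_equal(mean(reps), psi_at(tl, 36000),
               tolerance = 3 * 0.05 / sqrt(2 * 60) / abs(psi_at(tl, 36000)))
})

test_that("sub-resolution resistant conduits bias the observable distribution", {
  truth <- drydown_truth(seed = 14)
  cfg <- synthetic_config(n_conduits = 3000, small_fraction = 0.14,
                          coupling = "shift", small_shift_mpa = 1.5)
  pop <- gen_conduit_population(cfg, truth)
  # observable = conduits large enough to render >= 1 px at the pixel scale
  visible <- pop$diameter >= 2 * cfg$pixel_scale / sqrt(pi)
  expect_true(median(pop$threshold[visible]) > median(pop$threshold))
  # stochastic ordering of the whole distribution, checked on a tension grid
  grid <- seq(0.5, 8, by = 0.25)
  F_vis <- ecdf(-pop$threshold[visible])(grid)
  F_all <- ecdf(-pop$threshold)(grid)
  expect_true(all(F_vis >= F_all - 1e-9))
})

test_that("simulate_drydown writes a complete, reproducible dataset", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- synthetic_config(n_conduits = 25, psi_every = 7200)
  truth <- drydown_truth(seed = 15, duration = 7500)
  simulate_drydown(dir1, cfg, truth, format = "pgm")
  simulate_drydown(dir2, cfg, truth, format = "pgm")
  for (f in c("ae.csv", "psi.csv", "truth.json",
              file.path("frames", "manifest.csv")))
    expect_true(file.exists(file.path(dir1, f)))
  expect_identical(readLines(file.path(dir1, "truth.json")),
                   readLines(file.path(dir2, "truth.json")))
  expect_identical(readLines(file.path(dir1, "ae.csv")),
                   readLines(file.path(dir2, "ae.csv")))
  tj <- jsonlite::read_json(file.path(dir1, "truth.json"))
  expect_equal(tj$weibull_scale, truth$weibull_scale)
  expect_equal(tj$seed, 15L)
})
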