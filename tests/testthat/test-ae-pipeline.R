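test_that("binning counts hits into 1-min half-open bins and conserves them", {
  log <- ae_log(c(1, 10, 30, 59, 59.9, 60, 125), plant_id = "p")
  s <- bin_activity(log)
  expect_equal(s$rate, c(5, 1, 1))           # [0,60), [60,120), [120,180)
  expect_equal(s$bin_start, c(0, 60, 120))
  expect_equal(sum(s$rate), length(log$time)) # conservation
  # empty bin present with zero rate
  s2 <- bin_activity(ae_log(c(5, 130)))
  expect_equal(s2$rate, c(1, 0, 1))
  expect_error(bin_activity(ae_log(numeric(0))), "empty")
})

test_that("a Poisson stream has the expected mean rate", {
  set.seed(99)
  t <- cumsum(rexp(3000, rate = 0.2))
  t <- t[t < 7200]
  s <- bin_activity(ae_log(t))
  expect_equal(mean(s$rate), 12, tolerance = 0.05)  # 0.2/s = 12/min
})

test_that("amplitudes below the detection threshold are rejected", {
  expect_error(ae_log(c(1, 2), amplitude = c(40, 30)), "35")
  expect_silent(ae_log(c(1, 2), amplitude = c(40, 36)))
})

test_that("Savitzky-Golay smoothing preserves constants and ramps", {
  s <- structure(data.frame(bin_start = 0:40 * 60, bin_mid = 0:40 * 60 + 30,
                            rate = rep(5, 41)),
                 class = c("activity_series", "data.frame"))
  sm <- smooth_activity(s, window = 11, polyorder = 3)
  expect_equal(sm$smoothed_rate, rep(5, 41), tolerance = 1e-9)
  s$rate <- seq(0, 8, length.out = 41)
  sm <- smooth_activity(s, window = 11, polyorder = 1)
  expect_equal(sm$smoothed_rate, s$rate, tolerance = 1e-9)
  expect_error(smooth_activity(s, window = 10), "odd")
  expect_error(smooth_activity(s, window = 11, polyorder = 12), "smaller")
  expect_error(smooth_activity(s, window = 101), "exceeds")
})

test_that("smoothing equals a per-window least-squares polynomial oracle", {
  set.seed(3)
  n <- 61; w <- 9; p <- 2
  s <- structure(data.frame(bin_start = (0:(n - 1)) * 60,
                            bin_mid = (0:(n - 1)) * 60 + 30,
                            rate = rpois(n, 6)),
                 class = c("activity_series", "data.frame"))
  sm <- smooth_activity(s, window = w, polyorder = p)
  h <- (w - 1) / 2
  for (i in (h + 1):(n - h)) {       # interior points only
    idx <- (i - h):(i + h)
    fit <- lm(y ~ poly(x, p, raw = TRUE),
              data = data.frame(x = -h:h, y = s$rate[idx]))
    expect_equal(sm$smoothed_rate[i], max(0, unname(predict(fit)[h + 1])),
                 tolerance = 1e-8)
  }
})

test_that("psi_aemax is the smoothed global maximum, ties to more negative", {
  tl <- linear_timeline(0, 6000, -0.2, -6.2)
  base <- structure(data.frame(bin_start = 0:99 * 60, bin_mid = 0:99 * 60 + 30,
                               rate = 0),
                    class = c("activity_series", "data.frame"))
  # single triangular peak at bin 41
  s <- base; s$rate <- pmax(0, 10 - abs(seq_len(100) - 41))
  s <- smooth_activity(s, window = 5, polyorder = 2)
  s <- attach_psi(s, tl)
  expect_equal(as.numeric(find_psi_aemax(s)), s$psi[41], tolerance = 0.05)
  # two peaks: 8 then 10 per min -> argmax oracle picks the 10
  s2 <- base
  s2$rate <- pmax(0, 8 - abs(seq_len(100) - 20)) + pmax(0, 10 - abs(seq_len(100) - 70))
  s2$smoothed_rate <- s2$rate   # identity smoothing for the oracle check
  s2 <- attach_psi(s2, tl)
  expect_equal(as.numeric(find_psi_aemax(s2)), s2$psi[which.max(s2$rate)])
  # secondary peak appears in diagnostics
  pk <- attr(find_psi_aemax(s2), "peaks")
  expect_true(any(abs(pk$bin - 20) <= 1))
  # plateau tie breaks toward more negative psi
  s3 <- base; s3$rate[40:50] <- 7; s3$smoothed_rate <- s3$rate
  s3 <- attach_psi(s3, tl)
  expect_equal(as.numeric(find_psi_aemax(s3)), s3$psi[50])
  # all-zero series: no peak
  s4 <- base; s4$smoothed_rate <- 0; s4 <- attach_psi(s4, tl)
  expect_error(find_psi_aemax(s4), "no peak")
})

test_that("group summary matches the textbook mean/SE formulas", {
  g <- summarize_group(-2)
  expect_equal(g$mean, -2); expect_equal(g$se, 0); expect_true(attr(g, "single"))
  g2 <- summarize_group(c(-1, -3))
  expect_equal(g2$mean, -2); expect_equal(g2$se, 1)
  set.seed(8)
  for (i in 1:10) {
    v <- rnorm(sample(3:12, 1), -3, 0.5)
    g3 <- summarize_group(v)
    expect_equal(g3$mean, sum(v) / length(v))
    expect_equal(g3$se, sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / sqrt(length(v)))
  }
  expect_error(summarize_group(numeric(0)), "no values")
})

test_that("binned counts conserve hits on synthetic streams", {
  w <- small_world(seed = 4, n_conduits = 300)
  ae <- gen_ae_stream(w$pop, w$truth, w$cfg)
  s <- bin_activity(ae)
  expect_equal(sum(s$rate), length(ae$time))
  expect_true(all(diff(s$bin_start) == 60))
})

test_that("nuisance hits after the embolism peak do not move psi_aemax", {
  truth <- drydown_truth(seed = 12)
  cfg_off <- synthetic_config(n_conduits = 1500, small_fraction = 0,
                              coupling = "none", nuisance_rate_end = 0)
  cfg_on <- synthetic_config(n_conduits = 1500, small_fraction = 0,
                             coupling = "none", nuisance_rate_end = 4,
                             nuisance_onset = 0.85)
  pop <- gen_conduit_population(cfg_off, truth)
  tl <- gen_psi_trajectory(truth)
  p_off <- ae_analyze(gen_ae_stream(pop, truth, cfg_off), tl, window = 151)$psi_aemax
  p_on <- ae_analyze(gen_ae_stream(pop, truth, cfg_on), tl, window = 151)$psi_aemax
  expect_equal(p_on, p_off, tolerance = 0.15)
})
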