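#' Configuration for the synthetic drydown simulator
#'
#' Collects every tunable of the simulated bench-drydown experiment. Defaults
#' emulate a seedling hypocotyl monitored simultaneously with an acoustic
#' sensor and an optical clamp: frames every 150 s, a 35 dB acoustic
#' detection threshold, 2-3 proxy plants sacrificed per pressure-chamber
#' timepoint, and a conduit-diameter mixture with a ~14% point mass in the
#' 1 um class (the small-conduit feature whose invisibility to the optical
#' method the simulator is designed to reproduce).
#'
#' @param n_conduits Number of conduits in the rendered xylem region.
#' @param diameter_meanlog,diameter_sdlog Lognormal body of the diameter
#'   mixture (um); defaults give a median of ~6 um.
#' @param small_fraction Mass fraction of the point mass of small conduits
#'   (diameters uniform in [0.5, 1.5) um), in [0, 1).
#' @param coupling Diameter-threshold coupling: `"none"` (independent),
#'   `"shift"` (small-class thresholds shifted `small_shift_mpa` more
#'   negative; the pit-area-hypothesis emulation), or `"rank"` (comonotone:
#'   smallest diameter gets the most negative threshold).
#' @param small_shift_mpa Extra tension (MPa, positive number) applied to
#'   small-class thresholds under `coupling = "shift"`; default 1.5.
#' @param nuisance_rate_end Nuisance (non-embolism) AE rate at the end of the
#'   record, hits per minute. 0 disables the nuisance process.
#' @param nuisance_onset Fraction of the record after which nuisance signals
#'   start (default 0.7).
#' @param nuisance_k Exponential growth rate of the nuisance intensity,
#'   1/s (default gives ~e^3 growth over the nuisance window).
#' @param amplitude_mean,amplitude_sd Truncated-normal hit amplitudes, dB,
#'   truncated below at `detection_threshold`.
#' @param detection_threshold Acoustic detection threshold, dB (default 35).
#' @param frame_interval Seconds between optical frames (default 150).
#' @param pixel_scale um per pixel (default 2).
#' @param noise_sd Gaussian pixel noise SD, intensity units (default 1).
#' @param step_delta Intensity step of a conduit disk at embolism (default 40).
#' @param min_detectable_px Analysis-side minimum cluster size carried in the
#'   dataset metadata (default 4 px).
#' @param psi_every Seconds between pressure-chamber timepoints (default 3600).
#' @param psi_noise_sd Per-reading noise SD, MPa (default 0.05).
#' @param plants_per_timepoint Vector to draw the number of sacrificed plants
#'   per timepoint from (default 2:3).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_conduits = 500L,
                             diameter_meanlog = log(6), diameter_sdlog = 0.45,
                             small_fraction = 0.14,
                             coupling = c("none", "shift", "rank"),
                             small_shift_mpa = 1.5,
                             nuisance_rate_end = 0, nuisance_onset = 0.7,
                             nuisance_k = 1.4e-4,
                             amplitude_mean = 45, amplitude_sd = 8,
                             detection_threshold = 35,
                             frame_interval = 150, pixel_scale = 2,
                             noise_sd = 1, step_delta = 40,
                             min_detectable_px = 4L,
                             psi_every = 3600, psi_noise_sd = 0.05,
                             plants_per_timepoint = 2:3) {
  coupling <- match.arg(coupling)
  if (n_conduits < 0) stop("n_conduits must be >= 0")
  if (small_fraction < 0 || small_fraction >= 1)
    stop("small_fraction must lie in [0, 1)")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Ground truth of a synthetic drydown
#'
#' The stated world of one simulated experiment: the monotone non-increasing
#' water-potential trajectory and the Weibull threshold distribution, plus
#' the master seed. Air-seeding tensions are drawn as T ~ Weibull(shape,
#' scale) and the embolism threshold of a conduit is -T (MPa).
#'
#' @param weibull_scale Threshold-distribution scale, MPa tension, > 0.
#' @param weibull_shape Dimensionless shape, > 0.
#' @param seed Master integer seed; named substreams (population, thresholds,
#'   nuisance, image noise, psi measurements) are derived from it.
#' @param duration Drydown length, seconds (<= 72000, i.e. 20 h).
#' @param psi_start,psi_end Endpoints of the default linear trajectory, MPa.
#' @param psi_knots Optional data.frame (`time`, `psi`) overriding the linear
#'   default; must be monotone non-increasing.
#' @return A `drydown_truth` list.
#' @export
drydown_truth <- function(weibull_scale = 3.54, weibull_shape = 5.86,
                          seed = 1L, duration = 72000,
                          psi_start = -0.2, psi_end = -7,
                          psi_knots = NULL) {
  if (weibull_scale <= 0 || weibull_shape <= 0)
    stop("Weibull scale and shape must be positive")
  if (duration <= 0 || duration > 72000)
    stop("duration must be in (0, 72000] s (bench drydowns run up to 20 h)")
  if (is.null(psi_knots)) {
    psi_knots <- data.frame(time = c(0, duration), psi = c(psi_start, psi_end))
  }
  stopifnot(all(c("time", "psi") %in% names(psi_knots)))
  if (is.unsorted(psi_knots$time, strictly = TRUE))
    stop("psi_knots times must be strictly increasing")
  if (any(diff(psi_knots$psi) > 0))
    stop("psi trajectory must be monotone non-increasing")
  structure(list(weibull_scale = weibull_scale, weibull_shape = weibull_shape,
                 seed = as.integer(seed), duration = duration,
                 psi_knots = psi_knots),
            class = "drydown_truth")
}

# deterministic substream seeds derived from the master seed (kept < 2^31)
substream_seed <- function(seed, stream) {
  offsets <- c(population = 101L, thresholds = 211L, nuisance = 307L,
               noise = 401L, psi = 503L, amplitude = 601L)
  if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
  (as.integer(seed) %% 1000000L) * 2017L + offsets[[stream]]
}

#' Generate a synthetic conduit population
#'
#' Draws conduit diameters from the configured mixture (lognormal body plus
#' an optional point mass of sub-resolution conduits in the 1 um class),
#' lays the conduits out on a jittered non-overlapping grid, and assigns each
#' an air-seeding threshold -T with T ~ Weibull(shape, scale). Under
#' `coupling = "shift"` the small-class thresholds receive an extra
#' `small_shift_mpa` of tension; under `"rank"` thresholds are assigned
#' comonotonically (smallest conduit, most negative threshold).
#'
#' @param config A [synthetic_config()].
#' @param truth A [drydown_truth()].
#' @return A `conduit_population`: data.frame with columns `diameter` (um),
#'   `x`, `y` (um centers), `threshold` (MPa, < 0), `small` (logical);
#'   attributes `region_um` (square side) and the generating truth.
#' @export
gen_conduit_population <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"), inherits(truth, "drydown_truth"))
  n <- as.integer(config$n_conduits)
  if (n <= 0) stop("n_conduits must be positive to generate a population")
  set.seed(substream_seed(truth$seed, "population"))
  small <- stats::runif(n) < config$small_fraction
  d <- stats::rlnorm(n, config$diameter_meanlog, config$diameter_sdlog)
  d[small] <- stats::runif(sum(small), 0.5, 1.5)
  # jittered grid layout: cells wide enough that rendered disks can never
  # touch (a 2 px guard band keeps 8-connected components separate)
  cell <- max(d) + 4 * config$pixel_scale
  k <- ceiling(sqrt(n))
  idx <- sample.int(k * k, n)  # shuffle cells so spatial position is random
  cx <- ((idx - 1L) %% k + 0.5) * cell
  cy <- ((idx - 1L) %/% k + 0.5) * cell
  jit <- (cell - max(d) - 2 * config$pixel_scale) / 2
  x <- cx + stats::runif(n, -jit, jit)
  y <- cy + stats::runif(n, -jit, jit)
  set.seed(substream_seed(truth$seed, "thresholds"))
  tension <- stats::rweibull(n, shape = truth$weibull_shape,
                             scale = truth$weibull_scale)
  if (config$coupling == "rank") {
    tension <- sort(tension, decreasing = TRUE)[rank(d, ties.method = "first")]
  } else if (config$coupling == "shift") {
    tension[small] <- tension[small] + config$small_shift_mpa
  }
  structure(data.frame(diameter = d, x = x, y = y, threshold = -tension,
                       small = small),
            class = c("conduit_population", "data.frame"),
            region_um = k * cell, truth = truth)
}

#' Ground-truth water-potential trajectory as a timeline
#'
#' Returns the truth's monotone piecewise-linear Psi(t) as a `psi_timeline`,
#' directly usable by [psi_at()]; this is the noise-free trajectory the
#' pressure-chamber sampling observes.
#'
#' @param truth A [drydown_truth()].
#' @return A `psi_timeline`.
#' @export
gen_psi_trajectory <- function(truth) {
  stopifnot(inherits(truth, "drydown_truth"))
  structure(list(knots = truth$psi_knots, range = range(truth$psi_knots$time)),
            class = "psi_timeline")
}

# first time the trajectory reaches psi <= thr; NA if never reached
crossing_time <- function(truth, thr) {
  k <- truth$psi_knots
  out <- rep(NA_real_, length(thr))
  # thresholds above psi(0) are crossed at t = 0 (approx clamps there);
  # thresholds below the terminal psi are never crossed
  reachable <- thr >= min(k$psi)
  if (any(reachable)) {
    # psi non-increasing: invert on the (psi, time) staircase; approx needs
    # increasing x, so flip signs; ties.min picks the first crossing
    f <- stats::approx(-k$psi, k$time, xout = -thr[reachable],
                       ties = min, rule = 2L)
    out[reachable] <- f$y
  }
  out
}

#' Generate a synthetic acoustic-emission stream
#'
#' One embolism hit per conduit at the first time the trajectory crosses its
#' threshold, plus an optional inhomogeneous-Poisson nuisance process whose
#' rate grows exponentially late in the drydown (emulating micro-fracture
#' and tissue-dehydration signals that keep acoustic records from
#' plateauing). Amplitudes are truncated-normal above the detection
#' threshold; the default analysis uses counts only.
#'
#' @param pop A `conduit_population`.
#' @param truth The matching [drydown_truth()].
#' @param config The matching [synthetic_config()].
#' @return An `ae_log`, with attribute `n_embolism` (ground-truth embolism
#'   hit count).
#' @export
gen_ae_stream <- function(pop, truth, config) {
  stopifnot(inherits(pop, "conduit_population"))
  if (!nrow(pop)) {
    warning("empty conduit population: empty AE log")
    return(ae_log(numeric(0), numeric(0), "synthetic",
                  config$detection_threshold))
  }
  t_emb <- crossing_time(truth, pop$threshold)
  t_emb <- t_emb[!is.na(t_emb)]
  t_nui <- numeric(0)
  if (config$nuisance_rate_end > 0) {
    set.seed(substream_seed(truth$seed, "nuisance"))
    t0 <- config$nuisance_onset * truth$duration
    k <- config$nuisance_k
    rate_end <- config$nuisance_rate_end / 60   # hits/s at t = duration
    r0 <- rate_end / exp(k * (truth$duration - t0))
    lambda_max <- rate_end
    n_cand <- stats::rpois(1L, lambda_max * (truth$duration - t0))
    tc <- stats::runif(n_cand, t0, truth$duration)
    keep <- stats::runif(n_cand) < r0 * exp(k * (tc - t0)) / lambda_max
    t_nui <- tc[keep]
  }
  times <- c(t_emb, t_nui)
  set.seed(substream_seed(truth$seed, "amplitude"))
  amp <- truncnorm::rtruncnorm(length(times), a = config$detection_threshold,
                               mean = config$amplitude_mean,
                               sd = config$amplitude_sd)
  log <- ae_log(times, amp, plant_id = "synthetic",
                detection_threshold = config$detection_threshold)
  attr(log, "n_embolism") <- length(t_emb)
  log
}

render_disk_pixels <- function(x_um, y_um, d_um, pixel_scale, nrow_px, ncol_px) {
  # pixels whose center lies within d/2 of the conduit center
  r <- d_um / 2
  c0 <- x_um / pixel_scale; r0 <- y_um / pixel_scale
  cols <- max(1L, floor(c0 - r / pixel_scale)):min(ncol_px, ceiling(c0 + r / pixel_scale) + 1L)
  rows <- max(1L, floor(r0 - r / pixel_scale)):min(nrow_px, ceiling(r0 + r / pixel_scale) + 1L)
  cc <- rep(cols, each = length(rows)); rr <- rep(rows, length(cols))
  px <- (cc - 0.5) * pixel_scale; py <- (rr - 0.5) * pixel_scale
  sel <- (px - x_um)^2 + (py - y_um)^2 <= r^2
  cbind(row = rr[sel], col = cc[sel])
}

#' Generate a synthetic optical-vulnerability image stack
#'
#' Renders each conduit as a disk on a uniform background; at its embolism
#' time the disk's intensity steps by `step_delta`, and independent Gaussian
#' pixel noise is added per frame. Frames are captured every
#' `frame_interval` seconds from t = 0 to the end of the drydown. Conduits
#' whose rendered disk covers no pixel center are invisible by construction
#' (the sub-resolution detection limit).
#'
#' @param pop A `conduit_population`.
#' @param truth The matching [drydown_truth()].
#' @param config The matching [synthetic_config()].
#' @return An `image_stack` (see [image_stack()]), with attributes
#'   `rendered_area_px` (per-conduit pixel areas) and `embolism_time` (s,
#'   NA when the threshold is never crossed).
#' @export
gen_ov_stack <- function(pop, truth, config) {
  stopifnot(inherits(pop, "conduit_population"))
  ps <- config$pixel_scale
  side_px <- as.integer(ceiling(attr(pop, "region_um") / ps))
  r <- pop$diameter / 2
  side_um <- side_px * ps
  bad <- pop$x - r < 0 | pop$y - r < 0 | pop$x + r > side_um | pop$y + r > side_um
  if (any(bad)) stop("conduit(s) outside frame: ", paste(which(bad), collapse = ", "))
  pix <- lapply(seq_len(nrow(pop)), function(i)
    render_disk_pixels(pop$x[i], pop$y[i], pop$diameter[i], ps, side_px, side_px))
  area_px <- vapply(pix, nrow, integer(1L))
  t_emb <- crossing_time(truth, pop$threshold)
  times <- seq(0, truth$duration, by = config$frame_interval)
  base <- matrix(100, side_px, side_px)
  set.seed(substream_seed(truth$seed, "noise"))
  frames <- vector("list", length(times))
  ord <- order(t_emb, na.last = TRUE)
  nxt <- 1L
  for (f in seq_along(times)) {
    while (nxt <= length(ord) && !is.na(t_emb[ord[nxt]]) &&
           t_emb[ord[nxt]] <= times[f]) {
      p <- pix[[ord[nxt]]]
      if (nrow(p)) base[p] <- base[p] + config$step_delta
      nxt <- nxt + 1L
    }
    frames[[f]] <- if (config$noise_sd > 0)
      base + matrix(stats::rnorm(side_px * side_px, 0, config$noise_sd),
                    side_px, side_px)
    else base
  }
  stack <- image_stack(frames, times, pixel_scale = ps)
  attr(stack, "rendered_area_px") <- area_px
  attr(stack, "embolism_time") <- t_emb
  stack
}

#' Generate synthetic pressure-chamber measurements
#'
#' At each scheduled timepoint, 2-3 proxy plants are "sacrificed": readings
#' equal the true trajectory plus independent Gaussian noise (clamped at 0,
#' a pressure chamber cannot read positive water potentials).
#'
#' @param truth A [drydown_truth()].
#' @param config A [synthetic_config()].
#' @return data.frame with columns `time`, `psi`, `plant_id`, ready for
#'   [build_timeline()].
#' @export
gen_psi_measurements <- function(truth, config) {
  stopifnot(inherits(truth, "drydown_truth"), inherits(config, "synthetic_config"))
  set.seed(substream_seed(truth$seed, "psi"))
  times <- seq(0, truth$duration, by = config$psi_every)
  n_per <- sample(config$plants_per_timepoint, length(times), replace = TRUE)
  t_all <- rep(times, n_per)
  traj <- gen_psi_trajectory(truth)
  psi <- psi_at(traj, t_all) + stats::rnorm(length(t_all), 0, config$psi_noise_sd)
  data.frame(time = t_all, psi = pmin(psi, 0),
             plant_id = sprintf("proxy%03d", seq_along(t_all)))
}

#' Simulate a full drydown experiment and write it to disk
#'
#' Runs every generator and writes the dataset in the same formats the
#' analysis reads: `ae.csv` (`time_s,amplitude_db,plant_id`), `psi.csv`
#' (`time_s,psi_mpa,plant_id`), a `frames/` directory with `manifest.csv`
#' (`frame,filename,time_s`), and a `truth.json` sidecar carrying the
#' generating parameters so downstream fits can be scored.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [synthetic_config()].
#' @param truth A [drydown_truth()].
#' @param write_frames Write the image stack (default TRUE; the stack is the
#'   bulky part of a dataset).
#' @param format Frame format, `"png"` or `"pgm"` (plain-text).
#' @return Invisibly, a list with the in-memory objects (`pop`, `ae`,
#'   `stack`, `measurements`, `truth`, `config`).
#' @export
simulate_drydown <- function(out_dir, config = synthetic_config(),
                             truth = drydown_truth(), write_frames = TRUE,
                             format = c("png", "pgm")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- gen_conduit_population(config, truth)
  ae <- gen_ae_stream(pop, truth, config)
  meas <- gen_psi_measurements(truth, config)
  utils::write.csv(data.frame(time_s = ae$time, amplitude_db = ae$amplitude,
                              plant_id = ae$plant_id),
                   file.path(out_dir, "ae.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(time_s = meas$time, psi_mpa = meas$psi,
                              plant_id = meas$plant_id),
                   file.path(out_dir, "psi.csv"), row.names = FALSE, quote = FALSE)
  stack <- NULL
  if (write_frames) {
    stack <- gen_ov_stack(pop, truth, config)
    write_image_stack(stack, file.path(out_dir, "frames"), format = format)
  }
  sidecar <- list(
    weibull_scale = truth$weibull_scale, weibull_shape = truth$weibull_shape,
    seed = truth$seed, duration = truth$duration,
    psi_knots = truth$psi_knots,
    n_conduits = config$n_conduits, small_fraction = config$small_fraction,
    coupling = config$coupling, small_shift_mpa = config$small_shift_mpa,
    frame_interval = config$frame_interval, pixel_scale = config$pixel_scale,
    noise_sd = config$noise_sd, detection_threshold = config$detection_threshold)
  jsonlite::write_json(sidecar, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pop = pop, ae = ae, stack = stack, measurements = meas,
                 truth = truth, config = config))
}
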