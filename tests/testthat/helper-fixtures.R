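# shared fixture builders; everything is generated in code at test time

# tiny image stack: conduit disks as index matrices on a flat background
tiny_stack <- function(frames, times = NULL) {
  if (is.null(times)) times <- (seq_along(frames) - 1) * 150
  image_stack(frames, times)
}

flat_frame <- function(n = 20, value = 100) matrix(value, n, n)

# frame with a square "disk" of given size stepped by delta
stepped_frame <- function(n = 20, rows, cols, delta = 40, value = 100) {
  f <- flat_frame(n, value)
  f[rows, cols] <- f[rows, cols] + delta
  f
}

# small synthetic world used across tests: cheap but complete
small_world <- function(seed = 1, n_conduits = 120, ...) {
  truth <- drydown_truth(seed = seed)
  cfg <- synthetic_config(n_conduits = n_conduits,
                          diameter_meanlog = log(6), diameter_sdlog = 0.25, ...)
  list(truth = truth, cfg = cfg,
       pop = gen_conduit_population(cfg, truth))
}

linear_timeline <- function(t0 = 0, t1 = 72000, psi0 = -0.2, psi1 = -7) {
  build_timeline(data.frame(time = c(t0, t1), psi = c(psi0, psi1),
                            plant_id = c("a", "b")))
}
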