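#' Read an acoustic-emission event log from CSV
#'
#' Expects columns `time_s`, `amplitude_db`, `plant_id`. Events are sorted in
#' time; amplitudes below the detection threshold are rejected (the recorder
#' should never log them).
#'
#' @param path CSV file path.
#' @param detection_threshold dB, default 35 (typical ultrasonic AE setup).
#' @return An `ae_log` object.
#' @export
read_ae_csv <- function(path, detection_threshold = 35) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_s", "amplitude_db", "plant_id")
  if (!all(req %in% names(d)))
    stop("AE CSV must have columns time_s, amplitude_db, plant_id")
  ae_log(time = as.numeric(d$time_s), amplitude = as.numeric(d$amplitude_db),
         plant_id = if (nrow(d)) as.character(d$plant_id[1L]) else "unknown",
         detection_threshold = detection_threshold)
}

#' Construct an AE event log
#'
#' @param time Hit times, seconds (sorted internally).
#' @param amplitude Hit amplitudes, dB; must all be >= `detection_threshold`.
#' @param plant_id Identifier of the monitored individual.
#' @param detection_threshold Recorder threshold, dB (default 35).
#' @return An `ae_log` object.
#' @export
ae_log <- function(time, amplitude = NULL, plant_id = "plant1",
                   detection_threshold = 35) {
  stopifnot(is.numeric(time))
  if (is.null(amplitude)) amplitude <- rep(detection_threshold, length(time))
  stopifnot(length(amplitude) == length(time))
  if (length(amplitude) && any(amplitude < detection_threshold))
    stop(sprintf("amplitudes below the %g dB detection threshold are not valid hits",
                 detection_threshold))
  ord <- order(time)
  structure(list(time = time[ord], amplitude = amplitude[ord],
                 plant_id = as.character(plant_id),
                 detection_threshold = detection_threshold),
            class = "ae_log")
}

#' @export
print.ae_log <- function(x, ...) {
  cat(sprintf("AE log '%s': %d hits, threshold %g dB", x$plant_id,
              length(x$time), x$detection_threshold))
  if (length(x$time)) cat(sprintf(", t in [%g, %g] s", min(x$time), max(x$time)))
  cat("\n")
  invisible(x)
}

#' Bin AE hits into an acoustic-activity series
#'
#' Counts hits in contiguous half-open bins `[start, start + width)`. With the
#' default 60 s width the count per bin is the acoustic activity in
#' signals per minute. Empty bins are present with rate 0.
#'
#' @param log An `ae_log`.
#' @param bin_width Seconds, default 60.
#' @param t_end Optional end of record, s; defaults to the last hit time
#'   (ensures trailing silent bins when the record ran longer).
#' @return An `activity_series` data.frame: `bin_start`, `bin_mid`, `rate`.
#' @export
bin_activity <- function(log, bin_width = 60, t_end = NULL) {
  stopifnot(inherits(log, "ae_log"))
  if (!length(log$time)) stop("empty AE log: no activity to bin")
  if (is.null(t_end)) t_end <- max(log$time)
  n_bins <- max(1L, ceiling((t_end + 1e-9) / bin_width))
  idx <- pmin(floor(log$time / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  starts <- (seq_len(n_bins) - 1L) * bin_width
  structure(data.frame(bin_start = starts, bin_mid = starts + bin_width / 2,
                       rate = counts),
            class = c("activity_series", "data.frame"),
            bin_width = bin_width, plant_id = log$plant_id)
}

#' Savitzky-Golay filter coefficients
#'
#' Convolution weights of the central point of a moving local least-squares
#' polynomial of order `polyorder` over `window` points.
#'
#' @param window Odd window length (number of bins).
#' @param polyorder Polynomial order, < window.
#' @return Numeric vector of length `window`.
#' @keywords internal
sg_coefficients <- function(window, polyorder) {
  if (window %% 2L != 1L) stop("Savitzky-Golay window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than the window")
  h <- (window - 1L) %/% 2L
  x <- seq(-h, h)
  A <- outer(x, 0:polyorder, `^`)
  # row of the hat matrix for the window center
  (A %*% solve(crossprod(A), t(A)))[h + 1L, ]
}

#' Savitzky-Golay smooth an activity series
#'
#' Moving local polynomial least squares, the standard peak-preserving
#' smoother for AE rate series. Interior points use the central convolution
#' weights; within half a window of each edge the local polynomial is fitted
#' to the first/last full window and evaluated there (the usual
#' edge-interpolation rule). Negative smoothed rates are floored at 0.
#'
#' @param series An `activity_series` from [bin_activity()].
#' @param window Odd number of bins, default 31.
#' @param polyorder Polynomial order, default 3.
#' @return The series with a `smoothed_rate` column; parameters in attributes.
#' @export
smooth_activity <- function(series, window = 31L, polyorder = 3L) {
  stopifnot(inherits(series, "activity_series"))
  n <- nrow(series)
  if (window > n) stop(sprintf("window (%d) exceeds series length (%d)", window, n))
  y <- series$rate
  w <- sg_coefficients(window, polyorder)
  h <- (window - 1L) %/% 2L
  sm <- as.numeric(stats::filter(y, rev(w), sides = 2L))
  # edges: fit the polynomial once per end and evaluate inside the half-window
  fit_edge <- function(idx) {
    x <- seq_along(idx) - 1
    stats::lm.fit(outer(x, 0:polyorder, `^`), y[idx])$coefficients
  }
  cf <- fit_edge(1:window)
  sm[1:h] <- outer(0:(h - 1L), 0:polyorder, `^`) %*% cf
  cf <- fit_edge((n - window + 1L):n)
  sm[(n - h + 1L):n] <- outer((window - h):(window - 1L), 0:polyorder, `^`) %*% cf
  series$smoothed_rate <- pmax(sm, 0)
  attr(series, "sg_window") <- window
  attr(series, "sg_polyorder") <- polyorder
  series
}

#' Attach water potentials to an activity series
#'
#' Evaluates a [build_timeline()] timeline at each bin midpoint (bin edge vs
#' midpoint differs by at most half a bin, 30 s at the default width).
#'
#' @param series An `activity_series`.
#' @param timeline A `psi_timeline`.
#' @return The series with a `psi` column (MPa).
#' @export
attach_psi <- function(series, timeline) {
  stopifnot(inherits(series, "activity_series"))
  series$psi <- suppressWarnings(psi_at(timeline, series$bin_mid))
  series
}

#' Water potential at maximum acoustic activity (Psi_AEmax)
#'
#' Returns the Psi at the global maximum of the smoothed rate — the "main
#' peak" of acoustic activity, used as the 50%-embolism proxy. Ties (exact
#' plateaus) break toward the more negative Psi. Secondary local maxima are
#' reported in the `peaks` diagnostic attribute, since seedling records often
#' show additional early peaks attributed to vulnerable primary xylem.
#'
#' @param series An `activity_series` with `smoothed_rate` and `psi` columns
#'   (see [smooth_activity()], [attach_psi()]).
#' @return Psi_AEmax, MPa, with attribute `peaks` (diagnostic data.frame).
#' @export
find_psi_aemax <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  if (is.null(series$smoothed_rate)) stop("run smooth_activity() first")
  if (is.null(series$psi)) stop("attach a water-potential timeline first (attach_psi)")
  y <- series$smoothed_rate
  if (all(y == 0)) stop("all-zero smoothed activity: no peak")
  at_max <- which(y == max(y))
  pick <- at_max[which.min(series$psi[at_max])]   # plateau tie -> most negative
  interior <- which(diff(sign(diff(y))) < 0) + 1L # local maxima, diagnostics
  peaks <- data.frame(bin = interior, psi = series$psi[interior],
                      rate = y[interior])
  structure(series$psi[pick], peaks = peaks[order(-peaks$rate), ])
}

#' Summarize per-individual Psi_AEmax values for a group
#'
#' @param values Per-individual Psi_AEmax, MPa.
#' @return List with `mean`, `se` (sd/sqrt(n)), `n`. SE is 0 (flagged via
#'   attribute) for a single individual.
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (!n) stop("no values to summarize")
  se <- if (n > 1L) stats::sd(values) / sqrt(n) else 0
  structure(list(mean = mean(values), se = se, n = n),
            single = n == 1L, class = "ae_group_summary")
}

#' @export
print.ae_group_summary <- function(x, ...) {
  cat(sprintf("Psi_AEmax: %.2f +/- %.2f MPa (mean +/- SE, n = %d)\n",
              x$mean, x$se, x$n))
  invisible(x)
}

#' Run the full AE pipeline for one individual
#'
#' Bin at `bin_width`, smooth, attach Psi, and extract Psi_AEmax.
#'
#' @param log An `ae_log`.
#' @param timeline A `psi_timeline`.
#' @param bin_width Seconds, default 60.
#' @param window,polyorder Savitzky-Golay parameters (defaults 31, 3).
#' @return List with `psi_aemax` (MPa) and the annotated `series`.
#' @export
ae_analyze <- function(log, timeline, bin_width = 60, window = 31L, polyorder = 3L) {
  series <- bin_activity(log, bin_width = bin_width)
  window <- min(window, if (nrow(series) %% 2L) nrow(series) else nrow(series) - 1L)
  series <- smooth_activity(series, window = window, polyorder = polyorder)
  series <- attach_psi(series, timeline)
  psi <- find_psi_aemax(series)
  list(psi_aemax = as.numeric(psi), series = series,
       peaks = attr(psi, "peaks"),
       params = list(bin_width = bin_width, window = window, polyorder = polyorder))
}
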