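#' Read pressure-chamber water-potential readings from CSV
#'
#' Expects the columns `time_s`, `psi_mpa`, `plant_id` (header mandatory,
#' comma separated, dot decimal).
#'
#' @param path CSV file path.
#' @return data.frame with columns `time` (s), `psi` (MPa, <= 0), `plant_id`.
#' @export
read_psi_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_s", "psi_mpa", "plant_id")
  if (!all(req %in% names(d)))
    stop("psi CSV must have columns time_s, psi_mpa, plant_id")
  out <- data.frame(time = as.numeric(d$time_s), psi = as.numeric(d$psi_mpa),
                    plant_id = as.character(d$plant_id))
  if (any(out$psi > 0)) stop("psi readings must be <= 0 MPa")
  if (any(out$time < 0)) stop("times must be >= 0 s")
  out
}

#' Build a piecewise-linear water-potential timeline
#'
#' Discrete pressure-chamber readings are grouped in time (readings within
#' `grouping_tolerance` seconds of the running group start belong to one
#' timepoint), averaged per timepoint, and the resulting knots define a
#' piecewise-linear Psi(t). With 2-3 sacrificed plants per timepoint,
#' per-timepoint averaging is the natural reading of interpolating "between
#' consecutive measured potentials"; set `average = FALSE` to keep every
#' reading as its own knot (ties averaged regardless, since knot times must
#' be strictly increasing).
#'
#' Non-monotone knot sequences (Psi increasing with time) are kept as
#' measured but flagged with a warning: measurement noise, not a corrected
#' quantity.
#'
#' @param measurements data.frame with columns `time` (s) and `psi` (MPa);
#'   as returned by [read_psi_csv()] or [gen_psi_measurements()].
#' @param grouping_tolerance Seconds; readings this close are one timepoint.
#' @param average Average readings within a timepoint (default TRUE).
#' @return A `psi_timeline` object with a `knots` data.frame (`time`, `psi`).
#' @export
build_timeline <- function(measurements, grouping_tolerance = 60, average = TRUE) {
  d <- as.data.frame(measurements)
  stopifnot(all(c("time", "psi") %in% names(d)))
  d <- d[is.finite(d$time) & is.finite(d$psi), ]
  if (!nrow(d)) stop("no finite measurements")
  d <- d[order(d$time), ]
  if (average) {
    grp <- integer(nrow(d)); g <- 1L; t0 <- d$time[1L]
    for (i in seq_len(nrow(d))) {
      if (d$time[i] - t0 > grouping_tolerance) { g <- g + 1L; t0 <- d$time[i] }
      grp[i] <- g
    }
  } else {
    grp <- match(d$time, unique(d$time))
  }
  knots <- data.frame(
    time = as.numeric(tapply(d$time, grp, mean)),
    psi = as.numeric(tapply(d$psi, grp, mean)))
  knots <- knots[order(knots$time), ]
  rownames(knots) <- NULL
  if (nrow(knots) < 2L)
    stop("need at least 2 distinct timepoints after grouping to build a timeline")
  if (any(diff(knots$psi) > 0))
    warning("timeline is not monotone non-increasing (kept as measured)")
  structure(list(knots = knots, range = range(knots$time)), class = "psi_timeline")
}

#' @export
print.psi_timeline <- function(x, ...) {
  cat(sprintf("Water-potential timeline: %d knots, t in [%g, %g] s, psi in [%g, %g] MPa\n",
              nrow(x$knots), x$range[1L], x$range[2L],
              min(x$knots$psi), max(x$knots$psi)))
  invisible(x)
}

#' Evaluate a timeline at arbitrary times
#'
#' Exact linear interpolation between bracketing knots; knot times return the
#' knot values. Outside the measured range the `extrapolation` policy
#' applies: `"clamp"` (default) holds the end values and warns, `"linear"`
#' extends the first/last segment, `"error"` stops.
#'
#' @param timeline A `psi_timeline` from [build_timeline()].
#' @param t Time(s), seconds.
#' @param extrapolation One of `"clamp"`, `"linear"`, `"error"`.
#' @return Water potential(s), MPa.
#' @export
psi_at <- function(timeline, t, extrapolation = c("clamp", "linear", "error")) {
  stopifnot(inherits(timeline, "psi_timeline"), is.numeric(t))
  extrapolation <- match.arg(extrapolation)
  k <- timeline$knots
  outside <- t < k$time[1L] | t > k$time[nrow(k)]
  if (any(outside)) {
    if (extrapolation == "error")
      stop(sprintf("time(s) outside measured range [%g, %g] s",
                   k$time[1L], k$time[nrow(k)]))
    if (extrapolation == "clamp")
      warning("times outside measured range clamped to end values")
  }
  if (extrapolation == "linear") {
    # extend the first and last segments
    slope1 <- (k$psi[2L] - k$psi[1L]) / (k$time[2L] - k$time[1L])
    n <- nrow(k)
    slopeN <- (k$psi[n] - k$psi[n - 1L]) / (k$time[n] - k$time[n - 1L])
    out <- stats::approx(k$time, k$psi, xout = pmin(pmax(t, k$time[1L]), k$time[n]))$y
    lo <- t < k$time[1L]; hi <- t > k$time[n]
    out[lo] <- k$psi[1L] + slope1 * (t[lo] - k$time[1L])
    out[hi] <- k$psi[n] + slopeN * (t[hi] - k$time[n])
    return(out)
  }
  stats::approx(k$time, k$psi, xout = t, rule = 2L)$y
}

#' Export timeline knots as CSV
#'
#' @param timeline A `psi_timeline`.
#' @param path Output CSV path (`time_s,psi_mpa`).
#' @export
write_timeline_csv <- function(timeline, path) {
  stopifnot(inherits(timeline, "psi_timeline"))
  utils::write.csv(
    data.frame(time_s = timeline$knots$time, psi_mpa = timeline$knots$psi),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
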