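#' Two-parameter Weibull vulnerability curve
#'
#' Constructs a vulnerability curve (VC) object describing the fraction of
#' embolized xylem area as a function of water potential,
#' \deqn{F(\Psi) = 1 - \exp\{-(|\Psi|/scale)^{shape}\},}
#' the curve family conventionally fitted to optical and hydraulic
#' vulnerability data. `scale` is a tension (positive, MPa); water potentials
#' are stored signed-negative everywhere else in the package.
#'
#' @param scale Weibull scale, MPa tension, > 0. Named `scale` (not `b`) to
#'   avoid collision with the anatomical conduit-span symbol.
#' @param shape Weibull shape, dimensionless, > 0.
#' @return An object of class `weibull_vc`.
#' @examples
#' vc <- weibull_vc(scale = 3.54, shape = 5.86)
#' vc_fraction(vc, -3.54)  # 1 - exp(-1)
#' vc_quantile(vc, 0.5)
#' @export
weibull_vc <- function(scale, shape) {
  stopifnot(is.numeric(scale), is.numeric(shape),
            length(scale) == 1L, length(shape) == 1L)
  if (!is.finite(scale) || scale <= 0) stop("`scale` must be a positive tension (MPa)")
  if (!is.finite(shape) || shape <= 0) stop("`shape` must be positive")
  structure(list(scale = scale, shape = shape), class = "weibull_vc")
}

#' @export
print.weibull_vc <- function(x, ...) {
  cat(sprintf("Weibull vulnerability curve: scale = %.4g MPa, shape = %.4g\n",
              x$scale, x$shape))
  cat(sprintf("  Psi12 = %.2f  Psi50 = %.2f  Psi88 = %.2f MPa\n",
              vc_quantile(x, 0.12), vc_quantile(x, 0.5), vc_quantile(x, 0.88)))
  invisible(x)
}

#' Embolized fraction at a water potential
#'
#' Evaluates the Weibull curve \eqn{F(\Psi) = 1 - \exp\{-(|\Psi|/scale)^{shape}\}}.
#'
#' @param curve A [weibull_vc()] object.
#' @param psi Water potential(s), MPa, must be <= 0.
#' @return Fraction(s) in [0, 1].
#' @export
vc_fraction <- function(curve, psi) {
  stopifnot(inherits(curve, "weibull_vc"), is.numeric(psi))
  if (any(psi > 0, na.rm = TRUE)) stop("water potential must be <= 0 MPa")
  # expm1 keeps precision for very small tensions
  -expm1(-(abs(psi) / curve$scale)^curve$shape)
}

#' Water potential at a given embolized fraction (curve quantile)
#'
#' Closed-form inverse of the Weibull curve:
#' \eqn{\Psi_p = -scale \cdot (-\ln(1-p))^{1/shape}}. The 12%, 50% and 88%
#' quantiles are the standard vulnerability thresholds Psi12, Psi50, Psi88.
#'
#' @param curve A [weibull_vc()] object.
#' @param p Fraction(s) strictly inside (0, 1).
#' @return Water potential(s), MPa (negative).
#' @export
vc_quantile <- function(curve, p) {
  stopifnot(inherits(curve, "weibull_vc"), is.numeric(p))
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) stop("`p` must lie strictly in (0, 1)")
  -curve$scale * (-log1p(-p))^(1 / curve$shape)
}

#' Solve a Weibull curve through two quantile constraints
#'
#' Given two (water potential, fraction) pairs, recovers the unique Weibull
#' curve passing through both:
#' \deqn{shape = \frac{\ln[\ln(1-p_b)/\ln(1-p_a)]}{\ln(|\Psi_b|/|\Psi_a|)}}
#' and scale from either constraint. This is the algebra used to check
#' published (Psi12, Psi50, Psi88) triplets for internal consistency: solve
#' through Psi12 and Psi88, read off the 50% quantile.
#'
#' @param psi_a,psi_b Water potentials, MPa (negative), distinct tensions.
#' @param p_a,p_b Fractions in (0, 1), distinct.
#' @return A [weibull_vc()] object reproducing both inputs.
#' @examples
#' vc <- solve_from_two_quantiles(-0.96, 0.12, -2.16, 0.88)
#' round(vc_quantile(vc, 0.5), 2)
#' @export
solve_from_two_quantiles <- function(psi_a, p_a, psi_b, p_b) {
  stopifnot(is.numeric(psi_a), is.numeric(psi_b), is.numeric(p_a), is.numeric(p_b))
  if (psi_a > 0 || psi_b > 0) stop("water potentials must be <= 0 MPa")
  if (any(c(p_a, p_b) <= 0) || any(c(p_a, p_b) >= 1)) stop("fractions must lie in (0, 1)")
  ta <- abs(psi_a); tb <- abs(psi_b)
  if (ta == tb) stop("degenerate constraints: equal tensions")
  if (p_a == p_b) stop("degenerate constraints: equal fractions")
  shape <- log(log1p(-p_b) / log1p(-p_a)) / log(tb / ta)
  if (!is.finite(shape) || shape <= 0)
    stop("constraints are inconsistent with a monotone Weibull curve")
  scale <- ta / (-log1p(-p_a))^(1 / shape)
  weibull_vc(scale = scale, shape = shape)
}

empirical_crossing <- function(psi, frac, p) {
  # first tension at which the empirical fraction crosses p (linear interp)
  ord <- order(abs(psi))
  tens <- abs(psi)[ord]; f <- frac[ord]
  above <- which(f >= p)
  if (!length(above)) return(max(tens))
  i <- above[1L]
  if (i == 1L || f[i] == f[i - 1L]) return(tens[i])
  tens[i - 1L] + (p - f[i - 1L]) / (f[i] - f[i - 1L]) * (tens[i] - tens[i - 1L])
}

vc_start_values <- function(psi, frac) {
  # initialize from the empirical 12%/88% crossing points via the closed-form
  # two-quantile solver; removes starting-value sensitivity at extreme shapes
  t12 <- empirical_crossing(psi, frac, 0.12)
  t88 <- empirical_crossing(psi, frac, 0.88)
  if (t88 <= t12) {  # degenerate span: fall back to median crossing heuristic
    t50 <- empirical_crossing(psi, frac, 0.5)
    return(weibull_vc(scale = t50 / log(2)^(1 / 3), shape = 3))
  }
  solve_from_two_quantiles(-t12, 0.12, -t88, 0.88)
}

vc_rss <- function(par, tens, frac) {
  f <- -expm1(-(tens / exp(par[1L]))^exp(par[2L]))
  sum((frac - f)^2)
}

fit_vc_core <- function(psi, frac, start = NULL) {
  tens <- abs(psi)
  if (is.null(start)) start <- vc_start_values(psi, frac)
  p0 <- c(log(start$scale), log(start$shape))
  opt <- stats::optim(p0, vc_rss, tens = tens, frac = frac,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  # polish with BFGS; Nelder-Mead alone can stop short at steep shapes
  opt2 <- tryCatch(
    stats::optim(opt$par, vc_rss, tens = tens, frac = frac, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) opt)
  if (opt2$value <= opt$value) opt <- opt2
  list(curve = weibull_vc(exp(opt$par[1L]), exp(opt$par[2L])),
       rss = opt$value, convergence = opt$convergence)
}

#' Fit a Weibull vulnerability curve to percent-embolized-area data
#'
#' Unweighted least squares of embolized fraction (percent/100) against water
#' potential. The optimizer is initialized from the closed-form two-quantile
#' solver applied to the empirical 12%/88% crossing points, which keeps fits
#' stable even for near-step leaf curves (shape of order 50-100).
#'
#' @param points An `ov_series` (see [accumulate_area()]) or a data.frame with
#'   columns `psi` (MPa, <= 0) and either `percent` (0-100) or `fraction`.
#' @param min_points Minimum number of points required (default 4).
#' @return A `vc_fit` object: the fitted `weibull_vc`, the Psi12/50/88
#'   thresholds, residual sum of squares, and the data used (for CIs).
#' @seealso [ci_thresholds()] for confidence intervals.
#' @export
fit_vc <- function(points, min_points = 4L) {
  d <- as.data.frame(points)
  if (!"psi" %in% names(d)) stop("`points` must contain a `psi` column")
  frac <- if ("fraction" %in% names(d)) d$fraction else {
    if (!"percent" %in% names(d)) stop("`points` must contain `percent` or `fraction`")
    d$percent / 100
  }
  keep <- is.finite(d$psi) & is.finite(frac)
  psi <- d$psi[keep]; frac <- frac[keep]
  if (length(psi) < min_points)
    stop(sprintf("need at least %d finite points to fit", min_points))
  if (min(frac) > 0.5 || max(frac) < 0.5)
    warning("data do not span the 50% level; thresholds are extrapolated and CIs will be wide")
  fit <- fit_vc_core(psi, frac)
  if (fit$convergence != 0)
    stop(sprintf("vulnerability-curve fit did not converge (optim code %d, rss %.4g)",
                 fit$convergence, fit$rss))
  structure(list(
    curve = fit$curve,
    psi_ov12 = vc_quantile(fit$curve, 0.12),
    psi_ov50 = vc_quantile(fit$curve, 0.50),
    psi_ov88 = vc_quantile(fit$curve, 0.88),
    rss = fit$rss,
    n_points = length(psi),
    data = data.frame(psi = psi, fraction = frac)
  ), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("Weibull VC fit (n = %d, rss = %.4g)\n", x$n_points, x$rss))
  cat(sprintf("  scale = %.4g MPa  shape = %.4g\n", x$curve$scale, x$curve$shape))
  tab <- data.frame(threshold = c("Psi_OV12", "Psi_OV50", "Psi_OV88"),
                    psi_mpa = round(c(x$psi_ov12, x$psi_ov50, x$psi_ov88), 2))
  if (!is.null(x$ci)) {
    tab$ci_low <- round(x$ci[, "low"], 2)
    tab$ci_high <- round(x$ci[, "high"], 2)
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

profile_threshold_ci <- function(psi, frac, fit, p, level) {
  # SSR profiling: reparameterize by (tension at quantile p, shape); the CI is
  # the set of tensions whose profiled RSS passes the likelihood-ratio cut
  # n*log(RSS/RSS_min) <= qchisq(level, 1) under Gaussian errors.
  n <- length(psi); tens <- abs(psi)
  cut <- stats::qchisq(level, 1L)
  lp <- -log1p(-p)                       # -ln(1-p)
  rss_at <- function(tq) {
    f <- function(lsh) {
      sh <- exp(lsh)
      sc <- tq / lp^(1 / sh)
      vc_rss(c(log(sc), lsh), tens, frac)
    }
    stats::optimize(f, interval = log(c(1e-2, 1e4)), tol = 1e-10)$objective
  }
  # floor RSS0 so noise-free fits profile to a degenerate (near-zero-width)
  # interval instead of dividing by zero
  rss0 <- max(fit$rss, 1e-9 * sum(frac^2) / n, 1e-300)
  dev <- function(tq) n * log(max(rss_at(tq), 1e-300) / rss0) - cut
  tq0 <- abs(vc_quantile(fit$curve, p))
  bound <- function(direction) {
    step <- 0.05 * tq0 + 1e-3
    lo <- tq0; hi <- tq0
    for (i in 1:60) {
      cand <- tq0 + direction * step * i
      if (cand <= 0) return(0)
      if (dev(cand) > 0) { hi <- cand; break }
      lo <- cand
      if (i == 60) return(cand)  # never crossed: unbounded at this scale
    }
    stats::uniroot(dev, sort(c(lo, hi)), tol = 1e-6)$root
  }
  c(low = -bound(+1), high = -bound(-1))   # more tension = more negative psi
}

#' Confidence intervals for vulnerability thresholds
#'
#' Adds 95% (by default) confidence intervals for Psi12, Psi50 and Psi88 to a
#' fitted curve, either by case-resampling bootstrap (percentile intervals
#' over `B` refits) or by residual-sum-of-squares profiling of each threshold.
#'
#' @param fit A `vc_fit` from [fit_vc()].
#' @param method `"bootstrap"` or `"profile"`.
#' @param B Bootstrap replicates (ignored for profiling). Fewer than 200
#'   triggers a warning.
#' @param level Confidence level, default 0.95.
#' @param seed Optional integer seed for the bootstrap.
#' @return The `vc_fit` with a `ci` matrix (rows Psi12/50/88, columns
#'   low/high, MPa) and the method recorded.
#' @export
ci_thresholds <- function(fit, method = c("bootstrap", "profile"), B = 1000L,
                          level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "vc_fit"))
  method <- match.arg(method)
  psi <- fit$data$psi; frac <- fit$data$fraction
  probs <- c(0.12, 0.50, 0.88)
  if (method == "bootstrap") {
    if (B < 200L) warning("B < 200 bootstrap replicates gives unstable intervals")
    if (!is.null(seed)) set.seed(seed)
    n <- length(psi)
    qs <- matrix(NA_real_, nrow = B, ncol = 3L)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- tryCatch(fit_vc_core(psi[idx], frac[idx], start = fit$curve),
                     error = function(e) NULL)
      if (!is.null(bf)) qs[b, ] <- vc_quantile(bf$curve, probs)
    }
    a <- (1 - level) / 2
    ci <- t(apply(qs, 2L, stats::quantile,
                  probs = c(a, 1 - a), na.rm = TRUE, names = FALSE))
    colnames(ci) <- c("low", "high")
  } else {
    ci <- t(vapply(probs, function(p)
      profile_threshold_ci(psi, frac, fit, p, level), c(low = 0, high = 0)))
  }
  rownames(ci) <- c("psi_ov12", "psi_ov50", "psi_ov88")
  fit$ci <- ci
  fit$ci_method <- method
  fit$ci_level <- level
  fit
}
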