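#' Conduit diameter from lumen area
#'
#' Converts a measured lumen area to an equivalent diameter under the shape
#' model conventional for the taxon: circular lumina for angiosperm vessels
#' (`d = 2 sqrt(area/pi)`) and square lumina for conifer tracheids
#' (`d = sqrt(area)`).
#'
#' @param area Lumen area(s), um^2, > 0.
#' @param shape `"circle"` or `"square"`.
#' @return Diameter(s), um.
#' @export
diameter_from_area <- function(area, shape = c("circle", "square")) {
  shape <- match.arg(shape)
  if (any(!is.finite(area) | area <= 0)) stop("lumen areas must be positive")
  if (shape == "circle") 2 * sqrt(area / pi) else sqrt(area)
}

#' Hierarchical mean conduit diameter
#'
#' Mean of per-sample means — not the pooled mean — so a cross-section with
#' many measured conduits does not outweigh one with few. The SE is taken
#' across sample means (0, flagged, for a single sample).
#'
#' @param per_sample List of numeric vectors, one per cross-section sample.
#' @return List with `mean` (um), `se`, `n_samples`, `sample_means`.
#' @export
hierarchical_mean <- function(per_sample) {
  stopifnot(is.list(per_sample), length(per_sample) >= 1L)
  if (any(!vapply(per_sample, length, integer(1L))))
    stop("every sample must contain at least one measurement")
  m <- vapply(per_sample, mean, numeric(1L))
  n <- length(m)
  structure(list(mean = mean(m),
                 se = if (n > 1L) stats::sd(m) / sqrt(n) else 0,
                 n_samples = n, sample_means = m),
            single = n == 1L)
}

#' Hydraulic diameter
#'
#' The conductivity-weighted mean conduit diameter,
#' \deqn{d_h = \sum d^5 / \sum d^4,}
#' which up-weights wide conduits in proportion to their share of
#' Hagen-Poiseuille conductance. Always >= the arithmetic mean, with
#' equality only for identical diameters.
#'
#' @param diameters Conduit diameters, um, all > 0.
#' @return Hydraulic diameter, um.
#' @export
hydraulic_diameter <- function(diameters) {
  if (!length(diameters)) stop("no diameters supplied")
  if (any(!is.finite(diameters) | diameters <= 0)) stop("diameters must be positive")
  sum(diameters^5) / sum(diameters^4)
}

#' Conduit wall reinforcement (t/b)^2
#'
#' Mean squared ratio of double wall thickness `t` to conduit span `b` over
#' wall pairs whose span lies within `tolerance` of the hydraulic diameter
#' (the d_h +/- 1 um selection rule); implosion-resistance proxy. Fewer than
#' `min_pairs` qualifying pairs triggers a warning, none is an error.
#'
#' @param pairs data.frame with columns `t` (double wall thickness, um) and
#'   `span` (conduit diameter, um).
#' @param d_h Hydraulic diameter, um (see [hydraulic_diameter()]).
#' @param tolerance Half-width of the span selection band, um (default 1).
#' @param min_pairs Minimum recommended pair count (default 20).
#' @return Mean (t/b)^2; attributes `n_used` and `selected` (logical).
#' @export
wall_reinforcement <- function(pairs, d_h, tolerance = 1, min_pairs = 20L) {
  d <- as.data.frame(pairs)
  stopifnot(all(c("t", "span") %in% names(d)))
  if (any(d$t <= 0 | d$span <= 0)) stop("wall thickness and span must be positive")
  if (any(d$t >= 2 * d$span))
    warning("double wall thickness >= twice the span for some pairs: check units")
  sel <- d$span >= d_h - tolerance & d$span <= d_h + tolerance
  if (!any(sel)) stop(sprintf("no wall pairs with span within %.3g um of d_h = %.3g um",
                              tolerance, d_h))
  if (sum(sel) < min_pairs)
    warning(sprintf("only %d qualifying wall pairs (< %d recommended)",
                    sum(sel), min_pairs))
  structure(mean((d$t[sel] / d$span[sel])^2), n_used = sum(sel), selected = sel)
}

#' Conduit diameter class histogram
#'
#' Counts per half-open diameter class `[k w, (k+1) w)`; the 1 um class,
#' `[0, 1) .. ` label "1", is where sub-resolution conduits concentrate.
#'
#' @param diameters Conduit diameters, um, > 0.
#' @param width Class width, um (default 1).
#' @return Named integer vector of counts; names are the class upper edges
#'   (so class "1" is `[0, 1)`), counts sum to `length(diameters)`.
#' @export
class_histogram <- function(diameters, width = 1) {
  if (any(!is.finite(diameters) | diameters <= 0)) stop("diameters must be positive")
  cls <- floor(diameters / width)
  k_max <- max(cls)
  counts <- tabulate(cls + 1L, nbins = k_max + 1L)
  names(counts) <- (seq_len(k_max + 1L)) * width
  counts
}

#' Xylem ring geometry summary
#'
#' Width as the mean of the four cardinal-point readings; area proportion as
#' the percentage of the cross-section occupied by xylem.
#'
#' @param width_points Numeric vector of exactly 4 cardinal readings, um.
#' @param xylem_area Xylem ring area, um^2.
#' @param section_area Whole cross-section area, um^2; `NA` omits the
#'   proportion.
#' @return List with `width` (um) and `area_prop` (%, or `NA`).
#' @export
xylem_geometry <- function(width_points, xylem_area = NA_real_,
                           section_area = NA_real_) {
  if (length(width_points) != 4L)
    stop("xylem width is read at exactly 4 cardinal points")
  prop <- NA_real_
  if (is.finite(xylem_area) && is.finite(section_area)) {
    if (xylem_area <= 0 || section_area <= 0) stop("areas must be positive")
    prop <- 100 * xylem_area / section_area
  }
  list(width = mean(width_points), area_prop = prop)
}

#' Summarize the anatomy of a set of cross-section samples
#'
#' Applies the hierarchical averaging rule throughout: d_mean, d_h and
#' (t/b)^2 are computed per sample first, then averaged across samples.
#'
#' @param conduits data.frame with columns `sample_id`, `lumen_area_um2`
#'   and optionally `shape` (`"circle"`/`"square"`, or supply `shape=`).
#' @param wall_pairs Optional data.frame with columns `sample_id`, `t_um`,
#'   `span_um`.
#' @param shape Shape model used when the table has no `shape` column.
#' @param tolerance,min_pairs Passed to [wall_reinforcement()].
#' @return List with `d_mean`, `d_h`, `twb2` (each a [hierarchical_mean()]
#'   style summary, `twb2` NULL without wall pairs), `n_conduits`, and the
#'   pooled `class_hist`.
#' @export
anatomy_summary <- function(conduits, wall_pairs = NULL,
                            shape = c("circle", "square"),
                            tolerance = 1, min_pairs = 20L) {
  shape <- match.arg(shape)
  d <- as.data.frame(conduits)
  stopifnot(all(c("sample_id", "lumen_area_um2") %in% names(d)))
  shp <- if ("shape" %in% names(d)) as.character(d$shape) else rep(shape, nrow(d))
  diam <- ifelse(shp == "square", sqrt(d$lumen_area_um2),
                 2 * sqrt(d$lumen_area_um2 / pi))
  by_sample <- split(diam, d$sample_id)
  d_mean <- hierarchical_mean(by_sample)
  d_h_per <- vapply(by_sample, hydraulic_diameter, numeric(1L))
  d_h <- hierarchical_mean(as.list(d_h_per))
  twb2 <- NULL
  if (!is.null(wall_pairs)) {
    w <- as.data.frame(wall_pairs)
    stopifnot(all(c("sample_id", "t_um", "span_um") %in% names(w)))
    ids <- intersect(names(by_sample), unique(w$sample_id))
    per <- vapply(ids, function(id) {
      ws <- w[w$sample_id == id, ]
      as.numeric(wall_reinforcement(
        data.frame(t = ws$t_um, span = ws$span_um),
        d_h = d_h_per[[id]], tolerance = tolerance, min_pairs = min_pairs))
    }, numeric(1L))
    twb2 <- hierarchical_mean(as.list(per))
  }
  list(d_mean = d_mean, d_h = d_h, twb2 = twb2,
       n_conduits = length(diam), class_hist = class_histogram(diam))
}
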