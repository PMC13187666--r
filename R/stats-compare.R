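#' Difference between optical and acoustic 50%-embolism thresholds
#'
#' Delta = Psi_OV50 - Psi_AEmax, positive when the optical estimate is less
#' negative (the optical method "sees" embolism earlier), the key
#' cross-technique discrepancy statistic.
#'
#' @param psi_ov50,psi_aemax Water potentials, MPa (<= 0).
#' @return Difference, MPa.
#' @export
delta_psi <- function(psi_ov50, psi_aemax) {
  if (any(c(psi_ov50, psi_aemax) > 0)) stop("water potentials must be <= 0 MPa")
  psi_ov50 - psi_aemax
}

# Brown-Forsythe variant of Levene's test: ANOVA on |x - group median|
levene_test <- function(values, groups) {
  groups <- factor(groups)
  med <- tapply(values, groups, stats::median)
  z <- abs(values - med[groups])
  stats::anova(stats::lm(z ~ groups))[["Pr(>F)"]][1L]
}

# compact letter display: letters = maximal cliques of the non-significance
# graph, so two groups share a letter iff their pairwise test is n.s.
compact_letters <- function(levels_, nonsig_pairs) {
  g <- igraph::make_empty_graph(n = length(levels_), directed = FALSE)
  igraph::V(g)$name <- levels_
  if (nrow(nonsig_pairs)) {
    g <- igraph::add_edges(g, t(as.matrix(nonsig_pairs)))
  }
  cliques <- igraph::max_cliques(g)
  letters_ <- c(letters, LETTERS)
  out <- stats::setNames(rep("", length(levels_)), levels_)
  for (i in seq_along(cliques)) {
    members <- igraph::V(g)$name[as.integer(cliques[[i]])]
    out[members] <- paste0(out[members], letters_[i])
  }
  vapply(out, function(s) paste(sort(strsplit(s, "")[[1L]]), collapse = ""),
         character(1L))
}

#' One-way ANOVA with Tukey letters and assumption checks
#'
#' Shapiro-Wilk normality per group and a Brown-Forsythe Levene variance
#' test run first; failures are flagged (not auto-switched — the analysis
#' stays parametric and the flags travel with the result). Then one-way
#' ANOVA, Tukey HSD pairwise comparisons, and a compact letter display in
#' which two groups share a letter iff their pairwise difference is not
#' significant at `alpha`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2),
#'   or a data.frame with columns `group` and `value`.
#' @param alpha Significance level, default 0.05.
#' @return An `anova_tukey` object: `anova_p`, `tukey` (pairwise table),
#'   `letters`, `assumptions` (per-group Shapiro p, Levene p, flags),
#'   `means`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, integer(1L)) < 2L))
    stop("every group needs n >= 2")
  if (all(vapply(groups, stats::var, numeric(1L)) == 0) &&
      length(unique(vapply(groups, mean, numeric(1L)))) == 1L)
    stop("degenerate data: zero variance everywhere and equal means")
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups),
                                     vapply(groups, length, integer(1L))),
                                 levels = names(groups)))
  shapiro_p <- vapply(groups, function(g)
    if (length(unique(g)) < 3L) NA_real_ else stats::shapiro.test(g)$p.value,
    numeric(1L))
  lev_p <- tryCatch(levene_test(d$value, d$group), error = function(e) NA_real_)
  fit <- stats::aov(value ~ group, data = d)
  p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  nonsig <- as.data.frame(pairs[tk[, "p adj"] > alpha, , drop = FALSE],
                          stringsAsFactors = FALSE)
  letts <- compact_letters(names(groups), nonsig)
  structure(list(
    anova_p = p,
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL),
    letters = letts,
    assumptions = list(shapiro_p = shapiro_p, levene_p = lev_p,
                       normality_ok = all(shapiro_p > alpha, na.rm = TRUE),
                       variance_ok = is.na(lev_p) || lev_p > alpha),
    means = vapply(groups, mean, numeric(1L)),
    alpha = alpha), class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: p = %.4g (alpha = %g)\n", x$anova_p, x$alpha))
  if (!x$assumptions$normality_ok)
    cat("  ! Shapiro-Wilk flags non-normal group(s)\n")
  if (!x$assumptions$variance_ok)
    cat("  ! Levene flags heterogeneous variances\n")
  print(data.frame(group = names(x$means), mean = round(x$means, 3),
                   letter = x$letters[names(x$means)], row.names = NULL))
  invisible(x)
}

#' Compare two confidence intervals for overlap
#'
#' Two intervals are declared `"different"` iff they are strictly disjoint;
#' touching endpoints count as overlapping (`"same"`) — a conservative,
#' closed-interval rule.
#'
#' @param a,b Length-2 numeric vectors (any order within each).
#' @return `"different"` or `"same"`.
#' @export
ci_compare <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L)
  a <- sort(a); b <- sort(b)
  if (a[2L] < b[1L] || b[2L] < a[1L]) "different" else "same"
}

#' Pearson correlation matrix between traits and vulnerability thresholds
#'
#' Pairwise Pearson r and (unadjusted) p-values between each trait column
#' and each threshold column. With fewer than 5 paired observations —
#' typical when correlating species-level means over a handful of species —
#' a low-n warning fires: such correlations are descriptive only.
#'
#' @param traits data.frame of trait columns (e.g. xylem width, (t/b)^2).
#' @param thresholds data.frame of threshold columns (e.g. Psi_AEmax,
#'   Psi_OV50), same row order.
#' @return List of matrices `r` and `p` (traits x thresholds); zero-variance
#'   entries are NA and flagged with a warning.
#' @export
pearson_matrix <- function(traits, thresholds) {
  traits <- as.data.frame(traits); thresholds <- as.data.frame(thresholds)
  if (nrow(traits) != nrow(thresholds)) stop("row counts must match")
  n <- nrow(traits)
  if (n < 3L) stop("need at least 3 paired observations")
  if (n < 5L) warning(sprintf(
    "only n = %d paired observations: correlations are descriptive only", n))
  r <- matrix(NA_real_, ncol(traits), ncol(thresholds),
              dimnames = list(names(traits), names(thresholds)))
  p <- r
  for (i in seq_len(ncol(traits))) for (j in seq_len(ncol(thresholds))) {
    x <- traits[[i]]; y <- thresholds[[j]]
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      warning(sprintf("zero variance in pair (%s, %s): undefined correlation",
                      names(traits)[i], names(thresholds)[j]))
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}
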