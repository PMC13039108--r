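# Population statistics for per-track motion parameters: tie-corrected
# Kruskal-Wallis omnibus test with Dunn's pairwise z comparisons, Hartigan's
# dip statistic for multimodality with a bootstrap null, and descriptive
# summaries matching boxplot conventions (median, IQR, 5th/95th percentiles).

#' Kruskal-Wallis omnibus test with Dunn's multiple comparisons
#'
#' The omnibus test is the tie-corrected Kruskal-Wallis rank test. Dunn's
#' post hoc z statistic for groups i, j is
#' `(Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` with mean
#' ranks `Rbar`, pooled size `N` and tie correction
#' `T = sum(t^3 - t) / (12 (N - 1))`; two-sided p-values are adjusted
#' family-wise (Holm by default).
#'
#' @param values Numeric vector of the metric (e.g. per-track alpha or D).
#' @param groups Factor or vector of group labels, same length.
#' @param p_adjust Adjustment method for the pairwise p-values, passed to
#'   [stats::p.adjust()] (default `"holm"`).
#' @return A `group_stats` list: `kw_H`, `kw_df`, `kw_p`, `dunn_z` and
#'   `dunn_p` (symmetric matrices, unit diagonal for p), `group_sizes`,
#'   `p_adjust`. Groups with fewer than 2 observations are dropped with a
#'   warning; at least 2 groups must remain.
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "holm") {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  keep_lv <- names(which(table(groups) >= 2L))
  if (length(keep_lv) < nlevels(groups))
    warning("dropping group(s) with fewer than 2 observations: ",
            paste(setdiff(levels(groups), keep_lv), collapse = ", "))
  sel <- groups %in% keep_lv
  values <- values[sel]
  groups <- droplevels(groups[sel])
  k <- nlevels(groups)
  if (k < 2L) stop("kruskal_dunn needs at least 2 groups with n >= 2")
  lv0 <- levels(groups)
  if (length(unique(values)) == 1L) {
    # fully tied data: ties are maximally corrected, no evidence either way
    z1 <- matrix(0, k, k, dimnames = list(lv0, lv0))
    p1 <- matrix(1, k, k, dimnames = list(lv0, lv0))
    return(structure(list(kw_H = 0, kw_df = k - 1L, kw_p = 1,
                          dunn_z = z1, dunn_p = p1,
                          group_sizes = stats::setNames(tabulate(groups), lv0),
                          p_adjust = p_adjust),
                     class = "group_stats"))
  }

  kw <- stats::kruskal.test(values, groups)

  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n_g <- tabulate(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  lv <- levels(groups)
  z <- matrix(0, k, k, dimnames = list(lv, lv))
  p <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  pairs <- utils::combn(k, 2L)
  praw <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    zij <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / n_g[i] + 1 / n_g[j]))
    z[i, j] <- zij; z[j, i] <- -zij
    praw[c] <- 2 * stats::pnorm(-abs(zij))
  }
  padj <- stats::p.adjust(praw, method = p_adjust)
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    p[i, j] <- padj[c]; p[j, i] <- padj[c]
  }
  diag(p) <- 1
  structure(list(kw_H = unname(kw$statistic), kw_df = unname(kw$parameter),
                 kw_p = kw$p.value, dunn_z = z, dunn_p = p,
                 group_sizes = stats::setNames(n_g, lv),
                 p_adjust = p_adjust),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> Kruskal-Wallis H = %.4f (df = %d), p = %.4g\n",
              x$kw_H, x$kw_df, x$kw_p))
  cat(sprintf("Dunn pairwise p-values (%s-adjusted):\n", x$p_adjust))
  print(round(x$dunn_p, 4))
  invisible(x)
}

#' Hartigan's dip statistic
#'
#' The dip is the smallest uniform (sup-norm) distance between the
#' empirical CDF and any unimodal CDF. It is evaluated exactly through the
#' excess-mass identity: the dip equals half the maximum over the density
#' level `lambda` of the difference between the two-interval and
#' one-interval excess masses,
#' `E_m(lambda) = max over m disjoint closed intervals of
#' sum(F_n(I) - lambda * length(I))`.
#' Both excess-mass curves are piecewise linear and convex in `lambda`, and
#' their difference can only turn downward at a vertex of the one-interval
#' envelope, so the maximum is attained at one of those breakpoints; the
#' function enumerates them from the convex hull of the
#' (interval width, probability mass) pairs and evaluates both excess
#' masses exactly at each.
#'
#' @param x Numeric vector, `n >= 4`.
#' @return The dip statistic (scale and location invariant; >= 1/(2n) for
#'   samples with at least two distinct values, 0 if all values are equal).
#' @export
dip_stat <- function(x) {
  n <- length(x)
  if (n < 4L) stop("dip statistic requires at least 4 observations")
  x <- sort(x)
  u <- unique(x)
  m <- length(u)
  if (m == 1L) return(0)
  cum <- cumsum(tabulate(match(x, u), m)) / n   # F_n at each unique value
  # all closed intervals [u_i, u_j]: width and probability mass
  w <- outer(u, u, function(a, b) b - a)
  keep <- upper.tri(w, diag = TRUE)
  w <- w[keep]
  cmass <- outer(c(0, cum[-m]), cum, function(a, b) b - a)[keep]
  # upper envelope of the lines mass - lambda * width: vertices of the
  # upper concave hull over width give the E1 breakpoints
  o <- order(w, -cmass)
  w <- w[o]; cmass <- cmass[o]
  run <- cummax(cmass)
  keep1 <- cmass >= run & !duplicated(w)        # undominated: narrowest-for-mass
  w <- w[keep1]; cmass <- cmass[keep1]
  upperh <- upper_hull(w, cmass)
  slopes <- diff(upperh$c) / diff(upperh$w)
  lams <- unique(c(0, slopes[slopes > 0], 2 * n / min(diff(u))))
  d <- 0
  for (lam in lams) d <- max(d, excess_mass_diff(u, cum, lam))
  d / 2
}

# upper concave hull (as a function of w) of points sorted by w
upper_hull <- function(w, c) {
  top <- 0L
  hw <- numeric(length(w)); hc <- numeric(length(w))
  for (i in seq_along(w)) {
    while (top >= 2L &&
           (hc[top] - hc[top - 1L]) * (w[i] - hw[top]) <=
           (c[i] - hc[top]) * (hw[top] - hw[top - 1L])) {
      top <- top - 1L
    }
    top <- top + 1L
    hw[top] <- w[i]; hc[top] <- c[i]
  }
  list(w = hw[1:top], c = hc[1:top])
}

# E2(lambda) - E1(lambda) for the empirical CDF on unique values u with
# cumulative probabilities cum, by prefix/suffix scans over interval ends.
excess_mass_diff <- function(u, cum, lam) {
  m <- length(u)
  lo <- c(0, cum[-m])
  a <- lam * u - lo                       # best interval start term
  f1 <- cum - lam * u + cummax(a)         # best interval ending at j
  e1 <- max(f1)
  if (m < 2L) return(0)
  prefbest <- cummax(f1)
  b <- cum - lam * u
  sufmax <- rev(cummax(rev(b)))
  f2 <- a + sufmax                        # best interval starting at i
  sufbest <- rev(cummax(rev(f2)))
  e2 <- max(prefbest[1:(m - 1L)] + sufbest[2:m])
  max(e2 - e1, 0)
}

#' Hartigan's dip test for multimodality
#'
#' The p-value is the bootstrap probability that the dip of a Uniform(0, 1)
#' sample of the same size exceeds the observed dip; the uniform is the
#' standard calibration null for the dip test.
#'
#' @param values Numeric vector, `n >= 4`.
#' @param n_boot Number of bootstrap null draws (default 2000).
#' @param seed Integer seed making the bootstrap reproducible.
#' @param null_dips Optional precomputed vector of null dip values at the
#'   same `n` (see [dip_null()]); overrides `n_boot`/`seed`.
#' @return List with `dip_stat`, `dip_p`, `n`, `n_boot`.
#' @export
dip_test <- function(values, n_boot = 2000L, seed = 1L, null_dips = NULL) {
  n <- length(values)
  if (n < 4L) stop("dip test requires at least 4 observations")
  d <- dip_stat(values)
  if (is.null(null_dips)) null_dips <- dip_null(n, n_boot, seed)
  p <- (sum(null_dips >= d) + 1) / (length(null_dips) + 1)
  list(dip_stat = d, dip_p = p, n = n, n_boot = length(null_dips))
}

#' Bootstrap null distribution of the dip statistic
#'
#' Dips of `n_boot` Uniform(0, 1) samples of size `n`. Computing the table
#' once and passing it to [dip_test()] via `null_dips` avoids recomputation
#' when many samples of the same size are tested.
#'
#' @param n Sample size.
#' @param n_boot Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of `n_boot` null dip values.
#' @export
dip_null <- function(n, n_boot = 2000L, seed = 1L) {
  with_seed(seed, vapply(seq_len(n_boot),
                         function(k) dip_stat(stats::runif(n)), numeric(1L)))
}

#' Descriptive summaries per group
#'
#' Median, quartiles and 5th/95th percentiles per group (type-7 linear
#' interpolation, R's default), matching boxplots whose boxes cover the IQR
#' with whiskers to the 5th-95th percentile.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return data.frame `group, n, p5, q25, median, q75, p95`.
#' @export
summarize_groups <- function(values, groups) {
  groups <- as.factor(groups)
  rows <- lapply(levels(groups), function(g) {
    v <- values[groups == g]
    q <- stats::quantile(v, c(.05, .25, .5, .75, .95), type = 7)
    data.frame(group = g, n = length(v), p5 = q[[1L]], q25 = q[[2L]],
               median = q[[3L]], q75 = q[[4L]], p95 = q[[5L]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
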