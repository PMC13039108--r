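# Independent oracles used across the suite. These deliberately use naive
# double loops / exhaustive enumeration so that they share no code path with
# the package implementations they check.

# TA-MSD by literal double loop over realized pairs
brute_ta_msd <- function(frames, xy, max_lag = NULL) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 1L)
  span <- max(frames) - min(frames) + 1L
  if (is.null(max_lag)) max_lag <- span - 1L
  out <- rep(NA_real_, max_lag)
  for (d in seq_len(max_lag)) {
    acc <- 0; cnt <- 0L
    for (i in seq_along(frames)) {
      j <- which(frames == frames[i] + d)
      if (length(j) == 1L) {
        acc <- acc + sum((xy[j, ] - xy[i, ])^2)
        cnt <- cnt + 1L
      }
    }
    if (cnt > 0L) out[d] <- acc / cnt
  }
  out
}

# Tie-corrected Kruskal-Wallis H by the rank formula, written out
brute_kw_H <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  H <- 0
  for (g in levels(groups)) {
    idx <- groups == g
    H <- H + sum(r[idx])^2 / sum(idx)
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn z for one pair of groups, from first principles
brute_dunn_z <- function(values, groups, g1, g2) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  (mean(r[groups == g1]) - mean(r[groups == g2])) /
    sqrt(s2 * (1 / n1 + 1 / n2))
}

# All permutations of 1..n (for exhaustive assignment checks)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(all_perms(n - 1L), function(p) {
      rest <- setdiff(seq_len(n), i)
      c(i, rest[p])
    })
  }))
}

# Minimum-cost assignment by exhaustive permutation search
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  min(vapply(all_perms(n), function(p) sum(cost[cbind(seq_len(n), p)]),
             numeric(1L)))
}

# Dip statistic by brute force: explicit enumeration of one- and
# two-interval excess masses at every pairwise slope candidate plus a
# dense grid. Exact for the small n it is used at.
brute_dip <- function(x, n_grid = 4000) {
  x <- sort(x)
  u <- unique(x)
  m <- length(u)
  if (m == 1L) return(0)
  cum <- cumsum(tabulate(match(x, u), m)) / length(x)
  lo <- c(0, cum[-m])
  emd <- function(lam) {
    vals <- matrix(-Inf, m, m)
    for (i in 1:m) for (j in i:m)
      vals[i, j] <- (cum[j] - lo[i]) - lam * (u[j] - u[i])
    e1 <- max(vals)
    bestin <- function(a, b) max(vals[a:b, a:b][upper.tri(matrix(0, b - a + 1L, b - a + 1L), diag = TRUE)])
    e2 <- 0
    for (k in 1:(m - 1L))
      e2 <- max(e2, bestin(1L, k) + bestin(k + 1L, m))
    max(e2 - e1, 0)
  }
  sl <- c()
  for (i in 1:m) for (j in i:m) if (u[j] > u[i])
    sl <- c(sl, (cum[j] - lo[i]) / (u[j] - u[i]),
            (cum[j] - cum[i]) / (u[j] - u[i]),
            (lo[j] - lo[i]) / (u[j] - u[i]))
  lams <- unique(c(0, sl, seq(0, max(sl) * 2, length.out = n_grid)))
  max(vapply(lams, emd, numeric(1L))) / 2
}

# Analytic noiseless frame with Gaussian spots (independent of render_stack)
analytic_frame <- function(h, w, centers, sigma, amplitude, background) {
  img <- matrix(background, h, w)
  for (k in seq_len(nrow(centers))) {
    gx <- exp(-((0:(w - 1L)) - centers[k, 1L])^2 / (2 * sigma^2))
    gy <- exp(-((0:(h - 1L)) - centers[k, 2L])^2 / (2 * sigma^2))
    img <- img + amplitude * outer(gy, gx)
  }
  img
}
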