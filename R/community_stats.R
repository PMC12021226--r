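#' Pairwise community dissimilarity
#'
#' Bray-Curtis on (relative) abundances, `sum(|x - y|) / sum(x + y)` per pair,
#' or Jaccard on presence/absence, `1 - |intersection| / |union|`.
#'
#' @param x numeric matrix, samples in rows, taxa in columns. For
#'   `metric = "jaccard"` any positive cell counts as presence.
#' @param metric "bray_curtis" or "jaccard".
#' @return a symmetric matrix of class `dissimilarity` with zero diagonal and
#'   values in [0, 1]; attribute `metric` records the index used.
#' @export
dissimilarity <- function(x, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d[i, j] <- d[j, i] <- if (metric == "bray_curtis") {
      tot <- sum(x[i, ] + x[j, ])
      if (tot == 0) 0 else sum(abs(x[i, ] - x[j, ])) / tot
    } else {
      a <- x[i, ] > 0; b <- x[j, ] > 0
      u <- sum(a | b)
      if (u == 0) 0 else 1 - sum(a & b) / u
    }
  }
  structure(d, metric = metric, class = c("dissimilarity", "matrix"))
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes Kruskal's stress-1 by iterative majorization (Guttman transform)
#' alternated with monotone regression of the configuration distances on the
#' dissimilarity order (Kruskal's primary approach to ties: within tied
#' dissimilarities the fitted values are free to follow the configuration).
#' The first start is the classical-scaling solution; the remaining
#' `restarts - 1` starts are random. Deterministic given `seed`.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k number of dimensions (must be < n - 1).
#' @param restarts number of starts (default 20).
#' @param seed integer seed.
#' @param maxit,tol iteration cap and stress-change convergence tolerance.
#' @return object of class `nmds`: list with `points` (n x k), `stress`,
#'   `k`, `converged`, `restarts`.
#' @export
nmds <- function(d, k = 2L, restarts = 20L, seed = 1L, maxit = 500L,
                 tol = 1e-6) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of samples",
                   call. = FALSE)
  low <- which(lower.tri(d))
  delta <- d[low]
  ord <- order(delta)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      X <- if (r == 1L)
        suppressWarnings(stats::cmdscale(d, k = k))
      else matrix(stats::rnorm(n * k), n, k)
      if (ncol(X) < k)  # degenerate classical solution
        X <- cbind(X, matrix(stats::rnorm(n * (k - ncol(X))), n))
      fit <- nmds_one(X, delta, ord, low, n, k, maxit, tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    best$points <- scale(best$points, scale = FALSE)
    dimnames(best$points) <- list(rownames(d), paste0("NMDS", seq_len(k)))
    structure(list(points = best$points, stress = best$stress, k = k,
                   converged = best$converged, restarts = restarts),
              class = "nmds")
  })
}

nmds_one <- function(X, delta, ord, low, n, k, maxit, tol) {
  dist_vec <- function(X) {
    dm <- as.matrix(stats::dist(X))
    dm[low]
  }
  dv <- dist_vec(X)
  stress <- stress1(dv, delta, ord)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    # monotone (isotonic) fit of configuration distances on dissimilarity
    # order; ties in delta are pre-sorted by the current distances (primary
    # approach), so the pool-adjacent-violators fit never forces ties
    o2 <- order(delta, dv)
    dhat <- numeric(length(dv))
    dhat[o2] <- stats::isoreg(dv[o2])$yf
    # Guttman transform towards the fitted distances
    B <- matrix(0, n, n)
    ratio <- ifelse(dv > 0, dhat / dv, 0)
    B[low] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    Xn <- B %*% X / n
    dvn <- dist_vec(Xn)
    s_new <- stress1(dvn, delta, ord)
    if (is.finite(s_new) && abs(stress - s_new) < tol) {
      X <- Xn; dv <- dvn; stress <- s_new; converged <- TRUE
      break
    }
    if (s_new <= stress) { X <- Xn; dv <- dvn; stress <- s_new }
    else break  # majorization step failed to improve: stop at current X
  }
  list(points = X, stress = stress, converged = converged)
}

# Kruskal stress-1 with a fresh primary-approach monotone fit.
stress1 <- function(dv, delta, ord) {
  o2 <- order(delta, dv)
  dhat <- numeric(length(dv))
  dhat[o2] <- stats::isoreg(dv[o2])$yf
  ss <- sum(dv^2)
  if (ss == 0) return(0)
  sqrt(sum((dv - dhat)^2) / ss)
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("NMDS (%dD): stress = %.4f (%s, best of %d starts)\n",
              x$k, x$stress, if (x$converged) "converged" else
                "not converged", x$restarts))
  invisible(x)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the squared dissimilarities: SS_total = sum_{i<j} d_ij^2 / N,
#' SS_within = sum over groups of within-group pair sums / n_g, pseudo-F =
#' (SS_among / (g - 1)) / (SS_within / (N - g)), R^2 = SS_among / SS_total.
#' The p-value is (1 + #{F_perm >= F_obs}) / (1 + permutations) under random
#' relabelling of samples.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups factor-like group label per sample (at least 2 groups).
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return object of class `permanova`: list with `F`, `R2`, `p`,
#'   `permutations`, `df`.
#' @export
permanova <- function(d, groups, permutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  g <- nlevels(droplevels(groups))
  if (g < 2L) stop("PerMANOVA needs at least two groups", call. = FALSE)
  d2 <- d^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  fstat <- function(lab) {
    ss_within <- 0
    for (lev in levels(lab)) {
      idx <- which(lab == lev)
      if (length(idx) < 2L) next
      ss_within <- ss_within +
        sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
    }
    ss_among <- ss_total - ss_within
    (ss_among / (g - 1)) / (ss_within / (n - g))
  }
  f_obs <- fstat(droplevels(groups))
  ss_w <- 0
  for (lev in levels(droplevels(groups))) {
    idx <- which(groups == lev)
    if (length(idx) < 2L) next
    ss_w <- ss_w + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
  }
  r2 <- (ss_total - ss_w) / ss_total
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(permutations)) {
      if (fstat(droplevels(groups[sample.int(n)])) >= f_obs) exceed <- exceed + 1L
    }
    structure(list(F = f_obs, R2 = r2,
                   p = (1 + exceed) / (1 + permutations),
                   permutations = as.integer(permutations),
                   df = c(among = g - 1L, within = n - g)),
              class = "permanova")
  })
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PerMANOVA: F = %.3f (df %d, %d), R2 = %.3f, p = %.4f (%d permutations)\n",
              x$F, x$df[1], x$df[2], x$R2, x$p, x$permutations))
  invisible(x)
}

#' Estimated sample coverage
#'
#' Good-Turing style coverage estimate
#' `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`, where f1/f2 are the
#' singleton/doubleton counts and n the total reads. With no singletons the
#' estimate is 1.
#'
#' @param counts non-negative integer abundance vector.
#' @return coverage in [0, 1].
#' @export
coverage_estimate <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  f1 <- sum(counts == 1L); f2 <- sum(counts == 2L)
  if (f1 == 0) return(1)
  denom <- (n - 1) * f1 + 2 * f2
  1 - (f1 / n) * if (denom > 0) (n - 1) * f1 / denom else 1
}

# Expected coverage of a subsample of size m < n (hypergeometric form).
coverage_interpolated <- function(counts, m) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (m >= n) return(coverage_estimate(counts))
  1 - sum((counts / n) * exp(lchoose(n - counts, m) - lchoose(n - 1, m)))
}

# Extrapolated coverage at size n + mstar.
coverage_extrapolated <- function(counts, mstar) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  f1 <- sum(counts == 1L); f2 <- sum(counts == 2L)
  if (f1 == 0) return(1)
  A <- (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  1 - (f1 / n) * A^(mstar + 1)
}

# Expected Shannon entropy of a without-replacement subsample of size m
# (exact: linearity of expectation over the abundance-frequency counts).
entropy_interpolated <- function(counts, m) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (m > n) stop("interpolation size exceeds sample size")
  ks <- seq_len(m)
  h <- -(ks / m) * log(ks / m)
  h[ks == m] <- 0
  total <- 0
  for (ni in counts) {
    pk <- exp(lchoose(ni, ks) + lchoose(n - ni, m - ks) - lchoose(n, m))
    total <- total + sum(h * pk)
  }
  total
}

# Asymptotic entropy: Miller-Madow bias correction using the Chao1 richness
# estimate, so unseen taxa contribute to the correction term.
entropy_asymptotic <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  p <- counts / n
  h_obs <- -sum(p * log(p))
  f1 <- sum(counts == 1L); f2 <- sum(counts == 2L)
  s_hat <- length(counts) +
    if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2
  h_obs + (s_hat - 1) / (2 * n)
}

# Entropy at extrapolated size n + mstar: approaches the asymptote as 1/size,
# anchored at the observed point.
entropy_extrapolated <- function(counts, mstar) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  p <- counts / n
  h_obs <- -sum(p * log(p))
  h_inf <- max(entropy_asymptotic(counts), h_obs)
  h_inf - (h_inf - h_obs) * n / (n + mstar)
}

#' Coverage-based rarefaction/extrapolation curve of Shannon diversity
#'
#' Hill number of order 1 (the exponential of Shannon entropy, "effective
#' number of taxa") along a grid of sample sizes. Interpolated points use the
#' exact expected entropy of a without-replacement subsample; extrapolated
#' points approach a Chao1-corrected asymptotic entropy as 1/size, anchored
#' at the observed point. Each point also carries its estimated coverage.
#' Confidence intervals are percentile bootstrap (multinomial resampling of
#' the observed relative abundances; the unseen-species adjustment is
#' deliberately omitted).
#'
#' @param counts non-negative integer abundance vector (e.g. incidence counts
#'   of taxa over a season's samples).
#' @param grid integer grid of sizes; default 20 points from 1 to 2n.
#' @param reps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `re_curve`: data.frame with columns size,
#'   coverage, estimate, lcl, ucl, method (interpolated/observed/
#'   extrapolated); attribute `observed` holds the observed size, coverage
#'   and diversity.
#' @export
shannon_re_curve <- function(counts, grid = NULL, reps = 1000L, seed = 1L,
                             conf = 0.95) {
  counts <- as.integer(counts[counts > 0])
  n <- sum(counts)
  if (n == 0) stop("empty count vector", call. = FALSE)
  if (is.null(grid))
    grid <- unique(round(c(seq(1, n, length.out = 10),
                           seq(n, 2 * n, length.out = 11))))
  if (any(grid < 1)) stop("grid sizes must be >= 1", call. = FALSE)
  point <- function(cnt, m) {
    ntot <- sum(cnt)
    if (m <= ntot) exp(entropy_interpolated(cnt, m))
    else exp(entropy_extrapolated(cnt, m - ntot))
  }
  est <- vapply(grid, function(m) point(counts, m), numeric(1))
  cov <- vapply(grid, function(m) {
    if (m < n) coverage_interpolated(counts, m)
    else if (m == n) coverage_estimate(counts)
    else coverage_extrapolated(counts, m - n)
  }, numeric(1))
  p_hat <- counts / n
  boot <- with_seed(seed, {
    replicate(reps, {
      cnt <- as.vector(stats::rmultinom(1, n, p_hat))
      vapply(grid, function(m) point(cnt[cnt > 0], m), numeric(1))
    })
  })
  if (is.null(dim(boot))) boot <- matrix(boot, nrow = 1L)
  alpha <- (1 - conf) / 2
  lcl <- apply(boot, 1, stats::quantile, probs = alpha, names = FALSE)
  ucl <- apply(boot, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
  out <- data.frame(size = grid, coverage = cov, estimate = est,
                    lcl = pmin(lcl, est), ucl = pmax(ucl, est),
                    method = ifelse(grid < n, "interpolated",
                                    ifelse(grid == n, "observed",
                                           "extrapolated")))
  p <- counts / n
  attr(out, "observed") <- c(size = n, coverage = coverage_estimate(counts),
                             diversity = exp(-sum(p * log(p))))
  class(out) <- c("re_curve", "data.frame")
  out
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups, a two-sample rank statistic on the pooled pair
#' (midranks for ties), standardized with the tie-corrected variance and
#' referred to the studentized-range distribution with k = number of groups
#' (p = P(Q >= sqrt(2)|t|)).
#'
#' @param values numeric vector of observations (e.g. taxa per sample).
#' @param groups group label per observation.
#' @return data.frame with one row per group pair: group1, group2, statistic
#'   (standardized), p_value.
#' @export
steel_dwass <- function(values, groups) {
  groups <- as.factor(groups)
  lev <- levels(droplevels(groups))
  k <- length(lev)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  out <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- values[groups == lev[i]]
    y <- values[groups == lev[j]]
    ni <- length(x); nj <- length(y); N <- ni + nj
    r <- rank(c(x, y))
    W <- sum(r[seq_len(ni)])
    E <- ni * (N + 1) / 2
    V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    t_std <- if (V > 0) (W - E) / sqrt(V) else 0
    p <- stats::ptukey(sqrt(2) * abs(t_std), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = lev[i], group2 = lev[j],
                                 statistic = t_std, p_value = p,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
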