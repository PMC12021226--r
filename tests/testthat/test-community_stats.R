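test_that("dissimilarity indices match their definitions", {
  x <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0, 0.5), c = c(0.5, 0.5, 0))
  d <- dissimilarity(x, "bray_curtis")
  expect_equal(unname(d["a", "b"]), 0.5)
  expect_equal(unname(d["a", "c"]), 0)       # identical rows
  y <- rbind(a = c(1, 1, 0), b = c(0, 0, 1))
  expect_equal(unname(dissimilarity(y, "jaccard")["a", "b"]), 1)  # disjoint
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
})

test_that("binary Jaccard equals 1 - intersection/union on all 3-taxon pairs", {
  vecs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (i in seq_len(nrow(vecs))) for (j in seq_len(nrow(vecs))) {
    m <- rbind(vecs[i, ], vecs[j, ])
    d <- dissimilarity(m, "jaccard")[1, 2]
    u <- sum(vecs[i, ] | vecs[j, ])
    expected <- if (u == 0) 0 else 1 - sum(vecs[i, ] & vecs[j, ]) / u
    expect_equal(unname(d), expected)
  }
})

test_that("dissimilarities agree with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(2)
  m <- matrix(rpois(80, 4), 8, 10)
  rel <- m / rowSums(m)
  expect_equal(unclass(dissimilarity(rel, "bray_curtis")),
               as.matrix(vegan::vegdist(rel, "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(dissimilarity(m, "jaccard")),
               as.matrix(vegan::vegdist(m > 0, "jaccard")),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("NMDS recovers embeddable configurations with near-zero stress", {
  # three equidistant points embed exactly in the plane
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  fit <- nmds(d3, k = 2, restarts = 5, seed = 1)
  expect_lt(fit$stress, 1e-4)
  # collinear points embed exactly on a line
  x <- c(0, 1, 3, 6, 10)
  dl <- as.matrix(dist(x))
  fit1 <- nmds(dl, k = 1, restarts = 10, seed = 2)
  expect_lt(fit1$stress, 1e-4)
})

test_that("NMDS stress does not increase with dimensionality", {
  set.seed(3)
  m <- matrix(runif(20 * 6), 20, 6)
  d <- dissimilarity(m / rowSums(m), "bray_curtis")
  s2 <- nmds(d, k = 2, restarts = 10, seed = 4)$stress
  s3 <- nmds(d, k = 3, restarts = 10, seed = 4)$stress
  expect_lte(s3, s2 + 1e-6)
  # deterministic given the seed
  expect_identical(nmds(d, k = 2, restarts = 5, seed = 9),
                   nmds(d, k = 2, restarts = 5, seed = 9))
})

test_that("PerMANOVA detects separated clusters and rejects degenerate input", {
  # two maximally separated clusters: every permutation that mixes labels
  # lowers F, so p attains the 1/(perm+1) floor
  m <- rbind(matrix(rep(c(10, 0), each = 10), 10, 2),
             matrix(rep(c(0, 10), each = 10), 10, 2))
  d <- dissimilarity(m / rowSums(m), "bray_curtis")
  g <- rep(c("a", "b"), each = 10)
  fit <- permanova(d, g, permutations = 199, seed = 1)
  expect_equal(fit$p, 1 / 200)
  expect_gt(fit$F, 1)
  expect_true(fit$R2 >= 0 && fit$R2 <= 1)
  expect_error(permanova(d, rep("a", 20)), "two groups")
})

test_that("PerMANOVA matches vegan::adonis2 on the observed statistic", {
  skip_if_not_installed("vegan")
  set.seed(6)
  m <- matrix(rpois(15 * 8, 5), 15, 8)
  rel <- m / rowSums(m)
  g <- rep(c("a", "b", "c"), each = 5)
  d <- dissimilarity(rel, "bray_curtis")
  fit <- permanova(d, g, permutations = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
  expect_equal(fit$F, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("coverage estimates follow the singleton/doubleton plug-in", {
  expect_equal(coverage_estimate(c(5, 3, 2)), 1)       # no singletons
  expect_equal(coverage_estimate(c(1, 1, 1, 1)), 0)    # all singletons
  expect_equal(coverage_estimate(c(2, 2, 1)), 0.9)
})

test_that("the diversity curve is anchored at the observed Hill-1 point", {
  cnt <- c(40, 25, 20, 10, 3, 1, 1)
  n <- sum(cnt)
  cur <- shannon_re_curve(cnt, grid = c(10, 50, n, 150, 200), reps = 200,
                          seed = 1)
  p <- cnt / n
  h_obs <- exp(-sum(p * log(p)))
  expect_equal(cur$estimate[cur$size == n], h_obs, tolerance = 1e-9)
  expect_true(all(cur$lcl <= cur$estimate + 1e-12))
  expect_true(all(cur$ucl >= cur$estimate - 1e-12))
  expect_equal(unname(attr(cur, "observed")["diversity"]), h_obs)
  # equal counts over S taxa at large n: diversity approaches S
  eq <- rep(200, 6)
  cur2 <- shannon_re_curve(eq, grid = sum(eq), reps = 50, seed = 2)
  expect_equal(cur2$estimate, 6, tolerance = 1e-6)
  expect_error(shannon_re_curve(cnt, grid = 0), "grid sizes")
})

test_that("interpolated Hill-1 matches exhaustive subsampling", {
  cnt <- c(3, 2, 1)
  reads <- rep(seq_along(cnt), cnt)
  m <- 3
  combs <- utils::combn(length(reads), m)
  hs <- apply(combs, 2, function(ix) {
    p <- table(reads[ix]) / m
    -sum(p * log(p))
  })
  ei <- rbcldiet:::entropy_interpolated(cnt, m)
  # exact: expected subsample entropy is a linear functional of the counts
  expect_equal(ei, mean(hs), tolerance = 1e-12)
  # on the Hill scale the enumeration mean of exp(H) sits within the
  # convexity gap of exp(mean H)
  expect_equal(exp(ei), mean(exp(hs)), tolerance = 0.05)
})

test_that("Steel-Dwass behaves on crafted groups and is label-symmetric", {
  sd1 <- steel_dwass(c(1, 2, 3, 4, 1, 2, 3, 4),
                     rep(c("a", "b"), each = 4))
  expect_gt(sd1$p_value, 0.95)
  sd2 <- steel_dwass(c(1, 1, 1, 2, 9, 9, 10, 10),
                     rep(c("a", "b"), each = 4))
  expect_lt(sd2$p_value, 0.05)
  # relabelling the groups permutes rows but not p-values
  set.seed(7)
  v <- rnorm(18)
  g <- rep(c("x", "y", "z"), each = 6)
  a <- steel_dwass(v, g)
  b <- steel_dwass(v, factor(g, levels = c("z", "x", "y")))
  key <- function(df) {
    k <- apply(df[, 1:2], 1, function(r) paste(sort(r), collapse = "-"))
    stats::setNames(df$p_value, k)[sort(k)]
  }
  expect_equal(key(a), key(b))
})

test_that("Steel-Dwass at k = 2 orders p-values like the exact rank test", {
  set.seed(11)
  p_sd <- p_ex <- numeric(50)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, 0, 2))
    p_sd[i] <- steel_dwass(c(x, y), rep(c("a", "b"), each = 6))$p_value
    p_ex[i] <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  }
  expect_gt(stats::cor(p_sd, p_ex, method = "spearman"), 0.99)
})
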