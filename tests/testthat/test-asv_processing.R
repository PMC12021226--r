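test_that("dereplication groups exact sequences only", {
  s1 <- fixed_seq(80, 1); s2 <- fixed_seq(80, 2)
  tab <- dereplicate(list(A = c(rep(s1, 10), rep(s2, 5))))
  expect_equal(ncol(tab$counts), 2L)
  expect_equal(sort(as.integer(tab$counts)), c(5L, 10L))
  # a single substitution is its own ASV
  tab2 <- dereplicate(list(A = c(rep(s1, 10), sub_at(s1, 40))))
  expect_equal(ncol(tab2$counts), 2L)
  # reads with N are excluded and logged
  nread <- paste0("N", substr(s1, 2, 80))
  tab3 <- dereplicate(list(A = c(rep(s1, 3), nread)))
  expect_equal(ncol(tab3$counts), 1L)
  expect_equal(tab3$log$n_excluded, 1L)
  # an empty sample is kept as a zero row with a warning
  expect_warning(tab4 <- dereplicate(list(A = rep(s1, 2), B = character(0))),
                 "zero rows")
  expect_equal(unname(rowSums(tab4$counts)), c(2, 0))
})

test_that("two-parent chimeras are removed under the abundance condition", {
  p <- fixed_seq(262, 3)
  q <- sub_at(p, c(30, 200, 240))           # differs at 30, 200, 240
  a <- paste0(substr(p, 1, 100), substr(q, 101, 262))  # exact bimera
  tab <- dereplicate(list(A = c(rep(p, 50), rep(q, 50), rep(a, 5))))
  out <- remove_chimeras(tab)
  expect_false(a %in% out$asv_seq)
  expect_true(all(c(p, q) %in% out$asv_seq))
  expect_equal(out$log$chimera_removed, 5L)
  # no exact two-parent decomposition -> retained
  b <- sub_at(a, 150)
  tab2 <- dereplicate(list(A = c(rep(p, 50), rep(q, 50), rep(b, 5))))
  expect_true(b %in% remove_chimeras(tab2)$asv_seq)
  # more abundant than its would-be parents -> retained
  tab3 <- dereplicate(list(A = c(rep(p, 5), rep(q, 5), rep(a, 50))))
  expect_true(a %in% remove_chimeras(tab3)$asv_seq)
})

test_that("low-frequency filtering uses a strict per-sample threshold", {
  s <- vapply(1:3, function(i) fixed_seq(60, i), "")
  reads <- list(A = c(rep(s[1], 981), rep(s[2], 9), rep(s[3], 10)))
  tab <- filter_low_frequency(dereplicate(reads), threshold = 0.01)
  kept <- tab$asv_seq
  expect_false(s[2] %in% kept)   # 9/1000 = 0.9% < 1.0%
  expect_true(s[3] %in% kept)    # exactly 1.0% is retained
  expect_equal(tab$log$lowfreq_removed, 9L)
  # all above threshold -> unchanged
  reads2 <- list(A = c(rep(s[1], 50), rep(s[2], 50)))
  tab2 <- filter_low_frequency(dereplicate(reads2))
  expect_equal(sum(tab2$counts), 100)
})

test_that("rarefaction subsamples without replacement to exact depth", {
  s <- vapply(1:2, function(i) fixed_seq(60, i), "")
  reads <- list(A = c(rep(s[1], 900), rep(s[2], 100)),
                B = rep(s[1], 50))
  tab <- dereplicate(reads)
  expect_warning(r <- rarefy_table(tab, depth = 100, seed = 1), "dropping")
  expect_equal(rownames(r$counts), "A")
  expect_equal(unname(rowSums(r$counts)), 100)
  # a sample already at depth is unchanged
  tab2 <- dereplicate(list(A = c(rep(s[1], 70), rep(s[2], 30))))
  r2 <- rarefy_table(tab2, depth = 100, seed = 1)
  expect_equal(as.integer(r2$counts), c(70L, 30L))
  # single-ASV sample: all depth reads that ASV
  r3 <- rarefy_table(dereplicate(list(A = rep(s[1], 500))), depth = 120,
                     seed = 1)
  expect_equal(as.integer(r3$counts), 120L)
  expect_error(rarefy_table(tab2, depth = 0, seed = 1), "positive")
  # determinism
  ra <- rarefy_table(tab, depth = 100, seed = 7) |> suppressWarnings()
  rb <- rarefy_table(tab, depth = 100, seed = 7) |> suppressWarnings()
  expect_identical(ra$counts, rb$counts)
})

test_that("rarefied counts follow hypergeometric moments", {
  s <- vapply(1:2, function(i) fixed_seq(60, i), "")
  tab <- dereplicate(list(A = c(rep(s[1], 900), rep(s[2], 100))))
  id1 <- names(tab$asv_seq)[tab$asv_seq == s[1]]
  draws <- vapply(1:1000, function(sd)
    rarefy_table(tab, depth = 100, seed = sd)$counts[1, id1], numeric(1))
  # hypergeometric: mean 90, var = 100*.9*.1*(900/999)
  v <- 100 * 0.9 * 0.1 * (1000 - 100) / (1000 - 1)
  expect_lt(abs(mean(draws) - 90), 3 * sqrt(v / 1000))
  expect_lt(abs(var(draws) - v), 0.25 * v)
})

test_that("exact rarefaction curve matches definition and oracle", {
  expect_equal(rarefaction_curve(c(5, 5), 2)$richness,
               2 - 2 * choose(5, 2) / choose(10, 2))
  cnt <- c(12, 7, 3, 1, 1)
  expect_equal(rarefaction_curve(cnt, sum(cnt))$richness, 5)
  expect_equal(rarefaction_curve(cnt, 1)$richness, 1)
  skip_if_not_installed("vegan")
  sizes <- c(2, 5, 10, 20)
  expect_equal(rarefaction_curve(cnt, sizes)$richness,
               as.numeric(suppressWarnings(
                 vegan::rarefy(matrix(cnt, 1), sizes))),
               tolerance = 1e-10)
})

test_that("Monte-Carlo rarefaction converges to the closed form", {
  s <- vapply(1:4, function(i) fixed_seq(60, i), "")
  counts <- c(40, 30, 20, 10)
  tab <- dereplicate(list(A = rep(s, counts)))
  m <- 25
  rich <- vapply(1:1000, function(sd)
    sum(rarefy_table(tab, depth = m, seed = sd)$counts[1, ] > 0), numeric(1))
  expected <- rarefaction_curve(counts, m)$richness
  se <- sd(rich) / sqrt(length(rich))
  expect_lt(abs(mean(rich) - expected), 3 * se)
})

test_that("the stage pipeline never creates ASVs and never adds reads", {
  cfg <- sim_config(n_samples = 6, read_depth = 500, seed = 13)
  fl <- generate_flora(cfg)
  sim <- generate_samples(fl)
  raw <- dereplicate(sim$reads)
  nochim <- remove_chimeras(raw)
  filt <- filter_low_frequency(nochim)
  rar <- rarefy_table(filt, depth = 300, seed = 13)
  expect_true(all(nochim$asv_seq %in% raw$asv_seq))
  expect_true(all(filt$asv_seq %in% nochim$asv_seq))
  expect_true(all(rar$asv_seq %in% filt$asv_seq))
  expect_true(all(rowSums(nochim$counts) <= rowSums(raw$counts)))
  expect_true(all(rowSums(filt$counts) <= rowSums(nochim$counts)))
  expect_true(all(rowSums(rar$counts) == 300))
})
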