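# PERMANOVA and pairwise disparity tests.

# brute-force pseudo-F straight from the definition (group sums over an
# explicit double loop), independent of the package implementation
brute_force_F <- function(scores, labels) {
  n <- nrow(scores)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d2[i, j] <- sum((scores[i, ] - scores[j, ])^2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
  }
  g <- length(unique(labels))
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}

test_that("pseudo-F and the exact p match brute-force enumeration on 4 points", {
  set.seed(2)
  x <- matrix(rnorm(8), 4, 2)
  labels <- c("A", "A", "B", "B")
  res <- permanova(x, labels, n_permutations = 999, seed = 1)
  expect_true(res$exact)
  expect_equal(res$n_permutations, 6L)  # 4! / (2! 2!)
  expect_equal(res$pseudo_F, brute_force_F(x, labels), tolerance = 1e-12)
  # enumerate all 6 assignments by hand
  combos <- combn(4, 2)
  Fs <- apply(combos, 2, function(ii) {
    lab <- rep("B", 4); lab[ii] <- "A"
    brute_force_F(x, lab)
  })
  expect_equal(sort(res$permutation_Fs), sort(Fs), tolerance = 1e-10)
  expect_equal(res$p_value, mean(Fs >= res$pseudo_F - 1e-12))
})

test_that("exhaustive enumeration also matches for three unequal groups", {
  set.seed(5)
  x <- matrix(rnorm(14), 7, 2)
  labels <- c("A", "A", "A", "B", "B", "C", "C")
  res <- permanova(x, labels, n_permutations = 9999, seed = 1)
  expect_true(res$exact)
  expect_equal(res$n_permutations, choose(7, 3) * choose(4, 2))  # 210
  expect_equal(res$pseudo_F, brute_force_F(x, labels), tolerance = 1e-12)
  expect_gte(res$p_value, 1 / 210)
})

test_that("sampled p-values respect the (1 + exceed)/(1 + n) floor", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40), 20, 2),
             matrix(rnorm(40, mean = 30), 20, 2))
  labels <- rep(c("A", "B"), each = 20)
  res <- permanova(x, labels, n_permutations = 99, seed = 3)
  expect_false(res$exact)
  expect_equal(res$p_value, 1 / 100)
  expect_gt(res$p_value, 0)
  expect_equal(length(res$permutation_Fs), 99L)
})

test_that("pseudo-F grows with group separation and survives rotation", {
  set.seed(11)
  base <- matrix(rnorm(60), 30, 2)
  labels <- rep(c("A", "B"), each = 15)
  Fs <- vapply(c(0, 1, 2, 4), function(delta) {
    x <- base
    x[labels == "B", 1] <- x[labels == "B", 1] + delta
    permanova(x, labels, n_permutations = 99, seed = 1)$pseudo_F
  }, numeric(1))
  expect_true(all(diff(Fs) > 0))
  # rotation invariance of the permutation distribution (Euclidean)
  x <- base; x[labels == "B", 1] <- x[labels == "B", 1] + 2
  th <- 0.83
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  r1 <- permanova(x, labels, n_permutations = 199, seed = 7)
  r2 <- permanova(x %*% rot, labels, n_permutations = 199, seed = 7)
  expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-9)
  expect_equal(r1$permutation_Fs, r2$permutation_Fs, tolerance = 1e-9)
})

test_that("pseudo-F agrees with an independent PERMANOVA implementation", {
  skip_if_not_installed("vegan")
  set.seed(19)
  x <- rbind(matrix(rnorm(30), 15, 2),
             matrix(rnorm(30, mean = 1), 15, 2))
  labels <- rep(c("A", "B"), each = 15)
  res <- permanova(x, labels, n_permutations = 99, seed = 1)
  df <- data.frame(g = labels)
  va <- vegan::adonis2(stats::dist(x) ~ g, data = df, permutations = 99)
  expect_equal(res$pseudo_F, va$F[1], tolerance = 1e-8)
})

test_that("group size guards fire", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(permanova(x, c("A", "A", "A", "A", "B"), 99, 1), "n >= 2")
  expect_error(permanova(x, rep("A", 5), 99, 1), "2 groups")
})

test_that("pairwise tests honour Bonferroni monotonicity and skip tiny groups", {
  set.seed(30)
  x <- rbind(matrix(rnorm(60), 30, 2),
             matrix(rnorm(60, sd = 3), 30, 2),
             matrix(rnorm(20), 10, 2),
             matrix(rnorm(4), 2, 2))
  labels <- c(rep("a", 30), rep("b", 30), rep("c", 10), rep("tiny", 2))
  res <- pairwise_size_position_tests(x, labels, "sum_of_variances",
                                      n_resamples = 199, seed = 2)
  expect_equal(res$n_comparisons, 3L)          # a-b, a-c, b-c
  expect_equal(res$untestable, "tiny")
  expect_true(all(res$table$p_bonferroni >= res$table$p_raw))
  expect_true(all(res$table$p_bonferroni <= 1))
  expect_true(all(res$table$p_raw > 0))
  # single comparison: corrected equals raw
  res2 <- pairwise_size_position_tests(x[labels %in% c("a", "b"), ],
                                       labels[labels %in% c("a", "b")],
                                       "sum_of_variances",
                                       n_resamples = 199, seed = 2)
  expect_equal(res2$table$p_bonferroni, res2$table$p_raw)
})

test_that("pairwise tests are reproducible from the seed", {
  set.seed(31)
  x <- matrix(rnorm(120), 60, 2)
  labels <- rep(c("a", "b"), each = 30)
  r1 <- pairwise_size_position_tests(x, labels, n_resamples = 99, seed = 9)
  r2 <- pairwise_size_position_tests(x, labels, n_resamples = 99, seed = 9)
  expect_identical(r1$results[[1]]$null_values, r2$results[[1]]$null_values)
})

test_that("the pooled null is calibrated for identical groups", {
  # under H0 the raw p-value should be roughly uniform; its median over
  # replicates should sit near 0.5
  set.seed(77)
  ps <- vapply(1:60, function(i) {
    x <- matrix(rnorm(80), 40, 2)
    labels <- rep(c("a", "b"), each = 20)
    pairwise_size_position_tests(x, labels, "sum_of_variances",
                                 n_resamples = 99,
                                 seed = i)$table$p_raw
  }, numeric(1))
  expect_gt(median(ps), 0.25)
  expect_lt(median(ps), 0.75)
  expect_gt(mean(ps < 0.25), 0.05)
  expect_gt(mean(ps > 0.75), 0.05)
})

test_that("coarse grouping collapses fossil slices", {
  labs <- c("extant", "Cretaceous", "Eocene", "Miocene", "extant")
  expect_equal(coarse_grouping(labs),
               c("extant", "fossil", "fossil", "fossil", "extant"))
})
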