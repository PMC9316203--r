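# Morphospace: matrix assembly, PCA contract, effective components,
# PC-shape rendering, variance report.

make_embedding <- function(n = 60, seed = 2, n_points = 128, H = 12) {
  set.seed(seed)
  outs <- lapply(seq_len(n), function(i) {
    generate_outline(shape_params(
      posterior_rim_curvature = stats::rnorm(1, -0.1, 0.08),
      stylet_rel_length = stats::rnorm(1, 1.3, 0.08),
      stylet_thickness = max(0.02, stats::rnorm(1, 0.12, 0.025))),
      n_points = n_points)
  })
  cfs <- lapply(outs, function(o) efa_normalize(compute_efa(o, H)))
  assemble_matrix(cfs, groups = rep(c("a", "b"), length.out = n))
}

test_that("assembled matrix has 4H - 3 named columns in input order", {
  m <- make_embedding(n = 8, H = 20)
  expect_equal(ncol(m$matrix), 77L)
  expect_equal(m$manifest$name[1:5], c("d1", "a2", "b2", "c2", "d2"))
  expect_equal(nrow(m$manifest), 77L)
  # identical specimens give identical rows
  o <- generate_outline(shape_params(), 128)
  cf <- efa_normalize(compute_efa(o, 10))
  mm <- assemble_matrix(list(cf, cf))
  expect_identical(mm$matrix[1, ], mm$matrix[2, ])
})

test_that("assembly rejects unnormalized or mixed-harmonic input", {
  o <- generate_outline(shape_params(), 128)
  raw <- compute_efa(o, 10)
  expect_error(assemble_matrix(list(raw)), "normalized")
  n1 <- efa_normalize(compute_efa(o, 10))
  n2 <- efa_normalize(compute_efa(o, 12))
  expect_error(assemble_matrix(list(n1, n2)), "mixed")
})

test_that("column manifest round-trips through CSV", {
  m <- make_embedding(n = 6, H = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(m$manifest, f, row.names = FALSE)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$name, m$manifest$name)
  expect_equal(back$harmonic, m$manifest$harmonic)
})

test_that("PCA satisfies its algebraic contract", {
  m <- make_embedding(n = 40, H = 10)
  emb <- morphospace_pca(m)
  expect_equal(sum(emb$proportions), 1, tolerance = 1e-9)
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
  # trace identity: total variance preserved
  expect_equal(sum(emb$eigenvalues),
               sum(apply(m$matrix, 2, stats::var)), tolerance = 1e-9)
  # scores uncorrelated
  k <- sum(emb$eigenvalues > 1e-12)
  cc <- stats::cov(emb$scores[, 1:k])
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # reconstruction from all components reproduces the centered data
  xc <- sweep(m$matrix, 2, emb$mean_vector)
  expect_lt(max(abs(emb$scores %*% t(emb$loadings) - xc)), 1e-8)
})

test_that("PCA scores match an independent SVD oracle up to sign", {
  set.seed(55)
  x <- matrix(rnorm(500), 50, 10)
  emb <- morphospace_pca(x)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  oracle <- sv$u %*% diag(sv$d)
  for (j in seq_len(ncol(oracle))) {
    diff_same <- max(abs(emb$scores[, j] - oracle[, j]))
    diff_flip <- max(abs(emb$scores[, j] + oracle[, j]))
    expect_lt(min(diff_same, diff_flip), 1e-8)
  }
})

test_that("embedding is invariant (up to sign) to row permutation", {
  set.seed(66)
  x <- matrix(rnorm(300), 30, 10)
  perm <- sample.int(30)
  e1 <- morphospace_pca(x)
  e2 <- morphospace_pca(x[perm, ])
  expect_equal(e1$eigenvalues, e2$eigenvalues, tolerance = 1e-9)
  for (j in 1:5) {
    s1 <- e1$scores[perm, j]; s2 <- e2$scores[, j]
    expect_lt(min(max(abs(s1 - s2)), max(abs(s1 + s2))), 1e-8)
  }
})

test_that("the effective-component rule counts eigenvalues above the mean", {
  expect_equal(effective_components(c(5, 3, 1, 0.5, 0.5)), 2L)
  expect_equal(effective_components(rep(2, 6)), 0L)
  expect_equal(effective_components(c(19, 1, 1), rule = "cumulative_90"), 1L)
  expect_equal(effective_components(c(10, 1, 1), rule = "cumulative_90"), 2L)
  # degenerate all-equal case: pipeline falls back to 2 with a warning
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))  # isotropic covariance
  expect_warning(emb <- morphospace_pca(tri), "falling back")
  expect_equal(emb$effective_k, 2L)
})

test_that("a collinear point cloud has one effective dimension", {
  t <- seq(0, 1, length.out = 20)
  x <- cbind(t, 2 * t) + 5
  emb <- suppressWarnings(morphospace_pca(x))
  expect_equal(emb$proportions[1], 1, tolerance = 1e-12)
  expect_equal(sum(emb$eigenvalues > 1e-12), 1L)
})

test_that("multiplier 0 renders the mean shape for every component", {
  m <- make_embedding(n = 30, H = 10)
  emb <- morphospace_pca(m)
  r1 <- shape_along_pc(emb, 1, 0)
  r2 <- shape_along_pc(emb, min(2, emb$effective_k), 0)
  expect_equal(r1$points, r2$points, tolerance = 1e-12)
})

test_that("PC renders track the underlying thickness factor", {
  # pure thickness factor: the matching PC's +2 SD render must enclose
  # more area (thicker stylets) than the -2 SD render
  set.seed(12)
  outs <- lapply(1:40, function(i) {
    generate_outline(shape_params(
      stylet_thickness = stats::runif(1, 0.06, 0.2)), 128)
  })
  th_true <- vapply(outs, function(o) NA_real_, numeric(1))
  cfs <- lapply(outs, function(o) efa_normalize(compute_efa(o, 12)))
  emb <- morphospace_pca(assemble_matrix(cfs))
  hi <- shape_along_pc(emb, 1, 2)
  lo <- shape_along_pc(emb, 1, -2)
  a_hi <- abs(signed_area(hi$points))
  a_lo <- abs(signed_area(lo$points))
  expect_true(abs(a_hi - a_lo) / max(a_hi, a_lo) > 0.01)
  # sign convention makes the direction reproducible, check both renders
  # differ and the mean sits between them
  a_mean <- abs(signed_area(shape_along_pc(emb, 1, 0)$points))
  expect_true((a_hi - a_mean) * (a_mean - a_lo) > 0)
})

test_that("variance report flags the within-rounding case and rejects larger gaps", {
  rep1 <- variance_report(c(72.4, 17.9, 3.4), 93.8)
  expect_equal(rep1$cumulative, 93.7)
  expect_true(rep1$within_rounding)
  expect_match(rep1$message, "within rounding")
  rep2 <- variance_report(c(70.0, 17.9, 3.4), 93.8)
  expect_false(rep2$within_rounding)
})
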