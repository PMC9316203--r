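# Permutation and resampling tests on morphospace scores: a one-way
# PERMANOVA (pseudo-F on Euclidean distances, free permutation of group
# labels, exhaustive enumeration when feasible) and bootstrapped,
# Bonferroni-corrected pairwise tests of disparity differences with a
# pooled null.

#' One-way PERMANOVA on morphospace scores
#'
#' Partitions the total sum of squared Euclidean distances into between-
#' and within-group components and forms the pseudo-F statistic
#' `F = (SS_between / (g - 1)) / (SS_within / (N - g))`. Significance is
#' assessed by permuting the group labels; when the number of distinct
#' label arrangements is at most `n_permutations` the null is enumerated
#' exhaustively and the p-value is exact.
#'
#' @param scores Numeric matrix (specimens x components).
#' @param labels Group labels, length `nrow(scores)`; every group must
#'   have at least 2 members.
#' @param n_permutations Number of random permutations (ignored when
#'   enumeration is exhaustive).
#' @param seed Integer seed for the permutation draw.
#' @return Object of class `"permanova_result"`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `permutation_Fs`, `exact` flag, `seed`,
#'   `grouping`, `df`.
#' @export
permanova <- function(scores, labels, n_permutations = 9999L, seed = 1L) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2L)
    stop("permanova: need at least 2 groups", call. = FALSE)
  if (any(counts < 2L))
    stop("permanova: every group needs n >= 2 (got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         ")", call. = FALSE)
  N <- nrow(scores)
  g <- length(counts)
  D2 <- as.matrix(stats::dist(scores))^2
  sst <- sum(D2) / (2 * N)

  ssw_for <- function(lab) {
    s <- 0
    for (gr in unique(lab)) {
      idx <- lab == gr
      s <- s + sum(D2[idx, idx]) / (2 * sum(idx))
    }
    s
  }
  f_from_ssw <- function(ssw) ((sst - ssw) / (g - 1)) / (ssw / (N - g))
  F_obs <- f_from_ssw(ssw_for(labels))

  n_arr <- count_label_arrangements(as.integer(counts))
  if (!is.na(n_arr) && n_arr <= n_permutations) {
    arr <- label_arrangements(labels)
    Fs <- vapply(arr, function(lab) f_from_ssw(ssw_for(lab)), numeric(1))
    p <- mean(Fs >= F_obs - 1e-12)   # identity arrangement included
    exact <- TRUE
    n_used <- length(Fs)
  } else {
    set.seed(as.integer(seed))
    # vectorized over permutations: SSW via indicator algebra
    perms <- replicate(n_permutations, sample.int(N))
    Fs <- numeric(n_permutations)
    ssw_all <- numeric(n_permutations)
    lev <- names(counts)
    for (gr in lev) {
      members <- labels == gr
      Z <- matrix(0, N, n_permutations)
      Z[cbind(as.vector(perms[members, , drop = FALSE]),
              rep(seq_len(n_permutations), each = sum(members)))] <- 1
      ssw_all <- ssw_all + colSums(Z * (D2 %*% Z)) / (2 * sum(members))
    }
    Fs <- f_from_ssw(ssw_all)
    p <- (1 + sum(Fs >= F_obs - 1e-12)) / (1 + n_permutations)
    exact <- FALSE
    n_used <- n_permutations
  }
  structure(list(pseudo_F = F_obs, p_value = p, n_permutations = n_used,
                 permutation_Fs = Fs, exact = exact,
                 seed = as.integer(seed), grouping = names(counts),
                 df = c(between = g - 1L, within = N - g)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "<permanova> pseudo-F = %.4g (df %d, %d), p = %.4g (%s, %d arrangements)\n",
    x$pseudo_F, x$df[1], x$df[2], x$p_value,
    if (x$exact) "exact" else "sampled", x$n_permutations))
  invisible(x)
}

# number of distinct label arrangements N! / prod(n_g!); NA on overflow
count_label_arrangements <- function(counts) {
  lg <- lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  if (lg > log(1e15)) return(NA_real_)
  round(exp(lg))
}

# all distinct arrangements of a label vector (as a list of vectors)
label_arrangements <- function(labels) {
  lev <- unique(labels)
  counts <- vapply(lev, function(l) sum(labels == l), 1L)
  N <- length(labels)
  res <- list()
  recurse <- function(pos_left, lab_idx, current) {
    if (lab_idx == length(lev)) {
      current[pos_left] <- lev[lab_idx]
      res[[length(res) + 1L]] <<- current
      return(invisible(NULL))
    }
    sel <- utils::combn(length(pos_left), counts[lab_idx])
    for (j in seq_len(ncol(sel))) {
      cur <- current
      cur[pos_left[sel[, j]]] <- lev[lab_idx]
      recurse(pos_left[-sel[, j]], lab_idx + 1L, cur)
    }
  }
  recurse(seq_len(N), 1L, character(N))
  res
}

#' Pairwise bootstrapped disparity-difference tests
#'
#' For each pair of groups (both with at least `min_n` members) the
#' observed statistic is the absolute difference of the disparity metric
#' between the two groups. The null distribution pools the pair's rows
#' and repeatedly draws two bootstrap samples from the pool, each
#' rarefied to the smaller group's size — exchangeable under the null of
#' no disparity difference. Raw p-values are
#' `(1 + #null >= observed) / (1 + n_resamples)`; the Bonferroni
#' correction multiplies by the number of pairs actually tested. Groups
#' below `min_n` are reported as untestable.
#'
#' @param scores Numeric matrix (specimens x effective components).
#' @param labels Group labels.
#' @param metric `"sum_of_variances"` or `"average_displacement"`.
#' @param n_resamples Null resamples per pair.
#' @param seed Integer seed.
#' @param min_n Minimum group size for testing (default 3).
#' @return Object of class `"pairwise_tests"`: a list with `results`
#'   (list of per-pair records), `untestable` (character vector of
#'   skipped groups), `metric`, `n_comparisons`, `seed`, and a `table`
#'   data frame.
#' @export
pairwise_size_position_tests <- function(scores, labels,
                                         metric = c("sum_of_variances",
                                                    "average_displacement"),
                                         n_resamples = 999L, seed = 1L,
                                         min_n = 3L) {
  metric <- match.arg(metric)
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  fn <- switch(metric, sum_of_variances = sum_of_variances,
               average_displacement = average_displacement)
  lev <- unique(labels)
  sizes <- vapply(lev, function(l) sum(labels == l), 1L)
  testable <- lev[sizes >= min_n]
  untestable <- lev[sizes < min_n]
  if (length(testable) < 2L)
    stop("fewer than two groups reach the minimum size (", min_n, ")",
         call. = FALSE)
  pairs <- utils::combn(testable, 2L)
  n_comp <- ncol(pairs)
  set.seed(as.integer(seed))
  results <- vector("list", n_comp)
  for (j in seq_len(n_comp)) {
    ga <- pairs[1L, j]; gb <- pairs[2L, j]
    A <- scores[labels == ga, , drop = FALSE]
    B <- scores[labels == gb, , drop = FALSE]
    obs <- abs(fn(A) - fn(B))
    pool <- rbind(A, B)
    n_min <- min(nrow(A), nrow(B))
    np <- nrow(pool)
    null_vals <- vapply(seq_len(n_resamples), function(r) {
      s1 <- pool[sample.int(np, n_min, replace = TRUE), , drop = FALSE]
      s2 <- pool[sample.int(np, n_min, replace = TRUE), , drop = FALSE]
      suppressWarnings(
        tryCatch(abs(fn(s1) - fn(s2)), error = function(e) NA_real_))
    }, numeric(1))
    null_vals <- null_vals[!is.na(null_vals)]
    p_raw <- (1 + sum(null_vals >= obs - 1e-15)) / (1 + length(null_vals))
    results[[j]] <- list(pair = c(ga, gb), metric = metric,
                         observed_diff = obs, null_values = null_vals,
                         p_raw = p_raw, p_bonferroni = NA_real_,
                         n_resamples = length(null_vals),
                         seed = as.integer(seed))
  }
  for (j in seq_len(n_comp))
    results[[j]]$p_bonferroni <- min(1, results[[j]]$p_raw * n_comp)
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(group_a = r$pair[1], group_b = r$pair[2], metric = r$metric,
               observed_diff = r$observed_diff, p_raw = r$p_raw,
               p_bonferroni = r$p_bonferroni,
               n_resamples = r$n_resamples)))
  structure(list(results = results, untestable = untestable,
                 metric = metric, n_comparisons = n_comp,
                 seed = as.integer(seed), table = tab),
            class = "pairwise_tests")
}

#' @export
print.pairwise_tests <- function(x, ...) {
  cat(sprintf("<pairwise_tests> metric=%s, %d pair(s), Bonferroni x%d\n",
              x$metric, x$n_comparisons, x$n_comparisons))
  print(x$table, row.names = FALSE)
  if (length(x$untestable))
    cat("  untestable (below minimum size):",
        paste(x$untestable, collapse = ", "), "\n")
  invisible(x)
}

#' Collapse time-slice labels to the coarse fossil-vs-extant grouping
#'
#' @param labels Character vector of slice labels; everything except
#'   `extant_label` becomes `"fossil"`.
#' @param extant_label Label of the extant group.
#' @return Character vector with levels `"extant"` and `"fossil"`.
#' @export
coarse_grouping <- function(labels, extant_label = "extant") {
  ifelse(labels == extant_label, "extant", "fossil")
}
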