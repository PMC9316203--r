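# Group disparity in morphospace: occupied size (sum of variances) and
# position (average displacement), with bootstrap and rarefaction for
# unequal sample sizes. All metrics operate on score matrices restricted
# to the effective components; the morphospace origin (the grand mean of
# all specimens, i.e. score 0) is the reference point for position.

#' Sum of variances of a group's scores
#'
#' Disparity "size" metric: the sum over score columns of the sample
#' variance (n - 1 denominator) of the group's rows — equivalently the
#' trace of the group covariance matrix.
#'
#' @param scores Numeric matrix (group rows x components).
#' @return Numeric scalar.
#' @examples
#' sum_of_variances(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))  # 2/3
#' @export
sum_of_variances <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L)
    stop("sum_of_variances: need >= 2 rows (variance undefined)",
         call. = FALSE)
  sum(apply(scores, 2, stats::var))
}

#' Average displacement of a group's scores
#'
#' Disparity "position" metric: the mean over group members of the ratio
#' (distance from the morphospace origin) / (distance from the group
#' centroid). Values above 1 indicate a group displaced away from the
#' origin relative to its own spread. Members lying exactly at the
#' centroid are excluded with a warning; if all members coincide with the
#' centroid the metric is undefined.
#'
#' @param scores Numeric matrix (group rows x components).
#' @param origin Reference point (default the morphospace origin, 0).
#' @return Numeric scalar.
#' @examples
#' average_displacement(cbind(c(1, 3)))  # centroid 2; (1/1 + 3/1)/2 = 2
#' @export
average_displacement <- function(scores, origin = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L)
    stop("average_displacement: need >= 2 rows", call. = FALSE)
  if (is.null(origin)) origin <- numeric(ncol(scores))
  centroid <- colMeans(scores)
  d_orig <- row_norms(sweep(scores, 2, origin))
  d_cent <- row_norms(sweep(scores, 2, centroid))
  scale_ <- max(d_cent, d_orig, 1e-300)
  at_centroid <- d_cent <= 1e-12 * scale_
  if (all(at_centroid))
    stop("average_displacement: all members at the group centroid",
         call. = FALSE)
  if (any(at_centroid)) {
    warning(sum(at_centroid),
            " member(s) exactly at the group centroid excluded",
            call. = FALSE)
    d_orig <- d_orig[!at_centroid]
    d_cent <- d_cent[!at_centroid]
  }
  mean(d_orig / d_cent)
}

#' Bootstrap (and optionally rarefy) a disparity metric
#'
#' Each bootstrap replicate draws `rarefy_to` rows (default: the full
#' group size) with replacement from the group and recomputes the metric.
#' Rarefaction to a common size makes disparity comparable across groups
#' of very different n.
#'
#' @param scores Numeric matrix of the group's rows (effective components).
#' @param metric `"sum_of_variances"` or `"average_displacement"`.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param rarefy_to Rows per replicate; `NULL` = group size. Values below
#'   3 are refused (the metrics are unstable there).
#' @param seed Integer seed (required for reproducibility).
#' @param group Label stored in the result.
#' @return Object of class `"disparity_estimate"`: `metric`, `group`,
#'   `observed`, `bootstrap_values`, `n_boot`, `rarefied_n`, `ci95`,
#'   `seed`, `n`, `too_small` flag.
#' @export
bootstrap_disparity <- function(scores,
                                metric = c("sum_of_variances",
                                           "average_displacement"),
                                n_boot = 1000L, rarefy_to = NULL,
                                seed = 1L, group = NA_character_) {
  metric <- match.arg(metric)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  fn <- switch(metric, sum_of_variances = sum_of_variances,
               average_displacement = average_displacement)
  if (n < 3L) {
    warning("group ", group, " (n = ", n,
            ") too small for disparity; observed value reported, ",
            "no bootstrap", call. = FALSE)
    obs <- if (n >= 2L) fn(scores) else NA_real_
    return(structure(list(metric = metric, group = group, observed = obs,
                          bootstrap_values = numeric(0), n_boot = 0L,
                          rarefied_n = NA_integer_,
                          ci95 = c(NA_real_, NA_real_),
                          seed = as.integer(seed), n = n, too_small = TRUE),
                     class = "disparity_estimate"))
  }
  if (!is.null(rarefy_to)) {
    rarefy_to <- as.integer(rarefy_to)
    if (rarefy_to < 3L)
      stop("rarefy_to < 3: metric unstable at that size", call. = FALSE)
    if (rarefy_to > n)
      stop("rarefy_to exceeds the group size (", n, ")", call. = FALSE)
  }
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  draw_n <- if (is.null(rarefy_to)) n else rarefy_to
  obs <- fn(scores)
  set.seed(as.integer(seed))
  bv <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, draw_n, replace = TRUE)
    suppressWarnings(
      tryCatch(fn(scores[idx, , drop = FALSE]), error = function(e) 0))
  }, numeric(1))
  ci <- unname(stats::quantile(bv, c(0.025, 0.975), type = 7))
  structure(list(metric = metric, group = group, observed = obs,
                 bootstrap_values = bv, n_boot = n_boot,
                 rarefied_n = if (is.null(rarefy_to)) NA_integer_
                              else rarefy_to,
                 ci95 = ci, seed = as.integer(seed), n = n,
                 too_small = FALSE),
            class = "disparity_estimate")
}

#' @export
print.disparity_estimate <- function(x, ...) {
  cat(sprintf("<disparity_estimate> %s  group=%s  n=%d\n",
              x$metric, x$group, x$n))
  if (x$too_small) {
    cat("  flagged: too small for disparity; observed =",
        format(x$observed), "\n")
  } else {
    cat(sprintf("  observed %.5g  boot mean %.5g  ci95 [%.5g, %.5g]%s\n",
                x$observed, mean(x$bootstrap_values), x$ci95[1], x$ci95[2],
                if (!is.na(x$rarefied_n))
                  sprintf("  (rarefied to %d)", x$rarefied_n) else ""))
  }
  invisible(x)
}

#' Per-group disparity table for an embedding
#'
#' Convenience wrapper: restricts the scores to the effective components
#' and bootstraps both metrics per group.
#'
#' @param embedding A `"morphospace"` with `groups`.
#' @param groups Groups to include (default all).
#' @param n_boot,rarefy_to,seed Passed to [bootstrap_disparity()];
#'   `rarefy_to = "auto"` uses the smallest included group size that is
#'   at least 3.
#' @return Data frame, one row per group x metric.
#' @export
disparity_table <- function(embedding, groups = NULL, n_boot = 1000L,
                            rarefy_to = "auto", seed = 1L) {
  stopifnot(inherits(embedding, "morphospace"), !is.null(embedding$groups))
  sc <- embedding$scores[, seq_len(embedding$effective_k), drop = FALSE]
  gl <- embedding$groups
  if (is.null(groups)) groups <- unique(gl)
  sizes <- vapply(groups, function(g) sum(gl == g), 1L)
  if (identical(rarefy_to, "auto")) {
    eligible <- sizes[sizes >= 3L]
    rarefy_to <- if (length(eligible)) min(eligible) else NULL
  }
  rows <- list()
  for (g in groups) {
    sub <- sc[gl == g, , drop = FALSE]
    for (m in c("sum_of_variances", "average_displacement")) {
      rt <- if (!is.null(rarefy_to) && nrow(sub) >= 3L)
        min(rarefy_to, nrow(sub)) else NULL
      est <- suppressWarnings(
        bootstrap_disparity(sub, metric = m, n_boot = n_boot,
                            rarefy_to = rt, seed = seed, group = g))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, n = est$n, observed = est$observed,
        boot_mean = if (est$too_small) NA_real_
                    else mean(est$bootstrap_values),
        ci_low = est$ci95[1], ci_high = est$ci95[2],
        rarefied_n = est$rarefied_n, n_boot = est$n_boot,
        seed = est$seed, too_small = est$too_small)
    }
  }
  do.call(rbind, rows)
}
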