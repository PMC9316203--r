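# Morphospace construction: assemble the normalized-coefficient matrix,
# PCA on the (unstandardized) covariance, effective-component selection,
# and rendering of shape variation along principal components.

#' Assemble the coefficient matrix for PCA
#'
#' Rows are specimens (input order preserved), columns the normalized
#' coefficients excluding the constants fixed by normalization (`a1`,
#' `b1`, `c1` are dropped; `d1` is retained), i.e. `4 * H - 3` columns
#' for `H` harmonics.
#'
#' @param coeff_list List of normalized `efa_coef`, all with the same
#'   number of harmonics.
#' @param specimen_ids,groups Optional label vectors aligned with
#'   `coeff_list`.
#' @return A list with `matrix` (rownames = specimen ids) and
#'   `manifest` (data frame naming every column: coefficient and
#'   harmonic).
#' @export
assemble_matrix <- function(coeff_list, specimen_ids = NULL, groups = NULL) {
  stopifnot(length(coeff_list) >= 1L)
  ok <- vapply(coeff_list, function(cf)
    inherits(cf, "efa_coef") && isTRUE(cf$normalized), TRUE)
  if (!all(ok))
    stop("assemble_matrix: all inputs must be normalized efa_coef",
         call. = FALSE)
  H <- vapply(coeff_list, function(cf) cf$n_harmonics, 1L)
  if (length(unique(H)) != 1L)
    stop("assemble_matrix: mixed harmonic counts: ",
         paste(unique(H), collapse = ", "), call. = FALSE)
  m <- t(vapply(coeff_list, efa_flatten,
                numeric(4L * H[1L] - 3L)))
  if (is.null(specimen_ids))
    specimen_ids <- sprintf("spec_%03d", seq_len(nrow(m)))
  rownames(m) <- specimen_ids
  manifest <- data.frame(
    column = seq_len(ncol(m)),
    name = colnames(m),
    coefficient = substr(colnames(m), 1, 1),
    harmonic = as.integer(sub("^[abcd]", "", colnames(m))))
  list(matrix = m, manifest = manifest,
       specimen_ids = specimen_ids, groups = groups)
}

#' Principal component analysis of the coefficient matrix
#'
#' Centered, unstandardized covariance PCA. Scores are the centered data
#' projected on the eigenvectors; each loading's sign is fixed so its
#' largest-magnitude entry is positive (reproducible orientation).
#' The effective number of components (eigenvalue above the mean
#' eigenvalue; see [effective_components()]) is stored; a degenerate
#' zero count falls back to 2 with a warning.
#'
#' @param x A matrix, or the list returned by [assemble_matrix()].
#' @param groups Optional group labels (taken from `x` if present).
#' @param effective_rule `"mean_eigenvalue"` (default) or
#'   `"cumulative_90"` (smallest k with cumulative proportion >= 0.9).
#' @return Object of class `"morphospace"`: `scores`, `eigenvalues`,
#'   `proportions`, `effective_k`, `loadings`, `mean_vector`,
#'   `specimen_ids`, `groups`.
#' @export
morphospace_pca <- function(x, groups = NULL,
                            effective_rule = c("mean_eigenvalue",
                                               "cumulative_90")) {
  effective_rule <- match.arg(effective_rule)
  if (is.list(x) && !is.null(x$matrix)) {
    if (is.null(groups)) groups <- x$groups
    x <- x$matrix
  }
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("PCA needs at least 3 rows", call. = FALSE)
  if (anyNA(x)) stop("PCA input contains missing values", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  if (sum(xc^2) == 0) stop("PCA input has rank 0", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rot <- pc$rotation
  sco <- pc$x
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  prop <- ev / sum(ev)
  emb <- structure(
    list(scores = sco, eigenvalues = ev, proportions = prop,
         effective_k = NA_integer_, loadings = rot, mean_vector = mu,
         specimen_ids = rownames(x),
         groups = groups, effective_rule = effective_rule),
    class = "morphospace")
  k <- effective_components(emb, rule = effective_rule)
  if (k == 0L) {
    warning("effective-component rule returned 0; falling back to k = 2",
            call. = FALSE)
    k <- min(2L, length(ev))
  }
  emb$effective_k <- k
  emb
}

#' @export
print.morphospace <- function(x, ...) {
  k <- min(5L, length(x$proportions))
  cat(sprintf("<morphospace> %d specimens, %d components, effective k = %d\n",
              nrow(x$scores), length(x$eigenvalues), x$effective_k))
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$proportions[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Count effective principal components
#'
#' Default rule: the number of eigenvalues strictly greater than the mean
#' eigenvalue. With all eigenvalues equal the count is 0 (callers fall
#' back to 2). The alternative rule returns the smallest k whose
#' cumulative explained proportion reaches 90%.
#'
#' @param x A `"morphospace"` or a numeric vector of eigenvalues.
#' @param rule `"mean_eigenvalue"` or `"cumulative_90"`.
#' @return Integer count.
#' @export
effective_components <- function(x, rule = c("mean_eigenvalue",
                                             "cumulative_90")) {
  rule <- match.arg(rule)
  ev <- if (inherits(x, "morphospace")) x$eigenvalues else as.numeric(x)
  if (rule == "mean_eigenvalue") {
    m <- mean(ev)
    sum(ev > m * (1 + 1e-12))
  } else {
    cum <- cumsum(ev) / sum(ev)
    which(cum >= 0.9)[1L]
  }
}

#' Render the shape at a position along one principal component
#'
#' Reconstructs the outline corresponding to
#' `mean_vector + multiplier * sd_pc * loading_pc` in coefficient space
#' (multiplier in standard-deviation units of the component's scores).
#' `multiplier = 0` returns the mean shape for every component.
#'
#' @param embedding A `"morphospace"`.
#' @param pc_index Component index (<= `effective_k`).
#' @param multiplier Position along the component in SD units.
#' @param n_points Points in the rendered outline.
#' @return An [outline()].
#' @export
shape_along_pc <- function(embedding, pc_index = 1L, multiplier = 0,
                           n_points = 256L) {
  stopifnot(inherits(embedding, "morphospace"))
  pc_index <- as.integer(pc_index)
  if (pc_index < 1L || pc_index > embedding$effective_k)
    stop("pc_index must be in 1..effective_k", call. = FALSE)
  sdev <- sqrt(embedding$eigenvalues[pc_index])
  v <- embedding$mean_vector +
    multiplier * sdev * embedding$loadings[, pc_index]
  o <- efa_reconstruct(efa_unflatten(v), n_points = n_points)
  o$specimen_id <- sprintf("PC%d_%+gSD", pc_index, multiplier)
  o
}

#' Check printed variance proportions against a printed total
#'
#' Published explained-variance percentages are independently rounded, so
#' their sum can differ from the published cumulative total by up to
#' ~0.05 percentage points per term. This formatter sums the printed
#' per-component percentages and flags agreement with the stated total
#' when the discrepancy is at most `tol_pp` percentage points (default
#' 0.15) — within-rounding agreement, never exact equality.
#'
#' @param proportions_percent Per-component percentages as printed.
#' @param stated_total_percent The printed cumulative percentage.
#' @param tol_pp Tolerance in percentage points.
#' @return List with `cumulative`, `stated_total`, `discrepancy_pp`,
#'   `within_rounding` and a formatted `message`.
#' @examples
#' variance_report(c(72.4, 17.9, 3.4), 93.8)
#' @export
variance_report <- function(proportions_percent, stated_total_percent,
                            tol_pp = 0.15) {
  cum <- sum(proportions_percent)
  disc <- abs(cum - stated_total_percent)
  within <- disc <= tol_pp
  msg <- sprintf(
    "components %s sum to cumulative %.1f%%; stated total %.1f%% (%s, discrepancy %.2f pp)",
    paste(sprintf("%.1f%%", proportions_percent), collapse = " + "),
    cum, stated_total_percent,
    if (within) "within rounding" else "NOT within rounding", disc)
  list(cumulative = cum, stated_total = stated_total_percent,
       discrepancy_pp = disc, within_rounding = within, message = msg)
}

#' Scatter plot of the morphospace
#'
#' The two standard panels: PC2 vs PC1 and PC3 vs PC1 (when available),
#' with group colours and a convex-hull overlay of each group's occupied
#' area.
#'
#' @param embedding A `"morphospace"` with `groups` set.
#' @param pcs Length-2 integer vector of components to plot.
#' @param hull_groups Groups to overlay convex hulls for (default: all).
#' @return A ggplot object.
#' @export
plot_morphospace <- function(embedding, pcs = c(1L, 2L),
                             hull_groups = NULL) {
  stopifnot(inherits(embedding, "morphospace"), length(pcs) == 2L)
  df <- data.frame(x = embedding$scores[, pcs[1L]],
                   y = embedding$scores[, pcs[2L]],
                   group = embedding$groups %||% "all")
  if (is.null(hull_groups)) hull_groups <- unique(df$group)
  hulls <- do.call(rbind, lapply(hull_groups, function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    if (nrow(sub) < 3L) return(NULL)
    sub[grDevices::chull(sub$x, sub$y), , drop = FALSE]
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC%d (%.1f%%)", pcs[1L],
                              100 * embedding$proportions[pcs[1L]]),
                  y = sprintf("PC%d (%.1f%%)", pcs[2L],
                              100 * embedding$proportions[pcs[2L]]),
                  colour = "group") +
    ggplot2::theme_minimal()
  if (!is.null(hulls))
    p <- p + ggplot2::geom_polygon(
      data = hulls,
      ggplot2::aes(fill = .data$group),
      alpha = 0.15, colour = NA, show.legend = FALSE)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
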