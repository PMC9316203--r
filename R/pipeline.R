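# End-to-end orchestration: synthetic generation (or file input) ->
# standardized outlines -> elliptic Fourier coefficients -> PCA
# morphospace -> group disparity -> permutation tests -> written outputs.
# A run is fully determined by (config, seed): re-running writes
# byte-identical CSV/JSON outputs.

#' Build a pipeline configuration
#'
#' @param groups List of [group_spec()] for synthetic input, or `NULL`
#'   when reading outlines from `input_path`.
#' @param input_path Optional path to an outline file (see
#'   [read_outlines()]); used when `groups` is `NULL`.
#' @param input_format Format of `input_path`.
#' @param n_points Contour points per outline.
#' @param n_harmonics Harmonics for the Fourier analysis.
#' @param effective_rule Effective-component rule (see
#'   [morphospace_pca()]).
#' @param n_boot Bootstrap replicates per disparity estimate.
#' @param rarefy_to `"auto"` (smallest group with n >= 3), an integer, or
#'   `NULL` for no rarefaction.
#' @param disparity_groups Groups to include in the disparity stage
#'   (`NULL` = all). Per-group metrics are independent: dropping a group
#'   here leaves every other group's values unchanged.
#' @param n_permutations PERMANOVA permutations.
#' @param n_resamples Resamples per pairwise disparity test.
#' @param grouping `"coarse"` (fossil vs extant) or `"slices"` (each time
#'   slice separately) for the test stage.
#' @param extant_label Label treated as extant by the coarse grouping.
#' @param seed Integer seed; mandatory, drives every stochastic stage.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(groups = study_group_specs(),
                            input_path = NULL, input_format = NULL,
                            n_points = 512L, n_harmonics = 20L,
                            effective_rule = "mean_eigenvalue",
                            n_boot = 1000L, rarefy_to = "auto",
                            disparity_groups = NULL,
                            n_permutations = 9999L, n_resamples = 999L,
                            grouping = c("coarse", "slices"),
                            extant_label = "extant",
                            seed = 1L) {
  grouping <- match.arg(grouping)
  if (is.null(groups) && is.null(input_path))
    stop("either `groups` (synthetic) or `input_path` must be given",
         call. = FALSE)
  if (!is.null(input_path) && !file.exists(input_path))
    stop("input_path does not exist: ", input_path, call. = FALSE)
  if (is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(groups = groups, input_path = input_path,
                 input_format = input_format,
                 n_points = as.integer(n_points),
                 n_harmonics = as.integer(n_harmonics),
                 effective_rule = effective_rule,
                 n_boot = as.integer(n_boot), rarefy_to = rarefy_to,
                 disparity_groups = disparity_groups,
                 n_permutations = as.integer(n_permutations),
                 n_resamples = as.integer(n_resamples),
                 grouping = grouping, extant_label = extant_label,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) generate or read outlines; (2) resample at equal arc
#' length; (3) elliptic Fourier analysis + normalization; (4) PCA
#' morphospace with effective-component selection; (5) per-group
#' disparity with bootstrap/rarefaction; (6) PERMANOVA and pairwise
#' disparity tests under the configured grouping; (7) optionally write
#' coefficients/scores CSVs and results/manifest JSON to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param verbose Log one line per stage.
#' @return Object of class `"pipeline_result"` with elements `dataset`
#'   (synthetic runs only), `coefficients`, `embedding`, `disparity`,
#'   `permanova`, `pairwise_size`, `pairwise_position`, `variance_report`,
#'   `manifest`, and `paths` when written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_ <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # 1. outlines
  dataset <- NULL
  if (!is.null(config$groups)) {
    dataset <- stage("simulate",
      generate_dataset(config$groups, n_points = config$n_points,
                       seed = config$seed))
    outlines <- dataset$outlines
  } else {
    outlines <- stage("read",
      read_outlines(config$input_path, config$input_format))
    outlines <- stage("resample", lapply(outlines, function(o)
      resample_equal_arclength(o, m = config$n_points)))
  }
  groups_v <- vapply(outlines, function(o) o$group, "")
  ids <- vapply(outlines, function(o) o$specimen_id, "")
  log_("outlines: %d specimens (%s)", length(outlines),
       paste(sprintf("%s=%d", names(table(groups_v)), table(groups_v)),
             collapse = ", "))

  # 2-3. harmonic analysis
  coeffs <- stage("efa", lapply(outlines, function(o)
    efa_normalize(compute_efa(o, n_harmonics = config$n_harmonics))))
  log_("efa: %d harmonics, %d coefficients per specimen",
       config$n_harmonics, 4L * config$n_harmonics - 3L)

  # 4. morphospace
  mat <- stage("assemble", assemble_matrix(coeffs, specimen_ids = ids,
                                           groups = groups_v))
  emb <- stage("pca", morphospace_pca(mat,
                                      effective_rule = config$effective_rule))
  log_("pca: effective k = %d (%s)", emb$effective_k,
       paste(sprintf("PC%d %.1f%%", seq_len(min(4, length(emb$proportions))),
                     100 * emb$proportions[seq_len(min(4, length(emb$proportions)))]),
             collapse = ", "))
  vrep <- variance_report(
    round(100 * emb$proportions[seq_len(emb$effective_k)], 1),
    round(100 * sum(emb$proportions[seq_len(emb$effective_k)]), 1))

  # 5. disparity
  disp <- stage("disparity",
    disparity_table(emb, groups = config$disparity_groups,
                    n_boot = config$n_boot, rarefy_to = config$rarefy_to,
                    seed = config$seed + 1001L))
  small <- unique(disp$group[disp$too_small])
  if (length(small))
    log_("disparity: group(s) flagged too small: %s",
         paste(small, collapse = ", "))

  # 6. tests
  sc_eff <- emb$scores[, seq_len(emb$effective_k), drop = FALSE]
  test_labels <- if (config$grouping == "coarse")
    coarse_grouping(groups_v, config$extant_label) else groups_v
  perma <- stage("permanova",
    permanova(sc_eff, test_labels,
              n_permutations = config$n_permutations,
              seed = config$seed + 2002L))
  pw_size <- stage("pairwise_size",
    pairwise_size_position_tests(sc_eff, test_labels,
                                 metric = "sum_of_variances",
                                 n_resamples = config$n_resamples,
                                 seed = config$seed + 3003L))
  pw_pos <- stage("pairwise_position",
    pairwise_size_position_tests(sc_eff, test_labels,
                                 metric = "average_displacement",
                                 n_resamples = config$n_resamples,
                                 seed = config$seed + 4004L))
  log_("tests: permanova p = %.4g; size p = %s; position p = %s",
       perma$p_value,
       paste(signif(pw_size$table$p_bonferroni, 3), collapse = "/"),
       paste(signif(pw_pos$table$p_bonferroni, 3), collapse = "/"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("stylomorph")),
    seed = config$seed, n_specimens = length(outlines),
    group_sizes = as.list(table(groups_v)),
    n_points = config$n_points, n_harmonics = config$n_harmonics,
    normalization = "first-harmonic",
    effective_rule = config$effective_rule,
    effective_k = emb$effective_k,
    grouping = config$grouping,
    n_boot = config$n_boot, n_permutations = config$n_permutations,
    n_resamples = config$n_resamples)

  res <- structure(
    list(dataset = dataset, coefficients = coeffs, embedding = emb,
         disparity = disp, permanova = perma, pairwise_size = pw_size,
         pairwise_position = pw_pos, variance_report = vrep,
         manifest = manifest, config = config, paths = NULL),
    class = "pipeline_result")
  if (!is.null(out_dir)) res$paths <- write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$embedding)
  cat("  ", x$variance_report$message, "\n", sep = "")
  print(x$permanova)
  print(x$pairwise_size)
  print(x$pairwise_position)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(coefficients = file.path(out_dir, "coefficients.csv"),
             scores = file.path(out_dir, "scores.csv"),
             eigen = file.path(out_dir, "eigen_report.json"),
             disparity = file.path(out_dir, "disparity.csv"),
             tests = file.path(out_dir, "tests.json"),
             manifest = file.path(out_dir, "manifest.json"))
  emb <- res$embedding

  co <- do.call(rbind, lapply(seq_along(res$coefficients), function(i) {
    cf <- res$coefficients[[i]]
    data.frame(specimen_id = emb$specimen_ids[i],
               harmonic = seq_len(cf$n_harmonics),
               a = cf$a, b = cf$b, c = cf$c, d = cf$d,
               normalized = cf$normalized, size_scalar = cf$size_scalar)
  }))
  utils::write.csv(co, paths[["coefficients"]], row.names = FALSE)

  k <- emb$effective_k
  sc <- data.frame(specimen_id = emb$specimen_ids, group = emb$groups,
                   emb$scores[, seq_len(k), drop = FALSE])
  names(sc)[-(1:2)] <- paste0("PC", seq_len(k))
  utils::write.csv(sc, paths[["scores"]], row.names = FALSE)

  jsonlite::write_json(
    list(eigenvalues = emb$eigenvalues, proportions = emb$proportions,
         effective_k = k, effective_rule = emb$effective_rule,
         variance_report = res$variance_report[
           c("cumulative", "stated_total", "within_rounding")]),
    paths[["eigen"]], auto_unbox = TRUE, digits = NA)

  utils::write.csv(res$disparity, paths[["disparity"]], row.names = FALSE)

  jsonlite::write_json(
    list(grouping = res$config$grouping,
         permanova = res$permanova[c("pseudo_F", "p_value",
                                     "n_permutations", "exact", "seed")],
         pairwise_size = res$pairwise_size$table,
         pairwise_position = res$pairwise_position$table,
         untestable = res$pairwise_size$untestable),
    paths[["tests"]], auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(res$manifest, paths[["manifest"]], auto_unbox = TRUE)
  paths
}
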