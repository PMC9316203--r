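# Parametric generator of larval head + stylet outlines. The shape family
# is built to span the main axes of real owllion larval head variation:
# concavity of the posterior head rim, relative stylet length, and stylet
# thickness. One specimen = one closed contour (head capsule and stylets
# fused), since the harmonic analysis downstream requires a single closed
# curve.
#
# Construction (right half, midline = y axis, head occupying y in [0, L]):
#   - posterior rim: circular arc with signed sagitta
#     posterior_rim_curvature * head_width (negative = concave, the rim
#     indents anteriorly; positive = convex);
#   - lateral head margin: superellipse arc from the posterior corner to
#     the anterior shoulder;
#   - stylet: a tapered blade around a quadratic Bezier centerline rising
#     from the anterior rim, with optional cosmetic teeth on the inner
#     margin.
# The half is mirrored with mirror_half() and resampled at equal arc
# length, so every generated outline is closed, simple, counterclockwise
# and (noise-free) exactly bilaterally symmetric.

#' Shape parameters for one synthetic specimen
#'
#' @param head_length Head capsule length (length units, > 0).
#' @param head_width Head capsule width (> 0).
#' @param posterior_rim_curvature Signed, dimensionless. Negative values
#'   give a concave (anteriorly indented) posterior rim, positive a convex
#'   one; the rim's sagitta is `posterior_rim_curvature * head_width`.
#' @param stylet_rel_length Stylet length / head length, in (0.2, 3.0).
#' @param stylet_thickness Stylet maximum width / head width, in
#'   (0.01, 0.5).
#' @param stylet_curvature Signed, dimensionless; 0 = straight, positive =
#'   outward-curved blades.
#' @param tooth_count Integer >= 0; cosmetic bumps on the inner stylet
#'   margin.
#' @return Object of class `"shape_params"` (a validated named list).
#' @export
shape_params <- function(head_length = 1, head_width = 1,
                         posterior_rim_curvature = -0.1,
                         stylet_rel_length = 1.2,
                         stylet_thickness = 0.12,
                         stylet_curvature = 0.1,
                         tooth_count = 0L) {
  p <- list(head_length = head_length, head_width = head_width,
            posterior_rim_curvature = posterior_rim_curvature,
            stylet_rel_length = stylet_rel_length,
            stylet_thickness = stylet_thickness,
            stylet_curvature = stylet_curvature,
            tooth_count = as.integer(tooth_count))
  validate_shape_params(p)
  structure(p, class = "shape_params")
}

validate_shape_params <- function(p) {
  bad <- character()
  if (!isTRUE(p$head_length > 0)) bad <- c(bad, "head_length <= 0")
  if (!isTRUE(p$head_width > 0)) bad <- c(bad, "head_width <= 0")
  if (!isTRUE(p$stylet_rel_length > 0.2 && p$stylet_rel_length < 3.0))
    bad <- c(bad, "stylet_rel_length outside (0.2, 3.0)")
  if (!isTRUE(p$stylet_thickness > 0.01 && p$stylet_thickness < 0.5))
    bad <- c(bad, "stylet_thickness outside (0.01, 0.5)")
  if (!isTRUE(abs(p$posterior_rim_curvature) < 0.6))
    bad <- c(bad, "|posterior_rim_curvature| >= 0.6")
  if (!isTRUE(p$tooth_count >= 0L)) bad <- c(bad, "tooth_count < 0")
  if (length(bad))
    stop("invalid shape parameters: ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(p)
}

# parameter fields that receive Gaussian noise in generate_dataset()
shape_param_fields <- c("head_length", "head_width",
                        "posterior_rim_curvature", "stylet_rel_length",
                        "stylet_thickness", "stylet_curvature")

#' Generate the right half of a synthetic head + stylet outline
#'
#' Exposed mainly so the standardization steps ([straighten_stylet()],
#' [mirror_half()]) can be exercised on realistic halves; the returned
#' half outline carries stylet landmarks and the stylet index range.
#'
#' @param params A [shape_params()].
#' @return A [half_outline()] (right side), posterior midline point first.
#' @export
generate_half_outline <- function(params) {
  validate_shape_params(params)
  L <- params$head_length
  W <- params$head_width
  w <- W / 2
  s <- params$posterior_rim_curvature * W     # rim sagitta, apex y = -s
  S <- params$stylet_rel_length * L
  t0 <- params$stylet_thickness * W / 2
  q <- params$stylet_curvature

  x_in <- 0.08 * w
  x_out <- x_in + 2 * t0
  if (x_out > 0.92 * w)
    stop("stylet too thick for head width (stylet_thickness = ",
         signif(params$stylet_thickness, 3), ", head_width = ",
         signif(W, 3), ")", call. = FALSE)
  bx <- x_in + t0

  # posterior rim: circular arc (0, -s) -> (w, 0)
  n_rim <- 24L
  if (abs(s) < 1e-9 * W) {
    rim <- cbind(seq(0, w, length.out = n_rim), 0)
  } else {
    y0 <- (w^2 - s^2) / (2 * s)
    r <- abs(s + y0)
    th_a <- atan2(-s - y0, 0)
    th_b <- atan2(-y0, w)
    th <- seq(th_a, th_b, length.out = n_rim)
    rim <- cbind(r * cos(th), y0 + r * sin(th))
    rim[1L, ] <- c(0, -s); rim[n_rim, ] <- c(w, 0)
  }

  # stylet blade around a quadratic Bezier centerline
  b0 <- c(bx, L)
  b1 <- c(bx + 0.25 * q * S, L + 0.55 * S)
  b2 <- c(bx + 0.70 * q * S, L + S * (1 - 0.15 * q^2))
  n_sty <- if (params$tooth_count > 0L) 128L else 64L
  u <- seq(0, 1, length.out = n_sty)
  C <- cbind((1 - u)^2 * b0[1] + 2 * u * (1 - u) * b1[1] + u^2 * b2[1],
             (1 - u)^2 * b0[2] + 2 * u * (1 - u) * b1[2] + u^2 * b2[2])
  dC <- cbind(2 * (1 - u) * (b1[1] - b0[1]) + 2 * u * (b2[1] - b1[1]),
              2 * (1 - u) * (b1[2] - b0[2]) + 2 * u * (b2[2] - b1[2]))
  nrm <- cbind(dC[, 2], -dC[, 1]) / row_norms(dC)   # outward normal
  h <- t0 * (1 - u)^0.75
  outer_e <- C + nrm * h
  bump <- numeric(n_sty)
  if (params$tooth_count > 0L) {
    uj <- seq(0.45, 0.80, length.out = params$tooth_count)
    for (u0 in uj) bump <- bump + exp(-((u - u0) / 0.025)^2)
    bump <- 0.3 * t0 * bump
  }
  inner_e <- C - nrm * (h + bump)
  outer_base <- outer_e[1L, ]
  inner_base <- inner_e[1L, ]
  tip <- C[n_sty, , drop = FALSE]
  if (outer_base[2] < 0.4 * L || inner_base[1] < 0.02 * w ||
      outer_base[1] > 0.95 * w)
    stop("stylet base geometry invalid (stylet_curvature = ",
         signif(q, 3), ", stylet_thickness = ",
         signif(params$stylet_thickness, 3), ")", call. = FALSE)

  # lateral margin: superellipse from (w, 0) to the stylet's outer base
  n_lat <- 48L
  yb <- outer_base[2]
  yl <- seq(0, yb, length.out = n_lat + 1L)[-1L]
  pe <- 3
  xl <- outer_base[1] +
    (w - outer_base[1]) * pmax(0, 1 - (yl / yb)^pe)^(1 / pe)
  lateral <- cbind(xl, yl)
  lateral[n_lat, ] <- outer_base

  pts <- rbind(rim, lateral,
               outer_e[2:(n_sty - 1L), , drop = FALSE],
               tip,
               inner_e[(n_sty - 1L):1L, , drop = FALSE],
               c(0, L))
  # stylet: outer base (= last lateral point) through the inner base
  sty_start <- n_rim + n_lat
  sty_end <- n_rim + n_lat + 2L * (n_sty - 1L)      # inner base
  # landmarks on the inner margin: distal = first inner point after the
  # tip, proximal = inner base
  lm_distal <- n_rim + n_lat + n_sty
  lm_proximal <- sty_end
  half_outline(pts, side = "right",
               landmarks = list(proximal = lm_proximal, distal = lm_distal),
               stylet_range = sty_start:sty_end)
}

#' Generate one synthetic outline
#'
#' Builds the parametric half, mirrors it into a closed simple
#' counterclockwise contour, optionally jitters vertices, and resamples
#' at equal arc length starting from the anterior pole.
#'
#' @param params A [shape_params()].
#' @param n_points Number of equally spaced contour points (>= 64).
#' @param specimen_id,group Metadata for the returned [outline()].
#' @param jitter_sd Per-vertex Gaussian jitter, as a fraction of
#'   `head_width`; 0 (default) keeps the contour exactly bilaterally
#'   symmetric. Jitter draws from the current RNG stream.
#' @return An [outline()].
#' @export
generate_outline <- function(params, n_points = 512L,
                             specimen_id = "synthetic", group = NA_character_,
                             jitter_sd = 0) {
  half <- generate_half_outline(params)
  full <- tryCatch(
    mirror_half(half, specimen_id = specimen_id, group = group),
    error = function(e) {
      stop("parameter combination yields an invalid contour (",
           conditionMessage(e), "); offending parameters: ",
           paste(sprintf("%s=%.4g", shape_param_fields,
                         as.numeric(params[shape_param_fields])),
                 collapse = ", "),
           call. = FALSE)
    })
  if (jitter_sd > 0) {
    p <- full$points
    p <- p + matrix(stats::rnorm(length(p), sd = jitter_sd * params$head_width),
                    ncol = 2)
    full <- outline(p, specimen_id = specimen_id, group = group,
                    provenance = c(full$provenance, "vertex-jitter"))
  }
  resample_equal_arclength(full, m = n_points)
}

#' Specification of one synthetic group
#'
#' @param name Group label (unique within a dataset).
#' @param n Number of specimens (>= 1).
#' @param mean_params A [shape_params()] giving the group mean.
#' @param dispersion Named numeric vector of per-parameter standard
#'   deviations (entries >= 0); names among
#'   `head_length, head_width, posterior_rim_curvature,
#'   stylet_rel_length, stylet_thickness, stylet_curvature`. Missing
#'   entries default to 0.
#' @param seed_offset Integer added to the dataset seed for this group,
#'   so a group's draws do not depend on which other groups are present.
#' @return Object of class `"group_spec"`.
#' @export
group_spec <- function(name, n, mean_params, dispersion = numeric(),
                       seed_offset = 0L) {
  stopifnot(is.character(name), length(name) == 1L, n >= 1L)
  validate_shape_params(mean_params)
  disp <- stats::setNames(numeric(length(shape_param_fields)),
                          shape_param_fields)
  if (length(dispersion)) {
    unknown <- setdiff(names(dispersion), shape_param_fields)
    if (length(unknown))
      stop("unknown dispersion entries: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(dispersion < 0)) stop("dispersion entries must be >= 0",
                                  call. = FALSE)
    disp[names(dispersion)] <- dispersion
  }
  structure(list(name = name, n = as.integer(n), mean_params = mean_params,
                 dispersion = disp, seed_offset = as.integer(seed_offset)),
            class = "group_spec")
}

#' Default study-shaped group configuration
#'
#' Four labelled groups emulating a fossil-versus-extant larval dataset:
#' 243 extant, 46 Cretaceous, 9 Miocene and 2 Eocene specimens. Group
#' structure is expressed through three dominant shape factors —
#' posterior-rim concavity, relative stylet length and stylet thickness.
#' The extant group has twice the parameter dispersion of the fossil
#' groups (the extant fauna occupies the largest morphospace), and the
#' Cretaceous group is offset toward thicker stylets.
#'
#' @param extant_dispersion_scale Multiplier on the extant group's
#'   dispersion vector (default 1 = the standard design).
#' @return List of [group_spec()] objects.
#' @export
study_group_specs <- function(extant_dispersion_scale = 1) {
  base_disp <- c(head_width = 0.003,
                 posterior_rim_curvature = 0.042,
                 stylet_rel_length = 0.040,
                 stylet_thickness = 0.014,
                 stylet_curvature = 0.0026)
  extant_disp <- base_disp * 2 * extant_dispersion_scale
  extant_mean <- shape_params(head_length = 1, head_width = 0.95,
                              posterior_rim_curvature = -0.10,
                              stylet_rel_length = 1.30,
                              stylet_thickness = 0.11,
                              stylet_curvature = 0.12,
                              tooth_count = 2L)
  cret_mean <- shape_params(head_length = 1, head_width = 0.95,
                            posterior_rim_curvature = -0.04,
                            stylet_rel_length = 1.25,
                            stylet_thickness = 0.155,
                            stylet_curvature = 0.12,
                            tooth_count = 2L)
  mio_mean <- shape_params(head_length = 1, head_width = 0.95,
                           posterior_rim_curvature = -0.12,
                           stylet_rel_length = 1.35,
                           stylet_thickness = 0.11,
                           stylet_curvature = 0.12,
                           tooth_count = 2L)
  eoc_mean <- shape_params(head_length = 1, head_width = 0.95,
                           posterior_rim_curvature = -0.08,
                           stylet_rel_length = 1.15,
                           stylet_thickness = 0.10,
                           stylet_curvature = 0.12,
                           tooth_count = 2L)
  list(group_spec("extant", 243L, extant_mean, extant_disp, seed_offset = 0L),
       group_spec("Cretaceous", 46L, cret_mean, base_disp, seed_offset = 101L),
       group_spec("Miocene", 9L, mio_mean, base_disp, seed_offset = 202L),
       group_spec("Eocene", 2L, eoc_mean, base_disp, seed_offset = 303L))
}

#' Generate a labelled synthetic dataset
#'
#' Draws per-specimen shape parameters as group mean + Gaussian(0,
#' dispersion), regenerating any draw whose parameters or contour are
#' invalid (up to `retry_cap` attempts per specimen). Each group uses its
#' own RNG stream seeded from `seed + seed_offset`, so datasets are
#' reproducible and a group's specimens do not depend on the other groups.
#'
#' @param groups List of [group_spec()]; names must be unique.
#' @param n_points Contour points per outline.
#' @param seed Integer seed.
#' @param jitter_sd Optional per-vertex jitter (fraction of head width).
#' @param retry_cap Maximum redraws per specimen before erroring.
#' @return Object of class `"synthetic_dataset"`: a list with `outlines`
#'   (list of [outline()]), `truth` (data frame of drawn parameters),
#'   `config` (the group specs) and `seed`.
#' @examples
#' ds <- generate_dataset(study_group_specs(), n_points = 256, seed = 1)
#' table(vapply(ds$outlines, function(o) o$group, ""))
#' @export
generate_dataset <- function(groups = study_group_specs(), n_points = 512L,
                             seed = 1L, jitter_sd = 0, retry_cap = 100L) {
  nms <- vapply(groups, function(g) g$name, "")
  if (anyDuplicated(nms)) stop("group names must be unique", call. = FALSE)
  outlines <- list()
  truth <- list()
  for (g in groups) {
    set.seed((as.integer(seed) + g$seed_offset) %% .Machine$integer.max)
    for (i in seq_len(g$n)) {
      sid <- sprintf("%s_%03d", g$name, i)
      ok <- FALSE
      for (attempt in seq_len(retry_cap)) {
        draw <- as.numeric(g$mean_params[shape_param_fields]) +
          stats::rnorm(length(shape_param_fields)) * g$dispersion
        names(draw) <- shape_param_fields
        res <- tryCatch({
          pars <- do.call(shape_params,
                          c(as.list(draw),
                            list(tooth_count = g$mean_params$tooth_count)))
          generate_outline(pars, n_points = n_points, specimen_id = sid,
                           group = g$name, jitter_sd = jitter_sd)
        }, error = function(e) e)
        if (!inherits(res, "error")) {
          outlines[[sid]] <- res
          truth[[sid]] <- c(list(specimen_id = sid, group = g$name),
                            as.list(draw),
                            list(tooth_count = g$mean_params$tooth_count))
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("group '", g$name, "', specimen ", i, ": no valid outline in ",
             retry_cap, " attempts", call. = FALSE)
    }
  }
  structure(list(outlines = unname(outlines),
                 truth = do.call(rbind.data.frame,
                                 c(truth, list(stringsAsFactors = FALSE))),
                 config = groups, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  grp <- vapply(x$outlines, function(o) o$group, "")
  cat(sprintf("<synthetic_dataset> %d outlines, seed %d\n",
              length(x$outlines), x$seed))
  print(table(grp))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits a long-format outline CSV (`specimen_id, point_index, x, y`), a
#' labels CSV (`specimen_id, group`), the group configuration as JSON and
#' a manifest recording the seed.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(outlines = file.path(dir, "outlines.csv"),
             labels = file.path(dir, "labels.csv"),
             config = file.path(dir, "config.json"),
             manifest = file.path(dir, "manifest.json"))
  write_outlines(dataset$outlines, paths[["outlines"]], format = "xy_csv")
  labs <- data.frame(
    specimen_id = vapply(dataset$outlines, function(o) o$specimen_id, ""),
    group = vapply(dataset$outlines, function(o) o$group, ""))
  utils::write.csv(labs, paths[["labels"]], row.names = FALSE)
  cfg <- lapply(dataset$config, function(g)
    list(name = g$name, n = g$n,
         mean_params = unclass(g$mean_params),
         dispersion = as.list(g$dispersion),
         seed_offset = g$seed_offset))
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = dataset$seed,
                            n_outlines = length(dataset$outlines)),
                       paths[["manifest"]], auto_unbox = TRUE)
  invisible(paths)
}
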