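# Outline standardization: stylet straightening, half-mirroring and equal
# arc-length resampling. Convention: after orientation the
# anterior-posterior midline is the y-axis and y increases toward the
# stylets (head "up").

#' Construct a half outline
#'
#' An open polyline along one body side, running from the posterior
#' midline point to the anterior midline point. Both endpoints must lie
#' on the midline (x = 0 within tolerance). The stylet is a contiguous
#' index range of the polyline; two landmarks on its inner margin — the
#' innermost proximal point (articulation end) and the innermost distal
#' point (near the tip) — define its axis for straightening.
#'
#' @param points Two-column coordinate matrix, posterior midline point
#'   first, anterior midline point last.
#' @param side `"left"` or `"right"`.
#' @param landmarks Named integer vector or list with entries `proximal`
#'   and `distal`: row indices of the stylet's innermost proximal and
#'   innermost distal points. Optional if only mirroring is needed.
#' @param stylet_range Integer vector of contiguous row indices making up
#'   the stylet blade (outer margin, tip, inner margin). Must contain both
#'   landmarks. Required by [straighten_stylet()]; explicit indices always
#'   override any auto-detection done upstream.
#' @param midline_tol Absolute tolerance for the endpoint-on-midline check;
#'   default scales with the polyline extent.
#' @return Object of class `"half_outline"`.
#' @export
half_outline <- function(points, side = c("right", "left"),
                         landmarks = NULL, stylet_range = NULL,
                         midline_tol = NULL) {
  side <- match.arg(side)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L || nrow(points) < 4L)
    stop("half outline needs a two-column matrix with >= 4 points",
         call. = FALSE)
  span <- max(diff(range(points[, 1])), diff(range(points[, 2])))
  if (is.null(midline_tol)) midline_tol <- 1e-8 * max(span, 1e-300)
  n <- nrow(points)
  if (abs(points[1L, 1]) > midline_tol || abs(points[n, 1]) > midline_tol)
    stop("half outline endpoints must lie on the midline (|x| < tol)",
         call. = FALSE)
  if (!is.null(landmarks)) {
    landmarks <- as.list(landmarks)
    if (!all(c("proximal", "distal") %in% names(landmarks)))
      stop("`landmarks` needs entries 'proximal' and 'distal'", call. = FALSE)
    lp <- as.integer(landmarks$proximal); ld <- as.integer(landmarks$distal)
    if (lp < 1L || lp > n || ld < 1L || ld > n || lp == ld)
      stop("invalid landmark indices", call. = FALSE)
    landmarks <- list(proximal = lp, distal = ld)
  }
  if (!is.null(stylet_range)) {
    stylet_range <- as.integer(stylet_range)
    if (any(diff(stylet_range) != 1L))
      stop("`stylet_range` must be contiguous indices", call. = FALSE)
    if (min(stylet_range) < 1L || max(stylet_range) > n)
      stop("`stylet_range` out of bounds", call. = FALSE)
    if (!is.null(landmarks) &&
        !all(unlist(landmarks) %in% stylet_range))
      stop("`stylet_range` must contain both landmarks", call. = FALSE)
  }
  structure(list(points = unname(points), side = side,
                 landmarks = landmarks, stylet_range = stylet_range),
            class = "half_outline")
}

#' @export
print.half_outline <- function(x, ...) {
  cat(sprintf("<half_outline> side=%s  %d points", x$side, nrow(x$points)))
  if (!is.null(x$landmarks))
    cat(sprintf("  landmarks: proximal=%d distal=%d",
                x$landmarks$proximal, x$landmarks$distal))
  cat("\n")
  invisible(x)
}

#' Straighten the stylet of a half outline
#'
#' Rigidly rotates the stylet sub-polyline about the innermost proximal
#' landmark so that the proximal-to-distal landmark segment becomes
#' parallel to the anterior-posterior midline, with the distal landmark
#' anterior (larger y). All points outside the stylet range are left
#' untouched; the rotation is an isometry, so stylet arc length and all
#' pairwise distances within the stylet are preserved.
#'
#' @param half A [half_outline()] with `landmarks` and `stylet_range` set.
#' @return A new `half_outline` with the stylet straightened.
#' @export
straighten_stylet <- function(half) {
  stopifnot(inherits(half, "half_outline"))
  if (is.null(half$landmarks))
    stop("straighten_stylet: half outline has no landmarks", call. = FALSE)
  if (is.null(half$stylet_range))
    stop("straighten_stylet: half outline has no stylet_range", call. = FALSE)
  p <- half$points
  prox <- p[half$landmarks$proximal, ]
  dist_ <- p[half$landmarks$distal, ]
  v <- dist_ - prox
  len <- sqrt(sum(v^2))
  span <- max(diff(range(p[, 1])), diff(range(p[, 2])), 1e-300)
  if (len < 1e-12 * span)
    stop("straighten_stylet: coincident landmarks", call. = FALSE)
  # counterclockwise rotation taking the landmark axis onto the +y
  # midline direction
  ang <- atan2(v[1], v[2])
  idx <- half$stylet_range
  p[idx, ] <- rotate_points(p[idx, , drop = FALSE], ang, centre = prox)
  out <- half
  out$points <- p
  out
}

#' Mirror a half outline into a full closed outline
#'
#' Reflects the half across the midline (x = 0), appends the reflected
#' points in reverse traversal order, drops the duplicated midline
#' endpoints, and returns a closed, counterclockwise, mirror-symmetric
#' outline. With both endpoints on the midline the result has
#' `2 * (n_half - 2) + 2` points.
#'
#' @param half A [half_outline()].
#' @param specimen_id,group Metadata passed to [outline()].
#' @param check_simple If `TRUE` (default), error when the reflection
#'   produces a self-intersecting contour, naming the first crossing
#'   segment pair.
#' @return An [outline()].
#' @export
mirror_half <- function(half, specimen_id = "unnamed", group = NA_character_,
                        check_simple = TRUE) {
  stopifnot(inherits(half, "half_outline"))
  p <- half$points
  n <- nrow(p)
  # pin endpoints exactly onto the midline so the closure is exact
  p[c(1L, n), 1] <- 0
  refl <- cbind(-p[, 1], p[, 2])
  full <- rbind(p, refl[(n - 1L):2L, , drop = FALSE])
  outline(full, specimen_id = specimen_id, group = group,
          provenance = sprintf("mirrored-%s-half", half$side),
          check_simple = check_simple)
}

#' Resample an outline at equal arc-length spacing
#'
#' Returns `m` points equally spaced in arc length along the polygon,
#' starting at the anterior pole: the intersection of the outline with
#' the midline (x = 0) that has the largest y. Traversal direction
#' (counterclockwise) is preserved, as is the perimeter up to chord
#' shortening.
#'
#' @param x An [outline()] or a two-column coordinate matrix.
#' @param m Number of output points (>= 64 for downstream harmonic
#'   analysis; smaller values are refused).
#' @return An [outline()] with `m` points.
#' @export
resample_equal_arclength <- function(x, m = 512L) {
  if (inherits(x, "outline")) {
    p <- x$points
    sid <- x$specimen_id; grp <- x$group
    prov <- c(x$provenance, sprintf("resampled-m%d", m))
  } else {
    p <- as.matrix(x)
    sid <- "unnamed"; grp <- NA_character_
    prov <- sprintf("resampled-m%d", m)
  }
  m <- as.integer(m)
  if (m < 64L) stop("resample_equal_arclength: m must be >= 64", call. = FALSE)
  per <- perimeter(p)
  if (!is.finite(per) || per <= 0)
    stop("resample_equal_arclength: degenerate outline", call. = FALSE)

  # iterate the equal-arc pass to its equal-chord fixed point so that
  # the operation is idempotent: once consecutive spacing is uniform,
  # another pass lands on the same vertices
  q <- equal_arc_pass(p, m)
  for (iter in seq_len(400L)) {
    d <- q - q[c(2:m, 1L), , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    if (diff(range(len)) < 1e-8 * mean(len)) break
    q <- equal_arc_pass(q, m)
  }
  outline(q, specimen_id = sid, group = grp, provenance = prov)
}

# one pass of equal arc-length sampling along the polygon, starting at
# the anterior pole
equal_arc_pass <- function(p, m) {
  start <- anterior_pole(p)
  p <- start$points       # polygon with the pole inserted as a vertex
  k <- start$index        # index of the pole vertex
  n <- nrow(p)
  p <- p[c(k:n, seq_len(k - 1L)), , drop = FALSE]  # rotate pole to front

  seg <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE]) - p
  len <- sqrt(rowSums(seg^2))
  cs <- c(0, cumsum(len))
  total <- cs[length(cs)]
  s <- total * (seq_len(m) - 1L) / m
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx[idx > n] <- n
  frac <- (s - cs[idx]) / len[idx]
  frac[!is.finite(frac)] <- 0
  p[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
}

# locate the anterior pole (midline crossing with max y); returns the
# polygon with the crossing inserted as an exact-x=0 vertex and its index
anterior_pole <- function(p) {
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  span <- max(diff(range(x)), diff(range(y)), 1e-300)
  tol <- 1e-9 * span

  best_y <- -Inf; best <- NULL   # list(insert_after, point) or vertex index
  on_axis <- which(abs(x) <= tol)
  if (length(on_axis)) {
    i <- on_axis[which.max(y[on_axis])]
    best_y <- y[i]; best <- list(vertex = i)
  }
  crossing <- which((x < -tol & xn > tol) | (x > tol & xn < -tol))
  for (i in crossing) {
    t <- x[i] / (x[i] - xn[i])
    yc <- y[i] + t * (yn[i] - y[i])
    if (yc > best_y + tol) {
      best_y <- yc; best <- list(after = i, point = c(0, yc))
    }
  }
  if (is.null(best))
    stop("outline does not intersect the midline (x = 0); orient it first",
         call. = FALSE)
  if (!is.null(best$vertex)) {
    q <- p
    q[best$vertex, 1] <- 0
    list(points = q, index = best$vertex)
  } else {
    i <- best$after
    q <- rbind(p[seq_len(i), , drop = FALSE],
               best$point,
               if (i < n) p[(i + 1L):n, , drop = FALSE])
    list(points = q, index = i + 1L)
  }
}

#' Auto-detect stylet landmarks on a canonical half outline
#'
#' For a half outline already oriented head-up (stylet anterior, midline
#' at x = 0), finds the innermost distal and innermost proximal points of
#' the stylet as extrema along its inner margin: among stylet points, the
#' inner margin is the x-minimal side; the proximal landmark is its
#' posterior end and the distal landmark its anterior end. Ties are broken
#' toward the more distal (larger y) candidate. Intended as a convenience;
#' explicit indices always override.
#'
#' @param half A [half_outline()] with `stylet_range` set.
#' @return The half outline with `landmarks` filled in.
#' @export
detect_stylet_landmarks <- function(half) {
  stopifnot(inherits(half, "half_outline"))
  if (is.null(half$stylet_range))
    stop("detect_stylet_landmarks: stylet_range required", call. = FALSE)
  idx <- half$stylet_range
  p <- half$points[idx, , drop = FALSE]
  # inner margin: from the tip (max y) to the end of the range
  tip <- which.max(p[, 2])
  inner <- seq(tip, nrow(p))
  if (length(inner) < 2L)
    stop("detect_stylet_landmarks: stylet range has no inner margin",
         call. = FALSE)
  yin <- p[inner, 2]
  di <- inner[order(-yin, inner)[1L]]                 # most anterior
  pi_ <- inner[order(yin, -inner)[1L]]                # most posterior
  if (di == pi_) stop("detect_stylet_landmarks: degenerate stylet",
                      call. = FALSE)
  half$landmarks <- list(proximal = idx[pi_], distal = idx[di])
  half
}
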