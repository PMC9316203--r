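# Closed-outline container and basic polygon geometry used throughout the
# package. An outline is one specimen's digitized head + stylet contour:
# an implicitly closed polygon (last point != first point) stored
# counterclockwise.

#' Construct a closed outline
#'
#' An `outline` is the unit record of the pipeline: one specimen's closed
#' 2D contour plus metadata. The constructor validates and canonicalizes
#' the polygon: consecutive duplicate points are dropped, the closing
#' duplicate (first point repeated at the end) is removed, and clockwise
#' input is silently reversed to counterclockwise with a provenance note.
#'
#' @param points Two-column numeric matrix (or data frame) of x, y
#'   coordinates, ordered along the contour. Closure is implicit: the last
#'   point must not repeat the first.
#' @param specimen_id Character scalar identifying the specimen.
#' @param group Group label (e.g. `"extant"`, `"Cretaceous"`).
#' @param provenance Character vector of free-text processing notes.
#' @param check_simple If `TRUE`, verify the polygon is simple
#'   (non-self-intersecting) and error otherwise.
#' @return An object of class `"outline"` with fields `specimen_id`,
#'   `group`, `points` (counterclockwise matrix) and `provenance`.
#' @examples
#' sq <- outline(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)), "sq")
#' signed_area(sq$points)  # +1: reversed to counterclockwise
#' @export
outline <- function(points, specimen_id = "unnamed", group = NA_character_,
                    provenance = character(), check_simple = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("`points` must have two columns (x, y)", call. = FALSE)
  storage.mode(points) <- "double"
  if (anyNA(points) || any(!is.finite(points)))
    stop("outline '", specimen_id, "': non-finite coordinates", call. = FALSE)
  points <- drop_duplicate_points(points)
  if (nrow(points) < 3L)
    stop("outline '", specimen_id, "': fewer than 3 distinct points",
         call. = FALSE)
  a <- signed_area(points)
  scale2 <- max(apply(points, 2, function(v) diff(range(v))))^2
  if (abs(a) < 1e-12 * max(scale2, 1e-300))
    stop("outline '", specimen_id, "': degenerate (zero signed area)",
         call. = FALSE)
  if (a < 0) {
    points <- points[nrow(points):1L, , drop = FALSE]
    provenance <- c(provenance, "reversed-to-ccw")
  }
  if (check_simple) {
    cross <- polygon_first_crossing(points)
    if (!is.null(cross))
      stop("outline '", specimen_id, "': self-intersection between segments ",
           cross[1], " and ", cross[2], call. = FALSE)
  }
  structure(
    list(specimen_id = as.character(specimen_id),
         group = as.character(group),
         points = unname(points),
         provenance = provenance),
    class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %s  group=%s  %d points  perimeter=%.4g  area=%.4g\n",
              x$specimen_id, x$group, nrow(x$points),
              perimeter(x$points), signed_area(x$points)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

# drop consecutive (near-)duplicate vertices and the closing repeat
drop_duplicate_points <- function(p, tol = NULL) {
  n <- nrow(p)
  if (n < 2L) return(p)
  if (is.null(tol)) {
    span <- max(diff(range(p[, 1])), diff(range(p[, 2])), 1e-300)
    tol <- 1e-12 * span
  }
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  p <- p[c(TRUE, d > tol), , drop = FALSE]
  n <- nrow(p)
  if (n > 1L && sqrt(sum((p[1L, ] - p[n, ])^2)) <= tol)
    p <- p[-n, , drop = FALSE]
  p
}

#' Signed area of a polygon
#'
#' Shoelace formula; positive for counterclockwise traversal.
#' @param p Two-column coordinate matrix (implicitly closed).
#' @return Numeric scalar.
#' @export
signed_area <- function(p) {
  p <- as.matrix(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a closed polygon
#' @param p Two-column coordinate matrix (implicitly closed).
#' @return Numeric scalar.
#' @export
perimeter <- function(p) {
  p <- as.matrix(p)
  d <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE]) - p
  sum(sqrt(rowSums(d^2)))
}

#' Test whether a closed polygon is simple
#'
#' Checks all non-adjacent segment pairs for crossings, with a
#' bounding-box prefilter. Touching or overlapping collinear segments
#' count as non-simple.
#' @param p Two-column coordinate matrix (implicitly closed).
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(p) {
  is.null(polygon_first_crossing(p))
}

# first pair of crossing segment indices, or NULL if simple
polygon_first_crossing <- function(p) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n < 4L) return(NULL)
  ax <- p[, 1]; ay <- p[, 2]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  span <- max(diff(range(ax)), diff(range(ay)), 1e-300)
  eps <- 1e-10 * span^2

  lo_x <- pmin(ax, bx); hi_x <- pmax(ax, bx)
  lo_y <- pmin(ay, by); hi_y <- pmax(ay, by)

  # all pairs i < j with j - i > 1, excluding the closing pair (1, n)
  i <- rep.int(seq_len(n - 2L), pmax(n - seq_len(n - 2L) - 1L, 0L))
  j <- sequence(pmax(n - seq_len(n - 2L) - 1L, 0L),
                from = seq_len(n - 2L) + 2L)
  drop1 <- i == 1L & j == n
  if (any(drop1)) { i <- i[!drop1]; j <- j[!drop1] }
  # bounding-box prefilter
  bb <- lo_x[i] <= hi_x[j] & lo_x[j] <= hi_x[i] &
        lo_y[i] <= hi_y[j] & lo_y[j] <= hi_y[i]
  i <- i[bb]; j <- j[bb]
  if (!length(i)) return(NULL)

  d1 <- (bx[i] - ax[i]) * (ay[j] - ay[i]) - (by[i] - ay[i]) * (ax[j] - ax[i])
  d2 <- (bx[i] - ax[i]) * (by[j] - ay[i]) - (by[i] - ay[i]) * (bx[j] - ax[i])
  d3 <- (bx[j] - ax[j]) * (ay[i] - ay[j]) - (by[j] - ay[j]) * (ax[i] - ax[j])
  d4 <- (bx[j] - ax[j]) * (by[i] - ay[j]) - (by[j] - ay[j]) * (bx[i] - ax[j])

  proper <- ((d1 > eps & d2 < -eps) | (d1 < -eps & d2 > eps)) &
            ((d3 > eps & d4 < -eps) | (d3 < -eps & d4 > eps))
  if (any(proper)) {
    k <- which(proper)[1L]
    return(c(i[k], j[k]))
  }
  # collinear / touching candidates: all four determinants near zero
  col <- abs(d1) <= eps & abs(d2) <= eps & abs(d3) <= eps & abs(d4) <= eps
  if (any(col)) {
    for (k in which(col)) {
      ii <- i[k]; jj <- j[k]
      # project onto the segment's dominant axis and test interval overlap
      if (hi_x[ii] - lo_x[ii] >= hi_y[ii] - lo_y[ii]) {
        ov <- min(hi_x[ii], hi_x[jj]) - max(lo_x[ii], lo_x[jj])
      } else {
        ov <- min(hi_y[ii], hi_y[jj]) - max(lo_y[ii], lo_y[jj])
      }
      if (ov > 1e-9 * span) return(c(ii, jj))
    }
  }
  NULL
}

# rotate a two-column matrix by angle (radians, counterclockwise)
rotate_points <- function(p, angle, centre = c(0, 0)) {
  co <- cos(angle); si <- sin(angle)
  px <- p[, 1] - centre[1]; py <- p[, 2] - centre[2]
  cbind(centre[1] + co * px - si * py,
        centre[2] + si * px + co * py)
}

row_norms <- function(m) sqrt(rowSums(m^2))
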