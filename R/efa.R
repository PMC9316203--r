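# Clean-room elliptic Fourier analysis of closed polygonal outlines.
#
# The contour (x(t), y(t)), parameterized by arc length t over one
# traversal of perimeter T, is expanded as
#   x(t) = A0 + sum_n  a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T)
#   y(t) = C0 + sum_n  c_n cos(2 pi n t / T) + d_n sin(2 pi n t / T).
# For a polygon the speed dx/dt, dy/dt is piecewise constant, so every
# coefficient has an exact closed form (the classical piecewise-linear
# result); no FFT or truncation approximations are involved.
#
# Normalization follows the first-harmonic procedure: phase-shift the
# parameter so t = 0 sits at the first-harmonic ellipse's semi-major
# axis, rotate so that axis lies along +x, and divide by its length.
# After normalization a1 = 1 and b1 = c1 = 0; d1 (the signed first-
# harmonic aspect ratio) and all higher harmonics carry the shape.

#' Elliptic Fourier coefficients of a closed outline
#'
#' Computes the exact per-harmonic coefficients of the piecewise-linear
#' contour. Coefficients are returned unnormalized; see
#' [efa_normalize()].
#'
#' @param x An [outline()] or a two-column coordinate matrix (implicitly
#'   closed).
#' @param n_harmonics Number of harmonics (>= 1, at most half the number
#'   of contour points).
#' @return Object of class `"efa_coef"`: list with vectors `a`, `b`,
#'   `c`, `d` (length `n_harmonics`), centroid offsets `A0`, `C0`,
#'   `n_harmonics`, `normalized` flag and `size_scalar` (1 until
#'   normalization).
#' @examples
#' th <- 2 * pi * (0:255) / 256
#' ef <- compute_efa(cbind(cos(th), sin(th)), 8)
#' round(ef$a[1], 6); round(ef$d[1], 6)  # ~1, ~1 for the unit circle
#' @export
compute_efa <- function(x, n_harmonics = 20L) {
  p <- if (inherits(x, "outline")) x$points else as.matrix(x)
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1", call. = FALSE)
  if (n_harmonics > nrow(p) / 2)
    stop("n_harmonics (", n_harmonics, ") exceeds n_points/2 (",
         nrow(p) / 2, "): harmonics would alias", call. = FALSE)
  p <- drop_duplicate_points(p)
  K <- nrow(p)
  dx <- c(p[-1L, 1], p[1L, 1]) - p[, 1]
  dy <- c(p[-1L, 2], p[1L, 2]) - p[, 2]
  dt <- sqrt(dx^2 + dy^2)
  T <- sum(dt)
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-K])

  n <- seq_len(n_harmonics)
  w <- 2 * pi / T
  ang1 <- outer(t1, n) * w
  ang0 <- outer(t0, n) * w
  dcos <- cos(ang1) - cos(ang0)
  dsin <- sin(ang1) - sin(ang0)
  const <- T / (2 * pi^2 * n^2)
  vx <- dx / dt
  vy <- dy / dt
  a <- const * colSums(vx * dcos)
  b <- const * colSums(vx * dsin)
  cc <- const * colSums(vy * dcos)
  d <- const * colSums(vy * dsin)

  # DC terms: exact integral of the piecewise-linear x(t), y(t)
  xm <- (p[, 1] + c(p[-1L, 1], p[1L, 1])) / 2
  ym <- (p[, 2] + c(p[-1L, 2], p[1L, 2])) / 2
  A0 <- sum(dt * xm) / T
  C0 <- sum(dt * ym) / T

  structure(list(a = a, b = b, c = cc, d = d, A0 = A0, C0 = C0,
                 n_harmonics = n_harmonics, normalized = FALSE,
                 size_scalar = 1),
            class = "efa_coef")
}

#' @export
print.efa_coef <- function(x, ...) {
  cat(sprintf("<efa_coef> %d harmonics, %s  size_scalar=%.4g\n",
              x$n_harmonics,
              if (x$normalized) "normalized" else "raw",
              x$size_scalar))
  invisible(x)
}

#' Normalize elliptic Fourier coefficients
#'
#' First-harmonic normalization: removes translation (drops the DC
#' terms), starting point (phase shift to the first-harmonic semi-major
#' axis), rotation (aligns that axis with +x) and size (divides by the
#' semi-major axis length, stored as `size_scalar`). The 180-degree
#' phase/rotation ambiguity is resolved by requiring `a1 > 0` and making
#' the first even-harmonic coefficient of magnitude above 1e-7 positive
#' (the first harmonic itself, including `d1`, is unchanged by the
#' ambiguity, so it cannot discriminate).
#'
#' @param coeffs An unnormalized [compute_efa()] result.
#' @return A normalized `efa_coef` (`a[1] = 1`, `b[1] = c[1] = 0`,
#'   `A0 = C0 = 0`).
#' @export
efa_normalize <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa_coef"))
  if (coeffs$normalized)
    stop("coefficients are already normalized", call. = FALSE)
  a1 <- coeffs$a[1]; b1 <- coeffs$b[1]
  c1 <- coeffs$c[1]; d1 <- coeffs$d[1]
  mag <- a1^2 + b1^2 + c1^2 + d1^2
  if (mag < 1e-24)
    stop("degenerate first harmonic: cannot normalize", call. = FALSE)

  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  # the half-angle solution can pick the minor axis; take the candidate
  # with the larger first-harmonic amplitude at t = 0
  amp_at <- function(th) {
    (a1 * cos(th) + b1 * sin(th))^2 + (c1 * cos(th) + d1 * sin(th))^2
  }
  if (amp_at(theta + pi / 2) > amp_at(theta)) theta <- theta + pi / 2

  shifted <- apply_phase(coeffs, theta)
  psi <- atan2(shifted$c[1], shifted$a[1])
  rot <- apply_rotation(shifted, -psi)
  E <- rot$a[1]
  out <- rot
  out$a <- rot$a / E; out$b <- rot$b / E
  out$c <- rot$c / E; out$d <- rot$d / E

  # 180-degree ambiguity: theta + pi flips the sign of all even-harmonic
  # coefficients and leaves odd harmonics (incl. harmonic 1) unchanged;
  # canonicalize by the first significant even-harmonic entry
  ev <- seq(2L, out$n_harmonics, by = 2L)
  if (length(ev)) {
    flat <- as.vector(rbind(out$a[ev], out$b[ev], out$c[ev], out$d[ev]))
    k <- which(abs(flat) > 1e-7)
    if (length(k) && flat[k[1L]] < 0) {
      out$a[ev] <- -out$a[ev]; out$b[ev] <- -out$b[ev]
      out$c[ev] <- -out$c[ev]; out$d[ev] <- -out$d[ev]
    }
  }
  out$A0 <- 0; out$C0 <- 0
  out$normalized <- TRUE
  out$size_scalar <- E
  out
}

# reparameterize t -> t + theta * T / (2 pi): harmonic n is multiplied on
# the right by a rotation through n * theta
apply_phase <- function(coeffs, theta) {
  n <- seq_len(coeffs$n_harmonics)
  cn <- cos(n * theta); sn <- sin(n * theta)
  out <- coeffs
  out$a <- coeffs$a * cn + coeffs$b * sn
  out$b <- -coeffs$a * sn + coeffs$b * cn
  out$c <- coeffs$c * cn + coeffs$d * sn
  out$d <- -coeffs$c * sn + coeffs$d * cn
  out
}

# rotate the curve in the plane by angle psi (left multiplication)
apply_rotation <- function(coeffs, psi) {
  co <- cos(psi); si <- sin(psi)
  out <- coeffs
  out$a <- co * coeffs$a - si * coeffs$c
  out$c <- si * coeffs$a + co * coeffs$c
  out$b <- co * coeffs$b - si * coeffs$d
  out$d <- si * coeffs$b + co * coeffs$d
  A0 <- coeffs$A0; C0 <- coeffs$C0
  out$A0 <- co * A0 - si * C0
  out$C0 <- si * A0 + co * C0
  out
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Evaluates the truncated inverse Fourier sum at `n_points` equally
#' spaced parameter values.
#'
#' @param coeffs An `efa_coef`.
#' @param n_points Number of points to evaluate.
#' @param k Number of harmonics to use (`1 <= k <= n_harmonics`).
#' @return An [outline()].
#' @export
efa_reconstruct <- function(coeffs, n_points = 256L, k = coeffs$n_harmonics) {
  stopifnot(inherits(coeffs, "efa_coef"))
  k <- as.integer(k)
  if (k < 1L || k > coeffs$n_harmonics)
    stop("k must be in 1..n_harmonics", call. = FALSE)
  t <- (seq_len(n_points) - 1L) / n_points
  n <- seq_len(k)
  ang <- outer(t, n) * (2 * pi)
  cosm <- cos(ang); sinm <- sin(ang)
  x <- coeffs$A0 + cosm %*% coeffs$a[n] + sinm %*% coeffs$b[n]
  y <- coeffs$C0 + cosm %*% coeffs$c[n] + sinm %*% coeffs$d[n]
  outline(cbind(as.vector(x), as.vector(y)),
          specimen_id = "reconstruction",
          provenance = sprintf("efa-reconstruction-k%d", k))
}

#' Harmonic power spectrum
#'
#' Power of harmonic n is `(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`. Returned
#' fractions are relative to the total over the stored harmonics; the
#' cumulative fraction is nondecreasing and ends at 1.
#'
#' @param coeffs An `efa_coef`.
#' @return Data frame with columns `harmonic`, `power`, `fraction`,
#'   `cumulative`.
#' @export
harmonic_power <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa_coef"))
  pw <- (coeffs$a^2 + coeffs$b^2 + coeffs$c^2 + coeffs$d^2) / 2
  fr <- pw / sum(pw)
  data.frame(harmonic = seq_along(pw), power = pw, fraction = fr,
             cumulative = cumsum(fr))
}

#' Flatten normalized coefficients to the analysis vector
#'
#' Drops the entries fixed by normalization (`a1`, `b1`, `c1`) and
#' returns the remaining `4 * n_harmonics - 3` coefficients in the order
#' `d1, a2, b2, c2, d2, ..., aH, bH, cH, dH`.
#'
#' @param coeffs A normalized `efa_coef`.
#' @return Named numeric vector.
#' @export
efa_flatten <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa_coef"))
  if (!coeffs$normalized)
    stop("efa_flatten expects normalized coefficients", call. = FALSE)
  H <- coeffs$n_harmonics
  v <- c(coeffs$d[1],
         if (H > 1L) as.vector(rbind(coeffs$a[-1L], coeffs$b[-1L],
                                     coeffs$c[-1L], coeffs$d[-1L])))
  nm <- c("d1",
          if (H > 1L) as.vector(vapply(2:H, function(h)
            paste0(c("a", "b", "c", "d"), h), character(4))))
  stats::setNames(v, nm)
}

#' Rebuild an `efa_coef` object from a flattened analysis vector
#'
#' Inverse of [efa_flatten()]: inserts `a1 = 1`, `b1 = c1 = 0`.
#'
#' @param v Numeric vector of length `4 * H - 3`.
#' @return A normalized `efa_coef`.
#' @export
efa_unflatten <- function(v) {
  H <- (length(v) + 3L) / 4L
  if (H != round(H)) stop("vector length must be 4*H - 3", call. = FALSE)
  H <- as.integer(H)
  a <- c(1, numeric(H - 1L)); b <- numeric(H)
  cc <- numeric(H); d <- numeric(H)
  d[1] <- v[1]
  if (H > 1L) {
    rest <- matrix(v[-1L], nrow = 4L)
    a[-1L] <- rest[1L, ]; b[-1L] <- rest[2L, ]
    cc[-1L] <- rest[3L, ]; d[-1L] <- rest[4L, ]
  }
  structure(list(a = a, b = b, c = cc, d = d, A0 = 0, C0 = 0,
                 n_harmonics = H, normalized = TRUE, size_scalar = 1),
            class = "efa_coef")
}
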