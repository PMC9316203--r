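# Shared fixtures: canonical curves, random simple polygons, and an
# independent dense-quadrature oracle for the elliptic Fourier
# coefficients.

circle_points <- function(n = 256, r = 1, centre = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

ellipse_points <- function(n = 256, a = 2, b = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(a * cos(th), b * sin(th))
}

square_points <- function(side = 1) {
  side * rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
}

# star-shaped polygon: sorted angles, random radii -> always simple
random_simple_polygon <- function(n_vertices = 25, r_range = c(0.5, 1.5)) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  cbind(r * cos(th), r * sin(th))
}

# Fourier-series coefficients of the piecewise-linear contour by dense
# trapezoid quadrature of the defining integrals
#   a_n = (2/T) int x(t) cos(2 pi n t / T) dt   (etc.)
# independent of the closed-form path under test (integrates the
# coordinate functions, not their derivatives).
efa_quadrature <- function(p, n_harmonics, n_steps = 1e5) {
  p <- as.matrix(p)
  K <- nrow(p)
  d <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p
  len <- sqrt(rowSums(d^2))
  Tt <- sum(len)
  cum <- c(0, cumsum(len))
  per_edge <- pmax(2L, round(n_steps * len / Tt))
  t_all <- vector("list", K); x_all <- y_all <- w_all <- vector("list", K)
  for (i in seq_len(K)) {
    m <- per_edge[i]
    u <- seq(0, 1, length.out = m)
    t_all[[i]] <- cum[i] + u * len[i]
    x_all[[i]] <- p[i, 1] + u * d[i, 1]
    y_all[[i]] <- p[i, 2] + u * d[i, 2]
    h <- len[i] / (m - 1)
    w <- rep(h, m); w[c(1, m)] <- h / 2
    w_all[[i]] <- w
  }
  t <- unlist(t_all); x <- unlist(x_all); y <- unlist(y_all)
  w <- unlist(w_all)
  a <- b <- cc <- dd <- numeric(n_harmonics)
  for (n in seq_len(n_harmonics)) {
    cn <- cos(2 * pi * n * t / Tt); sn <- sin(2 * pi * n * t / Tt)
    a[n] <- 2 / Tt * sum(w * x * cn)
    b[n] <- 2 / Tt * sum(w * x * sn)
    cc[n] <- 2 / Tt * sum(w * y * cn)
    dd[n] <- 2 / Tt * sum(w * y * sn)
  }
  list(a = a, b = b, c = cc, d = dd,
       A0 = sum(w * x) / Tt, C0 = sum(w * y) / Tt)
}

# random similarity transform + start-point shift of a polygon
random_similarity <- function(p) {
  ang <- stats::runif(1, 0, 2 * pi)
  sc <- exp(stats::runif(1, -1, 1))
  tr <- stats::rnorm(2, sd = 5)
  q <- p %*% (sc * rbind(c(cos(ang), sin(ang)), c(-sin(ang), cos(ang))))
  q <- sweep(q, 2, tr, `+`)
  shift <- sample.int(nrow(q), 1)
  q[c(shift:nrow(q), seq_len(shift - 1L)), , drop = FALSE]
}

efa_coef_vector <- function(cf) c(cf$a, cf$b, cf$c, cf$d)

# small paper-shaped design scaled down for fast unit tests
small_group_specs <- function() {
  gs <- study_group_specs()
  sizes <- c(extant = 40L, Cretaceous = 15L, Miocene = 5L, Eocene = 2L)
  for (i in seq_along(gs)) gs[[i]]$n <- sizes[[gs[[i]]$name]]
  gs
}
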