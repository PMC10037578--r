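# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force two-sided signed-rank p: enumerate every sign assignment of
# the nonzero differences and recompute the positive rank sum each time
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n_le <- 0
  n_ge <- 0
  for (m in 0:(2^n - 1)) {
    signs <- bitwAnd(m, 2^(0:(n - 1))) > 0
    w <- sum(r[signs])
    if (w <= w_obs) n_le <- n_le + 1
    if (w >= w_obs) n_ge <- n_ge + 1
  }
  min(1, 2 * min(n_le, n_ge) / 2^n)
}

# dense parametric triangulation of a spherical cap (radius R, base radius
# a): numerical surface area to cross-check the 2*pi*R*h closed form
cap_area_numeric <- function(R, a, n_theta = 400, n_phi = 400) {
  alpha <- asin(a / R)
  th <- seq(0, alpha, length.out = n_theta + 1)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)
  pt <- function(t, p) R * c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
  area <- 0
  for (i in seq_len(n_theta)) {
    for (j in seq_len(n_phi)) {
      p1 <- pt(th[i], ph[j]);     p2 <- pt(th[i + 1], ph[j])
      p3 <- pt(th[i + 1], ph[j + 1]); p4 <- pt(th[i], ph[j + 1])
      tri <- function(u, v, w) {
        cr <- crossprod_vec(v - u, w - u)
        0.5 * sqrt(sum(cr^2))
      }
      area <- area + tri(p1, p2, p3) + tri(p1, p3, p4)
    }
  }
  area
}

crossprod_vec <- function(x, y) {
  c(x[2] * y[3] - x[3] * y[2],
    x[3] * y[1] - x[1] * y[3],
    x[1] * y[2] - x[2] * y[1])
}

# icosphere by repeated edge-midpoint subdivision of an icosahedron,
# vertices renormalised to the unit sphere
unit_icosphere <- function(subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mget(key, envir = mid_cache, ifnotfound = list(NULL))[[1]]
      if (!is.null(got)) return(got)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      id <- nrow(v)
      assign(key, id, envir = mid_cache)
      id
    }
    newf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c3 <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  list(vertices = v, faces = f)
}

# solid cube mask helper
cube_mask <- function(n = 10, spacing = c(1, 1, 1), pad = 3) {
  d <- n + 2 * pad
  arr <- array(FALSE, c(d, d, d))
  arr[(pad + 1):(pad + n), (pad + 1):(pad + n), (pad + 1):(pad + n)] <- TRUE
  bone_mask(arr, spacing)
}
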