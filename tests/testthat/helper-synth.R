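# Shared fixtures and independent oracles, built in code.

# Equilateral triangle corners with given centroid, size and orientation.
equilateral <- function(side = 1, angle = 0, center = c(0, 0)) {
  base <- rbind(c(-side / 2, -side * sqrt(3) / 6),
                c(side / 2, -side * sqrt(3) / 6),
                c(0, side * sqrt(3) / 3))
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(base %*% t(rot), 2, center, "+")
}

tri_state_of <- function(p) {
  triangle_state(p[1, 1], p[1, 2], p[2, 1], p[2, 2], p[3, 1], p[3, 2])
}

# Brute-force area-weighted mean elongation by explicit summation.
mean_q_brute <- function(tri) {
  sxx <- 0; sxy <- 0; sa <- 0
  for (i in seq_len(nrow(tri))) {
    sxx <- sxx + tri$area[i] * tri$qxx[i]
    sxy <- sxy + tri$area[i] * tri$qxy[i]
    sa <- sa + tri$area[i]
  }
  c(xx = sxx / sa, xy = sxy / sa)
}

# Brute-force weighted covariance (loop, no vectorized reuse).
wcov_brute <- function(w, a, b) {
  w <- w / sum(w)
  ma <- sum(w * a); mb <- sum(w * b)
  s <- 0
  for (i in seq_along(a)) s <- s + w[i] * (a[i] - ma) * (b[i] - mb)
  s
}

# Apply a 2x2 map to all cell centers of a tracked tissue frame.
apply_map_frame <- function(frame, m) {
  p <- as.matrix(frame$cells[, c("x", "y")]) %*% t(m)
  frame$cells$x <- p[, 1]; frame$cells$y <- p[, 2]
  vp <- as.matrix(frame$vertices[, c("x", "y")]) %*% t(m)
  frame$vertices$x <- vp[, 1]; frame$vertices$y <- vp[, 2]
  frame
}

# Does an open polyline self-intersect (non-adjacent segments)?
path_self_intersects <- function(x, y) {
  n <- length(x) - 1
  seg_int <- function(i, j) {
    p <- c(x[i], y[i], x[i + 1], y[i + 1])
    q <- c(x[j], y[j], x[j + 1], y[j + 1])
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
      (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(q[1:2], q[3:4], p[1:2]); d2 <- d(q[1:2], q[3:4], p[3:4])
    d3 <- d(p[1:2], p[3:4], q[1:2]); d4 <- d(p[1:2], p[3:4], q[3:4])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2))
    for (j in (i + 2):n)
      if (seg_int(i, j)) return(TRUE)
  FALSE
}
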