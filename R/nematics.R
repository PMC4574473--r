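## Nematic tensor algebra -----------------------------------------------------
##
## A nematic is a symmetric traceless 2x2 tensor, stored by its two free
## components (qxx, qxy).  Its axis is defined modulo pi; rotating the
## underlying object by phi rotates the component pair (qxx, qxy) by 2*phi.
## All functions here are vectorized over their arguments.

#' Rotate a nematic tensor
#'
#' Rotates the axis of a symmetric traceless 2x2 tensor by `phi` radians.
#' In component space `(qxx, qxy)` this is a rotation by `2 * phi`.
#'
#' @param qxx,qxy Nematic components (vectors of equal length).
#' @param phi Rotation angle in radians (object rotation, not component
#'   rotation).
#' @return A list with rotated components `qxx` and `qxy`.
#' @examples
#' rotate_nematic(0.3, 0, pi / 4) # pure-x elongation rotated to 45 degrees
#' @export
rotate_nematic <- function(qxx, qxy, phi) {
  c2 <- cos(2 * phi)
  s2 <- sin(2 * phi)
  list(qxx = c2 * qxx - s2 * qxy, qxy = s2 * qxx + c2 * qxy)
}

#' Magnitude and axis angle of a nematic
#'
#' @param qxx,qxy Nematic components.
#' @return A list with `norm` (magnitude, `sqrt(qxx^2 + qxy^2)`) and
#'   `angle` (axis angle in `[0, pi)`).
#' @export
nematic_norm_angle <- function(qxx, qxy) {
  list(norm = sqrt(qxx^2 + qxy^2),
       angle = (atan2(qxy, qxx) / 2) %% pi)
}

## Reference triangle: unit area, equilateral, one edge along +x.
## Side length l satisfies sqrt(3)/4 * l^2 = 1.
.ref_side <- 2 / 3^(1 / 4)
## Edge matrix E_ref = [c2 - c1 | c3 - c1] and its inverse (corners
## (0,0), (l,0), (l/2, l*sqrt(3)/2)).
.ref_edges <- matrix(c(.ref_side, 0, .ref_side / 2, .ref_side * sqrt(3) / 2),
                     2, 2)
.ref_edges_inv <- solve(.ref_edges)

#' Triangle state tensor: area, orientation and elongation nematic
#'
#' Factors the linear map `S` taking a fixed unit-area equilateral reference
#' triangle (one edge along +x) to the given triangle as
#' `S = sqrt(A) * exp(Q) * R(theta)`, where `R` is a rotation and `Q` a
#' symmetric traceless (nematic) tensor.  `Q` is the lab-frame elongation
#' of the triangle: rotating the corners by `phi` rotates the axis of `Q`
#' by `phi` and advances `theta` by `phi`.  Equilateral triangles of any
#' size and orientation have `Q = (0, 0)`.
#'
#' @param x1,y1,x2,y2,x3,y3 Corner coordinates (um), counter-clockwise;
#'   vectors of equal length for many triangles at once.
#' @return A data frame with columns `area` (um^2, signed; positive for
#'   counter-clockwise corners), `theta` (radians), `qxx`, `qxy`
#'   (dimensionless) and `degenerate` (logical; collinear corners).
#' @examples
#' l <- 2 / 3^0.25
#' triangle_state(0, 0, l, 0, l / 2, l * sqrt(3) / 2) # reference: Q = 0
#' @export
triangle_state <- function(x1, y1, x2, y2, x3, y3) {
  ## S = T %*% solve(.ref_edges), T = [r2 - r1 | r3 - r1]
  ia <- .ref_edges_inv[1, 1]; ib <- .ref_edges_inv[1, 2]
  ic <- .ref_edges_inv[2, 1]; id <- .ref_edges_inv[2, 2]
  tx2 <- x2 - x1; tx3 <- x3 - x1
  ty2 <- y2 - y1; ty3 <- y3 - y1
  s11 <- tx2 * ia + tx3 * ic
  s12 <- tx2 * ib + tx3 * id
  s21 <- ty2 * ia + ty3 * ic
  s22 <- ty2 * ib + ty3 * id
  dets <- s11 * s22 - s12 * s21
  degenerate <- dets < 1e-14 * pmax(tx2^2 + ty2^2, tx3^2 + ty3^2, 1e-300)
  dec <- .decompose_unimodular(s11, s12, s21, s22, ifelse(degenerate, NA, dets))
  data.frame(area = dets, theta = dec$theta,
             qxx = dec$qxx, qxy = dec$qxy, degenerate = degenerate)
}

## Decompose S (det > 0) as sqrt(det) * exp(Q) * R(theta); vectorized.
.decompose_unimodular <- function(s11, s12, s21, s22, dets) {
  ## Left polar factor H of B = S / sqrt(det): H^2 = B B^T, det H = 1, so
  ## H^2 = cosh(2q) I + sinh(2q) N with N the unit nematic (axis matrix).
  b11 <- s11; b12 <- s12; b21 <- s21; b22 <- s22 # scale cancels in ratios
  ## m = S S^T / det(S)  (equals B B^T)
  m11 <- (b11^2 + b12^2) / dets
  m22 <- (b21^2 + b22^2) / dets
  m12 <- (b11 * b21 + b12 * b22) / dets
  tr2 <- (m11 + m22) / 2            # cosh(2q)
  nxx <- (m11 - m22) / 2
  nxy <- m12
  sh2 <- sqrt(nxx^2 + nxy^2)        # sinh(2q)
  q <- 0.5 * log(tr2 + sh2)         # elongation magnitude
  scale <- ifelse(sh2 > 0, q / sh2, 0)
  qxx <- scale * nxx
  qxy <- scale * nxy
  ## theta from R = exp(-Q) B; the polar rotation angle of B itself equals
  ## the rotation angle of R because exp(-Q) is SPD:
  theta <- atan2(b21 - b12, b11 + b22)
  list(theta = theta, qxx = qxx, qxy = qxy)
}

#' Reconstruct triangle corners from a triangle state
#'
#' Inverse of [triangle_state()]: builds corners at
#' `sqrt(A) * exp(Q) * R(theta)` applied to the reference triangle, with the
#' first corner placed at `(x0, y0)`.
#'
#' @param area,theta,qxx,qxy Triangle state (scalars).
#' @param x0,y0 Position of the first corner.
#' @return A 3x2 matrix of corner coordinates.
#' @export
triangle_corners <- function(area, theta, qxx, qxy, x0 = 0, y0 = 0) {
  q <- sqrt(qxx^2 + qxy^2)
  if (q > 0) {
    n1 <- qxx / q; n2 <- qxy / q
    eq <- cosh(q) * diag(2) + sinh(q) * matrix(c(n1, n2, n2, -n1), 2, 2)
  } else {
    eq <- diag(2)
  }
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  s <- sqrt(area) * eq %*% rot
  ref <- rbind(c(0, 0), c(.ref_side, 0),
               c(.ref_side / 2, .ref_side * sqrt(3) / 2))
  sweep(ref %*% t(s), 2, c(-x0, -y0), "-")
}

## Polar rotation angle of 2x2 map(s) M = R(theta) H (H SPD); vectorized.
.polar_angle <- function(m11, m12, m21, m22) {
  atan2(m21 - m12, m11 + m22)
}

## Finite-interval kinematic decomposition of 2x2 maps with det > 0,
## vectorized.  The pure shear is the symmetric traceless part of the
## matrix logarithm of M (the constant-velocity-gradient view of the
## interval: exact equality across triangles for any affine deformation,
## exactly zero x-elongation bias for simple shear); the rotation angle
## is extracted from the polar factor of M.  Valid for rotation angles
## away from +-pi (per-frame tissue deformations are small).
.polar_log2 <- function(m11, m12, m21, m22) {
  dets <- m11 * m22 - m12 * m21
  if (any(dets <= 0)) stop("deformation map with non-positive determinant")
  s <- sqrt(dets)
  u11 <- m11 / s; u12 <- m12 / s; u21 <- m21 / s; u22 <- m22 / s
  h <- (u11 + u22) / 2                     # cos(theta) or cosh(mu)
  ## W = U - h I is traceless with W^2 = (h^2 - 1) I;
  ## log(U) = f(h) * W, f = theta/sin(theta) (h < 1) or mu/sinh(mu) (h > 1)
  f <- numeric(length(h))
  near <- abs(h - 1) < 1e-8
  rotl <- !near & h < 1
  shrl <- !near & h >= 1
  f[near] <- 1 - (h[near] - 1) / 3
  th <- acos(pmax(-1, pmin(1, h[rotl])))
  f[rotl] <- th / sin(th)
  mu <- acosh(h[shrl])
  f[shrl] <- mu / sinh(mu)
  w11 <- u11 - h; w22 <- u22 - h
  list(tr = log(dets),
       asym = atan2(m21 - m12, m11 + m22),  # polar rotation angle
       sxx = f * (w11 - w22) / 2,
       sxy = f * (u12 + u21) / 2)
}

#' Corotational elongation change of a triangle over a deformation
#'
#' The package's corotational convention: the change of a triangle's
#' elongation nematic, evaluated in the frame that removes both the
#' rotation and the geometric advection of the elongation axis, equals
#' the symmetric traceless part of `log(M)` of the deformation map.  Per
#' triangle, pure shear and corotational elongation change are therefore
#' identical for any non-degenerate deformation; this function exposes
#' the quantity directly from two corner sets for testing and
#' per-triangle bookkeeping.
#'
#' @param corners_t,corners_t2 3x2 corner matrices of the same triangle
#'   at the two ends of the interval.
#' @return `c(dqxx, dqxy)`: the corotational elongation change.
#' @export
corotational_delta_q <- function(corners_t, corners_t2) {
  e1 <- cbind(corners_t[2, ] - corners_t[1, ],
              corners_t[3, ] - corners_t[1, ])
  e2 <- cbind(corners_t2[2, ] - corners_t2[1, ],
              corners_t2[3, ] - corners_t2[1, ])
  m <- e2 %*% solve(e1)
  lg <- .polar_log2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
  c(dqxx = lg$sxx, dqxy = lg$sxy)
}

## Matrix exponential of a 2x2 matrix, closed form.
.expm2 <- function(m) {
  tr <- (m[1, 1] + m[2, 2]) / 2
  b <- m - tr * diag(2)                       # traceless part
  delta <- b[1, 1]^2 + b[1, 2] * b[2, 1]      # b %*% b = delta * I
  if (delta > 0) {
    mu <- sqrt(delta)
    f <- cosh(mu) * diag(2) + sinh(mu) / mu * b
  } else if (delta < 0) {
    mu <- sqrt(-delta)
    f <- cos(mu) * diag(2) + sin(mu) / mu * b
  } else {
    f <- diag(2) + b
  }
  exp(tr) * f
}

## Shoelace signed area of a polygon given coordinate vectors.
.polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

## Polygon centroid (area-weighted).
.polygon_centroid <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}
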