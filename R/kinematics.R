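## Per-interval triangle and tissue kinematics --------------------------------

#' Deformation of matched triangles between two frames
#'
#' For each triangle present (same cell triplet) in both triangulations,
#' computes from the linear map `M` carrying its corners at `t` to its
#' corners at `t + dt`:
#' * the relative area expansion rate `v = ln(det M) / dt`,
#' * the rotation rate `omega` (angle of the polar factor of `M` over
#'   `dt`),
#' * the pure shear rate `(vxx, vxy)`: the symmetric traceless part of
#'   `log(M) / dt` (the constant-velocity-gradient reading of the
#'   interval).
#'
#' Under an affine deformation of the whole network every triangle
#' reports identical `(v, omega, vxx, vxy)`; a pure rotation gives zero
#' shear and expansion; a superposed global rotation changes only
#' `omega` up to terms of second order in the per-interval deformation;
#' and for small deformations the shear rate agrees with the symmetric
#' traceless part of `(M - I)/dt` to second order.  The corotational
#' change of the triangle's elongation over the interval is identical to
#' `(vxx, vxy) * dt` by the package's corotational convention (see
#' [corotational_delta_q()]).
#'
#' @param tri_t,tri_t2 `triangulation` objects (see [triangulate_frame()]);
#'   triangles are matched by their unordered cell triplet.
#' @param dt Interval duration in hours; if `NULL`, taken from the frame
#'   times of the two triangulations.
#' @return A data frame of class `triangle_kinematics`: one row per
#'   matched triangle with `key`, `area` (at `t`), `area2`, `v`, `omega`,
#'   `vxx`, `vxy`, `qxx`, `qxy` (at `t`), `qxx2`, `qxy2` (at `t + dt`),
#'   `xc`, `yc` (centroid at `t`).
#' @export
triangle_deformation <- function(tri_t, tri_t2, dt = NULL) {
  if (is.null(dt)) dt <- attr(tri_t2, "time") - attr(tri_t, "time")
  if (!is.null(dt) && !is.na(dt) && dt <= 0) stop("dt must be positive")
  k1 <- .tri_key(tri_t$c1, tri_t$c2, tri_t$c3)
  k2 <- .tri_key(tri_t2$c1, tri_t2$c2, tri_t2$c3)
  j <- match(k1, k2)
  sel <- which(!is.na(j))
  a <- tri_t[sel, ]; b <- tri_t2[j[sel], ]
  keys <- k1[sel]
  keep <- !(a$degenerate | b$degenerate)
  if (!all(keep)) {
    warning("degenerate triangle(s) dropped from kinematics")
    a <- a[keep, ]; b <- b[keep, ]; keys <- keys[keep]
  }
  ## M = E2 %*% solve(E1), E = [r2 - r1 | r3 - r1]
  e1a <- a$x2 - a$x1; e1b <- a$x3 - a$x1
  e1c <- a$y2 - a$y1; e1d <- a$y3 - a$y1
  e2a <- b$x2 - b$x1; e2b <- b$x3 - b$x1
  e2c <- b$y2 - b$y1; e2d <- b$y3 - b$y1
  det1 <- e1a * e1d - e1b * e1c
  m11 <- (e2a * e1d - e2b * e1c) / det1
  m12 <- (-e2a * e1b + e2b * e1a) / det1
  m21 <- (e2c * e1d - e2d * e1c) / det1
  m22 <- (-e2c * e1b + e2d * e1a) / det1
  lg <- .polar_log2(m11, m12, m21, m22)
  data.frame(key = keys,
             area = a$area, area2 = b$area,
             v = lg$tr / dt, omega = lg$asym / dt,
             vxx = lg$sxx / dt, vxy = lg$sxy / dt,
             qxx = a$qxx, qxy = a$qxy, qxx2 = b$qxx, qxy2 = b$qxy,
             xc = (a$x1 + a$x2 + a$x3) / 3, yc = (a$y1 + a$y2 + a$y3) / 3,
             stringsAsFactors = FALSE)
}

#' Area-weighted tissue-scale kinematics
#'
#' The overall tissue pure shear rate is the area-weighted mean of the
#' per-triangle pure shear rates; the mean area expansion and rotation
#' rates come along.
#'
#' @param kin A `triangle_kinematics` data frame.
#' @return List with `vxx`, `vxy` (tissue shear rate), `v` (mean area
#'   expansion rate), `omega` (mean rotation rate), `total_area`.
#' @export
tissue_shear <- function(kin) {
  if (!nrow(kin)) stop("empty triangle set")
  w <- kin$area / sum(kin$area)
  list(vxx = sum(w * kin$vxx), vxy = sum(w * kin$vxy),
       v = sum(w * kin$v), omega = sum(w * kin$omega),
       total_area = sum(kin$area))
}

#' Corotational rate of change of mean triangle elongation
#'
#' Rate of change of the area-weighted mean elongation between two
#' triangulations of the same topology, corrected for the mean tissue
#' rotation: the later mean nematic is rotated back by the mean rotation
#' angle `omega * dt` before differencing.  On an interval with no
#' topological change, `tissue_shear() == corotational rate + correlation
#' term` exactly.
#'
#' @param tri_t,tri_t2 `triangulation` objects with identical triangle
#'   sets (no topological change in the interval).
#' @param dt Interval in hours (default from frame times).
#' @param omega Mean rotation rate used for the corotation; default is
#'   the area-weighted mean from [triangle_deformation()].
#' @return List with `dqxx_dt`, `dqxy_dt` and the `omega` used.
#' @export
corotational_mean_elongation_rate <- function(tri_t, tri_t2, dt = NULL,
                                              omega = NULL) {
  if (is.null(dt)) dt <- attr(tri_t2, "time") - attr(tri_t, "time")
  k1 <- .tri_key(tri_t$c1, tri_t$c2, tri_t$c3)
  k2 <- .tri_key(tri_t2$c1, tri_t2$c2, tri_t2$c3)
  if (!setequal(k1, k2))
    stop("topology changed within the interval; handle events upstream")
  if (is.null(omega)) {
    kin <- triangle_deformation(tri_t, tri_t2, dt)
    omega <- tissue_shear(kin)$omega
  }
  q1 <- mean_elongation(tri_t)
  q2 <- mean_elongation(tri_t2)
  q2r <- rotate_nematic(q2$qxx, q2$qxy, -omega * dt)
  list(dqxx_dt = (q2r$qxx - q1$qxx) / dt,
       dqxy_dt = (q2r$qxy - q1$qxy) / dt,
       omega = omega)
}

#' Shear from correlations of local fluctuations
#'
#' Covariance-form correlation contributions to tissue shear: the
#' area-expansion part couples local area expansion rate and local
#' elongation,
#' \deqn{D^e_{xx} = -(\langle v^m Q^m_{xx}\rangle - \langle v^m\rangle\langle Q^m_{xx}\rangle),}
#' and the rotational part couples local rotation rate and local
#' elongation,
#' \deqn{D^r_{xx} \simeq 2(\langle\omega^m Q^m_{xy}\rangle - \langle\omega^m\rangle\langle Q^m_{xy}\rangle),}
#' with `D^r_xy = -2 Cov(omega, Q_xx)` for the other component; all
#' averages are area-weighted.  These are the leading-order split of the
#' exact correlation term used by [run_decomposition()] (which defines
#' `D` as the topology-free closure residual).
#'
#' @param kin A `triangle_kinematics` data frame.
#' @param weights Optional weights (default: triangle areas at interval
#'   start).
#' @return List with `De = c(xx, xy)`, `Dr = c(xx, xy)` and their sum `D`.
#' @export
correlation_terms <- function(kin, weights = kin$area) {
  w <- weights / sum(weights)
  wcov <- function(a, b) sum(w * a * b) - sum(w * a) * sum(w * b)
  de <- c(xx = -wcov(kin$v, kin$qxx), xy = -wcov(kin$v, kin$qxy))
  dr <- c(xx = 2 * wcov(kin$omega, kin$qxy),
          xy = -2 * wcov(kin$omega, kin$qxx))
  list(De = de, Dr = dr, D = de + dr)
}

#' Spatial power spectrum of the local tissue rotation rate
#'
#' Bins per-triangle rotation rates onto a regular grid (mean of the
#' rates whose triangle centroid falls in each grid cell), subtracts the
#' mean, applies a 2D Hann window and returns the squared magnitude of
#' the 2D discrete Fourier transform as a function of the wave vector
#' `q = (qx, qy)` in rad/um, plus `q` in units of cycles per cell
#' diameter `d0`.
#'
#' @param kin A `triangle_kinematics` data frame (uses `omega`, `xc`,
#'   `yc`).
#' @param d0 Typical cell diameter in um (default 4).
#' @param grid_spacing Grid spacing in um (default `d0 / 2`).
#' @return List of class `rotation_spectrum`: `power` (matrix), `qx`,
#'   `qy` (rad/um), `q_peak` (the largest non-DC local maximum, rad/um),
#'   `q_peak_d0` (same in cycles per `d0`).
#' @export
rotation_power_spectrum <- function(kin, d0 = 4, grid_spacing = d0 / 2) {
  xr <- range(kin$xc); yr <- range(kin$yc)
  nx <- max(4L, floor(diff(xr) / grid_spacing) + 1L)
  ny <- max(4L, floor(diff(yr) / grid_spacing) + 1L)
  if (diff(xr) < 4 * grid_spacing || diff(yr) < 4 * grid_spacing)
    stop("region smaller than 4x4 grid cells")
  ix <- pmin(nx, pmax(1L, floor((kin$xc - xr[1]) / grid_spacing) + 1L))
  iy <- pmin(ny, pmax(1L, floor((kin$yc - yr[1]) / grid_spacing) + 1L))
  grid <- matrix(0, nx, ny)
  cnt <- matrix(0, nx, ny)
  for (k in seq_along(ix)) {
    grid[ix[k], iy[k]] <- grid[ix[k], iy[k]] + kin$omega[k]
    cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1
  }
  grid[cnt > 0] <- grid[cnt > 0] / cnt[cnt > 0]
  grid <- grid - mean(grid[cnt > 0])
  grid[cnt == 0] <- 0
  hann <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  win <- outer(hann(nx), hann(ny))
  ft <- fft(grid * win)
  pw <- Mod(ft)^2
  qx <- 2 * pi * (seq_len(nx) - 1) / (nx * grid_spacing)
  qx <- ifelse(qx > pi / grid_spacing, qx - 2 * pi / grid_spacing, qx)
  qy <- 2 * pi * (seq_len(ny) - 1) / (ny * grid_spacing)
  qy <- ifelse(qy > pi / grid_spacing, qy - 2 * pi / grid_spacing, qy)
  ## largest non-DC local maximum
  pk <- pw
  pk[1, 1] <- -Inf
  best <- arrayInd(which.max(pk), dim(pk))
  q_peak <- c(qx = qx[best[1]], qy = qy[best[2]])
  structure(list(power = pw, qx = qx, qy = qy, q_peak = q_peak,
                 q_peak_d0 = q_peak * d0 / (2 * pi), d0 = d0,
                 grid_spacing = grid_spacing),
            class = "rotation_spectrum")
}
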