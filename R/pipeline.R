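## End-to-end decomposition pipeline ------------------------------------------

#' Decompose tissue shear into cellular contributions over a video
#'
#' Runs the full triangle-method decomposition over every frame interval
#' of a tracked tissue: per-interval tissue shear rate, corotational mean
#' elongation change (cell-shape contribution), T1/division/extrusion
#' retriangulation contributions, and the correlation term, together with
#' cumulative curves and the closure residual
#' `v~ - (DQ/Dt + T + C + E + D)` (logged, never redistributed).
#'
#' @param tissue A [tracked_tissue()] (events detected/validated).
#' @param roi ROI name (see [roi_cells()]) or `NULL` for all cells.
#' @return A data frame of class `shear_series`: one row per interval
#'   with rate columns (`vxx`, `dqdt_xx`, `t_xx`, `c_xx`, `e_xx`, `d_xx`,
#'   diagnostic covariance split `de_xx`/`dr_xx`, all with `_xy`
#'   analogues, in 1/h), closure residuals, event counts, and cumulative
#'   columns `cum_*`.
#' @export
run_decomposition <- function(tissue, roi = NULL) {
  stopifnot(inherits(tissue, "tracked_tissue"))
  ids <- if (is.null(roi)) NULL else roi_cells(tissue, roi)
  nfr <- length(tissue$frames)
  if (nfr < 2) stop("need at least two frames")
  rows <- lapply(seq_len(nfr - 1), function(k)
    .decompose_interval(tissue, k, roi_ids = ids))
  res <- do.call(rbind, rows)
  for (nm in c("vxx", "vxy", "dqdt_xx", "dqdt_xy", "t_xx", "t_xy",
               "c_xx", "c_xy", "e_xx", "e_xy", "d_xx", "d_xy"))
    res[[paste0("cum_", nm)]] <- cumsum(res[[nm]] * res$dt)
  class(res) <- c("shear_series", "data.frame")
  res
}

#' @export
print.shear_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<shear_series> %d intervals, t = %.2f..%.2f h\n",
              n, x$time[1], x$time[n] + x$dt[n]))
  cat(sprintf("  cumulative xx: total %+.4f = shape %+.4f + T1 %+.4f + div %+.4f + extr %+.4f + corr %+.4f\n",
              x$cum_vxx[n], x$cum_dqdt_xx[n], x$cum_t_xx[n],
              x$cum_c_xx[n], x$cum_e_xx[n], x$cum_d_xx[n]))
  cat(sprintf("  max |closure residual|: %.3g 1/h\n",
              max(abs(c(x$closure_xx, x$closure_xy)))))
  invisible(x)
}

#' @export
plot.shear_series <- function(x, component = c("xx", "xy"),
                              cumulative = TRUE, ...) {
  component <- match.arg(component)
  pick <- function(stem) {
    col <- paste0(if (cumulative) "cum_" else "", stem, "_", component)
    if (stem == "v") col <- paste0(if (cumulative) "cum_" else "",
                                   "v", component)
    x[[col]]
  }
  t <- x$time + x$dt
  series <- list(total = pick("v"), `cell shape` = pick("dqdt"),
                 T1 = pick("t"), division = pick("c"),
                 extrusion = pick("e"), correlation = pick("d"))
  cols <- c("blue", "darkgreen", "red", "orange", "cyan3", "magenta")
  ylim <- range(unlist(series))
  graphics::plot(t, series[[1]], type = "l", col = cols[1], ylim = ylim,
                 xlab = "time (h)",
                 ylab = if (cumulative) paste0("cumulative shear (",
                                               component, ")")
                 else paste0("shear rate (", component, ", 1/h)"), ...)
  for (i in 2:6) graphics::lines(t, series[[i]], col = cols[i])
  graphics::legend("topleft", legend = names(series), col = cols, lty = 1,
                   cex = 0.7, bty = "n")
  invisible(x)
}

#' Shape nematic of a region outline
#'
#' Elongation nematic of a simple polygon from its normalized second area
#' moments, in the same gauge as the triangle elongation: a rectangle
#' with aspect ratio `ar` along x has `Q_xx = log(ar) / 2`
#' (`ar = exp(2 Q_xx)`), and any isotropic outline (circle, square) has
#' `Q = (0, 0)`.
#'
#' @param x,y Polygon vertex coordinates (closed implicitly).
#' @return List with `qxx`, `qxy`, `angle` (major axis, radians), `area`.
#' @export
region_shape_nematic <- function(x, y) {
  a <- .polygon_area(x, y)
  if (a < 0) { x <- rev(x); y <- rev(y); a <- -a }
  if (.polygon_self_intersects(x, y)) stop("self-intersecting polygon")
  ctr <- .polygon_centroid(x, y)
  xs <- x - ctr[1]; ys <- y - ctr[2]
  n <- length(xs); j <- c(2:n, 1)
  cr <- xs * ys[j] - xs[j] * ys
  ixx <- sum(cr * (xs^2 + xs * xs[j] + xs[j]^2)) / 12
  iyy <- sum(cr * (ys^2 + ys * ys[j] + ys[j]^2)) / 12
  ixy <- sum(cr * (xs * ys[j] + 2 * xs * ys + 2 * xs[j] * ys[j] +
                     xs[j] * ys)) / 24
  m <- matrix(c(ixx, ixy, ixy, iyy), 2, 2)
  ev <- eigen(m, symmetric = TRUE)
  q <- log(ev$values[1] / ev$values[2]) / 4
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  list(qxx = q * cos(2 * ang), qxy = q * sin(2 * ang),
       angle = ang %% pi, area = a)
}

.polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, x[c(2:n, 1)], y[c(2:n, 1)])
  inter <- function(p, q) {
    d1 <- (q[3] - q[1]) * (p[2] - q[2]) - (q[4] - q[2]) * (p[1] - q[1])
    d2 <- (q[3] - q[1]) * (p[4] - q[2]) - (q[4] - q[2]) * (p[3] - q[1])
    d3 <- (p[3] - p[1]) * (q[2] - p[2]) - (p[4] - p[2]) * (q[1] - p[1])
    d4 <- (p[3] - p[1]) * (q[4] - p[2]) - (p[4] - p[2]) * (q[3] - p[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (inter(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Convex-hull outline of the tracked cell centers of a frame
#'
#' Convenience outline for the blade-shape consistency check on synthetic
#' tissues.
#'
#' @param frame A [cell_network_frame()].
#' @param cells Optional cell id subset.
#' @return List with vectors `x`, `y` (counter-clockwise hull).
#' @export
frame_outline <- function(frame, cells = NULL) {
  cc <- frame$cells
  if (!is.null(cells)) cc <- cc[cc$cell_id %in% cells, ]
  h <- grDevices::chull(cc$x, cc$y)
  h <- rev(h) # chull returns clockwise
  list(x = cc$x[h], y = cc$y[h])
}

#' Average replicate shear series on a common time grid
#'
#' Linearly interpolates every cumulative column of each replicate to a
#' common grid (the overlap of the replicate time ranges) and returns
#' pointwise mean and standard deviation.
#'
#' @param series_list List of `shear_series` objects (>= 2), already
#'   aligned in time (e.g. to a shared reference event).
#' @param n_grid Number of grid points (default 50).
#' @return A data frame with `time` and, for every cumulative column,
#'   `<col>_mean` and `<col>_sd`.
#' @export
replicate_average <- function(series_list, n_grid = 50) {
  if (length(series_list) < 2) stop("need at least 2 replicate series")
  ends <- lapply(series_list, function(s) {
    tt <- s$time + s$dt
    range(tt)
  })
  lo <- max(vapply(ends, `[`, numeric(1), 1))
  hi <- min(vapply(ends, `[`, numeric(1), 2))
  if (lo >= hi) stop("replicate time ranges do not overlap")
  grid <- seq(lo, hi, length.out = n_grid)
  cols <- grep("^cum_", names(series_list[[1]]), value = TRUE)
  out <- data.frame(time = grid)
  for (cl in cols) {
    mat <- vapply(series_list, function(s)
      approxfun(s$time + s$dt, s[[cl]], rule = 2)(grid), numeric(n_grid))
    out[[paste0(cl, "_mean")]] <- rowMeans(mat)
    out[[paste0(cl, "_sd")]] <- apply(mat, 1, sd)
  }
  out
}
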