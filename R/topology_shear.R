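## Shear contributions of topological changes ---------------------------------
##
## During a topological change the triangulation changes discontinuously
## while the geometry does not.  The contribution of an event class to
## tissue shear is minus the jump in area-weighted mean triangle
## elongation caused solely by the retriangulation, evaluated at fixed
## geometry, divided by the interval duration.  Convention: T1 and
## extrusion jumps are evaluated at the pre-event frame's geometry,
## division jumps at the post-event frame's geometry (daughters merged
## into a virtual mother for the within-interval kinematics).  Because a
## retriangulation at fixed geometry retiles the same region, the total
## triangulated area is unchanged and per-event jumps add exactly.

## Merge each division's daughters into a virtual mother in a frame.
.merge_daughters <- function(frame, lineage) {
  if (!nrow(lineage)) return(frame)
  cells <- frame$cells
  vc <- frame$vertex_cells
  nb <- frame$neighbors
  for (i in seq_len(nrow(lineage))) {
    m <- lineage$mother[i]; d1 <- lineage$daughter1[i]
    d2 <- lineage$daughter2[i]
    j1 <- match(d1, cells$cell_id); j2 <- match(d2, cells$cell_id)
    if (is.na(j1) || is.na(j2)) stop("daughters not present in frame")
    w <- cells$area[c(j1, j2)]
    mrow <- cells[j1, ]
    mrow$cell_id <- m
    mrow$x <- sum(w * cells$x[c(j1, j2)]) / sum(w)
    mrow$y <- sum(w * cells$y[c(j1, j2)]) / sum(w)
    mrow$area <- sum(w)
    cells <- rbind(cells[-c(j1, j2), ], mrow)
    vc$cell_id[vc$cell_id %in% c(d1, d2)] <- m
    nb$cell_id[nb$cell_id %in% c(d1, d2)] <- m
    nb$neighbor_id[nb$neighbor_id %in% c(d1, d2)] <- m
  }
  ## drop duplicate incidences and now-degenerate vertices (< 3 cells)
  vc <- vc[!duplicated(vc[, c("vertex_id", "cell_id")]), ]
  sz <- table(vc$vertex_id)
  keep <- names(sz)[sz >= 3]
  vc <- vc[vc$vertex_id %in% keep, ]
  verts <- frame$vertices[as.character(frame$vertices$vertex_id) %in% keep, ]
  nb <- nb[nb$cell_id != nb$neighbor_id, ]
  nb <- nb[!duplicated(nb[, c("cell_id", "neighbor_id")]), ]
  cell_network_frame(frame$frame_index, frame$time, cells, nb, verts, vc)
}

## Evaluate a triangulation's triangle set on another frame's geometry.
.retriangulate_on <- function(tri, frame) {
  trips <- data.frame(vertex_id = tri$vertex_id,
                      c1 = tri$c1, c2 = tri$c2, c3 = tri$c3)
  .triangulation_from_triples(trips, frame)
}

## Area-weighted sum of (A * q) over a triangle subset, fixed denominator.
## Degenerate (collinear-center) triangles carry no elongation signal and
## are excluded.
.jump_sum <- function(tri, rows, denom) {
  rows <- rows[!tri$degenerate[rows]]
  c(xx = sum(tri$area[rows] * tri$qxx[rows]) / denom,
    xy = sum(tri$area[rows] * tri$qxy[rows]) / denom)
}

#' Shear contribution of topological changes between two triangulations
#'
#' Both triangulations must be evaluated at the same geometry (the
#' retriangulation jump is defined at fixed positions).  Each removed or
#' added triangle is assigned to an event: triangles containing an
#' extruded cell (removed) or spanned by its former neighbor ring (added)
#' belong to that extrusion; triangles containing a T1's lost cell pair
#' (removed) or gained pair (added) belong to that T1; triangles
#' containing a dividing mother (removed) or one of its daughters (added)
#' belong to that division.  Unassigned changed triangles are flagged in
#' the `unassigned` element, not silently attributed.
#'
#' @param tri_before,tri_after `triangulation` objects at identical
#'   geometry.
#' @param events List with optional elements `t1` (data frame `lost_a`,
#'   `lost_b`, `gained_a`, `gained_b`), `division` (`mother`, `daughter1`,
#'   `daughter2`), `extrusion` (`cell_id`, and attribute ring via
#'   `tri_before`).
#' @param dt Interval duration (h).
#' @return List with nematic rates `T`, `C`, `E` (each `c(xx, xy)`), the
#'   total jump rate `total` (equal to minus the mean-elongation jump
#'   over `dt`), and `unassigned` (keys of changed triangles not matched
#'   to an event).
#' @export
topological_contribution <- function(tri_before, tri_after, events = list(),
                                     dt = 1) {
  kb <- .tri_key(tri_before$c1, tri_before$c2, tri_before$c3)
  ka <- .tri_key(tri_after$c1, tri_after$c2, tri_after$c3)
  denom <- sum(tri_before$area)
  removed <- which(!(kb %in% ka))
  added <- which(!(ka %in% kb))
  qb <- mean_elongation(tri_before); qa <- mean_elongation(tri_after)
  total <- -c(xx = qa$qxx - qb$qxx, xy = qa$qxy - qb$qxy) / dt
  zero <- c(xx = 0, xy = 0)
  out <- list(T = zero, C = zero, E = zero, total = total,
              unassigned = character(0))
  has <- function(tri, rows, cells) {
    rows[(tri$c1[rows] %in% cells) + (tri$c2[rows] %in% cells) +
           (tri$c3[rows] %in% cells) >= length(cells)]
  }
  used_r <- integer(0); used_a <- integer(0)
  class_jump <- function(r_rows, a_rows) {
    (.jump_sum(tri_after, a_rows, denom) -
       .jump_sum(tri_before, r_rows, denom))
  }
  if (!is.null(events$extrusion) && nrow(events$extrusion)) {
    for (i in seq_len(nrow(events$extrusion))) {
      cid <- events$extrusion$cell_id[i]
      r <- has(tri_before, removed, cid)
      ring <- unique(c(tri_before$c1[r], tri_before$c2[r], tri_before$c3[r]))
      ring <- setdiff(ring, cid)
      a <- added[(tri_after$c1[added] %in% ring) &
                   (tri_after$c2[added] %in% ring) &
                   (tri_after$c3[added] %in% ring)]
      out$E <- out$E - class_jump(r, a) / dt
      used_r <- c(used_r, r); used_a <- c(used_a, a)
    }
  }
  if (!is.null(events$t1) && nrow(events$t1)) {
    for (i in seq_len(nrow(events$t1))) {
      r <- setdiff(has(tri_before, removed,
                       c(events$t1$lost_a[i], events$t1$lost_b[i])), used_r)
      a <- setdiff(has(tri_after, added,
                       c(events$t1$gained_a[i], events$t1$gained_b[i])),
                   used_a)
      out$T <- out$T - class_jump(r, a) / dt
      used_r <- c(used_r, r); used_a <- c(used_a, a)
    }
  }
  if (!is.null(events$division) && nrow(events$division)) {
    for (i in seq_len(nrow(events$division))) {
      r <- setdiff(has(tri_before, removed, events$division$mother[i]), used_r)
      a <- added[(tri_after$c1[added] %in%
                    c(events$division$daughter1[i],
                      events$division$daughter2[i])) |
                   (tri_after$c2[added] %in%
                      c(events$division$daughter1[i],
                        events$division$daughter2[i])) |
                   (tri_after$c3[added] %in%
                      c(events$division$daughter1[i],
                        events$division$daughter2[i]))]
      a <- setdiff(a, used_a)
      out$C <- out$C - class_jump(r, a) / dt
      used_r <- c(used_r, r); used_a <- c(used_a, a)
    }
  }
  out$unassigned <- c(kb[setdiff(removed, used_r)], ka[setdiff(added, used_a)])
  out
}

## Full decomposition of a single frame interval ------------------------------
##
## Telescoping that closes machine-exactly:
##   corot<Q>(post,post) - <Q>(pre,pre)
##     = corot J_div(post) + J_TE(pre) + K,
## with K the corotational kinematic change on the merged mid
## triangulation, so v~ = DQ/Dt + T + C + E + D with D := <v~> - K/dt.
.decompose_interval <- function(tissue, k, roi_ids = NULL) {
  f0 <- tissue$frames[[k]]; f1 <- tissue$frames[[k + 1]]
  dt <- f1$time - f0$time
  fi <- f1$frame_index
  lin <- tissue$lineage[tissue$lineage$frame == fi, , drop = FALSE]
  ext <- tissue$extrusions[tissue$extrusions$frame == fi, , drop = FALSE]
  t1 <- tissue$t1_events[tissue$t1_events$frame == fi, , drop = FALSE]
  tri_pre <- triangulate_frame(f0, cells = roi_ids)
  f1m <- .merge_daughters(f1, lin)
  roi_mid <- roi_ids
  if (!is.null(roi_ids) && nrow(lin))
    roi_mid <- setdiff(unique(c(roi_ids, lin$mother)),
                       c(lin$daughter1, lin$daughter2))
  tri_mid_post <- triangulate_frame(f1m, cells = roi_mid)
  tri_mid_pre <- .retriangulate_on(tri_mid_post, f0)
  tri_post <- triangulate_frame(f1, cells = roi_ids)
  kin <- triangle_deformation(tri_mid_pre, tri_mid_post, dt)
  ts <- tissue_shear(kin)
  phi <- ts$omega * dt
  me <- function(tri) {
    q <- mean_elongation(tri)
    c(xx = q$qxx, xy = q$qxy)
  }
  q_pre <- me(tri_pre); q_mid_pre <- me(tri_mid_pre)
  q_mid_post <- me(tri_mid_post); q_post <- me(tri_post)
  rot <- function(q) {
    r <- rotate_nematic(q["xx"], q["xy"], -phi)
    c(xx = unname(r$qxx), xy = unname(r$qxy))
  }
  kchange <- rot(q_mid_post) - q_mid_pre
  d_exact <- c(xx = ts$vxx, xy = ts$vxy) - kchange / dt
  ## T1 + extrusion jumps at pre geometry.  Extrusions are attributed
  ## per event; the T1 class takes the remainder of the full
  ## retriangulation jump, so that margin-crossing T1 waves (whose
  ## changed triangles extend into the excluded boundary ring) cannot
  ## break the closure.
  te <- topological_contribution(
    tri_pre, tri_mid_pre,
    events = list(t1 = t1, extrusion = ext), dt = dt)
  jte <- q_mid_pre - q_pre
  t_term <- -jte / dt - te$E
  ## division jump at post geometry, corotated back over the interval
  cd <- topological_contribution(
    tri_mid_post, tri_post,
    events = list(division = lin), dt = dt)
  c_term <- rot(cd$total)
  dqdt <- (rot(q_post) - q_pre) / dt
  corr <- correlation_terms(kin)
  residual <- c(xx = ts$vxx, xy = ts$vxy) -
    (dqdt + t_term + te$E + c_term + d_exact)
  data.frame(
    time = f0$time, dt = dt,
    vxx = ts$vxx, vxy = ts$vxy, v = ts$v, omega = ts$omega,
    dqdt_xx = dqdt["xx"], dqdt_xy = dqdt["xy"],
    t_xx = t_term["xx"], t_xy = t_term["xy"],
    c_xx = c_term["xx"], c_xy = c_term["xy"],
    e_xx = te$E["xx"], e_xy = te$E["xy"],
    d_xx = d_exact["xx"], d_xy = d_exact["xy"],
    de_xx = corr$De["xx"], de_xy = corr$De["xy"],
    dr_xx = corr$Dr["xx"], dr_xy = corr$Dr["xy"],
    closure_xx = residual["xx"], closure_xy = residual["xy"],
    n_t1 = nrow(t1), n_division = nrow(lin), n_extrusion = nrow(ext),
    unassigned = length(te$unassigned) + length(cd$unassigned),
    row.names = NULL)
}

#' Orientation of a cell-cell connection from flanking triangle centers
#'
#' For every interior bond (cell pair shared by two triangles) the
#' orientation of the line connecting the two triangle centroids, the
#' robust proxy for the orientation of short bonds.
#'
#' @param tri A `triangulation`.
#' @param pairs Optional data frame `a`, `b` restricting to specific cell
#'   pairs.
#' @return Data frame `a`, `b`, `angle` (radians in `[0, pi)`).
#' @export
bond_orientation <- function(tri, pairs = NULL) {
  edges <- rbind(
    data.frame(a = pmin(tri$c1, tri$c2), b = pmax(tri$c1, tri$c2),
               xc = (tri$x1 + tri$x2 + tri$x3) / 3,
               yc = (tri$y1 + tri$y2 + tri$y3) / 3),
    data.frame(a = pmin(tri$c2, tri$c3), b = pmax(tri$c2, tri$c3),
               xc = (tri$x1 + tri$x2 + tri$x3) / 3,
               yc = (tri$y1 + tri$y2 + tri$y3) / 3),
    data.frame(a = pmin(tri$c1, tri$c3), b = pmax(tri$c1, tri$c3),
               xc = (tri$x1 + tri$x2 + tri$x3) / 3,
               yc = (tri$y1 + tri$y2 + tri$y3) / 3))
  key <- paste(edges$a, edges$b, sep = "|")
  if (!is.null(pairs)) {
    want <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b), sep = "|")
    edges <- edges[key %in% want, ]
    key <- key[key %in% want]
  }
  sp <- split(seq_len(nrow(edges)), key)
  sp <- sp[vapply(sp, length, integer(1)) == 2L]
  if (!length(sp))
    return(data.frame(a = numeric(0), b = numeric(0), angle = numeric(0)))
  out <- do.call(rbind, lapply(sp, function(ij) {
    dxy <- c(edges$xc[ij[2]] - edges$xc[ij[1]],
             edges$yc[ij[2]] - edges$yc[ij[1]])
    data.frame(a = edges$a[ij[1]], b = edges$b[ij[1]],
               angle = atan2(dxy[2], dxy[1]) %% pi)
  }))
  rownames(out) <- NULL
  out
}

#' Angular statistics of gained and lost cell-cell connections
#'
#' Pools T1 events in a time window, measures the orientation of each
#' lost connection (in the pre-event triangulation) and gained connection
#' (post-event), bins the angles, and subtracts the angular distribution
#' of all connections so that an isotropically rearranging network gives
#' zero in every bin.
#'
#' @param tissue A [tracked_tissue()] with detected T1 events.
#' @param window Time window `c(t0, t1)` in hours, or `NULL` for all.
#' @param bin_width Angular bin width in radians (default 15 degrees).
#' @return List of class `bond_angle_histogram`: `breaks`, `mids`,
#'   `gained_eff`, `lost_eff` (effective proportions per bin; raw
#'   distributions each sum to 1 before subtraction), `n_gained`,
#'   `n_lost`.
#' @export
gain_loss_histograms <- function(tissue, window = NULL,
                                 bin_width = pi / 12) {
  t1 <- tissue$t1_events
  times <- vapply(tissue$frames, `[[`, numeric(1), "time")
  fidx <- vapply(tissue$frames, `[[`, integer(1), "frame_index")
  if (!is.null(window)) {
    et <- times[match(t1$frame, fidx)]
    t1 <- t1[et >= window[1] & et <= window[2], , drop = FALSE]
  }
  if (!nrow(t1)) stop("no T1 events in window")
  breaks <- seq(0, pi, by = bin_width)
  lost_ang <- numeric(0); gained_ang <- numeric(0); all_ang <- numeric(0)
  for (f in unique(t1$frame)) {
    k <- match(f, fidx)
    tri_pre <- triangulate_frame(tissue$frames[[k - 1]])
    tri_post <- triangulate_frame(tissue$frames[[k]])
    ev <- t1[t1$frame == f, ]
    la <- bond_orientation(tri_pre, data.frame(a = ev$lost_a, b = ev$lost_b))
    ga <- bond_orientation(tri_post,
                           data.frame(a = ev$gained_a, b = ev$gained_b))
    lost_ang <- c(lost_ang, la$angle)
    gained_ang <- c(gained_ang, ga$angle)
    all_ang <- c(all_ang, bond_orientation(tri_pre)$angle)
  }
  hcount <- function(a) {
    h <- graphics::hist(a, breaks = breaks, plot = FALSE)$counts
    if (sum(h) == 0) h else h / sum(h)
  }
  bg <- hcount(all_ang)
  structure(list(breaks = breaks, mids = breaks[-1] - bin_width / 2,
                 gained_eff = hcount(gained_ang) - bg,
                 lost_eff = hcount(lost_ang) - bg,
                 n_gained = length(gained_ang), n_lost = length(lost_ang)),
            class = "bond_angle_histogram")
}

#' T1 transition rate per cell per hour
#'
#' @param tissue A [tracked_tissue()] with detected events.
#' @param window Sliding window width in hours (default 1).
#' @return Data frame `time`, `rate` (T1 per cell per hour) evaluated at
#'   every frame time.
#' @export
t1_rate <- function(tissue, window = 1) {
  times <- vapply(tissue$frames, `[[`, numeric(1), "time")
  fidx <- vapply(tissue$frames, `[[`, integer(1), "frame_index")
  ncell <- vapply(tissue$frames, function(f) nrow(f$cells), integer(1))
  et <- times[match(tissue$t1_events$frame, fidx)]
  rate <- vapply(times, function(t) {
    lo <- t - window / 2; hi <- t + window / 2
    n <- sum(et >= lo & et <= hi)
    span <- min(hi, max(times)) - max(lo, min(times))
    if (span <= 0) span <- window
    n / (mean(ncell) * span)
  }, numeric(1))
  data.frame(time = times, rate = rate)
}

#' Attribute correlation shear to triangles about to undergo a T1
#'
#' Splits the covariance-form correlation term of each interval between
#' the set of triangles that will disappear in a T1 transition within the
#' next `horizon` frames and the remaining triangles, using shared global
#' means so that the two parts add exactly to the total.
#'
#' @param tissue A [tracked_tissue()] with detected T1 events.
#' @param horizon Look-ahead in frames (default 9).
#' @return Data frame per interval: `time`, `subset_dxx`, `rest_dxx`,
#'   `total_dxx` (and `_dxy` analogues), `area_fraction` of the flagged
#'   subset, `truncated` (intervals whose horizon exceeds the video end).
#' @export
correlation_attribution <- function(tissue, horizon = 9L) {
  nfr <- length(tissue$frames)
  fidx <- vapply(tissue$frames, `[[`, integer(1), "frame_index")
  tris <- lapply(tissue$frames, triangulate_frame)
  ## keys of triangles destroyed by each T1, indexed by pre-event frame slot
  doomed <- vector("list", nfr)
  for (i in seq_len(nrow(tissue$t1_events))) {
    f <- tissue$t1_events$frame[i]
    k <- match(f, fidx)
    tp <- tris[[k - 1]]
    sel <- ((tp$c1 %in% c(tissue$t1_events$lost_a[i],
                          tissue$t1_events$lost_b[i])) +
              (tp$c2 %in% c(tissue$t1_events$lost_a[i],
                            tissue$t1_events$lost_b[i])) +
              (tp$c3 %in% c(tissue$t1_events$lost_a[i],
                            tissue$t1_events$lost_b[i]))) >= 2
    doomed[[k]] <- c(doomed[[k]], .tri_key(tp$c1, tp$c2, tp$c3)[sel])
  }
  out <- vector("list", nfr - 1)
  for (k in seq_len(nfr - 1)) {
    kin <- triangle_deformation(tris[[k]], tris[[k + 1]],
                                tissue$frames[[k + 1]]$time -
                                  tissue$frames[[k]]$time)
    hi <- min(nfr, k + horizon)
    flagged <- unique(unlist(doomed[(k + 1):hi]))
    inset <- kin$key %in% flagged
    w <- kin$area / sum(kin$area)
    vb <- sum(w * kin$v); ob <- sum(w * kin$omega)
    qxb <- sum(w * kin$qxx); qyb <- sum(w * kin$qxy)
    part <- function(sel) {
      c(xx = sum(w[sel] * (-(kin$v[sel] - vb) * (kin$qxx[sel] - qxb) +
                             2 * (kin$omega[sel] - ob) * (kin$qxy[sel] - qyb))),
        xy = sum(w[sel] * (-(kin$v[sel] - vb) * (kin$qxy[sel] - qyb) -
                             2 * (kin$omega[sel] - ob) * (kin$qxx[sel] - qxb))))
    }
    s <- part(inset); r <- part(!inset)
    out[[k]] <- data.frame(
      time = tissue$frames[[k]]$time,
      subset_dxx = s["xx"], subset_dxy = s["xy"],
      rest_dxx = r["xx"], rest_dxy = r["xy"],
      total_dxx = s["xx"] + r["xx"], total_dxy = s["xy"] + r["xy"],
      area_fraction = sum(w[inset]),
      truncated = (k + horizon) > nfr, row.names = NULL)
  }
  do.call(rbind, out)
}
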