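## Synthetic tracked-tissue generator -----------------------------------------
##
## Kinematic (no mechanics) generator: cells live on a perturbed hexagonal
## lattice, move by scripted affine maps or sliding-row patterns, and
## undergo scripted T1 transitions, divisions and extrusions.  The
## generator returns exact polygon-free network geometry (cell centers +
## full topology), event records, and an analytic budget of the expected
## cumulative shear contributions.

#' Script describing a synthetic tracked tissue
#'
#' @param rows,cols Lattice size in cells.
#' @param spacing Lattice constant in um (default 4, a typical cell
#'   diameter).
#' @param disorder Amplitude of uniform vertex jitter applied to initial
#'   cell centers, as a fraction of `spacing` (jittered positions are
#'   transported by the scripted motion, so the motion stays exactly
#'   affine per cell).
#' @param frames Number of frames.
#' @param dt Frame interval in hours (default 1/12 h = 5 min).
#' @param shear_xx,shear_xy Pure shear rate components (1/h).
#' @param rotation Rigid rotation rate (rad/h).
#' @param dilation Isotropic area expansion rate (1/h).
#' @param events Data frame with columns `frame`, `type` (`"t1"`,
#'   `"division"`, `"extrusion"`), `cell_a`, `cell_b` (T1 bond), `cell`
#'   (division/extrusion target) and `axis` (division axis, radians).  An
#'   event at frame `f` happens between frames `f - 1` and `f`.
#' @param sliding List `list(rate = , block = , phase = , hyst = )`:
#'   alternating blocks of `block` rows slide along +x/-x at `rate` cell
#'   diameters per hour (the sliding-row pattern producing rows of
#'   opposite simple shear and no net pure shear).  `phase` (optional)
#'   gives per-row initial offsets in units of the spacing, recycled
#'   across rows; staggered phases desynchronize the neighbor-exchange
#'   waves of different row pairs.  `hyst` (default 0.25) lets bonds
#'   persist past the symmetric exchange point, as short bonds do in a
#'   real tissue.  Mutually exclusive with the affine rates.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `synth_script`.
#' @export
synth_script <- function(rows = 10, cols = 10, spacing = 4, disorder = 0,
                         frames = 2, dt = 1 / 12,
                         shear_xx = 0, shear_xy = 0, rotation = 0,
                         dilation = 0, events = NULL, sliding = NULL,
                         seed = 1L) {
  structure(list(rows = rows, cols = cols, spacing = spacing,
                 disorder = disorder, frames = frames, dt = dt,
                 shear_xx = shear_xx, shear_xy = shear_xy,
                 rotation = rotation, dilation = dilation,
                 events = events, sliding = sliding, seed = as.integer(seed)),
            class = "synth_script")
}

## -- lattice topology --------------------------------------------------------

.hex_lattice <- function(rows, cols, spacing) {
  r <- rep(seq_len(rows) - 1L, each = cols)
  i <- rep(seq_len(cols) - 1L, times = rows)
  id <- r * cols + i + 1L
  x <- spacing * (i + 0.5 * (r %% 2L))
  y <- spacing * sqrt(3) / 2 * r
  boundary <- r == 0L | r == rows - 1L | i == 0L | i == cols - 1L
  adj <- list()
  add <- function(a, b) rbind(cbind(pmin(a, b), pmax(a, b)))
  pairs <- list()
  ## same row
  sel <- i < cols - 1L
  pairs[[1]] <- cbind(id[sel], id[sel] + 1L)
  ## across rows
  up <- r < rows - 1L
  even <- up & (r %% 2L == 0L)
  odd <- up & (r %% 2L == 1L)
  p <- list()
  p[[1]] <- cbind(id[even], id[even] + cols)              # (r,i)-(r+1,i)
  sel <- even & i > 0L
  p[[2]] <- cbind(id[sel], id[sel] + cols - 1L)           # (r,i)-(r+1,i-1)
  p[[3]] <- cbind(id[odd], id[odd] + cols)                # (r,i)-(r+1,i)
  sel <- odd & i < cols - 1L
  p[[4]] <- cbind(id[sel], id[sel] + cols + 1L)           # (r,i)-(r+1,i+1)
  pairs <- do.call(rbind, c(pairs, p))
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  list(cells = data.frame(cell_id = id, x0 = x, y0 = y,
                          base_area = spacing^2 * sqrt(3) / 2,
                          boundary = boundary, row = r, col = i),
       pairs = unique(as.data.frame(setNames(as.data.frame(pairs),
                                             c("a", "b")))))
}

## adjacency list from a pair table
.adj_list <- function(pairs, ids) {
  al <- split(c(pairs$b, pairs$a), c(pairs$a, pairs$b))
  out <- setNames(vector("list", length(ids)), ids)
  out[names(al)] <- lapply(al, sort)
  out
}

## all 3-cliques (a < b < c) of the adjacency
.cliques3 <- function(pairs, adj) {
  res <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$a[k]; b <- pairs$b[k]
    cm <- intersect(adj[[as.character(a)]], adj[[as.character(b)]])
    cm <- cm[cm > b]
    if (length(cm)) res[[k]] <- cbind(a, b, cm)
  }
  m <- do.call(rbind, res)
  if (is.null(m)) m <- matrix(integer(0), 0, 3)
  as.data.frame(setNames(as.data.frame(m), c("c1", "c2", "c3")))
}

## -- event surgery on the topology state -------------------------------------

.topo_t1 <- function(topo, a, b) {
  adj <- .adj_list(topo$pairs, topo$cells$cell_id)
  common <- intersect(adj[[as.character(a)]], adj[[as.character(b)]])
  if (length(common) != 2)
    stop("T1 bond (", a, ",", b, ") lacks exactly two common neighbors")
  keep <- !(topo$pairs$a == min(a, b) & topo$pairs$b == max(a, b))
  topo$pairs <- topo$pairs[keep, ]
  topo$pairs <- rbind(topo$pairs,
                      data.frame(a = min(common), b = max(common)))
  topo$last_t1 <- c(lost = sort(c(a, b)), gained = sort(common))
  topo
}

.ring_of <- function(topo, cell, pos) {
  adj <- .adj_list(topo$pairs, topo$cells$cell_id)
  nb <- adj[[as.character(cell)]]
  ci <- match(cell, topo$cells$cell_id)
  ni <- match(nb, topo$cells$cell_id)
  ang <- atan2(pos$y[ni] - pos$y[ci], pos$x[ni] - pos$x[ci])
  nb[order(ang)]
}

.topo_extrusion <- function(topo, cell, pos) {
  ring <- .ring_of(topo, cell, pos)
  topo$pairs <- topo$pairs[topo$pairs$a != cell & topo$pairs$b != cell, ]
  topo$cells <- topo$cells[topo$cells$cell_id != cell, ]
  if (length(ring) > 3)
    topo$rings <- c(topo$rings, list(ring))
  topo
}

.topo_division <- function(topo, mother, axis, pos, map_inv) {
  ring <- .ring_of(topo, mother, pos)
  ci <- match(mother, topo$cells$cell_id)
  ni <- match(ring, topo$cells$cell_id)
  ang <- atan2(pos$y[ni] - pos$y[ci], pos$x[ni] - pos$x[ci])
  ## neighbors closest to the two ends of the division plane (axis +- pi/2)
  dplane <- function(t) {
    d <- abs(((ang - t) + pi) %% (2 * pi) - pi)
    ring[which.min(d)]
  }
  na <- dplane(axis + pi / 2)
  nb <- dplane(axis - pi / 2)
  if (na == nb) stop("degenerate division: plane neighbors coincide")
  ## split ring into the two arcs strictly between na and nb
  k <- length(ring)
  ia <- match(na, ring); ib <- match(nb, ring)
  idx <- c(seq_len(k), seq_len(k))
  arc1 <- ring[idx[(ia + 1):(ib + (ib <= ia) * k - 1)]]
  arc2 <- setdiff(ring, c(na, nb, arc1))
  ## which daughter owns which arc: d1 sits at +axis from the mother
  side <- sin(ang - axis) # > 0: counter-clockwise side of the axis
  d1 <- max(topo$cells$cell_id) + 1L
  d2 <- d1 + 1L
  own1 <- if (length(arc1) == 0 ||
              mean(cos(ang[match(arc1, ring)] - axis)) >= 0) d1 else d2
  own2 <- if (own1 == d1) d2 else d1
  ## daughter base positions: event-frame offset pulled back to frame 0
  delta <- 0.25 * sqrt(topo$cells$base_area[ci])
  off <- delta * c(cos(axis), sin(axis))
  p_now <- c(pos$x[ci], pos$y[ci])
  base1 <- map_inv %*% (p_now + off)
  base2 <- map_inv %*% (p_now - off)
  mrow <- topo$cells[ci, ]
  topo$cells <- topo$cells[-ci, ]
  topo$cells <- rbind(topo$cells,
    data.frame(cell_id = c(d1, d2),
               x0 = c(base1[1], base2[1]), y0 = c(base1[2], base2[2]),
               base_area = mrow$base_area / 2,
               boundary = mrow$boundary, row = mrow$row, col = mrow$col))
  topo$pairs <- topo$pairs[topo$pairs$a != mother & topo$pairs$b != mother, ]
  newp <- rbind(
    data.frame(a = d1, b = d2),
    data.frame(a = pmin(own1, c(na, nb, arc1)),
               b = pmax(own1, c(na, nb, arc1))),
    data.frame(a = pmin(own2, c(na, nb, arc2)),
               b = pmax(own2, c(na, nb, arc2))))
  topo$pairs <- unique(rbind(topo$pairs, newp))
  topo$last_div <- c(mother = mother, d1 = d1, d2 = d2)
  topo
}

## -- frame assembly ----------------------------------------------------------

## positions of all cells of `topo` at total map `m` (2x2)
.positions <- function(topo, m, slide = NULL, t = 0, spacing = 1) {
  x <- topo$cells$x0; y <- topo$cells$y0
  if (!is.null(slide)) {
    sgn <- 1 - 2 * ((topo$cells$row %/% slide$block) %% 2)
    ph <- if (is.null(slide$phase)) 0 else
      slide$phase[topo$cells$row %% length(slide$phase) + 1L]
    x <- x + (sgn * slide$rate * t + ph) * spacing
  }
  list(x = m[1, 1] * x + m[1, 2] * y, y = m[2, 1] * x + m[2, 2] * y)
}

## Rebuild across-row adjacency from bracketing x positions.  `hyst`
## shifts the bracketing window against the relative sliding direction:
## bonds persist past the symmetric exchange point (as short bonds do in
## a real tissue), which makes the retriangulation jumps release
## x-elongation (cumulative T_xx > 0 compensated by D_xx < 0).
.sliding_pairs <- function(topo, pos, spacing_x, rowsign, hyst = 0.25) {
  cells <- topo$cells
  rows <- sort(unique(cells$row))
  prs <- list()
  same <- topo$pairs[cells$row[match(topo$pairs$a, cells$cell_id)] ==
                       cells$row[match(topo$pairs$b, cells$cell_id)], ]
  for (r in rows[-length(rows)]) {
    i0 <- which(cells$row == r); i1 <- which(cells$row == r + 1)
    relv <- rowsign[match(r + 1, rows)] - rowsign[match(r, rows)]
    shift <- hyst * spacing_x * sign(relv)
    for (k in i0) {
      dx <- pos$x[i1] - pos$x[k]
      hit <- i1[dx > -spacing_x + shift & dx < spacing_x + shift]
      if (length(hit))
        prs[[length(prs) + 1]] <- data.frame(
          a = pmin(cells$cell_id[k], cells$cell_id[hit]),
          b = pmax(cells$cell_id[k], cells$cell_id[hit]))
    }
  }
  unique(rbind(same, do.call(rbind, prs)))
}

## build a cell_network_frame from topology + positions
.assemble_frame <- function(topo, pos, frame_index, time, det_scale) {
  cells <- data.frame(cell_id = topo$cells$cell_id,
                      x = pos$x, y = pos$y,
                      area = topo$cells$base_area * det_scale,
                      boundary = topo$cells$boundary)
  adj <- .adj_list(topo$pairs, cells$cell_id)
  ## CCW neighbor order by angle
  nb <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    nbr <- adj[[as.character(cells$cell_id[i])]]
    if (is.null(nbr) || !length(nbr)) return(NULL)
    j <- match(nbr, cells$cell_id)
    ang <- atan2(cells$y[j] - cells$y[i], cells$x[j] - cells$x[i])
    data.frame(cell_id = cells$cell_id[i], ord = seq_along(nbr),
               neighbor_id = nbr[order(ang)])
  }))
  ## vertices: 3-cliques + explicit k-fold rings
  cl <- .cliques3(topo$pairs, adj)
  ring_sets <- topo$rings
  vlist <- c(lapply(seq_len(nrow(cl)), function(i) unlist(cl[i, ])),
             ring_sets)
  if (!length(vlist))
    stop("degenerate topology (no network vertices); a sliding script ",
         "hit an exact neighbor-exchange tie - perturb rate or frame count")
  interior_cell <- !cells$boundary
  names(interior_cell) <- cells$cell_id
  verts <- list(); vcel <- list()
  for (vi in seq_along(vlist)) {
    members <- vlist[[vi]]
    j <- match(members, cells$cell_id)
    cx <- mean(cells$x[j]); cy <- mean(cells$y[j])
    ang <- atan2(cells$y[j] - cy, cells$x[j] - cx)
    members <- members[order(ang)]
    verts[[vi]] <- data.frame(vertex_id = vi, x = cx, y = cy,
                              interior = all(interior_cell[as.character(members)]))
    vcel[[vi]] <- data.frame(vertex_id = vi, ord = seq_along(members),
                             cell_id = members)
  }
  cell_network_frame(frame_index, time, cells, nb,
                     do.call(rbind, verts), do.call(rbind, vcel))
}

## -- generator ---------------------------------------------------------------

#' Generate a synthetic tracked tissue from a script
#'
#' Deterministic given the script's seed.  The returned tissue carries an
#' attribute `budget`: the analytic/oracle expectation of the cumulative
#' shear contributions over the whole video (components `total`,
#' `cell_shape`, `t1`, `division`, `extrusion`, `correlation`, each an
#' `(xx, xy)` pair), against which the decomposition pipeline can be
#' checked.  Topological-event jump values in the budget are computed by
#' a whole-patch recomputation of mean triangle elongation before and
#' after retriangulation at fixed geometry (T1/extrusion at the pre-event
#' frame's geometry, divisions at the post-event frame's).
#'
#' @param script A [synth_script()].
#' @return A [tracked_tissue()] with attribute `budget`.
#' @export
generate_tissue <- function(script) {
  stopifnot(inherits(script, "synth_script"))
  set.seed(script$seed)
  lat <- .hex_lattice(script$rows, script$cols, script$spacing)
  if (script$disorder > 0) {
    amp <- script$disorder * script$spacing
    lat$cells$x0 <- lat$cells$x0 + runif(nrow(lat$cells), -amp, amp)
    lat$cells$y0 <- lat$cells$y0 + runif(nrow(lat$cells), -amp, amp)
  }
  topo <- list(cells = lat$cells, pairs = lat$pairs, rings = list())
  g <- matrix(c(script$dilation / 2 + script$shear_xx,
                script$shear_xy + script$rotation,
                script$shear_xy - script$rotation,
                script$dilation / 2 - script$shear_xx), 2, 2)
  ev <- script$events
  frames <- vector("list", script$frames)
  lineage <- list(); extr <- list(); t1s <- list()
  jumps <- list()
  slide <- script$sliding
  for (k in seq_len(script$frames)) {
    t <- (k - 1) * script$dt
    m <- .expm2(g * t)
    dets <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
    if (!is.null(ev)) {
      evk <- ev[ev$frame == k, , drop = FALSE]
      for (e in seq_len(nrow(evk))) {
        type <- evk$type[e]
        pos_pre <- .positions(topo, .expm2(g * (t - script$dt)), slide,
                              t - script$dt, script$spacing)
        if (type == "t1") {
          pre_frame <- .assemble_frame(topo, pos_pre, k - 1L, t - script$dt, 1)
          topo <- .topo_t1(topo, evk$cell_a[e], evk$cell_b[e])
          mid_frame <- .assemble_frame(topo, pos_pre, k - 1L, t - script$dt, 1)
          jumps[[length(jumps) + 1]] <- .oracle_jump(pre_frame, mid_frame, "t1")
          t1s[[length(t1s) + 1]] <- data.frame(
            frame = k, lost_a = topo$last_t1[1], lost_b = topo$last_t1[2],
            gained_a = topo$last_t1[3], gained_b = topo$last_t1[4])
        } else if (type == "extrusion") {
          pre_frame <- .assemble_frame(topo, pos_pre, k - 1L, t - script$dt, 1)
          topo2 <- .topo_extrusion(topo, evk$cell[e], pos_pre)
          pos2 <- .positions(topo2, .expm2(g * (t - script$dt)), slide,
                             t - script$dt, script$spacing)
          mid_frame <- .assemble_frame(topo2, pos2, k - 1L, t - script$dt, 1)
          jumps[[length(jumps) + 1]] <- .oracle_jump(pre_frame, mid_frame,
                                                     "extrusion")
          topo <- topo2
          extr[[length(extr) + 1]] <- data.frame(cell_id = evk$cell[e],
                                                 frame = k)
        } else if (type == "division") {
          pos_now <- .positions(topo, m, slide, t, script$spacing)
          pre_frame <- .assemble_frame(topo, pos_now, k, t, dets)
          topo <- .topo_division(topo, evk$cell[e], evk$axis[e], pos_now,
                                 solve(m))
          pos2 <- .positions(topo, m, slide, t, script$spacing)
          post_frame <- .assemble_frame(topo, pos2, k, t, dets)
          jumps[[length(jumps) + 1]] <- .oracle_jump(pre_frame, post_frame,
                                                     "division")
          lineage[[length(lineage) + 1]] <- data.frame(
            mother = topo$last_div[1], daughter1 = topo$last_div[2],
            daughter2 = topo$last_div[3], frame = k)
        }
      }
    }
    pos <- .positions(topo, m, slide, t, script$spacing)
    if (!is.null(slide)) {
      rows <- sort(unique(topo$cells$row))
      rowsign <- 1 - 2 * ((rows %/% slide$block) %% 2)
      topo$pairs <- .sliding_pairs(topo, pos, script$spacing, rowsign,
                                   hyst = if (is.null(slide$hyst)) 0.25
                                          else slide$hyst)
    }
    frames[[k]] <- .assemble_frame(topo, pos, k, t, dets)
  }
  rbind_or <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  tis <- tracked_tissue(
    frames,
    lineage = rbind_or(lineage, NULL),
    extrusions = rbind_or(extr, NULL),
    t1_events = rbind_or(t1s, NULL))
  attr(tis, "budget") <- .script_budget(script, jumps)
  tis
}

## Whole-patch mean-elongation jump (oracle route for event budgets)
.oracle_jump <- function(frame_before, frame_after, type) {
  tb <- triangulate_frame(frame_before)
  ta <- triangulate_frame(frame_after)
  mb <- mean_elongation(tb)
  ma <- mean_elongation(ta)
  list(type = type, dqxx = ma$qxx - mb$qxx, dqxy = ma$qxy - mb$qxy)
}

.script_budget <- function(script, jumps) {
  tt <- (script$frames - 1) * script$dt
  sumj <- function(type) {
    sel <- vapply(jumps, function(j) j$type == type, logical(1))
    c(xx = -sum(vapply(jumps[sel], `[[`, numeric(1), "dqxx")),
      xy = -sum(vapply(jumps[sel], `[[`, numeric(1), "dqxy")))
  }
  t1 <- sumj("t1"); dv <- sumj("division"); ex <- sumj("extrusion")
  total <- c(xx = script$shear_xx * tt, xy = script$shear_xy * tt)
  if (!is.null(script$sliding)) total <- c(xx = 0, xy = 0)
  list(total = total,
       cell_shape = total - t1 - dv - ex,
       t1 = t1, division = dv, extrusion = ex,
       correlation = c(xx = 0, xy = 0),
       duration = tt)
}

#' Canonical T1 frame pair on a four-cell quartet
#'
#' Two frames bracketing a single neighbor exchange: the central bond
#' between the left/right cell pair shrinks and flips to connect the
#' top/bottom pair.  `progress` sets how far the four centers have moved
#' along the exchange path at the second frame.
#'
#' @param progress Geometric progress of the exchange in `[0, 1]` at the
#'   second frame (0: original geometry; 1: fully exchanged).
#' @param spacing Center spacing scale in um.
#' @param dt Frame interval in hours.
#' @param flip_frame Frame (1 or 2) at which the topological flip is
#'   recorded; default 2 (the flip happens within the interval).
#' @return A [tracked_tissue()] with two frames and one recorded T1.
#' @export
canonical_t1 <- function(progress = 1, spacing = 4, dt = 1 / 12,
                         flip_frame = 2L) {
  ## cells 1 (left), 2 (right), 3 (top), 4 (bottom)
  s <- spacing
  geom <- function(p) {
    data.frame(cell_id = 1:4,
               x = c(-s * (1 - 0.4 * p), s * (1 - 0.4 * p), 0, 0),
               y = c(0, 0, s * (0.6 + 0.4 * p), -s * (0.6 + 0.4 * p)),
               area = s^2 * sqrt(3) / 2, boundary = FALSE)
  }
  topo_for <- function(flipped) {
    if (!flipped)
      list(pairs = data.frame(a = c(1, 1, 1, 2, 2),
                              b = c(2, 3, 4, 3, 4)),
           trips = rbind(c(1, 2, 3), c(1, 2, 4)))
    else
      list(pairs = data.frame(a = c(1, 1, 2, 2, 3),
                              b = c(3, 4, 3, 4, 4)),
           trips = rbind(c(1, 3, 4), c(2, 3, 4)))
  }
  mk <- function(idx, time, p, flipped) {
    cells <- geom(p)
    tp <- topo_for(flipped)
    nb <- do.call(rbind, lapply(1:4, function(cid) {
      nbr <- c(tp$pairs$b[tp$pairs$a == cid], tp$pairs$a[tp$pairs$b == cid])
      j <- match(nbr, cells$cell_id)
      ang <- atan2(cells$y[j] - cells$y[cid], cells$x[j] - cells$x[cid])
      data.frame(cell_id = cid, ord = seq_along(nbr),
                 neighbor_id = nbr[order(ang)])
    }))
    verts <- do.call(rbind, lapply(1:2, function(vi) {
      j <- tp$trips[vi, ]
      data.frame(vertex_id = vi, x = mean(cells$x[j]), y = mean(cells$y[j]),
                 interior = TRUE)
    }))
    vcel <- do.call(rbind, lapply(1:2, function(vi) {
      members <- tp$trips[vi, ]
      cx <- mean(cells$x[members]); cy <- mean(cells$y[members])
      ang <- atan2(cells$y[members] - cy, cells$x[members] - cx)
      data.frame(vertex_id = vi, ord = 1:3, cell_id = members[order(ang)])
    }))
    cell_network_frame(idx, time, cells, nb, verts, vcel)
  }
  f1 <- mk(1L, 0, 0, flip_frame <= 1L)
  f2 <- mk(2L, dt, progress, flip_frame <= 2L)
  t1 <- if (flip_frame == 2L)
    data.frame(frame = 2L, lost_a = 1, lost_b = 2, gained_a = 3, gained_b = 4)
  else NULL
  tracked_tissue(list(f1, f2), t1_events = t1)
}
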