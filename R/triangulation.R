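## Triangulation of the cell network ------------------------------------------

#' Tile a cell network with triangles from cell centers
#'
#' Every interior vertex of the cellular network touching three cells
#' gives one triangle whose corners are the three cell centers.  A k-fold
#' vertex (k > 3) is decomposed deterministically: the k-gon of adjacent
#' cell centers (in the vertex's cyclic cell order, oriented
#' counter-clockwise) is fan-triangulated from the lowest cell id.  The
#' resulting triangles tile the region spanned by the cell centers without
#' gaps or overlaps.
#'
#' Degenerate (collinear-center) triangles are kept in the table but
#' flagged, and are excluded from averages by [mean_elongation()] with a
#' warning.
#'
#' @param frame A [cell_network_frame()].
#' @param cells Optional vector of cell ids; only vertices all of whose
#'   incident cells are in this set are used (ROI restriction).
#' @param interior_only Use only vertices flagged interior (default
#'   `TRUE`); margin vertices have incomplete cell sets.
#' @return A data frame of class `triangulation`: one row per triangle
#'   with columns `triangle_id`, `vertex_id`, `c1`, `c2`, `c3` (cell ids,
#'   counter-clockwise), corner coordinates `x1..y3`, `area`, `theta`,
#'   `qxx`, `qxy`, `degenerate`, plus attributes `frame_index`, `time` and
#'   `total_area`.
#' @export
triangulate_frame <- function(frame, cells = NULL, interior_only = TRUE) {
  vc <- frame$vertex_cells
  use <- frame$vertices$vertex_id
  if (interior_only) use <- frame$vertices$vertex_id[frame$vertices$interior]
  if (!is.null(cells)) {
    bad <- unique(vc$vertex_id[!(vc$cell_id %in% cells)])
    use <- setdiff(use, bad)
  }
  vc <- vc[vc$vertex_id %in% use, ]
  vc <- vc[order(vc$vertex_id, vc$ord), ]
  trips <- .vertex_triples(vc)
  .triangulation_from_triples(trips, frame)
}

## Split each vertex's cyclic cell ring into triangles (fan from the
## lowest cell id for k > 3).  `vc` must be ordered by (vertex_id, ord).
.vertex_triples <- function(vc) {
  if (!nrow(vc))
    return(data.frame(vertex_id = integer(0), c1 = integer(0),
                      c2 = integer(0), c3 = integer(0)))
  rings <- split(vc$cell_id, vc$vertex_id)
  out <- lapply(names(rings), function(vid) {
    ring <- rings[[vid]]
    k <- length(ring)
    if (k < 3) return(NULL)
    if (k > 3) {   # rotate so the lowest id leads, keep cyclic order
      i0 <- which.min(ring)
      ring <- ring[c(i0:k, seq_len(i0 - 1))]
    }
    data.frame(vertex_id = rep(vid, k - 2),
               c1 = ring[1], c2 = ring[2:(k - 1)], c3 = ring[3:k])
  })
  do.call(rbind, out)
}

.triangulation_from_triples <- function(trips, frame) {
  cells <- frame$cells
  i1 <- match(trips$c1, cells$cell_id)
  i2 <- match(trips$c2, cells$cell_id)
  i3 <- match(trips$c3, cells$cell_id)
  if (anyNA(c(i1, i2, i3))) stop("triangle references unknown cell id")
  x1 <- cells$x[i1]; y1 <- cells$y[i1]
  x2 <- cells$x[i2]; y2 <- cells$y[i2]
  x3 <- cells$x[i3]; y3 <- cells$y[i3]
  ## orient counter-clockwise
  sa <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- sa < 0
  tmp <- trips$c2[flip]; trips$c2[flip] <- trips$c3[flip]; trips$c3[flip] <- tmp
  tmpx <- x2[flip]; x2[flip] <- x3[flip]; x3[flip] <- tmpx
  tmpy <- y2[flip]; y2[flip] <- y3[flip]; y3[flip] <- tmpy
  st <- triangle_state(x1, y1, x2, y2, x3, y3)
  res <- data.frame(triangle_id = seq_len(nrow(trips)),
                    vertex_id = trips$vertex_id,
                    c1 = trips$c1, c2 = trips$c2, c3 = trips$c3,
                    x1 = x1, y1 = y1, x2 = x2, y2 = y2, x3 = x3, y3 = y3,
                    area = st$area, theta = st$theta,
                    qxx = st$qxx, qxy = st$qxy, degenerate = st$degenerate)
  structure(res, class = c("triangulation", "data.frame"),
            frame_index = frame$frame_index, time = frame$time,
            total_area = sum(st$area[!st$degenerate]))
}

## Canonical key for a triangle: cell triplet, order-independent.
.tri_key <- function(c1, c2, c3) {
  a <- pmin(c1, c2, c3)
  c_ <- pmax(c1, c2, c3)
  b <- as.numeric(c1) + as.numeric(c2) + as.numeric(c3) -
    as.numeric(a) - as.numeric(c_)
  paste(a, b, c_, sep = "|")
}

#' Area-weighted mean elongation of a triangulation
#'
#' The average of the triangle elongation nematics weighted by triangle
#' area, so that the triangle average equals the tissue-scale deformation
#' of the tiled region.
#'
#' @param tri A `triangulation` (or any data frame with `area`, `qxx`,
#'   `qxy`, `degenerate`).
#' @param cell Optional cell id: average only over triangles having this
#'   cell as a corner (per-cell elongation).
#' @return A list with `qxx`, `qxy` and `total_area`.
#' @export
mean_elongation <- function(tri, cell = NULL) {
  if (!is.null(cell))
    tri <- tri[tri$c1 == cell | tri$c2 == cell | tri$c3 == cell, ]
  if (!nrow(tri)) stop("empty triangulation")
  if (any(tri$degenerate)) {
    warning(sum(tri$degenerate), " degenerate triangle(s) excluded")
    tri <- tri[!tri$degenerate, ]
  }
  w <- tri$area / sum(tri$area)
  list(qxx = sum(w * tri$qxx), qxy = sum(w * tri$qxy),
       total_area = sum(tri$area))
}
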