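## Tracked cell-network data model and I/O ------------------------------------

#' Construct a single-time-point cell network
#'
#' @param frame_index Integer frame number (0-based or 1-based, but
#'   consecutive across a [tracked_tissue()]).
#' @param time Time of the frame in hours (hAPF).
#' @param cells Data frame with columns `cell_id`, `x`, `y` (um, cell
#'   center), `area` (um^2) and optionally `boundary` (logical; cells on
#'   the tissue margin, excluded from triangulation-based averages).
#' @param neighbors Data frame with columns `cell_id`, `ord`, `neighbor_id`
#'   giving each cell's neighbors in counter-clockwise cyclic order.
#' @param vertices Data frame with columns `vertex_id`, `x`, `y` and
#'   `interior` (logical; vertices whose full set of incident cells is
#'   known).
#' @param vertex_cells Data frame with columns `vertex_id`, `ord`,
#'   `cell_id`: the cells incident to each vertex in cyclic order.  Every
#'   interior vertex must touch at least three cells.
#' @return An object of class `cell_network_frame`.
#' @export
cell_network_frame <- function(frame_index, time, cells, neighbors,
                               vertices, vertex_cells) {
  if (is.null(cells$boundary)) cells$boundary <- FALSE
  structure(list(frame_index = as.integer(frame_index), time = time,
                 cells = cells, neighbors = neighbors,
                 vertices = vertices, vertex_cells = vertex_cells),
            class = "cell_network_frame")
}

#' @export
print.cell_network_frame <- function(x, ...) {
  cat(sprintf("<cell_network_frame> frame %d, t = %.3f h: %d cells, %d vertices\n",
              x$frame_index, x$time, nrow(x$cells), nrow(x$vertices)))
  invisible(x)
}

#' Construct a tracked tissue (time-lapse cell network)
#'
#' Cell ids are stable across frames between birth and loss.  Divisions are
#' recorded in `lineage`; an event recorded at frame `f` happened in the
#' interval between frames `f - 1` and `f` (daughters exist from frame `f`
#' on; an extruded cell is last seen at `f - 1`).
#'
#' @param frames List of [cell_network_frame()] objects, ordered in time.
#' @param lineage Data frame `mother`, `daughter1`, `daughter2`, `frame`.
#' @param extrusions Data frame `cell_id`, `frame`.
#' @param t1_events Data frame `frame`, `lost_a`, `lost_b`, `gained_a`,
#'   `gained_b`: the cell pair losing contact and the pair gaining the
#'   reciprocal contact.
#' @param roi Data frame `cell_id`, `roi` assigning cells to named regions
#'   of interest.
#' @return An object of class `tracked_tissue`.
#' @export
tracked_tissue <- function(frames, lineage = NULL, extrusions = NULL,
                           t1_events = NULL, roi = NULL) {
  empty <- function(...) {
    cols <- c(...)
    as.data.frame(setNames(rep(list(integer(0)), length(cols)), cols))
  }
  if (is.null(lineage)) lineage <- empty("mother", "daughter1", "daughter2", "frame")
  if (is.null(extrusions)) extrusions <- empty("cell_id", "frame")
  if (is.null(t1_events)) t1_events <- empty("frame", "lost_a", "lost_b",
                                             "gained_a", "gained_b")
  if (is.null(roi)) {
    ids <- sort(unique(unlist(lapply(frames, function(f) f$cells$cell_id))))
    roi <- data.frame(cell_id = ids, roi = "all")
  }
  structure(list(frames = frames, lineage = lineage, extrusions = extrusions,
                 t1_events = t1_events, roi = roi),
            class = "tracked_tissue")
}

#' @export
print.tracked_tissue <- function(x, ...) {
  cat(sprintf(paste0("<tracked_tissue> %d frames (t = %.2f..%.2f h), ",
                     "%d divisions, %d extrusions, %d T1 events\n"),
              length(x$frames), x$frames[[1]]$time,
              x$frames[[length(x$frames)]]$time,
              nrow(x$lineage), nrow(x$extrusions), nrow(x$t1_events)))
  invisible(x)
}

## Unordered adjacency pairs of a frame as a character key vector "a|b", a < b.
.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

.adjacency_keys <- function(frame, within = NULL) {
  nb <- frame$neighbors
  if (!is.null(within))
    nb <- nb[nb$cell_id %in% within & nb$neighbor_id %in% within, ]
  unique(.pair_key(nb$cell_id, nb$neighbor_id))
}

#' Validate a tracked tissue
#'
#' Checks the structural invariants: symmetric neighbor relation,
#' counter-clockwise neighbor order for interior cells, positive cell
#' areas, interior vertices touching at least three cells, stable cell
#' ids, and consistency of recorded division/extrusion/T1 events with the
#' topology difference of adjacent frames.
#'
#' @param tissue A [tracked_tissue()].
#' @return `tissue`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_tissue <- function(tissue) {
  stopifnot(inherits(tissue, "tracked_tissue"))
  for (fr in tissue$frames) {
    if (any(fr$cells$area <= 0))
      stop("frame ", fr$frame_index, ": non-positive cell area")
    key_f <- .pair_key(fr$neighbors$cell_id, fr$neighbors$neighbor_id)
    key_r <- .pair_key(fr$neighbors$neighbor_id, fr$neighbors$cell_id)
    tab <- table(key_f)
    if (any(tab != 2L))
      stop("frame ", fr$frame_index, ": non-symmetric neighbor relation")
    nvc <- table(fr$vertex_cells$vertex_id)
    int_ids <- fr$vertices$vertex_id[fr$vertices$interior]
    if (length(int_ids) && any(nvc[as.character(int_ids)] < 3L))
      stop("frame ", fr$frame_index, ": interior vertex with fewer than 3 cells")
    ## CCW neighbor order around interior cells
    inner <- fr$cells$cell_id[!fr$cells$boundary]
    if (length(inner)) {
      nb <- fr$neighbors[fr$neighbors$cell_id %in% inner, ]
      nb <- nb[order(nb$cell_id, nb$ord), ]
      idx <- match(nb$neighbor_id, fr$cells$cell_id)
      for (cid in unique(nb$cell_id)) {
        sel <- nb$cell_id == cid
        if (sum(sel) >= 3) {
          a <- .polygon_area(fr$cells$x[idx[sel]], fr$cells$y[idx[sel]])
          if (a <= 0)
            stop("frame ", fr$frame_index, ": neighbor order of cell ", cid,
                 " is not counter-clockwise")
        }
      }
    }
  }
  .check_events(tissue)
  invisible(tissue)
}

## Event/topology consistency between adjacent frames.
.check_events <- function(tissue) {
  nfr <- length(tissue$frames)
  all_ids <- lapply(tissue$frames, function(f) f$cells$cell_id)
  for (k in seq_len(nfr - 1)) {
    f0 <- tissue$frames[[k]]; f1 <- tissue$frames[[k + 1]]
    fi <- f1$frame_index
    born <- setdiff(all_ids[[k + 1]], all_ids[[k]])
    dead <- setdiff(all_ids[[k]], all_ids[[k + 1]])
    lin <- tissue$lineage[tissue$lineage$frame == fi, , drop = FALSE]
    ext <- tissue$extrusions[tissue$extrusions$frame == fi, , drop = FALSE]
    if (!setequal(born, c(lin$daughter1, lin$daughter2)))
      stop("event/topology mismatch: frame ", fi,
           " has untracked new cells not covered by lineage")
    if (!setequal(dead, c(lin$mother, ext$cell_id)))
      stop("event/topology mismatch: frame ", fi,
           " cell loss not covered by lineage/extrusion records")
    shared <- intersect(all_ids[[k]], all_ids[[k + 1]])
    lost <- setdiff(.adjacency_keys(f0, shared), .adjacency_keys(f1, shared))
    gained <- setdiff(.adjacency_keys(f1, shared), .adjacency_keys(f0, shared))
    t1 <- tissue$t1_events[tissue$t1_events$frame == fi, , drop = FALSE]
    if (nrow(t1)) {
      rec_lost <- .pair_key(t1$lost_a, t1$lost_b)
      rec_gain <- .pair_key(t1$gained_a, t1$gained_b)
      if (!all(rec_lost %in% lost) || !all(rec_gain %in% gained))
        stop("event/topology mismatch: recorded T1 at frame ", fi,
             " not present in the topology difference")
    }
  }
  ## orphan lineage entries
  known <- unique(unlist(all_ids))
  bad <- !(tissue$lineage$mother %in% known)
  if (any(bad)) stop("orphan lineage entries: unknown mother cell id")
  invisible(tissue)
}

#' Detect topological events by diffing adjacent-frame topology
#'
#' Populates the division, extrusion and T1 lists of a tracked tissue by
#' comparing cell presence and cell-cell adjacency between consecutive
#' frames.  A T1 transition is a lost cell-cell contact plus a reciprocal
#' gained contact among the same four cells; divisions are taken from the
#' lineage table (and checked against cell appearance); a cell whose id
#' disappears without daughters is an extrusion (T2).
#'
#' Lost/gained contacts that cannot be paired into a T1 pattern are kept
#' in `attr(tissue$t1_events, "ambiguous")` and flagged with a warning,
#' not silently resolved.
#'
#' @param tissue A [tracked_tissue()].
#' @return The tissue with `extrusions` and `t1_events` repopulated.
#' @export
detect_events <- function(tissue) {
  stopifnot(inherits(tissue, "tracked_tissue"))
  nfr <- length(tissue$frames)
  all_ids <- lapply(tissue$frames, function(f) f$cells$cell_id)
  ext <- list(); t1 <- list(); amb <- list()
  for (k in seq_len(nfr - 1)) {
    f0 <- tissue$frames[[k]]; f1 <- tissue$frames[[k + 1]]
    fi <- f1$frame_index
    dead <- setdiff(all_ids[[k]], all_ids[[k + 1]])
    lin <- tissue$lineage[tissue$lineage$frame == fi, , drop = FALSE]
    extruded <- setdiff(dead, lin$mother)
    if (length(extruded))
      ext[[length(ext) + 1]] <- data.frame(cell_id = extruded, frame = fi)
    shared <- intersect(all_ids[[k]], all_ids[[k + 1]])
    k0 <- .adjacency_keys(f0, shared); k1 <- .adjacency_keys(f1, shared)
    lost <- setdiff(k0, k1); gained <- setdiff(k1, k0)
    if (length(lost) || length(gained)) {
      nb0 <- f0$neighbors
      nbr_of <- function(c) nb0$neighbor_id[nb0$cell_id == c]
      g_used <- rep(FALSE, length(gained))
      gl <- strsplit(gained, "|", fixed = TRUE)
      for (lk in lost) {
        ab <- strsplit(lk, "|", fixed = TRUE)[[1]]
        common <- intersect(nbr_of(ab[1]), nbr_of(ab[2]))
        hit <- which(!g_used & vapply(gl, function(cd)
          all(cd %in% as.character(common)), logical(1)))
        if (length(hit) >= 1) {
          cd <- gl[[hit[1]]]; g_used[hit[1]] <- TRUE
          t1[[length(t1) + 1]] <- data.frame(
            frame = fi, lost_a = ab[1], lost_b = ab[2],
            gained_a = cd[1], gained_b = cd[2])
        } else {
          amb[[length(amb) + 1]] <- data.frame(frame = fi, kind = "lost",
                                               pair = lk)
        }
      }
      for (gk in gained[!g_used])
        amb[[length(amb) + 1]] <- data.frame(frame = fi, kind = "gained",
                                             pair = gk)
    }
  }
  tissue$extrusions <- if (length(ext)) do.call(rbind, ext) else
    tissue$extrusions[0, ]
  t1df <- if (length(t1)) do.call(rbind, t1) else
    data.frame(frame = integer(0), lost_a = character(0),
               lost_b = character(0), gained_a = character(0),
               gained_b = character(0))
  ## keep ids in the native type of the cell table
  proto <- tissue$frames[[1]]$cells$cell_id
  if (is.numeric(proto) && nrow(t1df))
    for (cl in c("lost_a", "lost_b", "gained_a", "gained_b"))
      t1df[[cl]] <- if (is.integer(proto)) as.integer(t1df[[cl]]) else
        as.numeric(t1df[[cl]])
  if (length(amb)) {
    attr(t1df, "ambiguous") <- do.call(rbind, amb)
    warning("ambiguous topology changes flagged in attr(t1_events, 'ambiguous')")
  }
  tissue$t1_events <- t1df
  tissue
}

#' Cell ids belonging to a region of interest
#' @param tissue A [tracked_tissue()].
#' @param roi ROI name, or `NULL` for all cells.
#' @return Vector of cell ids.
#' @export
roi_cells <- function(tissue, roi = NULL) {
  if (is.null(roi)) return(tissue$roi$cell_id)
  tissue$roi$cell_id[tissue$roi$roi == roi]
}
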