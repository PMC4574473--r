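## On-disk schema for tracked tissues -----------------------------------------
##
## Two dialects of one relational schema:
##   * a directory of CSV files (always available), and
##   * a single SQLite database (one file per video) via RSQLite.
## Tables: frames(frame_index, time), cells(frame_index, cell_id, x, y,
## area, boundary), neighbors(frame_index, cell_id, ord, neighbor_id),
## vertices(frame_index, vertex_id, x, y, interior),
## vertex_cells(frame_index, vertex_id, ord, cell_id),
## lineage(mother, daughter1, daughter2, frame), extrusions(cell_id, frame),
## t1_events(frame, lost_a, lost_b, gained_a, gained_b), roi(cell_id, roi).

## Bonds of a frame, derived from the vertex rings: each adjacent cell
## pair, with the (up to two) vertices flanking the shared boundary.
.frame_bonds <- function(frame) {
  vc <- frame$vertex_cells
  vc <- vc[order(vc$vertex_id, vc$ord), ]
  rings <- split(vc$cell_id, vc$vertex_id)
  prs <- do.call(rbind, lapply(names(rings), function(vid) {
    ring <- rings[[vid]]
    nxt <- c(ring[-1], ring[1])
    data.frame(a = pmin(ring, nxt), b = pmax(ring, nxt),
               vertex_id = as.integer(vid))
  }))
  key <- paste(prs$a, prs$b, sep = "|")
  agg <- split(prs$vertex_id, key)
  ab <- do.call(rbind, strsplit(names(agg), "|", fixed = TRUE))
  data.frame(bond_id = seq_along(agg),
             cell_a = as.numeric(ab[, 1]), cell_b = as.numeric(ab[, 2]),
             vertex_1 = vapply(agg, `[`, integer(1), 1),
             vertex_2 = vapply(agg, function(v)
               if (length(v) > 1) v[2] else NA_integer_, integer(1)),
             row.names = NULL)
}

.tissue_tables <- function(tissue) {
  bindfr <- function(get) do.call(rbind, lapply(tissue$frames, get))
  list(
    frames = data.frame(
      frame_index = vapply(tissue$frames, `[[`, integer(1), "frame_index"),
      time = vapply(tissue$frames, `[[`, numeric(1), "time")),
    cells = bindfr(function(f) cbind(frame_index = f$frame_index, f$cells)),
    neighbors = bindfr(function(f) cbind(frame_index = f$frame_index,
                                         f$neighbors)),
    vertices = bindfr(function(f) cbind(frame_index = f$frame_index,
                                        f$vertices)),
    vertex_cells = bindfr(function(f) cbind(frame_index = f$frame_index,
                                            f$vertex_cells)),
    bonds = bindfr(function(f) cbind(frame_index = f$frame_index,
                                     .frame_bonds(f))),
    lineage = tissue$lineage, extrusions = tissue$extrusions,
    t1_events = tissue$t1_events, roi = tissue$roi)
}

.tissue_from_tables <- function(tb, validate = TRUE) {
  frames <- lapply(seq_len(nrow(tb$frames)), function(i) {
    fi <- tb$frames$frame_index[i]
    cells <- tb$cells[tb$cells$frame_index == fi, -1, drop = FALSE]
    if (!is.null(cells$boundary))
      cells$boundary <- as.logical(cells$boundary)
    verts <- tb$vertices[tb$vertices$frame_index == fi, -1, drop = FALSE]
    verts$interior <- as.logical(verts$interior)
    cell_network_frame(
      frame_index = fi, time = tb$frames$time[i],
      cells = `rownames<-`(cells, NULL),
      neighbors = `rownames<-`(
        tb$neighbors[tb$neighbors$frame_index == fi, -1, drop = FALSE], NULL),
      vertices = `rownames<-`(verts, NULL),
      vertex_cells = `rownames<-`(
        tb$vertex_cells[tb$vertex_cells$frame_index == fi, -1, drop = FALSE],
        NULL))
  })
  tis <- tracked_tissue(frames, lineage = tb$lineage,
                        extrusions = tb$extrusions,
                        t1_events = tb$t1_events, roi = tb$roi)
  if (validate) validate_tissue(tis)
  tis
}

#' Write a tracked tissue to disk
#'
#' @param tissue A [tracked_tissue()].
#' @param path Directory (CSV dialect) or file path (SQLite dialect).
#' @param format `"csv"` or `"sqlite"`; `"sqlite"` needs the RSQLite
#'   package.
#' @return `path`, invisibly.
#' @seealso [read_tracked_tissue()]
#' @export
write_tracked_tissue <- function(tissue, path, format = c("csv", "sqlite")) {
  format <- match.arg(format)
  tb <- .tissue_tables(tissue)
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tb)) {
      df <- tb[[nm]]
      for (cl in names(df))                  # full-precision round trip
        if (is.double(df[[cl]])) df[[cl]] <- format(df[[cl]], digits = 17)
      write.csv(df, file.path(path, paste0(nm, ".csv")), row.names = FALSE)
    }
  } else {
    if (!requireNamespace("RSQLite", quietly = TRUE))
      stop("the sqlite dialect needs the RSQLite package")
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    for (nm in names(tb))
      DBI::dbWriteTable(con, nm, tb[[nm]], overwrite = TRUE)
  }
  invisible(path)
}

#' Read a tracked tissue from disk
#'
#' Reads the relational schema written by [write_tracked_tissue()] (a
#' directory of CSV tables or a single SQLite file), validates all
#' structural invariants and rejects inconsistent event records.
#'
#' @param path Directory or SQLite file path.
#' @param validate Run [validate_tissue()] on the result (default `TRUE`).
#' @return A [tracked_tissue()].
#' @export
read_tracked_tissue <- function(path, validate = TRUE) {
  required <- c("frames", "cells", "neighbors", "vertices", "vertex_cells",
                "bonds", "lineage", "extrusions", "t1_events", "roi")
  if (dir.exists(path)) {
    files <- file.path(path, paste0(required, ".csv"))
    missing <- required[!file.exists(files)]
    if (length(missing))
      stop("missing tables: ", paste(missing, collapse = ", "))
    tb <- setNames(lapply(files, read.csv), required)
  } else if (file.exists(path)) {
    if (!requireNamespace("RSQLite", quietly = TRUE))
      stop("the sqlite dialect needs the RSQLite package")
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    have <- DBI::dbListTables(con)
    missing <- setdiff(required, have)
    if (length(missing))
      stop("missing tables: ", paste(missing, collapse = ", "))
    tb <- setNames(lapply(required, function(nm) DBI::dbReadTable(con, nm)),
                   required)
  } else stop("no such path: ", path)
  required_cols <- list(
    cells = c("frame_index", "cell_id", "x", "y", "area"),
    neighbors = c("frame_index", "cell_id", "ord", "neighbor_id"),
    vertices = c("frame_index", "vertex_id", "x", "y", "interior"),
    vertex_cells = c("frame_index", "vertex_id", "ord", "cell_id"))
  for (nm in names(required_cols)) {
    miss <- setdiff(required_cols[[nm]], names(tb[[nm]]))
    if (length(miss))
      stop("table ", nm, " is missing columns: ", paste(miss, collapse = ", "))
  }
  .tissue_from_tables(tb, validate = validate)
}
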