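#' Sheet geometry: a lattice of minicolumns grouped into macrocolumns
#'
#' Builds the spatial scaffold of the model: an \code{n_rows} by \code{n_cols}
#' lattice of minicolumns (pitch \code{pitch_um} micrometres), tiled into
#' square macrocolumns of \code{macro_edge} minicolumns per side.  Units are
#' indexed 1..n in row-major order (row varies slowest).
#'
#' @param n_rows,n_cols minicolumn counts; both must be divisible by
#'   \code{macro_edge}.
#' @param macro_edge minicolumns per macrocolumn side (default 10, giving the
#'   canonical 10x10-minicolumn macrocolumn).
#' @param pitch_um centre-to-centre minicolumn spacing in micrometres.
#' @param boundary \code{"torus"} (distances use the minimal image, no edges)
#'   or \code{"zero_flux"} (plain planar Euclidean distance; edge units simply
#'   lack some neighbours).
#' @return An object of class \code{sheet_geometry}.
#' @examples
#' g <- sheet_geometry(30, 30)
#' g$n_units
#' @export
sheet_geometry <- function(n_rows, n_cols, macro_edge = 10, pitch_um = 50,
                           boundary = c("torus", "zero_flux")) {
  boundary <- match.arg(boundary)
  stopifnot(n_rows >= 1, n_cols >= 1, macro_edge >= 1, pitch_um > 0)
  if (n_rows %% macro_edge != 0 || n_cols %% macro_edge != 0)
    stop("n_rows and n_cols must be divisible by macro_edge")
  n <- n_rows * n_cols
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  # macrocolumn index, row-major over macro blocks
  mrow <- (row - 1L) %/% macro_edge
  mcol <- (col - 1L) %/% macro_edge
  macro <- mrow * (n_cols %/% macro_edge) + mcol + 1L
  g <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    macro_edge = as.integer(macro_edge), pitch_um = pitch_um,
    boundary = boundary, n_units = as.integer(n),
    row = row, col = col, macro = as.integer(macro),
    n_macros = as.integer((n_rows %/% macro_edge) * (n_cols %/% macro_edge))
  )
  class(g) <- "sheet_geometry"
  g
}

#' @export
print.sheet_geometry <- function(x, ...) {
  cat(sprintf("<sheet_geometry> %d x %d minicolumns (%d units), %d macrocolumns (%dx%d each),\n",
              x$n_rows, x$n_cols, x$n_units, x$n_macros, x$macro_edge, x$macro_edge))
  cat(sprintf("  pitch %g um, %s boundary\n", x$pitch_um, x$boundary))
  invisible(x)
}

#' Unit index from (row, col)
#'
#' @param geom a \code{sheet_geometry}.
#' @param row,col 1-based lattice coordinates (vectorised).
#' @return integer unit indices.
#' @export
unit_index <- function(geom, row, col) {
  stopifnot(all(row >= 1 & row <= geom$n_rows), all(col >= 1 & col <= geom$n_cols))
  as.integer((row - 1L) * geom$n_cols + col)
}

#' Unit centre coordinates in micrometres
#'
#' @param geom a \code{sheet_geometry}.
#' @param ids unit indices (default all).
#' @return two-column matrix (x = column direction, y = row direction), um.
#' @export
unit_coords <- function(geom, ids = seq_len(geom$n_units)) {
  cbind(x = (geom$col[ids] - 1) * geom$pitch_um,
        y = (geom$row[ids] - 1) * geom$pitch_um)
}

#' Pairwise distance between units under the geometry's metric
#'
#' Torus geometry uses the minimal-image convention; zero-flux uses plain
#' Euclidean distance.  Vectorised over pairs (\code{i}, \code{j} recycled).
#'
#' @param geom a \code{sheet_geometry}.
#' @param i,j unit indices.
#' @return distances in micrometres.
#' @export
sheet_distance <- function(geom, i, j) {
  d <- sheet_displacement(geom, i, j)
  unname(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Displacement vector from unit i to unit j (um), minimal image on a torus
#'
#' @inheritParams sheet_distance
#' @return two-column matrix of (dx, dy) in micrometres.
#' @export
sheet_displacement <- function(geom, i, j) {
  dx <- (geom$col[j] - geom$col[i]) * geom$pitch_um
  dy <- (geom$row[j] - geom$row[i]) * geom$pitch_um
  if (geom$boundary == "torus") {
    Lx <- geom$n_cols * geom$pitch_um
    Ly <- geom$n_rows * geom$pitch_um
    dx <- dx - Lx * round(dx / Lx)
    dy <- dy - Ly * round(dy / Ly)
  }
  cbind(dx = dx, dy = dy)
}

#' Lattice offsets within a Euclidean radius
#'
#' Enumerates all integer lattice offsets (dr, dc) with
#' \code{sqrt(dr^2 + dc^2) <= radius_units}.  For radius 5 this disc contains
#' 81 offsets, the canonical patch footprint.
#'
#' @param radius_units radius in units of the lattice pitch.
#' @return two-column integer matrix of offsets (includes the origin).
#' @export
lattice_disc_offsets <- function(radius_units) {
  stopifnot(radius_units >= 0)
  r <- floor(radius_units)
  dr <- rep(-r:r, each = 2 * r + 1)
  dc <- rep(-r:r, times = 2 * r + 1)
  keep <- dr^2 + dc^2 <= radius_units^2
  cbind(dr = dr[keep], dc = dc[keep])
}

#' Units within a lattice disc around a centre unit
#'
#' @param geom a \code{sheet_geometry}.
#' @param center unit index.
#' @param radius_units disc radius in lattice pitches.
#' @return integer unit indices (on zero-flux sheets, offsets falling outside
#'   the sheet are dropped; on a torus they wrap).
#' @export
disc_members <- function(geom, center, radius_units) {
  off <- lattice_disc_offsets(radius_units)
  r <- geom$row[center] + off[, "dr"]
  c <- geom$col[center] + off[, "dc"]
  if (geom$boundary == "torus") {
    r <- ((r - 1L) %% geom$n_rows) + 1L
    c <- ((c - 1L) %% geom$n_cols) + 1L
  } else {
    keep <- r >= 1 & r <= geom$n_rows & c >= 1 & c <= geom$n_cols
    r <- r[keep]; c <- c[keep]
  }
  sort(unique(unit_index(geom, r, c)))
}

#' Macrocolumn centre units
#'
#' @param geom a \code{sheet_geometry}.
#' @return integer vector, one unit index per macrocolumn (closest unit to the
#'   geometric block centre).
#' @export
macro_centers <- function(geom) {
  me <- geom$macro_edge
  nmc <- geom$n_cols %/% me
  vapply(seq_len(geom$n_macros), function(m) {
    mrow <- (m - 1L) %/% nmc
    mcol <- (m - 1L) %% nmc
    r <- mrow * me + (me + 1L) %/% 2L
    c <- mcol * me + (me + 1L) %/% 2L
    unit_index(geom, r, c)
  }, integer(1))
}

#' Direct (4-neighbourhood) macrocolumn neighbours
#'
#' @param geom a \code{sheet_geometry}.
#' @param m macrocolumn index.
#' @return integer vector of neighbouring macrocolumn indices; on a torus all
#'   four exist, under zero-flux only those inside the sheet.
#' @export
macro_neighbours <- function(geom, m) {
  nmc <- geom$n_cols %/% geom$macro_edge
  nmr <- geom$n_rows %/% geom$macro_edge
  mrow <- (m - 1L) %/% nmc
  mcol <- (m - 1L) %% nmc
  cand <- rbind(c(mrow - 1L, mcol), c(mrow + 1L, mcol),
                c(mrow, mcol - 1L), c(mrow, mcol + 1L))
  if (geom$boundary == "torus") {
    cand[, 1] <- cand[, 1] %% nmr
    cand[, 2] <- cand[, 2] %% nmc
  } else {
    keep <- cand[, 1] >= 0 & cand[, 1] < nmr & cand[, 2] >= 0 & cand[, 2] < nmc
    cand <- cand[keep, , drop = FALSE]
  }
  unique(as.integer(cand[, 1] * nmc + cand[, 2] + 1L))
}
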