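#' Connectivity generator parameters
#'
#' Parameters of the three-type mesoscopic connectivity: dense local
#' excitatory (E->E) and local feed-forward inhibitory (E->I) connections with
#' a Gaussian distance fall-off and a hard cutoff radius, plus remote patchy
#' excitatory projections organised per macrocolumn.
#'
#' @param sigma_um std of the Gaussian connection-probability fall-off, um.
#' @param local_radius_um hard cutoff for local connections, um.
#' @param n_patches_per_macro remote patches owned by each macrocolumn.
#' @param patch_radius_units patch radius in minicolumns (lattice pitches).
#' @param max_patch_distance_um maximal distance from a macrocolumn centre at
#'   which its patch centres are placed.
#' @param n_out_remote outgoing remote connections drawn per minicolumn
#'   (duplicates collapse, so this is a cap on the remote out-degree).
#' @param n_shared_patches patches each macrocolumn reuses from one direct
#'   neighbouring macrocolumn.
#' @param w_local,w_remote,w_self_e connection weights: local (E->E and E->I),
#'   remote E->E, and the self-excitation placed on the diagonal of the E->E
#'   matrix.
#' @return an object of class \code{connectivity_params}.
#' @seealso [standard_connectivity_params()] for the packaged preset.
#' @export
connectivity_params <- function(sigma_um, local_radius_um,
                                n_patches_per_macro, patch_radius_units,
                                max_patch_distance_um, n_out_remote,
                                n_shared_patches,
                                w_local, w_remote, w_self_e) {
  stopifnot(sigma_um > 0, local_radius_um > 0, n_patches_per_macro >= 0,
            patch_radius_units >= 0, max_patch_distance_um > 0,
            n_out_remote >= 0, n_shared_patches >= 0,
            n_shared_patches <= n_patches_per_macro,
            w_local >= 0, w_remote >= 0, w_self_e >= 0)
  structure(list(sigma_um = sigma_um, local_radius_um = local_radius_um,
                 n_patches_per_macro = n_patches_per_macro,
                 patch_radius_units = patch_radius_units,
                 max_patch_distance_um = max_patch_distance_um,
                 n_out_remote = n_out_remote,
                 n_shared_patches = n_shared_patches,
                 w_local = w_local, w_remote = w_remote, w_self_e = w_self_e),
            class = "connectivity_params")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Sample local connections with Gaussian distance fall-off
#'
#' Every ordered pair (i -> j), i != j, at distance d <= \code{radius_um}
#' under the geometry's metric is connected independently with probability
#' \code{exp(-d^2 / (2 sigma_um^2))}.  No connections beyond the cutoff and
#' no self-connections (self-coupling lives on the matrix diagonal).
#'
#' @param geom a \code{sheet_geometry}.
#' @param sigma_um Gaussian fall-off std, um.
#' @param radius_um hard cutoff, um.
#' @param seed integer seed; the same seed regenerates the same adjacency.
#' @return sparse logical adjacency (\code{ngCMatrix}), entry (i, j) = TRUE
#'   meaning i projects to j.
#' @export
sample_local_connections <- function(geom, sigma_um, radius_um, seed) {
  stopifnot(sigma_um > 0, radius_um > 0)
  r_units <- radius_um / geom$pitch_um
  off <- lattice_disc_offsets(r_units)
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  d_um <- sqrt(off[, 1]^2 + off[, 2]^2) * geom$pitch_um
  p <- exp(-d_um^2 / (2 * sigma_um^2))
  n <- geom$n_units
  with_seed(seed, {
    from_all <- integer(0); to_all <- integer(0)
    for (k in seq_len(nrow(off))) {
      r2 <- geom$row + off[k, 1]
      c2 <- geom$col + off[k, 2]
      if (geom$boundary == "torus") {
        r2 <- ((r2 - 1L) %% geom$n_rows) + 1L
        c2 <- ((c2 - 1L) %% geom$n_cols) + 1L
        ok <- rep(TRUE, n)
      } else {
        ok <- r2 >= 1 & r2 <= geom$n_rows & c2 >= 1 & c2 <= geom$n_cols
      }
      draw <- stats::runif(n) < p[k]
      sel <- which(ok & draw)
      if (length(sel)) {
        from_all <- c(from_all, sel)
        to_all <- c(to_all, unit_index(geom, r2[sel], c2[sel]))
      }
    }
    Matrix::sparseMatrix(i = from_all, j = to_all, x = TRUE,
                         dims = c(n, n))
  })
}

#' Sample remote patchy connections
#'
#' Per macrocolumn, \code{n_patches_per_macro} patch centres are drawn
#' uniformly among units within \code{max_patch_distance_um} of the
#' macrocolumn centre; \code{n_shared_patches} of them are replaced by
#' patches reused from one uniformly chosen direct neighbouring macrocolumn
#' (which can carry targets beyond the distance bound).  A patch consists of
#' all units within \code{patch_radius_units} of its centre.  Each minicolumn
#' then draws \code{n_out_remote} targets uniformly with replacement from the
#' union of its macrocolumn's patch members, with duplicates (and self hits)
#' collapsed.
#'
#' @param geom a \code{sheet_geometry}.
#' @param params a \code{connectivity_params}.
#' @param seed integer seed.
#' @return list with \code{layout} (class \code{patch_layout}: data.frame of
#'   patches with owner macro, centre unit, shared flag; \code{members} list;
#'   \code{share_partner} integer vector) and \code{adj} (sparse logical
#'   adjacency, i -> j).
#' @export
sample_remote_patches <- function(geom, params, seed) {
  if (params$max_patch_distance_um < params$patch_radius_units * geom$pitch_um)
    stop("max_patch_distance_um must be at least the patch radius in um")
  centers <- macro_centers(geom)
  n_mac <- geom$n_macros
  npm <- params$n_patches_per_macro
  # candidate centre pools
  pools <- lapply(seq_len(n_mac), function(m) {
    d <- sheet_distance(geom, centers[m], seq_len(geom$n_units))
    which(d <= params$max_patch_distance_um)
  })
  if (any(vapply(pools, length, 1L) < npm))
    stop("geometry too small to place ", npm,
         " patches within max_patch_distance_um")
  with_seed(seed, {
    own <- lapply(seq_len(n_mac), function(m)
      sample(pools[[m]], npm, replace = FALSE))
    partner <- vapply(seq_len(n_mac), function(m) {
      nb <- macro_neighbours(geom, m)
      nb[sample.int(length(nb), 1)]
    }, integer(1))
    final <- own
    nsh <- params$n_shared_patches
    if (nsh > 0) {
      for (m in seq_len(n_mac)) {
        shared <- own[[partner[m]]][sample.int(npm, nsh)]
        final[[m]][seq_len(nsh)] <- shared
      }
    }
    all_centers <- unlist(final)
    members <- lapply(all_centers, disc_members, geom = geom,
                      radius_units = params$patch_radius_units)
    layout <- data.frame(
      patch = seq_along(all_centers),
      owner_macro = rep(seq_len(n_mac), each = npm),
      center = all_centers,
      shared = rep(c(rep(TRUE, nsh), rep(FALSE, npm - nsh)), n_mac)
    )
    # per-unit target draws from the union of the owner macro's patch members
    unions <- lapply(seq_len(n_mac), function(m) {
      idx <- which(layout$owner_macro == m)
      sort(unique(unlist(members[idx])))
    })
    n <- geom$n_units
    from_all <- vector("list", n); to_all <- vector("list", n)
    for (i in seq_len(n)) {
      pool <- unions[[geom$macro[i]]]
      tgt <- unique(pool[sample.int(length(pool), params$n_out_remote,
                                    replace = TRUE)])
      tgt <- tgt[tgt != i]
      to_all[[i]] <- tgt
      from_all[[i]] <- rep.int(i, length(tgt))
    }
    adj <- Matrix::sparseMatrix(i = unlist(from_all), j = unlist(to_all),
                                x = TRUE, dims = c(n, n))
    layout_obj <- structure(list(patches = layout, members = members,
                                 share_partner = partner,
                                 own_centers = own, geom = geom),
                            class = "patch_layout")
    list(layout = layout_obj, adj = adj)
  })
}

#' Assemble the four weight matrices of the sheet
#'
#' Builds the coupling structure from sampled adjacencies: the E->E matrix is
#' \code{w_local * local_ee + w_remote * remote_ee} off the diagonal with the
#' self-excitation \code{w_self_e} on the diagonal; the E->I matrix is
#' \code{w_local * local_ei} off the diagonal with the within-unit E->I
#' constant (\code{unit_params$c_ei}) on the diagonal; I->E and I->I are
#' purely diagonal (\code{c_ie}, \code{c_ii}).  Long-range inhibition is not
#' included.  Pairs connected both locally and remotely sum their weights.
#'
#' All matrices are stored in input convention: \code{(w \%*\% u)[i]} is the
#' input to unit i, i.e. the transpose of the sampled i -> j adjacency.
#'
#' @param local_ee,local_ei,remote_ee sparse logical adjacencies (i -> j).
#' @param unit_params a \code{unit_params} (within-unit constants).
#' @param conn_params a \code{connectivity_params} (weights).
#' @param geom the shared \code{sheet_geometry}.
#' @param layout optional \code{patch_layout} carried for provenance.
#' @param seeds optional named list of the seeds used, for provenance.
#' @return an object of class \code{connectivity_model}.
#' @export
assemble_weight_matrices <- function(local_ee, local_ei, remote_ee,
                                     unit_params, conn_params, geom,
                                     layout = NULL, seeds = NULL) {
  n <- geom$n_units
  stopifnot(all(dim(local_ee) == n), all(dim(local_ei) == n),
            all(dim(remote_ee) == n))
  one <- function(m) {
    m <- methods::as(methods::as(m, "dMatrix"), "generalMatrix")
    m@x[] <- 1
    m
  }
  ee_off <- Matrix::t(conn_params$w_local * one(local_ee) +
                      conn_params$w_remote * one(remote_ee))
  ei_off <- Matrix::t(conn_params$w_local * one(local_ei))
  ee_off <- Matrix::drop0(ee_off); Matrix::diag(ee_off) <- 0
  ei_off <- Matrix::drop0(ei_off); Matrix::diag(ei_off) <- 0
  ee_off <- Matrix::drop0(ee_off); ei_off <- Matrix::drop0(ei_off)
  n_local <- Matrix::nnzero(local_ee)
  n_remote <- Matrix::nnzero(remote_ee)
  model <- structure(list(
    geom = geom,
    ee_off = methods::as(ee_off, "CsparseMatrix"),
    ei_off = methods::as(ei_off, "CsparseMatrix"),
    diag_ee = conn_params$w_self_e,
    diag_ei = unit_params$c_ei,
    diag_ie = unit_params$c_ie,
    diag_ii = unit_params$c_ii,
    n_local = n_local, n_remote = n_remote,
    local_remote_ratio = if (n_remote > 0) n_local / n_remote else Inf,
    conn_params = conn_params, layout = layout, seeds = seeds
  ), class = "connectivity_model")
  model
}

#' @export
print.connectivity_model <- function(x, ...) {
  cat(sprintf("<connectivity_model> %d units, %s boundary\n",
              x$geom$n_units, x$geom$boundary))
  cat(sprintf("  local E->E connections: %d, remote E->E: %d (ratio %.2f), local E->I: %d\n",
              x$n_local, x$n_remote, x$local_remote_ratio,
              Matrix::nnzero(x$ei_off)))
  cat(sprintf("  diagonals: self-E %g, E->I %g, I->E %g, I->I %g\n",
              x$diag_ee, x$diag_ei, x$diag_ie, x$diag_ii))
  invisible(x)
}

#' Full weight matrix accessors
#'
#' Return the four coupling matrices including diagonals, in input convention
#' (\code{(w \%*\% state)[i]} = input to unit i).  \code{w_ie} and
#' \code{w_ii} are strictly diagonal.
#'
#' @param model a \code{connectivity_model}.
#' @return a sparse \code{Matrix}.
#' @export
w_ee <- function(model) model$ee_off + Matrix::Diagonal(model$geom$n_units, model$diag_ee)

#' @rdname w_ee
#' @export
w_ei <- function(model) model$ei_off + Matrix::Diagonal(model$geom$n_units, model$diag_ei)

#' @rdname w_ee
#' @export
w_ie <- function(model) Matrix::Diagonal(model$geom$n_units, model$diag_ie)

#' @rdname w_ee
#' @export
w_ii <- function(model) Matrix::Diagonal(model$geom$n_units, model$diag_ii)

#' Build the full connectivity model from presets
#'
#' Convenience wrapper: samples local E->E, local E->I (same algorithm and
#' parameters, independent seed stream) and remote patchy adjacencies, and
#' assembles the weight matrices.
#'
#' @param geom a \code{sheet_geometry}.
#' @param conn_params a \code{connectivity_params}.
#' @param unit_params a \code{unit_params}.
#' @param seed integer master seed; sub-seeds for the three samplers are
#'   derived deterministically from it.
#' @return a \code{connectivity_model}.
#' @export
build_connectivity <- function(geom, conn_params = standard_connectivity_params(),
                               unit_params = standard_unit_params(),
                               seed = 1L) {
  seeds <- list(local_ee = seed, local_ei = seed + 1000003L,
                remote = seed + 2000003L)
  local_ee <- sample_local_connections(geom, conn_params$sigma_um,
                                       conn_params$local_radius_um,
                                       seeds$local_ee)
  local_ei <- sample_local_connections(geom, conn_params$sigma_um,
                                       conn_params$local_radius_um,
                                       seeds$local_ei)
  rem <- sample_remote_patches(geom, conn_params, seeds$remote)
  assemble_weight_matrices(local_ee, local_ei, rem$adj, unit_params,
                           conn_params, geom, layout = rem$layout,
                           seeds = seeds)
}

#' Degree and distance statistics of a connectivity model
#'
#' @param model a \code{connectivity_model}.
#' @param breaks_um distance histogram breaks (um); defaults to one-pitch bins
#'   up to the observed maximum.
#' @return list with per-type (\code{ee_off} split into local+remote is not
#'   recoverable after assembly, so types are \code{ee} and \code{ei})
#'   in/out-degree tables and distance histograms.
#' @export
connection_statistics <- function(model, breaks_um = NULL) {
  geom <- model$geom
  stat_one <- function(m_in) {
    # m_in is input convention: entry (i, j) = weight of j -> i
    tm <- methods::as(m_in, "TsparseMatrix")
    from <- tm@j + 1L; to <- tm@i + 1L
    d <- sheet_distance(geom, from, to)
    br <- breaks_um
    if (is.null(br)) br <- seq(0, max(d) + geom$pitch_um, by = geom$pitch_um)
    list(n = length(from),
         in_degree = tabulate(to, nbins = geom$n_units),
         out_degree = tabulate(from, nbins = geom$n_units),
         distance_hist = graphics::hist(d, breaks = br, plot = FALSE))
  }
  list(ee = stat_one(model$ee_off), ei = stat_one(model$ei_off))
}

segments_cross <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  # proper (open-segment) crossing: touching an endpoint does not count
  o <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- o(q1x, q1y, q2x, q2y, p1x, p1y)
  d2 <- o(q1x, q1y, q2x, q2y, p2x, p2y)
  d3 <- o(p1x, p1y, p2x, p2y, q1x, q1y)
  d4 <- o(p1x, p1y, p2x, p2y, q2x, q2y)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Remove connections that intersect microincision cuts
#'
#' Returns a copy of the model in which every off-diagonal connection whose
#' straight chord between unit centres (minimal-image representative on a
#' torus) properly crosses any cut segment is removed, in all connection
#' types.  Diagonal (within-unit) coupling is untouched.
#'
#' @param model a \code{connectivity_model}.
#' @param cuts numeric matrix with columns \code{x0, y0, x1, y1} (um), one cut
#'   segment per row.
#' @return a \code{connectivity_model} with fewer connections.
#' @export
apply_microincision <- function(model, cuts) {
  cuts <- matrix(as.numeric(cuts), ncol = 4,
                 dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  geom <- model$geom
  xy <- unit_coords(geom)
  if (any(cuts[, c(1, 3)] < -geom$pitch_um) ||
      any(cuts[, c(1, 3)] > geom$n_cols * geom$pitch_um) ||
      any(cuts[, c(2, 4)] < -geom$pitch_um) ||
      any(cuts[, c(2, 4)] > geom$n_rows * geom$pitch_um))
    stop("cut segments must lie within the sheet bounds")
  filter_mat <- function(m_in) {
    tm <- methods::as(m_in, "TsparseMatrix")
    from <- tm@j + 1L; to <- tm@i + 1L
    disp <- sheet_displacement(geom, from, to)
    p1 <- xy[from, , drop = FALSE]
    p2x <- p1[, 1] + disp[, 1]; p2y <- p1[, 2] + disp[, 2]
    cut <- rep(FALSE, length(from))
    for (k in seq_len(nrow(cuts)))
      cut <- cut | segments_cross(p1[, 1], p1[, 2], p2x, p2y,
                                  cuts[k, 1], cuts[k, 2], cuts[k, 3], cuts[k, 4])
    Matrix::sparseMatrix(i = to[!cut], j = from[!cut], x = tm@x[!cut],
                         dims = dim(m_in))
  }
  model$ee_off <- filter_mat(model$ee_off)
  model$ei_off <- filter_mat(model$ei_off)
  model$n_local <- NA_integer_; model$n_remote <- NA_integer_
  model$cuts <- rbind(model$cuts, cuts)
  model
}

#' Export / import a connectivity model as MatrixMarket + metadata
#'
#' Writes \code{ee_off.mtx}, \code{ei_off.mtx}, a JSON sidecar with geometry,
#' diagonal constants, parameters and seeds, and (when present) the patch
#' layout as a CSV.
#'
#' @param model a \code{connectivity_model}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_connectivity <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(model$ee_off, file.path(dir, "ee_off.mtx"))
  Matrix::writeMM(model$ei_off, file.path(dir, "ei_off.mtx"))
  g <- model$geom
  meta <- list(geometry = g[c("n_rows", "n_cols", "macro_edge", "pitch_um",
                              "boundary")],
               diagonals = model[c("diag_ee", "diag_ei", "diag_ie", "diag_ii")],
               conn_params = unclass(model$conn_params),
               seeds = model$seeds)
  jsonlite::write_json(meta, file.path(dir, "connectivity.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$layout)) {
    lay <- model$layout$patches
    lay$members <- vapply(model$layout$members,
                          function(m) paste(m, collapse = " "), "")
    utils::write.csv(lay, file.path(dir, "patches.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "connectivity.json"),
                              simplifyVector = TRUE)
  g <- meta$geometry
  geom <- sheet_geometry(g$n_rows, g$n_cols, g$macro_edge, g$pitch_um,
                         g$boundary)
  model <- structure(list(
    geom = geom,
    ee_off = methods::as(Matrix::readMM(file.path(dir, "ee_off.mtx")),
                         "CsparseMatrix"),
    ei_off = methods::as(Matrix::readMM(file.path(dir, "ei_off.mtx")),
                         "CsparseMatrix"),
    diag_ee = meta$diagonals$diag_ee, diag_ei = meta$diagonals$diag_ei,
    diag_ie = meta$diagonals$diag_ie, diag_ii = meta$diagonals$diag_ii,
    conn_params = do.call(connectivity_params, meta$conn_params),
    seeds = meta$seeds, layout = NULL
  ), class = "connectivity_model")
  model$n_local <- NA_integer_; model$n_remote <- NA_integer_
  model
}
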