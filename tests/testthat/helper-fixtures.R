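# shared fixtures, built once per test session

.fixture_env <- new.env(parent = emptyenv())

small_sheet_fixture <- function(boundary = "torus") {
  key <- paste0("sheet_", boundary)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_test_fixture("small_sheet", seed = 42,
                                             boundary = boundary)
  .fixture_env[[key]]
}

mid_sheet_fixture <- function() {
  if (is.null(.fixture_env$mid)) {
    geom <- standard_geometry(2 / 5)
    .fixture_env$mid <- list(geom = geom,
                             model = build_connectivity(geom, seed = 42),
                             globals = standard_unit_params())
  }
  .fixture_env$mid
}

# a fully deterministic, translation-symmetric model: complete local discs
# (no sampling), no remote patches -- every unit has an identical
# neighbourhood on the torus
symmetric_model_fixture <- function() {
  if (is.null(.fixture_env$symm)) {
    geom <- standard_geometry(1 / 5, boundary = "torus")
    off <- lattice_disc_offsets(6)
    off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
    n <- geom$n_units
    from <- integer(0); to <- integer(0)
    for (k in seq_len(nrow(off))) {
      r2 <- ((geom$row + off[k, 1] - 1L) %% geom$n_rows) + 1L
      c2 <- ((geom$col + off[k, 2] - 1L) %% geom$n_cols) + 1L
      from <- c(from, seq_len(n))
      to <- c(to, unit_index(geom, r2, c2))
    }
    adj <- Matrix::sparseMatrix(i = from, j = to, x = TRUE, dims = c(n, n))
    empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = logical(0),
                                  dims = c(n, n))
    cp <- standard_connectivity_params()
    cp$w_local <- 0.053  # ~ same total weight as the sampled preset
    model <- assemble_weight_matrices(adj, adj, empty,
                                      standard_unit_params(), cp, geom)
    .fixture_env$symm <- list(geom = geom, model = model,
                              globals = standard_unit_params())
  }
  .fixture_env$symm
}

# model with no off-diagonal connections at all (decoupled sheet)
decoupled_model_fixture <- function() {
  if (is.null(.fixture_env$deco)) {
    geom <- sheet_geometry(10, 10, macro_edge = 5)
    n <- geom$n_units
    empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = logical(0), dims = c(n, n))
    model <- assemble_weight_matrices(empty, empty, empty,
                                      standard_unit_params(),
                                      standard_connectivity_params(), geom)
    .fixture_env$deco <- list(geom = geom, model = model)
  }
  .fixture_env$deco
}

full_sheet_fixture <- function() {
  if (is.null(.fixture_env$full)) {
    geom <- standard_geometry(1, boundary = "zero_flux")
    .fixture_env$full <- list(geom = geom,
                              model = build_connectivity(geom, seed = 21),
                              globals = standard_unit_params())
  }
  .fixture_env$full
}
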