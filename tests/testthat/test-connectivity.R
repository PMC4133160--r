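test_that("local sampler respects the hard cutoff and excludes self", {
  g <- sheet_geometry(30, 30, boundary = "torus")
  adj <- sample_local_connections(g, sigma_um = 100, radius_um = 300, seed = 3)
  tm <- as(adj, "TsparseMatrix")
  from <- tm@i + 1L; to <- tm@j + 1L
  expect_true(all(sheet_distance(g, from, to) <= 300 + 1e-9))
  expect_true(all(from != to))
})

test_that("local connection frequency follows the truncated Gaussian law", {
  g <- sheet_geometry(30, 30, boundary = "torus")
  adj <- sample_local_connections(g, sigma_um = 100, radius_um = 300, seed = 5)
  # group ordered pairs by exact offset distance; every unit sees every
  # offset on the torus, so each distance bin has n_units * multiplicity
  # Bernoulli trials
  off <- lattice_disc_offsets(6)
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  d <- sqrt(off[, 1]^2 + off[, 2]^2) * g$pitch_um
  tm <- as(adj, "TsparseMatrix")
  from <- tm@i + 1L; to <- tm@j + 1L
  dconn <- sheet_distance(g, from, to)
  total_trials <- 0
  for (dd in unique(round(d, 6))) {
    n_trials <- g$n_units * sum(abs(d - dd) < 1e-6)
    p <- exp(-dd^2 / (2 * 100^2))
    k <- sum(abs(dconn - dd) < 1e-6)
    se <- sqrt(n_trials * p * (1 - p))
    expect_lt(abs(k - n_trials * p), 3 * se + 1)
    total_trials <- total_trials + n_trials
  }
  expect_gte(total_trials, 1e4)
})

test_that("samplers are seed-reproducible and seeds differ", {
  g <- sheet_geometry(30, 30)
  a <- sample_local_connections(g, 100, 300, seed = 7)
  b <- sample_local_connections(g, 100, 300, seed = 7)
  c <- sample_local_connections(g, 100, 300, seed = 8)
  expect_identical(as(a, "TsparseMatrix")@i, as(b, "TsparseMatrix")@i)
  expect_false(identical(as(a, "TsparseMatrix")@i,
                         as(c, "TsparseMatrix")@i))
  r1 <- sample_remote_patches(g, standard_connectivity_params(), seed = 7)
  r2 <- sample_remote_patches(g, standard_connectivity_params(), seed = 7)
  expect_identical(r1$layout$patches, r2$layout$patches)
  expect_identical(as(r1$adj, "TsparseMatrix")@i,
                   as(r2$adj, "TsparseMatrix")@i)
})

test_that("zero-flux sampling never creates wrap-around connections", {
  g <- sheet_geometry(30, 30, boundary = "zero_flux")
  adj <- sample_local_connections(g, 150, 300, seed = 2)
  tm <- as(adj, "TsparseMatrix")
  from <- tm@i + 1L; to <- tm@j + 1L
  # planar displacement of every connection stays within the cutoff
  dx <- abs(g$col[to] - g$col[from]); dy <- abs(g$row[to] - g$row[from])
  expect_true(all(dx <= 6 & dy <= 6))
})

test_that("remote patches obey size, out-degree and sharing contracts", {
  g <- sheet_geometry(30, 30, boundary = "torus")
  cp <- standard_connectivity_params()
  r <- sample_remote_patches(g, cp, seed = 13)
  sizes <- vapply(r$layout$members, length, 1L)
  expect_true(all(sizes <= 81))
  expect_true(all(sizes == 81))  # torus: full discs everywhere
  expect_equal(nrow(r$layout$patches),
               g$n_macros * cp$n_patches_per_macro)
  # out-degree capped by n_out_remote
  outdeg <- Matrix::rowSums(r$adj)
  expect_true(all(outdeg <= cp$n_out_remote))
  expect_gt(mean(outdeg), cp$n_out_remote * 0.8)
  # sharing map names exactly one direct macrocolumn neighbour
  expect_identical(length(r$layout$share_partner), g$n_macros)
  for (m in seq_len(g$n_macros))
    expect_true(r$layout$share_partner[m] %in% macro_neighbours(g, m))
  # shared patches actually come from the partner's originally drawn layout
  pt <- r$layout$patches
  for (m in seq_len(g$n_macros)) {
    shared_centers <- pt$center[pt$owner_macro == m & pt$shared]
    partner_centers <- r$layout$own_centers[[r$layout$share_partner[m]]]
    expect_true(all(shared_centers %in% partner_centers))
  }
  # patches placed too far are rejected by construction
  expect_error(sample_remote_patches(
    g, standard_connectivity_params(), seed = 1)$layout, NA)
})

test_that("assembled matrices have the contracted structure", {
  fx <- small_sheet_fixture()
  m <- fx$model
  n <- fx$geom$n_units
  expect_true(all(Matrix::diag(m$ee_off) == 0))
  expect_true(all(Matrix::diag(m$ei_off) == 0))
  expect_true(all(m$ee_off@x >= 0))
  full_ee <- w_ee(m)
  expect_equal(unique(Matrix::diag(full_ee)), m$conn_params$w_self_e)
  # I->E and I->I strictly diagonal
  expect_identical(Matrix::nnzero(w_ie(m) -
    Matrix::Diagonal(n, m$diag_ie)), 0L)
  expect_identical(Matrix::nnzero(w_ii(m) -
    Matrix::Diagonal(n, m$diag_ii)), 0L)
  # empty adjacencies degenerate to the diagonal
  d <- decoupled_model_fixture()
  expect_identical(Matrix::nnzero(d$model$ee_off), 0L)
  expect_equal(as.matrix(w_ee(d$model)),
               diag(d$model$conn_params$w_self_e, d$geom$n_units),
               ignore_attr = TRUE)
})

test_that("realized local:remote ratio matches a direct count", {
  g <- sheet_geometry(30, 30)
  cp <- standard_connectivity_params()
  up <- standard_unit_params()
  le <- sample_local_connections(g, cp$sigma_um, cp$local_radius_um, 101)
  li <- sample_local_connections(g, cp$sigma_um, cp$local_radius_um, 102)
  re <- sample_remote_patches(g, cp, 103)
  m <- assemble_weight_matrices(le, li, re$adj, up, cp, g)
  expect_identical(m$n_local, Matrix::nnzero(le))
  expect_identical(m$n_remote, Matrix::nnzero(re$adj))
  expect_equal(m$local_remote_ratio,
               Matrix::nnzero(le) / Matrix::nnzero(re$adj))
})

test_that("connection statistics satisfy the handshake identity", {
  fx <- small_sheet_fixture()
  st <- connection_statistics(fx$model)
  for (type in st) {
    expect_identical(sum(type$in_degree), type$n)
    expect_identical(sum(type$out_degree), type$n)
  }
  # local E->I distances live within (0, cutoff]
  d <- st$ei$distance_hist
  nz <- d$counts > 0
  expect_true(all(d$mids[nz] <= standard_connectivity_params()$local_radius_um))
})

test_that("microincision removes exactly the chords crossing the cuts", {
  g <- sheet_geometry(20, 20, macro_edge = 10, boundary = "zero_flux")
  cp <- standard_connectivity_params()
  le <- sample_local_connections(g, cp$sigma_um, cp$local_radius_um, 11)
  li <- sample_local_connections(g, cp$sigma_um, cp$local_radius_um, 12)
  n <- g$n_units
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = logical(0), dims = c(n, n))
  m <- assemble_weight_matrices(le, li, empty, standard_unit_params(), cp, g)
  # a closed rectangle enclosing a 4x4 block of units
  xy <- unit_coords(g)
  lo <- 7.5 * g$pitch_um; hi <- 11.5 * g$pitch_um
  ov <- g$pitch_um / 2  # overshoot the corners so no chord sneaks through
  cuts <- rbind(c(lo - ov, lo, hi + ov, lo), c(hi, lo - ov, hi, hi + ov),
                c(hi + ov, hi, lo - ov, hi), c(lo, hi + ov, lo, lo - ov))
  cut_model <- apply_microincision(m, cuts)
  # oracle: brute-force segment intersection over all remaining chords
  seg_int <- function(p1, p2, q1, q2) {
    o <- function(a, b, c) (b[1]-a[1])*(c[2]-a[2]) - (b[2]-a[2])*(c[1]-a[1])
    d1 <- o(q1, q2, p1); d2 <- o(q1, q2, p2)
    d3 <- o(p1, p2, q1); d4 <- o(p1, p2, q2)
    d1 * d2 < 0 && d3 * d4 < 0
  }
  tm <- as(cut_model$ee_off, "TsparseMatrix")
  from <- tm@j + 1L; to <- tm@i + 1L
  crossing <- 0L
  for (k in seq_along(from)) {
    for (cc in seq_len(nrow(cuts))) {
      if (seg_int(xy[from[k], ], xy[to[k], ], cuts[cc, 1:2], cuts[cc, 3:4]))
        crossing <- crossing + 1L
    }
  }
  expect_identical(crossing, 0L)
  # inside block is now disconnected from outside in the EE graph
  inside <- which(xy[, 1] > lo & xy[, 1] < hi & xy[, 2] > lo & xy[, 2] < hi)
  expect_identical(Matrix::nnzero(cut_model$ee_off[inside, -inside]), 0L)
  expect_identical(Matrix::nnzero(cut_model$ee_off[-inside, inside]), 0L)
  # a single cut removes fewer connections than two parallel cuts
  one_cut <- apply_microincision(m, cuts[1, , drop = FALSE])
  two_cuts <- apply_microincision(m, cuts[1:2, ])
  expect_lt(Matrix::nnzero(two_cuts$ee_off), Matrix::nnzero(one_cut$ee_off))
  # a cut far from all connections changes nothing (diagonal-only model)
  d <- decoupled_model_fixture()
  unchanged <- apply_microincision(d$model,
                                   matrix(c(100, 100, 200, 200), 1))
  expect_identical(Matrix::nnzero(unchanged$ee_off), 0L)
})

test_that("connectivity export/import round-trips", {
  fx <- small_sheet_fixture()
  dir <- withr::local_tempdir()
  write_connectivity(fx$model, dir)
  back <- read_connectivity(dir)
  expect_equal(as.matrix(back$ee_off), as.matrix(fx$model$ee_off),
               ignore_attr = TRUE)
  expect_equal(back$diag_ie, fx$model$diag_ie)
  expect_equal(back$conn_params$sigma_um, fx$model$conn_params$sigma_um)
  expect_true(file.exists(file.path(dir, "patches.csv")))
})
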