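test_that("all-background simulation yields zero recruitment", {
  fx <- small_sheet_fixture()
  res <- simulate_sheet(fx$model, fx$globals,
                        noise = noise_spec(0.5, 2), duration = 3000)
  rep <- detect_recruited_units(res)
  expect_identical(sum(rep$recruited), 0L)
  expect_true(all(rep$fraction == 0))
  expect_equal(rep$final_percent, 0)
})

test_that("a fully oscillatory sheet is recruited wall to wall", {
  fx <- small_sheet_fixture()
  glob <- update_unit_params(fx$globals, p_basal = -0.5)
  res <- simulate_sheet(fx$model, glob, noise = noise_spec(0.5, 2),
                        duration = 6000)
  rep <- detect_recruited_units(res)
  expect_gt(rep$final_percent, 95)
  # fraction course is non-decreasing (no counter-intervention scheduled)
  expect_true(all(diff(rep$fraction) >= -1e-12))
})

test_that("recruitment detector requires synchrony, not just amplitude", {
  # synthetic result: half the units oscillate coherently, half carry
  # independent phase-scrambled oscillations
  geom <- sheet_geometry(20, 20, macro_edge = 10)
  t <- seq(0, 4000, by = 8)
  n <- geom$n_units
  set.seed(9)
  u <- matrix(0.2, length(t), n)
  coherent <- which(geom$col <= 10)
  u[, coherent] <- 0.4 + 0.15 * sin(2 * pi * 10 * t / 1000)
  scrambled <- which(geom$col > 10)
  for (i in scrambled)
    u[, i] <- 0.4 + 0.15 * sin(2 * pi * stats::runif(1, 5, 25) * t / 1000 +
                               stats::runif(1, 0, 2 * pi))
  res <- structure(list(u = u, t_units = t, geom = geom,
                        noise = noise_spec(0, 1)),
                   class = "simulation_result")
  rep <- detect_recruited_units(res, sync_radius = 3)
  # interior coherent units are recruited; scrambled ones mostly are not
  interior <- which(geom$col <= 7 & geom$col >= 4)
  expect_gt(mean(rep$recruited[interior]), 0.9)
  expect_lt(mean(rep$recruited[scrambled]), 0.3)
})

test_that("planted wavefront speed is recovered within 2%", {
  for (speed in c(0.2, 1, 5)) {
    fx <- make_test_fixture("planted_wavefront", seed = 3,
                            speed_m_per_s = speed, onset_noise_ms = 0)
    est <- estimate_wavefront_speed(fx$report, fx$geom, fx$seed_region)
    expect_identical(est$status, "ok")
    expect_lt(abs(est$speed_m_per_s - speed) / speed, 0.02)
    expect_gt(est$r_squared, 0.9)
  }
})

test_that("simultaneous onsets give an undefined speed", {
  fx <- make_test_fixture("planted_wavefront", seed = 3)
  fx$report$onset_ms[] <- 500
  est <- estimate_wavefront_speed(fx$report, fx$geom, fx$seed_region)
  expect_identical(est$status, "speed undefined")
  expect_true(is.na(est$speed_m_per_s))
})

test_that("planted oscillation fixture is flagged at the right frequency", {
  fx <- make_test_fixture("planted_oscillation", seed = 6, freq_hz = 12,
                          amplitude = 0.3)
  for (ch in seq_len(ncol(fx$series))) {
    det <- detect_oscillation(fx$series[, ch], fx$dt)
    expect_true(det$oscillating)
    n_win <- sum(fx$t_ms > 0.2 * max(fx$t_ms))
    expect_lt(abs(det$frequency - 12), 1000 / (n_win * fx$dt) + 1e-9)
    expect_equal(det$amplitude, 0.3, tolerance = 0.15)
  }
})

test_that("subcluster placement is exact, disjoint and contiguous", {
  geom <- standard_geometry(1)
  lay <- place_subclusters(geom, 2250, 17, placement_seed = 5)
  expect_identical(sort(unique(lay$sizes)), c(132L, 133L))
  expect_identical(sum(lay$sizes), 2250L)
  expect_identical(anyDuplicated(unlist(lay$members)), 0L)
  # contiguity oracle: flood fill over the 4-neighbourhood
  contiguous <- function(members) {
    left <- setdiff(members, members[1])
    frontier <- members[1]
    while (length(frontier) && length(left)) {
      nb <- unique(unlist(lapply(frontier, function(i) {
        r <- geom$row[i]; c <- geom$col[i]
        ok <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
        ok <- ok[ok[, 1] >= 1 & ok[, 1] <= geom$n_rows &
                 ok[, 2] >= 1 & ok[, 2] <= geom$n_cols, , drop = FALSE]
        unit_index(geom, ok[, 1], ok[, 2])
      })))
      frontier <- intersect(nb, left)
      left <- setdiff(left, frontier)
    }
    length(left) == 0
  }
  for (k in c(1, 8, 17)) expect_true(contiguous(lay$members[[k]]))
  # single cluster degenerates to one contiguous patch of the exact size
  one <- place_subclusters(geom, 400, 1, placement_seed = 2)
  expect_identical(length(one$members[[1]]), 400L)
  expect_true(contiguous(one$members[[1]]))
  # determinism
  again <- place_subclusters(geom, 2250, 17, placement_seed = 5)
  expect_identical(lay$members, again$members)
  expect_error(place_subclusters(sheet_geometry(10, 10, 5), 99, 30,
                                 placement_seed = 1, max_tries = 2),
               "disjointly")
})

test_that("bistable microdomain probe classifies sizes against drive", {
  fx <- mid_sheet_fixture()
  sc <- run_recruitment_scan(
    fx$model, fx$globals, template = "bistable_microdomain_probe",
    axis_x = list(param = "n_units", values = c(80, 400)),
    axis_y = list(param = "p_basal", values = c(-2, 0.5)),
    trials = 1, duration = 4000, seed = 3)
  expect_identical(nrow(sc), 4L)
  lab <- function(nu, pm) sc$label[sc$x == nu & sc$y == pm]
  # microdomain at surround-level P stays background at any size
  expect_identical(lab(80, -2), "monostable_background")
  expect_identical(lab(400, -2), "monostable_background")
  # a large, strongly driven microdomain ignites on its own
  expect_identical(lab(400, 0.5), "monostable_oscillatory")
})

test_that("recruitment scan aggregates trials with dispersion", {
  fx <- small_sheet_fixture()
  sc <- run_recruitment_scan(
    fx$model, fx$globals, template = "pulse_stimulus",
    axis_x = list(param = "n_units", values = c(40, 150)),
    axis_y = list(param = "p_basal", values = fx$globals$p_basal),
    trials = 2, duration = 2500, seed = 11)
  expect_identical(nrow(sc), 2L)
  expect_true(all(sc$n_trials == 2L))
  expect_true(all(!is.na(sc$sd)))
  expect_true(all(sc$mean >= 0 & sc$mean <= 100))
})
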