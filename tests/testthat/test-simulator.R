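test_that("noise is shared within macrocolumns with standard moments", {
  g <- sheet_geometry(20, 20, macro_edge = 10)
  spec <- noise_spec(coupling = 1, seed = 4)
  nz <- generate_noise(g, spec, 200, per_unit = TRUE)
  for (m in 1:4) {
    cols <- which(g$macro == m)
    expect_true(all(nz[, cols] == nz[, cols[1]]))
  }
  # distinct macrocolumns receive distinct streams
  expect_false(identical(nz[, which(g$macro == 1)[1]],
                         nz[, which(g$macro == 2)[1]]))
  big <- generate_noise(g, spec, 25000, per_unit = FALSE)
  n <- length(big)
  expect_lt(abs(mean(big)), 3 / sqrt(n))
  expect_lt(abs(stats::sd(big) - 1), 3 / sqrt(2 * n))
  # reproducible
  expect_identical(generate_noise(g, spec, 50), generate_noise(g, spec, 50))
})

test_that("decoupled sheet reproduces the single-unit integrator bit-for-bit", {
  d <- decoupled_model_fixture()
  up <- standard_unit_params()
  n_steps <- 400L
  spec <- noise_spec(coupling = up$noise_coupling, seed = 31)
  res <- simulate_sheet(d$model, up, noise = spec, duration = n_steps * 2,
                        init = list(u = rep(0.3, d$geom$n_units),
                                    v = rep(0.1, d$geom$n_units)),
                        u_stride = 1)
  noise_units <- generate_noise(d$geom, spec, n_steps, per_unit = TRUE)
  # the decoupled unit's recurrent couplings are the model diagonals
  up_eff <- update_unit_params(up, c_ee = d$model$diag_ee,
                               c_ei = d$model$diag_ei,
                               c_ie = d$model$diag_ie,
                               c_ii = d$model$diag_ii)
  for (i in c(1L, 37L, 100L)) {
    tr <- simulate_unit(up_eff, c(0.3, 0.1), duration = n_steps * 2, dt = 2,
                        noise = noise_units[, i])
    expect_identical(res$u[, i], tr$u)
  }
})

test_that("noiseless homogeneous torus stays exactly homogeneous", {
  fx <- symmetric_model_fixture()
  res <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0, 1),
                        duration = 600, u_stride = 1)
  expect_lt(max(apply(res$u, 1, stats::var)), 1e-12)
  expect_true(all(res$u >= 0 & res$u <= 1))
})

test_that("zero noise coupling equals the deterministic run", {
  fx <- small_sheet_fixture()
  a <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0, 1),
                      duration = 300)
  b <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0, 99),
                      duration = 300)
  expect_identical(a$u, b$u)
})

test_that("sheet states stay in [0,1] under noise and stimulation", {
  fx <- small_sheet_fixture()
  res <- simulate_sheet(
    fx$model, fx$globals,
    stimuli = stimulus_spec("input_pulse", 1:50, 30, onset = 100,
                            duration = 20),
    noise = noise_spec(2, 5), duration = 1000, u_stride = 1,
    record_v_units = TRUE)
  expect_true(all(res$u >= 0 & res$u <= 1))
  expect_true(all(res$v >= 0 & res$v <= 1))
})

test_that("determinism: seeds fully determine the output", {
  fx <- small_sheet_fixture()
  a <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0.5, 8),
                      duration = 400)
  b <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0.5, 8),
                      duration = 400)
  c <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0.5, 9),
                      duration = 400)
  expect_identical(a$u, b$u)
  expect_identical(a$macro_u, b$macro_u)
  expect_false(identical(a$u, c$u))
})

test_that("state resets set u (not v) and pulses add input", {
  fx <- small_sheet_fixture()
  mask <- 1:30
  res <- simulate_sheet(fx$model, fx$globals,
                        stimuli = stimulus_spec("state_reset", mask, 1,
                                                onset = 100),
                        noise = noise_spec(0, 1), duration = 200,
                        u_stride = 1, record_v_units = TRUE)
  k <- which(res$t_units == 100)
  expect_true(all(res$u[k, mask] == 1))
  expect_true(all(res$v[k, mask] < 0.5))       # v untouched by the reset
  expect_true(all(res$u[k, -mask] < 0.5))
  # a pulse drives the masked units up without touching others first
  res2 <- simulate_sheet(fx$model, fx$globals,
                         stimuli = stimulus_spec("input_pulse", mask, 20,
                                                 onset = 50, duration = 20),
                         noise = noise_spec(0, 1), duration = 120,
                         u_stride = 1)
  k2 <- which(res2$t_units == 80)
  expect_gt(mean(res2$u[k2, mask]), 0.5)
})

test_that("ramps interpolate linearly and clamp outside their window", {
  v <- cortexsheet:::ramp_value_per_step(
    ramp_spec("p_basal", -3, -1, t_start = 100, t_end = 300), 250, 2)
  expect_equal(v[1:50], rep(-3, 50))
  expect_equal(v[200:250], rep(-1, 51))
  expect_equal(v[101], -3 + (-1 - -3) * (200 - 100) / 200)
})

test_that("very large finite delay speed reproduces the undelayed path", {
  fx <- small_sheet_fixture()
  a <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0.5, 3),
                      duration = 300, u_stride = 1)
  b <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0.5, 3),
                      duration = 300, u_stride = 1, delay_speed = 1e7)
  expect_lt(max(abs(a$u - b$u)), 1e-12)
  # finite delays change the trajectory
  d <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0.5, 3),
                      duration = 300, u_stride = 1, delay_speed = 0.05)
  expect_gt(max(abs(a$u - d$u)), 1e-6)
  expect_error(simulate_sheet(fx$model, fx$globals, duration = 20,
                              delay_speed = 1e-4), "delay buffer")
})

test_that("macrocolumn LFP proxy is the spatial mean of the unit signal", {
  fx <- symmetric_model_fixture()
  res <- simulate_sheet(fx$model, fx$globals, noise = noise_spec(0, 1),
                        duration = 200, u_stride = 1)
  # uniform sheet: every macro LFP equals the common unit value
  expect_equal(res$macro_u[, 1], res$u[, 1], tolerance = 1e-12)
  expect_lt(max(res$macro_u) - min(res$macro_u[1, ]), 1)
  lfp <- compute_lfp(res)
  expect_identical(lfp, res$macro_u)
  expect_error(compute_lfp(res, "nonsense"))
})

test_that("step halving changes the deterministic macrocolumn LFP by < 5% RMS", {
  fx <- small_sheet_fixture()
  glob <- update_unit_params(fx$globals, p_basal = -1)  # active dynamics
  a <- simulate_sheet(fx$model, glob, noise = noise_spec(0, 1),
                      duration = 2000, dt = 2)
  b <- simulate_sheet(fx$model, glob, noise = noise_spec(0, 1),
                      duration = 2000, dt = 1)
  xa <- rowMeans(a$macro_u)
  xb <- rowMeans(b$macro_u)[seq(1, nrow(b$macro_u), by = 2)]
  rms <- sqrt(mean((xa - xb)^2)) / max(sqrt(mean(xa^2)), 1e-12)
  expect_lt(rms, 0.05)
})

test_that("stimulus threshold probe matches a grid scan within one step", {
  fx <- small_sheet_fixture()
  mask <- cortexsheet:::central_disc(fx$geom, 60)
  crit <- function(res) max(res$macro_u[res$t_macro >= 200, ]) > 0.35
  probe <- stimulus_threshold_probe(fx$model, fx$globals, probe_mask = mask,
                                    response_criterion = crit,
                                    bracket = c(0.1, 40),
                                    noise = noise_spec(0.5, 6),
                                    duration = 900, pulse_onset = 200,
                                    pulse_duration = 20)
  expect_identical(probe$status, "ok")
  # grid oracle at 0.25 resolution
  amps <- seq(0.1, 40, by = 0.25)
  responds <- function(amp) {
    res <- simulate_sheet(fx$model, fx$globals,
                          stimuli = stimulus_spec("input_pulse", mask, amp,
                                                  200, 20),
                          noise = noise_spec(0.5, 6), duration = 900,
                          u_stride = 1e6)
    crit(res)
  }
  # bisect the grid coarsely instead of scanning every point
  lo <- 1L; hi <- length(amps)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (responds(amps[mid])) hi <- mid else lo <- mid
  }
  expect_lt(abs(probe$threshold - amps[hi]), 0.25 + probe$threshold * 0.02)
  # criterion never satisfied -> no threshold in range
  none <- stimulus_threshold_probe(fx$model, fx$globals, probe_mask = mask,
                                   response_criterion = function(res) FALSE,
                                   bracket = c(0.1, 1),
                                   noise = noise_spec(0.5, 6),
                                   duration = 400)
  expect_identical(none$status, "no threshold in range")
  expect_true(is.na(none$threshold))
})
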