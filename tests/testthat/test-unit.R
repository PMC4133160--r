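test_that("sigmoid midpoint, symmetry and saturation", {
  sp <- sigmoid_params(1.7, 0.8)
  expect_equal(wc_sigmoid(0.8, sp), 0.5)
  for (d in c(0.1, 1, 7))
    expect_equal(wc_sigmoid(0.8 + d, sp) + wc_sigmoid(0.8 - d, sp), 1)
  expect_equal(wc_sigmoid(0.8 + 50 / 1.7, sp), 1, tolerance = 1e-9)
  expect_true(all(diff(wc_sigmoid(seq(-20, 20, 0.1), sp)) > 0))
  expect_error(wc_sigmoid(NaN, sp), "non-finite")
})

test_that("drift vanishes at the decoupled leak-drive balance", {
  up <- unit_params(0, 0, 0, 0, p_basal = -1, q_basal = -2,
                    tau_e = 10, tau_i = 20)
  u_star <- wc_sigmoid(-1, up$sigmoid)
  v_star <- wc_sigmoid(-2, up$sigmoid)
  d <- unit_drift(u_star, v_star, up)
  expect_equal(d$du, 0); expect_equal(d$dv, 0)
  # u above the balance point decays (sign of the leak)
  expect_lt(unit_drift(u_star + 0.2, v_star, up)$du, 0)
})

test_that("finite-difference slope of the trajectory matches the drift", {
  up <- standard_unit_params()
  dt <- 0.5
  tr <- simulate_unit(up, c(0.3, 0.1), duration = 100, dt = dt)
  for (k in c(2, 50, 150)) {
    d <- unit_drift(tr$u[k], tr$v[k], up)
    expect_equal((tr$u[k + 1] - tr$u[k]) / dt, d$du, tolerance = 1e-10)
    expect_equal((tr$v[k + 1] - tr$v[k]) / dt, d$dv, tolerance = 1e-10)
  }
})

test_that("decoupled unit has exactly one fixed point at (f(P), f(Q))", {
  up <- unit_params(0, 0, 0, 0, p_basal = 0.5, q_basal = -1,
                    tau_e = 10, tau_i = 20)
  fp <- find_unit_fixed_points(up, 100)
  expect_identical(nrow(fp), 1L)
  expect_equal(fp$u, wc_sigmoid(0.5, up$sigmoid), tolerance = 1e-9)
  expect_equal(fp$v, wc_sigmoid(-1, up$sigmoid), tolerance = 1e-9)
  expect_identical(fp$stability, "stable_node")
})

test_that("fixed points agree with a brute-force sign-change oracle", {
  up <- update_unit_params(standard_unit_params(), p_basal = -0.5)
  fp <- find_unit_fixed_points(up, 200)
  fp <- fp[fp$stability != "unresolved", ]
  # oracle: 400 x 400 grid, cells where both drift components change sign
  gr <- seq(0, 1, length.out = 400)
  U <- matrix(rep(gr, 400), 400)
  V <- matrix(rep(gr, each = 400), 400)
  d <- unit_drift(as.vector(U), as.vector(V), up)
  FU <- matrix(d$du, 400); FV <- matrix(d$dv, 400)
  sgn <- function(M) {
    h <- M[-400, -400]
    (h * M[-1, -400] <= 0) | (h * M[-400, -1] <= 0) | (h * M[-1, -1] <= 0)
  }
  cells <- which(sgn(FU) & sgn(FV), arr.ind = TRUE)
  # every polished root lies in (or adjacent to) an oracle cell
  for (r in seq_len(nrow(fp))) {
    du <- abs(gr[cells[, 1]] - fp$u[r])
    dv <- abs(gr[cells[, 2]] - fp$v[r])
    expect_lt(min(pmax(du, dv)), 2.5 / 400)
  }
  # the standard interictal unit is a bistable switch at this P:
  # low node, saddle, high node
  expect_identical(sum(fp$stability %in% c("stable_node", "stable_focus")), 2L)
  expect_identical(sum(fp$stability == "saddle"), 1L)
})

test_that("single unit shows no limit cycle across a P sweep", {
  up <- standard_unit_params()
  for (P in seq(-6, 4, by = 1)) {
    p <- update_unit_params(up, p_basal = P)
    fp <- find_unit_fixed_points(p, 100)
    stable <- fp[fp$stability %in% c("stable_node", "stable_focus"), ]
    expect_gte(nrow(stable), 1L)
    set.seed(7)
    for (k in 1:3) {
      tr <- simulate_unit(p, stats::runif(2), duration = 3000, dt = 2)
      tl <- tr[tr$t > 2400, ]
      # converged to one of the located fixed points, not a cycle
      expect_lt(max(tl$u) - min(tl$u), 0.01)
      expect_lt(min(sqrt((stable$u - mean(tl$u))^2 +
                         (stable$v - mean(tl$v))^2)), 0.02)
    }
  }
})

test_that("trajectory started at a stable fixed point stays put", {
  up <- update_unit_params(standard_unit_params(), p_basal = -3)
  fp <- find_unit_fixed_points(up, 100)
  fp <- fp[fp$stability == "stable_node", ][1, ]
  tr <- simulate_unit(up, c(fp$u, fp$v), duration = 1000, dt = 2)
  expect_lt(max(abs(tr$u - fp$u)), 1e-12)
  expect_lt(max(abs(tr$v - fp$v)), 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  up <- standard_unit_params()
  a <- simulate_unit(up, c(0.2, 0.2), 500, noise_seed = 9)
  b <- simulate_unit(up, c(0.2, 0.2), 500, noise_seed = 9)
  d <- simulate_unit(up, c(0.2, 0.2), 500, noise_seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$u, d$u))
})

test_that("decoupled relaxation follows exp(-t/tau_e) toward f(P)", {
  up <- unit_params(0, 0, 0, 0, p_basal = 2.5, q_basal = -3,
                    tau_e = 10, tau_i = 20)
  # f is constant in the decoupled unit, so u(t) = f(P)(1 - exp(-t/tau_e))
  tr <- simulate_unit(up, c(0, 0), duration = 30, dt = 0.05)
  target <- wc_sigmoid(2.5, up$sigmoid)
  keep <- tr$t > 0 & tr$t < 20
  fit <- stats::lm(log(1 - tr$u[keep] / target) ~ tr$t[keep])
  tau_hat <- -1 / stats::coef(fit)[2]
  expect_lt(abs(tau_hat - 10) / 10, 0.02)
})

test_that("states stay inside the unit square whenever dt <= min(tau)", {
  set.seed(11)
  for (k in 1:10) {
    up <- unit_params(runif(1, 0, 8), runif(1, 0, 15), runif(1, 0, 8),
                      runif(1, 0, 5), runif(1, -4, 2), runif(1, -4, 0),
                      tau_e = runif(1, 5, 20), tau_i = runif(1, 5, 30),
                      noise_coupling = runif(1, 0, 2))
    tr <- simulate_unit(up, runif(2), duration = 500,
                        dt = min(up$tau_e, up$tau_i), noise_seed = k)
    expect_true(all(tr$u >= 0 & tr$u <= 1))
    expect_true(all(tr$v >= 0 & tr$v <= 1))
  }
  expect_warning(simulate_unit(standard_unit_params(), c(0.5, 0.5),
                               duration = 100, dt = 15), "boundedness")
})

test_that("halving the step changes the noiseless trajectory only slightly", {
  up <- update_unit_params(standard_unit_params(), p_basal = -1)
  a <- simulate_unit(up, c(0.6, 0.05), duration = 2000, dt = 2)
  b <- simulate_unit(up, c(0.6, 0.05), duration = 2000, dt = 1)
  expect_lt(abs(utils::tail(a$u, 1) - utils::tail(b$u, 1)), 0.05)
})
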