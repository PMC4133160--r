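#' Sigmoid response parameters
#'
#' The population response function is a logistic sigmoid,
#' \code{f(x) = 1 / (1 + exp(-steepness * (x - offset)))}, arising from a
#' distribution of firing thresholds in the underlying population.
#'
#' @param steepness slope of the sigmoid (> 0).
#' @param offset input value at which the sigmoid crosses 1/2.
#' @return an object of class \code{sigmoid_params}.
#' @export
sigmoid_params <- function(steepness, offset) {
  stopifnot(is.finite(steepness), is.finite(offset), steepness > 0)
  structure(list(steepness = steepness, offset = offset),
            class = "sigmoid_params")
}

#' Logistic population response function
#'
#' @param x input (vectorised); must be finite.
#' @param params a \code{sigmoid_params}.
#' @return values in (0, 1), strictly increasing in \code{x}.
#' @export
wc_sigmoid <- function(x, params) {
  if (any(!is.finite(x))) stop("wc_sigmoid: non-finite input x")
  1 / (1 + exp(-params$steepness * (x - params$offset)))
}

#' Wilson-Cowan minicolumn parameters
#'
#' Parameters of one excitatory-inhibitory (E-I) population pair:
#' \deqn{\tau_e \dot u = -u + f(c_{ee} u - c_{ie} v + P + e_{ext})}
#' \deqn{\tau_i \dot v = -v + f(c_{ei} u - c_{ii} v + Q + i_{ext})}
#' where u, v are fractional firing activities in [0, 1], P and Q are basal
#' inputs, and noise (coupling strength \code{noise_coupling}, the model's B)
#' enters the excitatory input.
#'
#' @param c_ee,c_ie,c_ei,c_ii non-negative within-unit coupling constants.
#' @param p_basal,q_basal basal inputs to E and I (P, Q).
#' @param tau_e,tau_i membrane time constants, ms (> 0).
#' @param noise_coupling noise coupling strength B (>= 0).
#' @param sigmoid a \code{sigmoid_params}.
#' @return an object of class \code{unit_params}.
#' @seealso [standard_unit_params()] for the packaged interictal preset.
#' @export
unit_params <- function(c_ee, c_ie, c_ei, c_ii, p_basal, q_basal,
                        tau_e, tau_i, noise_coupling = 0,
                        sigmoid = sigmoid_params(1, 4)) {
  stopifnot(c_ee >= 0, c_ie >= 0, c_ei >= 0, c_ii >= 0,
            tau_e > 0, tau_i > 0, noise_coupling >= 0,
            inherits(sigmoid, "sigmoid_params"))
  structure(list(c_ee = c_ee, c_ie = c_ie, c_ei = c_ei, c_ii = c_ii,
                 p_basal = p_basal, q_basal = q_basal,
                 tau_e = tau_e, tau_i = tau_i,
                 noise_coupling = noise_coupling, sigmoid = sigmoid),
            class = "unit_params")
}

#' @export
print.unit_params <- function(x, ...) {
  cat(sprintf("<unit_params> c_ee=%g c_ie=%g c_ei=%g c_ii=%g P=%g Q=%g\n",
              x$c_ee, x$c_ie, x$c_ei, x$c_ii, x$p_basal, x$q_basal))
  cat(sprintf("  tau_e=%g ms tau_i=%g ms B=%g sigmoid(a=%g, theta=%g)\n",
              x$tau_e, x$tau_i, x$noise_coupling,
              x$sigmoid$steepness, x$sigmoid$offset))
  invisible(x)
}

#' Modify a unit_params object
#'
#' Convenience for parameter scans: returns a copy with the named fields
#' replaced.
#'
#' @param params a \code{unit_params}.
#' @param ... named scalar replacements (e.g. \code{p_basal = -1}).
#' @return a \code{unit_params}.
#' @export
update_unit_params <- function(params, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), setdiff(names(params), "sigmoid"))
  bad <- setdiff(bad, "sigmoid")
  if (length(bad)) stop("unknown unit parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(repl)) params[[nm]] <- repl[[nm]]
  do.call(unit_params, params)
}

#' Deterministic right-hand side of the minicolumn equations
#'
#' @param u,v fractional firing activities (vectorised).
#' @param params a \code{unit_params}.
#' @param external_e,external_i additional input to the E and I populations
#'   (network input, stimulation, noise).
#' @return list with components \code{du} and \code{dv} (rates per ms).
#' @export
unit_drift <- function(u, v, params, external_e = 0, external_i = 0) {
  if (any(!is.finite(u)) || any(!is.finite(v))) stop("unit_drift: non-finite state")
  in_e <- params$c_ee * u - params$c_ie * v + params$p_basal + external_e
  in_i <- params$c_ei * u - params$c_ii * v + params$q_basal + external_i
  list(du = (-u + wc_sigmoid(in_e, params$sigmoid)) / params$tau_e,
       dv = (-v + wc_sigmoid(in_i, params$sigmoid)) / params$tau_i)
}

unit_jacobian <- function(u, v, params) {
  a <- params$sigmoid$steepness
  fe <- wc_sigmoid(params$c_ee * u - params$c_ie * v + params$p_basal, params$sigmoid)
  fi <- wc_sigmoid(params$c_ei * u - params$c_ii * v + params$q_basal, params$sigmoid)
  dfe <- a * fe * (1 - fe)
  dfi <- a * fi * (1 - fi)
  matrix(c((-1 + dfe * params$c_ee) / params$tau_e,
           (-dfe * params$c_ie) / params$tau_e,
           (dfi * params$c_ei) / params$tau_i,
           (-1 - dfi * params$c_ii) / params$tau_i),
         2, 2, byrow = TRUE)
}

classify_eigenvalues <- function(ev, marginal_tol = 1e-8, imag_tol = 1e-8) {
  re <- Re(ev); im <- Im(ev)
  if (max(abs(re)) < marginal_tol) return("marginal")
  focus <- any(abs(im) > imag_tol)
  if (all(re < 0)) return(if (focus) "stable_focus" else "stable_node")
  if (all(re > 0)) return(if (focus) "unstable_focus" else "unstable_node")
  "saddle"
}

#' Locate and classify the fixed points of a single minicolumn
#'
#' Evaluates the drift field on a regular grid over [0,1]^2, takes every cell
#' in which both components change sign as a root candidate, polishes each
#' candidate by damped Newton iteration on the analytic Jacobian, classifies
#' each converged root by its Jacobian eigenvalues, and deduplicates within
#' \code{dedup_tol}.  Candidates whose polishing fails to converge are
#' reported with \code{stability = "unresolved"} rather than dropped.
#'
#' @param params a \code{unit_params}.
#' @param grid_resolution grid points per axis (>= 50).
#' @param dedup_tol state-space deduplication tolerance.
#' @return data.frame with columns \code{u}, \code{v}, \code{stability},
#'   \code{lambda1}, \code{lambda2} (complex eigenvalues), class
#'   \code{unit_fixed_points}.
#' @export
find_unit_fixed_points <- function(params, grid_resolution = 200,
                                   dedup_tol = 1e-6) {
  stopifnot(grid_resolution >= 50)
  gr <- seq(0, 1, length.out = grid_resolution)
  U <- matrix(rep(gr, times = grid_resolution), grid_resolution)
  V <- matrix(rep(gr, each = grid_resolution), grid_resolution)
  d <- unit_drift(as.vector(U), as.vector(V), params)
  FU <- matrix(d$du, grid_resolution)
  FV <- matrix(d$dv, grid_resolution)
  # cells where each component changes sign across any edge
  sgn_change <- function(M) {
    h <- M[-grid_resolution, -grid_resolution]
    (h * M[-1, -grid_resolution] <= 0) | (h * M[-grid_resolution, -1] <= 0) |
      (h * M[-1, -1] <= 0)
  }
  cand <- which(sgn_change(FU) & sgn_change(FV), arr.ind = TRUE)
  newton <- function(u0, v0) {
    x <- c(u0, v0)
    for (k in 1:60) {
      dr <- unit_drift(x[1], x[2], params)
      f <- c(dr$du, dr$dv)
      if (max(abs(f)) < 1e-12) break
      J <- unit_jacobian(x[1], x[2], params)
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      # damping keeps the iterate inside a loose box around [0,1]^2
      lam <- 1
      repeat {
        xn <- x - lam * step
        if (all(xn > -0.5 & xn < 1.5)) break
        lam <- lam / 2
        if (lam < 1e-6) return(NULL)
      }
      x <- xn
    }
    dr <- unit_drift(x[1], x[2], params)
    if (max(abs(c(dr$du, dr$dv))) > 1e-9) return(NULL)
    x
  }
  roots <- list(); unresolved <- list()
  for (k in seq_len(nrow(cand))) {
    u0 <- gr[cand[k, 1]]; v0 <- gr[cand[k, 2]]
    r <- newton(u0, v0)
    if (is.null(r)) unresolved[[length(unresolved) + 1L]] <- c(u0, v0)
    else roots[[length(roots) + 1L]] <- r
  }
  out <- data.frame(u = numeric(0), v = numeric(0), stability = character(0))
  out$lambda1 <- complex(0); out$lambda2 <- complex(0)
  if (length(roots)) {
    m <- do.call(rbind, roots)
    keep <- rep(TRUE, nrow(m))
    for (i in seq_len(nrow(m))) if (keep[i]) {
      for (j in seq_len(nrow(m))) if (j > i && keep[j] &&
          max(abs(m[i, ] - m[j, ])) < dedup_tol) keep[j] <- FALSE
    }
    m <- m[keep, , drop = FALSE]
    m[m < 0] <- 0; m[m > 1] <- 1
    ev <- t(apply(m, 1, function(x) eigen(unit_jacobian(x[1], x[2], params),
                                          only.values = TRUE)$values))
    out <- data.frame(u = m[, 1], v = m[, 2],
                      stability = apply(ev, 1, classify_eigenvalues))
    out$lambda1 <- as.complex(ev[, 1]); out$lambda2 <- as.complex(ev[, 2])
  }
  if (length(unresolved)) {
    m <- do.call(rbind, unresolved)
    un <- data.frame(u = m[, 1], v = m[, 2], stability = "unresolved")
    un$lambda1 <- as.complex(NA); un$lambda2 <- as.complex(NA)
    out <- rbind(out, un)
  }
  class(out) <- c("unit_fixed_points", "data.frame")
  out
}

#' Simulate a single decoupled minicolumn
#'
#' Fixed-step explicit Euler integration of one E-I unit.  Noise (standard
#' normal per step, scaled by \code{noise_coupling}) enters the excitatory
#' input only.  With \code{noise_seed = NULL} and \code{noise = NULL} the
#' trajectory is fully deterministic.
#'
#' @param params a \code{unit_params}.
#' @param init numeric length-2 vector \code{c(u, v)} in [0,1]^2.
#' @param duration total simulated time, ms.
#' @param dt step size, ms (default 2).
#' @param noise_seed integer seed for the per-step noise stream, or NULL.
#' @param noise optional precomputed per-step noise vector (length = number of
#'   steps); overrides \code{noise_seed}.  Used to share a noise slice with a
#'   sheet simulation.
#' @param external_e optional per-step additional E input (scalar or vector).
#' @return data.frame with columns \code{t}, \code{u}, \code{v}; the first row
#'   is the initial state at t = 0.
#' @export
simulate_unit <- function(params, init = c(0.1, 0.1), duration, dt = 2,
                          noise_seed = NULL, noise = NULL, external_e = 0) {
  stopifnot(dt > 0, duration >= dt, length(init) == 2,
            all(init >= 0 & init <= 1))
  if (dt > min(params$tau_e, params$tau_i))
    warning("dt exceeds min(tau_e, tau_i): state boundedness is no longer guaranteed")
  n_steps <- floor(duration / dt)
  if (is.null(noise)) {
    if (!is.null(noise_seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      set.seed(noise_seed)
      noise <- stats::rnorm(n_steps)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    } else noise <- numeric(n_steps)
  }
  stopifnot(length(noise) >= n_steps)
  ext <- rep_len(external_e, n_steps)
  par <- c(params$c_ee, params$c_ie, params$c_ei, params$c_ii,
           params$p_basal, params$q_basal, params$tau_e, params$tau_i,
           params$noise_coupling, params$sigmoid$steepness,
           params$sigmoid$offset)
  m <- cpp_simulate_unit(par, init, n_steps, dt, noise[seq_len(n_steps)], ext)
  data.frame(t = seq(0, by = dt, length.out = n_steps + 1),
             u = m[, 1], v = m[, 2])
}
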