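#' Per-macrocolumn shared noise specification
#'
#' At every step one standard-normal value is drawn per macrocolumn and
#' broadcast to all its minicolumns (all minicolumns of a macrocolumn receive
#' identical noise), scaled by the coupling strength B at the point of use.
#'
#' @param coupling noise coupling strength B (>= 0).
#' @param seed integer seed for the noise stream.
#' @return an object of class \code{noise_spec}.
#' @export
noise_spec <- function(coupling = standard_unit_params()$noise_coupling,
                       seed = 1L) {
  stopifnot(coupling >= 0)
  structure(list(coupling = coupling, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate the shared-noise array
#'
#' @param geom a \code{sheet_geometry}.
#' @param spec a \code{noise_spec}.
#' @param n_steps number of steps (> 0).
#' @param per_unit if TRUE (default) broadcast to a (time x units) matrix;
#'   otherwise return the raw (time x macrocolumns) draws.
#' @return numeric matrix of standard-normal values (unscaled by coupling).
#' @export
generate_noise <- function(geom, spec, n_steps, per_unit = TRUE) {
  stopifnot(n_steps > 0)
  m <- with_seed(spec$seed,
                 matrix(stats::rnorm(n_steps * geom$n_macros),
                        nrow = n_steps, ncol = geom$n_macros))
  if (per_unit) m[, geom$macro, drop = FALSE] else m
}

#' Heterogeneity override
#'
#' A spatially masked override of a unit parameter or of the feed-forward
#' (between-unit) input scale.  \code{ffw_e_scale} / \code{ffw_i_scale}
#' multiply the off-diagonal excitatory / inhibitory-population network input
#' of the masked units (e.g. value 1.5 = "1.5 times stronger feed-forward
#' excitation"); they only accept \code{mode = "scale"}.
#'
#' @param field one of \code{"p_basal"}, \code{"q_basal"},
#'   \code{"ffw_e_scale"}, \code{"ffw_i_scale"}.
#' @param mask integer unit indices the override applies to.
#' @param value override value.
#' @param mode \code{"absolute"} (replace) or \code{"scale"} (multiply the
#'   global value).
#' @return an object of class \code{het_override}; pass a list of these as
#'   the \code{het} argument of [simulate_sheet()].
#' @export
het_override <- function(field = c("p_basal", "q_basal", "ffw_e_scale",
                                   "ffw_i_scale"),
                         mask, value, mode = c("absolute", "scale")) {
  field <- match.arg(field); mode <- match.arg(mode)
  if (startsWith(field, "ffw")) mode <- "scale"
  stopifnot(length(mask) >= 1, is.finite(value))
  structure(list(field = field, mask = as.integer(mask), value = value,
                 mode = mode), class = "het_override")
}

#' Linear parameter ramp
#'
#' The targeted quantity is interpolated linearly from \code{from} at
#' \code{t_start} to \code{to} at \code{t_end} and clamped outside; inside
#' \code{mask} (default: whole sheet) the ramped value replaces the base
#' value at every step.
#'
#' @param param one of \code{"p_basal"}, \code{"q_basal"},
#'   \code{"ffw_e_scale"}, \code{"ffw_i_scale"}.
#' @param from,to start and end values.
#' @param t_start,t_end ramp interval, ms (t_start <= t_end).
#' @param mask integer unit indices (NULL = all units).
#' @return an object of class \code{ramp_spec}.
#' @export
ramp_spec <- function(param = c("p_basal", "q_basal", "ffw_e_scale",
                                "ffw_i_scale"),
                      from, to, t_start, t_end, mask = NULL) {
  param <- match.arg(param)
  stopifnot(t_start <= t_end, is.finite(from), is.finite(to))
  structure(list(param = param, from = from, to = to,
                 t_start = t_start, t_end = t_end, mask = mask),
            class = "ramp_spec")
}

#' Stimulus specification
#'
#' \code{input_pulse} adds \code{amplitude} to the excitatory input of the
#' masked units between \code{onset} and \code{onset + duration};
#' \code{state_reset} instantaneously sets the excitatory activity u of the
#' masked units to \code{amplitude} at \code{onset} (v is untouched).
#'
#' @param kind \code{"input_pulse"} or \code{"state_reset"}.
#' @param mask nonempty integer unit indices.
#' @param amplitude pulse amplitude (input units) or reset value (state
#'   units, in [0, 1]).
#' @param onset onset time, ms.
#' @param duration pulse duration, ms (ignored for resets).
#' @return an object of class \code{stimulus_spec}.
#' @export
stimulus_spec <- function(kind = c("input_pulse", "state_reset"), mask,
                          amplitude, onset, duration = 0) {
  kind <- match.arg(kind)
  stopifnot(length(mask) >= 1, duration >= 0, onset >= 0)
  if (kind == "state_reset") stopifnot(amplitude >= 0, amplitude <= 1)
  structure(list(kind = kind, mask = as.integer(mask), amplitude = amplitude,
                 onset = onset, duration = duration),
            class = "stimulus_spec")
}

#' Background fixed point of the sheet mean field
#'
#' Computes the low (background) fixed point of the effective mean-field
#' unit, whose recurrent couplings are the diagonal constants plus the mean
#' off-diagonal input weight per unit.
#'
#' @param model a \code{connectivity_model}.
#' @param globals a \code{unit_params}.
#' @return numeric c(u, v).
#' @export
background_state <- function(model, globals) {
  n <- model$geom$n_units
  k_ee <- sum(model$ee_off) / n
  k_ei <- sum(model$ei_off) / n
  eff <- update_unit_params(globals,
                            c_ee = model$diag_ee + k_ee,
                            c_ei = model$diag_ei + k_ei,
                            c_ie = model$diag_ie, c_ii = model$diag_ii)
  u <- 0.02; v <- 0.02
  for (k in 1:500) {
    u <- wc_sigmoid(eff$c_ee * u - eff$c_ie * v + eff$p_basal, eff$sigmoid)
    v <- wc_sigmoid(eff$c_ei * u - eff$c_ii * v + eff$q_basal, eff$sigmoid)
  }
  c(u = u, v = v)
}

ramp_value_per_step <- function(r, n_steps, dt) {
  t <- (seq_len(n_steps) - 1) * dt
  frac <- if (r$t_end > r$t_start)
    pmin(pmax((t - r$t_start) / (r$t_end - r$t_start), 0), 1)
  else as.numeric(t >= r$t_start)
  r$from + frac * (r$to - r$from)
}

#' Simulate the coupled cortical sheet
#'
#' Fixed-step explicit Euler integration of all minicolumns.  Per step, the
#' excitatory input to unit i is
#' \code{(ffw_e_i * net_ee_i) + w_self_e u_i - c_ie v_i + P_i(t) + B xi(t)}
#' with \code{net_ee = ee_off \%*\% u} and one shared noise value xi per
#' macrocolumn; the inhibitory-population input is analogous with the E->I
#' matrix, Q, and no noise.  Ramps override P/Q/feed-forward scales inside
#' their masks; pulses add input; state resets set u after the step at their
#' onset.  With a finite \code{delay_speed} (m/s), off-diagonal contributions
#' use source activity delayed by \code{round(distance / (speed dt))} steps
#' (one-pitch distance bins); \code{delay_speed = Inf} reproduces the
#' undelayed path exactly.
#'
#' @param model a \code{connectivity_model}.
#' @param globals a \code{unit_params}; its \code{c_ee}/\code{c_ei} are
#'   superseded by the model's diagonal constants.
#' @param het list of [het_override()]s (or a single one), or NULL.
#' @param ramps list of [ramp_spec()]s, or NULL.
#' @param stimuli list of [stimulus_spec()]s, or NULL.
#' @param noise a [noise_spec()]; \code{coupling = 0} gives a deterministic
#'   run.
#' @param duration total simulated time, ms.
#' @param dt step, ms (default 2).
#' @param init \code{"background"} (mean-field background fixed point in all
#'   units), or a list with numeric vectors \code{u} and \code{v}.
#' @param delay_speed signal propagation speed in m/s; Inf (default) =
#'   instantaneous.
#' @param u_stride store the full per-unit u field every \code{u_stride}
#'   steps (macrocolumn means are always stored every step).
#' @param record_v_units also store the per-unit v field.
#' @return an object of class \code{simulation_result} with elements
#'   \code{t_macro}, \code{macro_u}, \code{macro_v} (per-step macrocolumn
#'   means), \code{t_units}, \code{u} (downsampled per-unit field,
#'   time x units), optional \code{v}, final states, geometry and the echoed
#'   schedule/seeds.
#' @export
simulate_sheet <- function(model, globals = standard_unit_params(),
                           het = NULL, ramps = NULL, stimuli = NULL,
                           noise = noise_spec(), duration, dt = 2,
                           init = "background", delay_speed = Inf,
                           u_stride = 4L, record_v_units = FALSE) {
  geom <- model$geom
  n <- geom$n_units
  stopifnot(dt > 0, duration >= dt)
  if (dt > min(globals$tau_e, globals$tau_i))
    warning("dt exceeds min(tau_e, tau_i): state boundedness is no longer guaranteed")
  n_steps <- as.integer(floor(duration / dt))
  if (inherits(het, "het_override")) het <- list(het)
  if (inherits(ramps, "ramp_spec")) ramps <- list(ramps)
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)

  P0 <- rep(globals$p_basal, n); Q0 <- rep(globals$q_basal, n)
  ffe <- rep(1, n); ffi <- rep(1, n)
  for (h in het %||% list()) {
    base <- switch(h$field, p_basal = P0, q_basal = Q0,
                   ffw_e_scale = ffe, ffw_i_scale = ffi)
    val <- if (h$mode == "absolute") h$value else base[h$mask] * h$value
    base[h$mask] <- val
    switch(h$field, p_basal = P0 <- base, q_basal = Q0 <- base,
           ffw_e_scale = ffe <- base, ffw_i_scale = ffi <- base)
  }

  cramps <- lapply(ramps %||% list(), function(r) {
    list(target = match(r$param, c("p_basal", "q_basal", "ffw_e_scale",
                                   "ffw_i_scale")) - 1L,
         mask = as.integer((r$mask %||% seq_len(n)) - 1L),
         value = ramp_value_per_step(r, n_steps, dt))
  })

  init_list <- init
  cstims <- list()
  for (s in stimuli %||% list()) {
    step_on <- as.integer(round(s$onset / dt))
    if (s$kind == "state_reset" && step_on == 0L) {
      # reset at t = 0 folds into the initial condition
      if (identical(init_list, "background")) {
        bg <- background_state(model, globals)
        init_list <- list(u = rep(bg[1], n), v = rep(bg[2], n))
      }
      init_list$u[s$mask] <- s$amplitude
      next
    }
    cstims[[length(cstims) + 1L]] <- list(
      kind = if (s$kind == "input_pulse") 0L else 1L,
      mask = as.integer(s$mask - 1L),
      amplitude = s$amplitude,
      step_on = step_on,
      step_off = step_on + max(1L, as.integer(round(s$duration / dt))))
  }

  if (identical(init_list, "background")) {
    bg <- background_state(model, globals)
    init_list <- list(u = rep(bg[1], n), v = rep(bg[2], n))
  }
  stopifnot(length(init_list$u) == n, length(init_list$v) == n,
            all(init_list$u >= 0 & init_list$u <= 1),
            all(init_list$v >= 0 & init_list$v <= 1))

  noise_m <- if (noise$coupling > 0)
    generate_noise(geom, noise, n_steps, per_unit = FALSE)
  else matrix(0, n_steps, geom$n_macros)

  ee_off <- model$ee_off; ei_off <- model$ei_off
  delay_ee <- list(); delay_ei <- list(); delay_steps <- integer(0)
  if (is.finite(delay_speed)) {
    stopifnot(delay_speed > 0)
    um_per_step <- delay_speed * 1000 * dt  # m/s = 1000 um/ms
    split_mat <- function(m) {
      tm <- methods::as(m, "TsparseMatrix")
      d <- sheet_distance(geom, tm@j + 1L, tm@i + 1L)
      # distances binned at one-pitch resolution before quantising to steps
      d_bin <- round(d / geom$pitch_um) * geom$pitch_um
      steps <- as.integer(round(d_bin / um_per_step))
      split(data.frame(i = tm@i + 1L, j = tm@j + 1L, x = tm@x), steps)
    }
    see <- split_mat(ee_off); sei <- split_mat(ei_off)
    keys <- sort(unique(as.integer(c(names(see), names(sei)))))
    mk <- function(df) if (is.null(df)) Matrix::sparseMatrix(i = integer(0),
        j = integer(0), x = numeric(0), dims = c(n, n))
      else Matrix::sparseMatrix(i = df$i, j = df$j, x = df$x, dims = c(n, n))
    zero <- mk(NULL)
    ee_off <- mk(see[["0"]]); ei_off <- mk(sei[["0"]])
    for (k in setdiff(keys, 0L)) {
      delay_ee[[length(delay_ee) + 1L]] <- mk(see[[as.character(k)]])
      delay_ei[[length(delay_ei) + 1L]] <- mk(sei[[as.character(k)]])
      delay_steps <- c(delay_steps, k)
    }
    if (length(delay_steps) && max(delay_steps) >= n_steps)
      stop("delay buffer longer than simulation")
  }

  out <- cpp_simulate_sheet(
    methods::as(ee_off, "CsparseMatrix"), methods::as(ei_off, "CsparseMatrix"),
    rep(model$diag_ee, n), rep(model$diag_ei, n),
    rep(model$diag_ie, n), rep(model$diag_ii, n),
    P0, Q0, globals$tau_e, globals$tau_i,
    noise$coupling, globals$sigmoid$steepness, globals$sigmoid$offset,
    ffe, ffi, noise_m, as.integer(geom$macro - 1L), geom$n_macros,
    n_steps, dt, init_list$u, init_list$v,
    cramps, cstims, delay_ee, delay_ei, as.integer(delay_steps),
    as.integer(u_stride), record_v_units)

  structure(list(
    t_macro = seq(0, by = dt, length.out = n_steps + 1),
    macro_u = out$macro_u, macro_v = out$macro_v,
    t_units = seq(0, by = dt * u_stride,
                  length.out = n_steps %/% u_stride + 1),
    u = out$u, v = if (record_v_units) out$v else NULL,
    u_final = as.numeric(out$u_final), v_final = as.numeric(out$v_final),
    geom = geom, dt = dt, duration = duration, u_stride = as.integer(u_stride),
    globals = globals, noise = noise, het = het, ramps = ramps,
    stimuli = stimuli, delay_speed = delay_speed,
    P0 = P0, Q0 = Q0
  ), class = "simulation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %g ms at dt=%g ms, %d units (%d macrocolumns)\n",
              x$duration, x$dt, x$geom$n_units, x$geom$n_macros))
  cat(sprintf("  per-unit field stored every %d steps (%d frames); noise B=%g seed=%d\n",
              x$u_stride, nrow(x$u), x$noise$coupling, x$noise$seed))
  invisible(x)
}

#' Local-field-potential proxy per macrocolumn
#'
#' The LFP proxy is the macrocolumn spatial average of a per-unit signal:
#' the excitatory firing activity (default, the convention used throughout)
#' or the net synaptic input to the excitatory populations.
#'
#' @param result a \code{simulation_result}.
#' @param mode \code{"e_activity"} or \code{"net_input"} (the latter needs
#'   \code{record_v_units = TRUE} and the \code{model}).
#' @param model the \code{connectivity_model} of the run (only for
#'   \code{"net_input"}).
#' @return matrix (time x macrocolumns); for \code{"e_activity"} at the
#'   per-step rate, for \code{"net_input"} at the stored per-unit frame rate.
#' @export
compute_lfp <- function(result, mode = c("e_activity", "net_input"),
                        model = NULL) {
  mode <- match.arg(mode)
  if (mode == "e_activity") return(result$macro_u)
  if (is.null(result$v) || is.null(model))
    stop("net_input mode requires record_v_units = TRUE and the model")
  geom <- result$geom
  n <- geom$n_units
  # net synaptic input to E at stored frames; masked P ramps re-evaluated at
  # frame times
  P <- matrix(rep(result$P0, each = nrow(result$u)), nrow(result$u), n)
  for (r in result$ramps %||% list()) {
    t <- result$t_units
    if (r$param != "p_basal") next
    frac <- pmin(pmax((t - r$t_start) / max(r$t_end - r$t_start, 1e-9), 0), 1)
    P[, r$mask %||% seq_len(n)] <- r$from + frac * (r$to - r$from)
  }
  net <- as.matrix(Matrix::tcrossprod(result$u, model$ee_off)) +
    model$diag_ee * result$u - model$diag_ie * result$v + P
  agg <- vapply(seq_len(geom$n_macros), function(m)
    rowMeans(net[, geom$macro == m, drop = FALSE]), numeric(nrow(net)))
  agg
}

#' Minimal pulse amplitude that elicits a criterion response
#'
#' Bisection (at most \code{max_iter} iterations, relative tolerance
#' \code{tol}) on the amplitude of an input pulse delivered to
#' \code{probe_mask}, with the noise seed frozen so that the amplitude ->
#' response map is deterministic.
#'
#' @param model a \code{connectivity_model}.
#' @param globals a \code{unit_params}.
#' @param het list of [het_override()]s or NULL.
#' @param probe_mask units receiving the probe pulse.
#' @param response_criterion function(simulation_result) -> logical.
#' @param bracket numeric c(lo, hi) amplitudes straddling the criterion.
#' @param noise a [noise_spec()] (frozen across evaluations).
#' @param duration,dt simulation window per evaluation, ms.
#' @param pulse_onset,pulse_duration probe pulse timing, ms.
#' @param tol relative bisection tolerance.
#' @param max_iter maximum bisection iterations.
#' @return list with \code{threshold} (NA if no sign change in the bracket),
#'   \code{status} ("ok" or "no threshold in range"), \code{n_evals}, and the
#'   final bracket.
#' @export
stimulus_threshold_probe <- function(model, globals, het = NULL, probe_mask,
                                     response_criterion, bracket,
                                     noise = noise_spec(),
                                     duration = 2000, dt = 2,
                                     pulse_onset = 200, pulse_duration = 20,
                                     tol = 1e-2, max_iter = 20L) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  evals <- 0L
  responds <- function(amp) {
    evals <<- evals + 1L
    res <- simulate_sheet(model, globals, het = het,
                          stimuli = stimulus_spec("input_pulse", probe_mask,
                                                  amp, pulse_onset,
                                                  pulse_duration),
                          noise = noise, duration = duration, dt = dt,
                          u_stride = 1000000L)
    isTRUE(response_criterion(res))
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- responds(lo); r_hi <- responds(hi)
  if (r_lo == r_hi)
    return(list(threshold = NA_real_, status = "no threshold in range",
                n_evals = evals, bracket = c(lo, hi)))
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (responds(mid) == r_hi) hi <- mid else lo <- mid
    if ((hi - lo) / max(abs(hi), 1e-12) < tol) break
  }
  list(threshold = (lo + hi) / 2, status = "ok", n_evals = evals,
       bracket = c(lo, hi))
}
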