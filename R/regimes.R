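#' Detect sustained oscillation in a scalar time series
#'
#' A series is called oscillatory when, over the analysis window (the last
#' \code{window_ms} after discarding the initial \code{transient_frac} of the
#' run), the peak-to-trough amplitude exceeds \code{amp_threshold} and the
#' dominant spectral frequency lies inside \code{freq_band}.
#'
#' @param x numeric series (e.g. the macrocolumn-mean E activity).
#' @param dt sampling step of \code{x}, ms.
#' @param window_ms analysis window length, ms (default: everything after the
#'   transient); must be shorter than the series.
#' @param amp_threshold peak-to-trough threshold (fractional firing units).
#' @param freq_band numeric c(lo, hi), Hz.
#' @param transient_frac fraction of the series discarded as transient.
#' @return list with \code{oscillating} (logical) and the metrics
#'   \code{amplitude} (peak-to-trough), \code{frequency} (Hz, dominant),
#'   \code{regularity} (fraction of spectral power in the dominant bin).
#' @export
detect_oscillation <- function(x, dt, window_ms = NULL, amp_threshold = 0.1,
                               freq_band = c(1, 30), transient_frac = 0.2) {
  n <- length(x)
  stopifnot(n >= 8, dt > 0)
  start <- floor(n * transient_frac) + 1L
  xs <- x[start:n]
  if (!is.null(window_ms)) {
    w <- round(window_ms / dt)
    if (w >= n) stop("analysis window must be shorter than the series")
    if (w < length(xs)) xs <- xs[(length(xs) - w + 1L):length(xs)]
  }
  amp <- max(xs) - min(xs)
  m <- length(xs)
  spec <- Mod(stats::fft(xs - mean(xs)))[2:(m %/% 2)]^2
  freqs <- seq_len(m %/% 2 - 1) / (m * dt / 1000)  # Hz
  k <- which.max(spec)
  dom <- freqs[k]
  # regularity: power within one bin of the peak (tolerant of leakage)
  kk <- max(1, k - 1):min(length(spec), k + 1)
  reg <- if (sum(spec) > 0) sum(spec[kk]) / sum(spec) else 0
  list(oscillating = amp > amp_threshold && dom >= freq_band[1] &&
         dom <= freq_band[2],
       amplitude = amp, frequency = dom, regularity = reg)
}

#' Regime-classification probe settings
#'
#' @param duration simulated time per probe run, ms.
#' @param dt step, ms.
#' @param noise_seed seed of the (frozen) noise stream.
#' @param amp_threshold,freq_band,transient_frac passed to
#'   [detect_oscillation()].
#' @param upper_mean post-transient mean-u level above which a
#'   non-oscillatory state counts as the upper (permanently firing) state.
#' @return an object of class \code{regime_probe}.
#' @export
regime_probe <- function(duration = 4000, dt = 2, noise_seed = 1L,
                         amp_threshold = 0.1, freq_band = c(1, 30),
                         transient_frac = 0.2, upper_mean = 0.8) {
  structure(list(duration = duration, dt = dt, noise_seed = noise_seed,
                 amp_threshold = amp_threshold, freq_band = freq_band,
                 transient_frac = transient_frac, upper_mean = upper_mean),
            class = "regime_probe")
}

state_label <- function(x, probe) {
  det <- detect_oscillation(x, probe$dt, amp_threshold = probe$amp_threshold,
                            freq_band = probe$freq_band,
                            transient_frac = probe$transient_frac)
  n <- length(x)
  post <- x[(floor(n * probe$transient_frac) + 1L):n]
  if (det$oscillating) "oscillatory"
  else if (mean(post) > probe$upper_mean) "upper"
  else "background"
}

#' Classify the mean-field regime of the coupled sheet
#'
#' Two-run protocol: run A starts from the background state; run B starts
#' from a strongly excited state: u is reset to 1 inside \code{reset_mask}
#' (by default one half of the sheet -- a fully synchronized whole-sheet
#' reset collapses through a single global inhibition wave and misses
#' spatially asynchronous oscillatory attractors; the half-sheet reset
#' breaks that symmetry while still strongly exciting the sheet).  The
#' post-transient sheet-mean E activity of each run is labelled oscillatory /
#' background / upper, and the pair is combined:
#' A background + B background = \code{monostable_background};
#' A background + B oscillatory = \code{bistable_background_oscillation};
#' A oscillatory + B oscillatory = \code{monostable_oscillation};
#' A background + B upper = \code{bistable_background_upper}.
#' Any other combination is labelled \code{unresolved} (never silently
#' coerced).
#'
#' @param model a \code{connectivity_model}.
#' @param globals a \code{unit_params}.
#' @param probe a [regime_probe()].
#' @param het optional list of [het_override()]s applied in both runs.
#' @param reset_mask units whose u is reset to 1 in run B (default: the left
#'   half of the sheet).
#' @return list with \code{label} and the per-run states and metrics.
#' @export
classify_regime <- function(model, globals, probe = regime_probe(),
                            het = NULL, reset_mask = NULL) {
  if (is.null(reset_mask))
    reset_mask <- which(model$geom$col <= model$geom$n_cols / 2)
  run <- function(reset_high) {
    init <- "background"
    if (reset_high) {
      bg <- background_state(model, globals)
      n <- model$geom$n_units
      u0 <- rep(bg[1], n); u0[reset_mask] <- 1
      init <- list(u = u0, v = rep(bg[2], n))
    }
    res <- simulate_sheet(model, globals, het = het,
                          noise = noise_spec(globals$noise_coupling,
                                             probe$noise_seed),
                          duration = probe$duration, dt = probe$dt,
                          init = init, u_stride = 1000000L)
    rowMeans(res$macro_u)
  }
  xa <- run(FALSE); xb <- run(TRUE)
  a <- state_label(xa, probe); b <- state_label(xb, probe)
  label <-
    if (a == "background" && b == "background") "monostable_background"
    else if (a == "background" && b == "oscillatory") "bistable_background_oscillation"
    else if (a == "oscillatory" && b == "oscillatory") "monostable_oscillation"
    else if (a == "background" && b == "upper") "bistable_background_upper"
    else "unresolved"
  list(label = label, run_a = a, run_b = b)
}

apply_scan_param <- function(globals, het, param, value) {
  if (param %in% c("ffw_e_scale", "ffw_i_scale")) {
    list(globals = globals,
         het = c(het %||% list(),
                 list(het_override(param, mask = NA, value = value,
                                   mode = "scale"))))
  } else {
    args <- list(globals); args[[param]] <- value
    list(globals = do.call(update_unit_params, args), het = het)
  }
}

#' Two-dimensional regime map
#'
#' Runs [classify_regime()] on every grid point of two scanned parameters.
#' Parameters can be any scalar [unit_params()] field (e.g. \code{p_basal},
#' \code{q_basal}) or the feed-forward scales \code{ffw_e_scale} /
#' \code{ffw_i_scale} (global multipliers on the between-unit E->E / E->I
#' input, i.e. the feed-forward excitation and inhibition weights).
#'
#' @param model a \code{connectivity_model} (a reduced sheet is commonly used
#'   for speed; the geometry used is recorded in the result).
#' @param globals baseline \code{unit_params}.
#' @param axis_x,axis_y lists \code{list(param = "p_basal", values = ...)}.
#' @param probe a [regime_probe()].
#' @return data.frame of class \code{regime_map} with columns \code{x},
#'   \code{y}, \code{label}; axis names, geometry and probe stored as
#'   attributes.
#' @export
scan_regime_2d <- function(model, globals = standard_unit_params(),
                           axis_x, axis_y, probe = regime_probe()) {
  stopifnot(length(axis_x$values) >= 1, length(axis_y$values) >= 1)
  grid <- expand.grid(x = axis_x$values, y = axis_y$values)
  labels <- character(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    sx <- apply_scan_param(globals, NULL, axis_x$param, grid$x[k])
    sy <- apply_scan_param(sx$globals, sx$het, axis_y$param, grid$y[k])
    het <- sy$het
    if (!is.null(het))
      het <- lapply(het, function(h) {
        if (length(h$mask) == 1 && is.na(h$mask))
          h$mask <- seq_len(model$geom$n_units)
        h
      })
    labels[k] <- classify_regime(model, sy$globals, probe, het = het)$label
  }
  out <- data.frame(x = grid$x, y = grid$y, label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "axis_x") <- axis_x$param
  attr(out, "axis_y") <- axis_y$param
  attr(out, "geometry") <- model$geom[c("n_rows", "n_cols", "boundary")]
  attr(out, "probe") <- probe
  class(out) <- c("regime_map", "data.frame")
  out
}

#' Write a regime map as a tabular file
#'
#' @param map a \code{regime_map}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_regime_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
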