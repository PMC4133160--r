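analytic_signal <- function(x) {
  # columnwise analytic signal (Hilbert transform via FFT)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x)
  stats::mvfft(X * h, inverse = TRUE) / n
}

neighbour_matrix <- function(geom, radius_units) {
  off <- lattice_disc_offsets(radius_units)
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  n <- geom$n_units
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    r2 <- geom$row + off[k, 1]; c2 <- geom$col + off[k, 2]
    if (geom$boundary == "torus") {
      r2 <- ((r2 - 1L) %% geom$n_rows) + 1L
      c2 <- ((c2 - 1L) %% geom$n_cols) + 1L
      ok <- rep(TRUE, n)
    } else ok <- r2 >= 1 & r2 <= geom$n_rows & c2 >= 1 & c2 <= geom$n_cols
    sel <- which(ok)
    from <- c(from, sel); to <- c(to, unit_index(geom, r2[sel], c2[sel]))
  }
  A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  # row-normalise: row i averages over the neighbours of i
  Matrix::Diagonal(n, 1 / Matrix::rowSums(A)) %*% A
}

col_max <- function(m) Reduce(pmax, asplit(m, 1))
col_min <- function(m) Reduce(pmin, asplit(m, 1))

#' Detect recruited (seizure-core) units
#'
#' A unit counts as recruited from the first time a sliding analysis window
#' shows (i) peak-to-trough amplitude above \code{amp_threshold}, (ii) at
#' least \code{min_cycles} oscillation cycles (upward mean-crossings), and
#' (iii) mean phase coherence with the units within \code{sync_radius}
#' (phase-locking value against the neighbourhood mean phase) above
#' \code{coherence_threshold} -- high-amplitude oscillation synchronous with
#' its neighbourhood up to a phase shift.  Windows are evaluated every
#' \code{cadence_ms}; within the first qualifying window the onset time is
#' refined to the first frame at which the activity departs from the
#' window-start baseline by half the amplitude threshold.
#'
#' @param result a \code{simulation_result} (uses the stored per-unit field).
#' @param amp_threshold peak-to-trough threshold, fractional firing units.
#' @param min_cycles minimum complete cycles per window.
#' @param sync_radius neighbourhood radius, lattice units.
#' @param coherence_threshold phase-locking threshold in [0, 1].
#' @param window_ms sliding window length, ms.
#' @param cadence_ms cadence at which windows are evaluated, ms.
#' @param baseline_mask unit indices of the imposed hyperactive region
#'   (microdomain / stimulated set); used for the surround-normalised
#'   percentage.
#' @return object of class \code{recruitment_report}: per-unit \code{recruited}
#'   (ever qualified) and \code{onset_ms}; \code{fraction} (time course at
#'   cadence, relative to all units; non-decreasing by construction) and
#'   \code{fraction_surround}; \code{active} / \code{active_fraction} /
#'   \code{active_percent} (units qualifying in the evaluated window itself,
#'   which can fall after an intervention); \code{final_percent} and
#'   \code{final_percent_surround}; detector settings.
#' @export
detect_recruited_units <- function(result, amp_threshold = 0.1,
                                   min_cycles = 3, sync_radius = 3,
                                   coherence_threshold = 0.8,
                                   window_ms = 1000, cadence_ms = 300,
                                   baseline_mask = NULL) {
  x <- result$u
  dt_f <- result$t_units[2] - result$t_units[1]
  n_frames <- nrow(x); n <- ncol(x)
  w <- round(window_ms / dt_f)
  if (w >= n_frames) stop("analysis window longer than the simulation")
  geom <- result$geom

  an <- analytic_signal(x - matrix(colMeans(x), n_frames, n, byrow = TRUE))
  phi <- Arg(an)
  rm(an); gc(FALSE)
  z_re <- cos(phi); z_im <- sin(phi)
  rm(phi); gc(FALSE)
  NB <- neighbour_matrix(geom, sync_radius)
  nb_re <- as.matrix(Matrix::tcrossprod(z_re, NB))
  nb_im <- as.matrix(Matrix::tcrossprod(z_im, NB))
  nb_mod <- pmax(sqrt(nb_re^2 + nb_im^2), 1e-12)
  # z * conj(neighbour mean direction)
  zc_re <- (z_re * nb_re + z_im * nb_im) / nb_mod
  zc_im <- (z_im * nb_re - z_re * nb_im) / nb_mod
  rm(z_re, z_im, nb_re, nb_im, nb_mod); gc(FALSE)

  starts <- seq(1L, n_frames - w, by = max(1L, round(cadence_ms / dt_f)))
  t_win <- result$t_units[starts + w]  # window end times
  onset <- rep(NA_real_, n)
  frac <- numeric(length(starts))
  active_frac <- numeric(length(starts))
  active_last <- logical(n)
  for (kk in seq_along(starts)) {
    idx <- starts[kk]:(starts[kk] + w)
    sl <- x[idx, , drop = FALSE]
    amp <- col_max(sl) - col_min(sl)
    mu <- colMeans(sl)
    s <- sign(sweep(sl, 2, mu))
    cycles <- colSums(diff(s) > 0)
    plv <- sqrt(colMeans(zc_re[idx, , drop = FALSE])^2 +
                colMeans(zc_im[idx, , drop = FALSE])^2)
    ok <- amp > amp_threshold & cycles >= min_cycles &
      plv >= coherence_threshold
    active_frac[kk] <- mean(ok)
    if (kk == length(starts)) active_last <- ok
    newly <- which(ok & is.na(onset))
    if (length(newly)) {
      # refine onset inside the qualifying window: first departure from the
      # window-start baseline by half the amplitude threshold
      n_base <- max(2L, round(length(idx) / 10))
      for (i in newly) {
        base <- stats::median(sl[seq_len(n_base), i])
        cross <- which(abs(sl[, i] - base) > amp_threshold / 2)
        onset[i] <- if (length(cross)) result$t_units[idx[cross[1]]]
                    else t_win[kk]
      }
    }
    frac[kk] <- mean(!is.na(onset))
  }
  recruited <- !is.na(onset)
  surround <- if (is.null(baseline_mask)) seq_len(n)
              else setdiff(seq_len(n), baseline_mask)
  frac_sur <- vapply(t_win, function(tt)
    mean(recruited[surround] & onset[surround] <= tt + 1e-9), numeric(1))
  structure(list(
    recruited = recruited, onset_ms = onset,
    t_window = t_win, fraction = frac, fraction_surround = frac_sur,
    active = active_last, active_fraction = active_frac,
    active_percent = 100 * mean(active_last),
    final_percent = 100 * mean(recruited),
    final_percent_surround = 100 * mean(recruited[surround]),
    baseline_mask = baseline_mask,
    settings = list(amp_threshold = amp_threshold, min_cycles = min_cycles,
                    sync_radius = sync_radius,
                    coherence_threshold = coherence_threshold,
                    window_ms = window_ms, cadence_ms = cadence_ms),
    geom = geom, noise_seed = result$noise$seed
  ), class = "recruitment_report")
}

#' @export
print.recruitment_report <- function(x, ...) {
  cat(sprintf("<recruitment_report> %d/%d units recruited (%.1f%%; %.1f%% of surround)\n",
              sum(x$recruited), length(x$recruited), x$final_percent,
              x$final_percent_surround))
  invisible(x)
}

#' Recruitment wavefront speed from onset times
#'
#' Robust (Theil-Sen) linear fit of oscillation-onset time against distance
#' from the seed region; the speed is the inverse slope.  Pairwise slopes are
#' subsampled for large unit counts.
#'
#' @param report a \code{recruitment_report}.
#' @param geom the \code{sheet_geometry} of the run.
#' @param seed_region unit indices of the seed (stimulated or hyperactive)
#'   region; these units are excluded from the fit.
#' @param min_units minimum recruited units outside the seed region.
#' @param max_pairs pairwise-slope subsample cap.
#' @return list with \code{speed_m_per_s} (NA when undefined),
#'   \code{status} ("ok" or "speed undefined"), \code{r_squared} of the
#'   least-squares fit, \code{residual_sd_ms}, and \code{n_units}.
#' @export
estimate_wavefront_speed <- function(report, geom, seed_region,
                                     min_units = 20, max_pairs = 20000) {
  onset <- report$onset_ms
  cand <- setdiff(which(!is.na(onset)), seed_region)
  if (length(cand) < min_units)
    stop("need at least ", min_units, " recruited units outside the seed region")
  # distance to the nearest seed unit
  d <- rep(Inf, geom$n_units)
  for (s in seed_region)
    d <- pmin(d, sheet_distance(geom, s, seq_len(geom$n_units)))
  x <- d[cand]; y <- onset[cand]
  if (stats::sd(x) < 1e-9)
    return(list(speed_m_per_s = NA_real_, status = "speed undefined",
                r_squared = NA_real_, residual_sd_ms = NA_real_,
                n_units = length(cand)))
  m <- length(x)
  pairs <- if (m * (m - 1) / 2 <= max_pairs) {
    utils::combn(m, 2)
  } else {
    with_seed(1L, matrix(sample.int(m, 2 * max_pairs, replace = TRUE), 2))
  }
  dx <- x[pairs[2, ]] - x[pairs[1, ]]
  dy <- y[pairs[2, ]] - y[pairs[1, ]]
  keep <- abs(dx) > 1e-9
  slope <- stats::median(dy[keep] / dx[keep])  # ms per um
  if (!is.finite(slope) || abs(slope) < 1e-9)
    return(list(speed_m_per_s = NA_real_, status = "speed undefined",
                r_squared = NA_real_, residual_sd_ms = NA_real_,
                n_units = length(cand)))
  fit <- stats::lm(y ~ x)
  list(speed_m_per_s = (1 / slope) / 1000,  # um/ms -> m/s
       status = "ok",
       r_squared = suppressWarnings(summary(fit)$r.squared),
       residual_sd_ms = stats::sd(y - slope * x),
       n_units = length(cand))
}

grow_quasi_disc <- function(geom, center, size) {
  # the `size` lattice units nearest to the centre (ties broken by index)
  d <- sheet_distance(geom, center, seq_len(geom$n_units))
  order(d, seq_len(geom$n_units))[seq_len(size)]
}

#' Place disjoint contiguous subclusters of hyperactive units
#'
#' Splits \code{total_units} into \code{n_subclusters} contiguous
#' quasi-discs of as-equal-as-possible size (within one unit), each grown
#' around a uniformly drawn centre; overlapping draws are rejected and
#' redrawn up to \code{max_tries} times per subcluster.
#'
#' @param geom a \code{sheet_geometry}.
#' @param total_units total hyperactive units (<= sheet size).
#' @param n_subclusters number of subclusters (<= total_units).
#' @param placement_seed integer seed.
#' @param max_tries redraw budget per subcluster.
#' @return object of class \code{cluster_layout}: list with \code{members}
#'   (list of integer vectors), \code{sizes}, \code{centers},
#'   \code{all_units}, and the seed.
#' @export
place_subclusters <- function(geom, total_units, n_subclusters,
                              placement_seed = 1L, max_tries = 100L) {
  total_units <- as.integer(total_units)
  n_subclusters <- as.integer(n_subclusters)
  stopifnot(total_units <= geom$n_units, n_subclusters >= 1,
            n_subclusters <= total_units)
  base <- total_units %/% n_subclusters
  sizes <- rep(base, n_subclusters)
  extra <- total_units - base * n_subclusters
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  with_seed(placement_seed, {
    members <- vector("list", n_subclusters)
    taken <- logical(geom$n_units)
    for (k in seq_len(n_subclusters)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        center <- sample.int(geom$n_units, 1)
        mem <- grow_quasi_disc(geom, center, sizes[k])
        if (!any(taken[mem])) {
          members[[k]] <- sort(mem)
          taken[mem] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place subcluster ", k, " disjointly within ",
             max_tries, " redraws")
    }
    structure(list(members = members, sizes = sizes,
                   centers = vapply(members, function(m) m[1], integer(1)),
                   all_units = sort(unlist(members)),
                   placement_seed = placement_seed),
              class = "cluster_layout")
  })
}

#' @export
print.cluster_layout <- function(x, ...) {
  cat(sprintf("<cluster_layout> %d units in %d subclusters (sizes %s)\n",
              length(x$all_units), length(x$members),
              paste(unique(x$sizes), collapse = "/")))
  invisible(x)
}

microdomain_ramp <- function(mask, p_target, t_start = 200, t_end = 1200,
                             p_from) {
  ramp_spec("p_basal", from = p_from, to = p_target,
            t_start = t_start, t_end = t_end, mask = mask)
}

#' Recruitment scan over a two-axis grid of scenario settings
#'
#' Runs one of four scenario templates per grid cell, applies the
#' recruitment detector, and aggregates mean and dispersion over
#' \code{trials} repeats (noise seed and placement seed are advanced
#' together per trial).
#'
#' Templates:
#' \describe{
#'   \item{pulse_stimulus}{axes: \code{n_units} stimulated (contiguous patch
#'     at a random position) x surround \code{p_basal}; a fixed input pulse
#'     is delivered to the patch.}
#'   \item{oscillatory_microdomain}{axes: microdomain \code{n_units} x
#'     surround \code{p_basal}; the microdomain's P is ramped to the
#'     oscillatory preset.}
#'   \item{subcluster_network}{axes: total hyperactive \code{n_units} x
#'     \code{n_subclusters}; all subclusters ramped to the oscillatory
#'     preset; surround fixed at \code{globals$p_basal}.}
#'   \item{bistable_microdomain_probe}{axes: microdomain \code{n_units} x
#'     microdomain \code{p_basal}; the microdomain is classified
#'     monostable-background / bistable / monostable-oscillatory by a local
#'     two-initial-condition probe instead of the recruitment detector.}
#' }
#'
#' @param model a \code{connectivity_model}.
#' @param globals surround \code{unit_params}.
#' @param template one of the template names above.
#' @param axis_x,axis_y lists \code{list(param = <name>, values = <numeric>)}
#'   with params as described per template.
#' @param trials repeats per cell (>= 1).
#' @param duration simulated time per run, ms.
#' @param seed master seed; trial seeds derive from it.
#' @param pulse_amplitude,pulse_duration input pulse settings
#'   (pulse_stimulus template).
#' @param detector list of overrides passed to [detect_recruited_units()].
#' @param surround_normalised report the recruited percentage relative to
#'   units outside the imposed region (TRUE) or to all units.
#' @return data.frame of class \code{scan_result} with columns \code{x},
#'   \code{y}, \code{mean}, \code{sd}, \code{n_trials} (for the probe
#'   template, \code{label} of the majority call and \code{agreement}).
#' @export
run_recruitment_scan <- function(model, globals = standard_unit_params(),
                                 template = c("pulse_stimulus",
                                              "oscillatory_microdomain",
                                              "subcluster_network",
                                              "bistable_microdomain_probe"),
                                 axis_x, axis_y, trials = 1L,
                                 duration = 6000, seed = 1L,
                                 pulse_amplitude = 20, pulse_duration = 20,
                                 detector = list(),
                                 surround_normalised = TRUE) {
  template <- match.arg(template)
  geom <- model$geom
  p_osc <- sheet_p_presets()[["oscillatory"]]
  grid <- expand.grid(x = axis_x$values, y = axis_y$values)
  out <- data.frame(grid, mean = NA_real_, sd = NA_real_,
                    n_trials = as.integer(trials))
  if (template == "bistable_microdomain_probe") {
    out$label <- NA_character_; out$agreement <- NA_real_
  }
  for (cell in seq_len(nrow(grid))) {
    vals <- numeric(0); labs <- character(0)
    for (tr in seq_len(trials)) {
      sd_seed <- seed + 7919L * (tr - 1L) + 104729L * (cell - 1L)
      res <- tryCatch(
        run_scan_cell(model, globals, template, grid$x[cell], grid$y[cell],
                      axis_x$param, axis_y$param, duration, sd_seed,
                      pulse_amplitude, pulse_duration, detector,
                      surround_normalised, p_osc),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning("cell (", grid$x[cell], ", ", grid$y[cell], ") trial ", tr,
                " failed: ", conditionMessage(res))
        next
      }
      if (template == "bistable_microdomain_probe") labs <- c(labs, res)
      else vals <- c(vals, res)
    }
    if (template == "bistable_microdomain_probe") {
      if (length(labs)) {
        tab <- table(labs)
        out$label[cell] <- names(tab)[which.max(tab)]
        out$agreement[cell] <- max(tab) / length(labs)
      }
    } else if (length(vals)) {
      out$mean[cell] <- mean(vals)
      out$sd[cell] <- if (length(vals) > 1) stats::sd(vals) else NA_real_
    }
    out$n_trials[cell] <- if (template == "bistable_microdomain_probe")
      length(labs) else length(vals)
  }
  attr(out, "template") <- template
  attr(out, "axes") <- c(x = axis_x$param, y = axis_y$param)
  class(out) <- c("scan_result", "data.frame")
  out
}

run_scan_cell <- function(model, globals, template, xv, yv, xp, yp,
                          duration, seed, pulse_amplitude, pulse_duration,
                          detector, surround_normalised, p_osc) {
  geom <- model$geom
  get_par <- function(name, default) {
    if (identical(xp, name)) return(xv)
    if (identical(yp, name)) return(yv)
    default
  }
  n_units <- round(get_par("n_units", 400))
  surr_p <- get_par("p_basal", globals$p_basal)
  glob <- update_unit_params(globals, p_basal = surr_p)

  if (template == "subcluster_network") {
    n_sub <- round(get_par("n_subclusters", 1))
    layout <- place_subclusters(geom, n_units, n_sub, placement_seed = seed)
    mask <- layout$all_units
  } else {
    layout <- place_subclusters(geom, n_units, 1, placement_seed = seed)
    mask <- layout$all_units
  }

  if (template == "bistable_microdomain_probe") {
    p_micro <- get_par("p_basal", globals$p_basal)
    glob <- globals  # surround stays at the global preset
    het <- het_override("p_basal", mask, p_micro, "absolute")
    run_mean <- function(init_high) {
      init <- "background"
      if (init_high) {
        bg <- background_state(model, glob)
        u0 <- rep(bg[1], geom$n_units); u0[mask] <- 1
        init <- list(u = u0, v = rep(bg[2], geom$n_units))
      }
      res <- simulate_sheet(model, glob, het = het,
                            noise = noise_spec(glob$noise_coupling, seed),
                            duration = duration, init = init,
                            u_stride = 4L)
      rowMeans(res$u[, mask, drop = FALSE])
    }
    dt_f <- 2 * 4
    lab <- function(xm) {
      det <- detect_oscillation(xm, dt_f)
      if (det$oscillating) "oscillatory"
      else if (mean(xm[(length(xm) %/% 2):length(xm)]) > 0.8) "upper"
      else "background"
    }
    a <- lab(run_mean(FALSE)); b <- lab(run_mean(TRUE))
    return(if (a == "background" && b == "background") "monostable_background"
           else if (a == "background" && b %in% c("oscillatory", "upper"))
             "bistable"
           else if (a == "oscillatory") "monostable_oscillatory"
           else "unresolved")
  }

  ramps <- NULL; stimuli <- NULL
  if (template == "pulse_stimulus") {
    stimuli <- stimulus_spec("input_pulse", mask, pulse_amplitude,
                             onset = 400, duration = pulse_duration)
  } else {
    ramps <- microdomain_ramp(mask, p_osc, p_from = glob$p_basal)
  }
  res <- simulate_sheet(model, glob, ramps = ramps, stimuli = stimuli,
                        noise = noise_spec(glob$noise_coupling, seed),
                        duration = duration, u_stride = 4L)
  args <- c(list(result = res, baseline_mask = mask), detector)
  rep <- do.call(detect_recruited_units, args)
  if (surround_normalised) rep$final_percent_surround else rep$final_percent
}
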