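#' Scenario configuration
#'
#' Turn-key drivers reproducing the package's canonical experiments: the
#' three classes of focal seizure onset plus the two intervention
#' experiments.  All scenario inputs are presets derived from
#' [standard_unit_params()], [standard_connectivity_params()] and
#' [sheet_p_presets()]; \code{overrides} can replace any of the documented
#' per-scenario settings.
#'
#' @param name one of \code{class1_global_ramp}, \code{class2a_pulse},
#'   \code{class2b_microdomain}, \code{class3a_subclusters},
#'   \code{class3b_bistable_microdomains}, \code{counter_stimulation},
#'   \code{microincision}.
#' @param geometry_scale linear sheet-size factor (1 = 150 x 150).
#' @param seed master seed (connectivity, placement and noise streams are
#'   derived from it; no hidden entropy).
#' @param outdir optional output directory for artifacts.
#' @param overrides named list of scenario-specific setting replacements.
#' @return an object of class \code{scenario_config}.
#' @export
scenario_config <- function(name = c("class1_global_ramp", "class2a_pulse",
                                     "class2b_microdomain",
                                     "class3a_subclusters",
                                     "class3b_bistable_microdomains",
                                     "counter_stimulation", "microincision"),
                            geometry_scale = 1, seed = 1L, outdir = NULL,
                            overrides = list()) {
  name <- match.arg(name)
  structure(list(name = name, geometry_scale = geometry_scale,
                 seed = as.integer(seed), outdir = outdir,
                 overrides = overrides),
            class = "scenario_config")
}

scenario_settings <- function(config) {
  p <- sheet_p_presets()
  scale <- config$geometry_scale
  n_tot <- round(2250 * scale^2)          # 10% of the sheet
  micro_n <- max(200, round(300 * scale^2))
  s <- switch(config$name,
    class1_global_ramp = list(
      boundary = "torus", duration = 6000,
      ramp = list(from = p[["deep_background"]], to = -1,
                  t_start = 500, t_end = 4000),
      het_scale = 1.5, het_frac = 0.12),
    class2a_pulse = list(
      boundary = "torus", duration = 8000,
      p_bistable = p[["bistable"]], p_monostable = p[["interictal"]],
      pulse_n = micro_n, pulse_amplitude = 20, pulse_duration = 20,
      pulse_onset = 1000),
    class2b_microdomain = list(
      boundary = "torus", duration = 9000,
      p_bistable = p[["bistable"]], p_monostable = p[["interictal"]],
      micro_n = micro_n, p_micro = p[["microdomain_target"]],
      ramp_window = c(500, 1500)),
    class3a_subclusters = list(
      boundary = "torus", duration = 10000,
      p_surround = p[["interictal"]], total_units = n_tot,
      n_subclusters = 17, p_micro = p[["microdomain_target"]],
      ramp_window = c(200, 1200)),
    class3b_bistable_microdomains = list(
      boundary = "torus", duration = 24000,
      p_surround = p[["interictal"]], p_micro = -1.3,
      n_domains = max(4, round(15 * scale)), domain_n = micro_n,
      stim_times = seq(0, 21000, by = 3000), pulse_n = micro_n,
      pulse_amplitude = 20, pulse_duration = 20),
    counter_stimulation = list(
      boundary = "torus", duration = 8000,
      p_bistable = -1.6, pulse_n = 1200,
      pulse_amplitude = 20, pulse_duration = 20, pulse_onset = 1000,
      counter_onset = 2000, counter_cover_factor = 3),
    microincision = list(
      boundary = "zero_flux", duration = 9000,
      p_bistable = p[["near_pinning"]], micro_n = micro_n,
      p_micro = p[["microdomain_target"]], ramp_window = c(500, 1500))
  )
  utils::modifyList(s, config$overrides)
}

scenario_contract <- function(artifact, name, passed, detail) {
  artifact$contracts <- rbind(artifact$contracts,
                              data.frame(contract = name, passed = passed,
                                         detail = detail))
  artifact
}

#' Run a canonical scenario
#'
#' Builds the sheet and connectivity from presets, runs the scenario's
#' simulation protocol, applies the recruitment detector, and evaluates the
#' scenario's dynamical contract (e.g. "the microdomain stays isolated in a
#' monostable surround").  Contract violations raise an error naming the
#' contract unless \code{enforce_contracts = FALSE}.
#'
#' @param config a [scenario_config()].
#' @param enforce_contracts stop on a violated contract (default TRUE).
#' @return an object of class \code{run_artifact}: the simulation result(s),
#'   recruitment report(s), the evaluated \code{contracts} table, and the
#'   configuration echo.  If \code{config$outdir} is set, macrocolumn traces,
#'   the contracts table and a JSON run manifest are written there.
#' @export
run_scenario <- function(config, enforce_contracts = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  s <- scenario_settings(config)
  geom <- standard_geometry(config$geometry_scale, boundary = s$boundary)
  model <- build_connectivity(geom, seed = config$seed)
  up <- standard_unit_params()
  art <- structure(list(scenario = config$name, config = config,
                        settings = s, contracts = NULL,
                        results = list(), reports = list()),
                   class = "run_artifact")
  art <- switch(config$name,
    class1_global_ramp = scenario_class1(art, geom, model, up, s, config),
    class2a_pulse = scenario_class2a(art, geom, model, up, s, config),
    class2b_microdomain = scenario_class2b(art, geom, model, up, s, config),
    class3a_subclusters = scenario_class3a(art, geom, model, up, s, config),
    class3b_bistable_microdomains =
      scenario_class3b(art, geom, model, up, s, config),
    counter_stimulation = scenario_counter(art, geom, model, up, s, config),
    microincision = scenario_incision(art, geom, model, up, s, config))
  if (!is.null(config$outdir)) write_run_artifact(art, config$outdir)
  if (enforce_contracts && !all(art$contracts$passed)) {
    bad <- art$contracts[!art$contracts$passed, ]
    stop("scenario contract violated: ",
         paste(bad$contract, "(", bad$detail, ")", collapse = "; "))
  }
  art
}

central_disc <- function(geom, n_units) {
  center <- unit_index(geom, round(geom$n_rows / 2), round(geom$n_cols / 2))
  grow_quasi_disc(geom, center, n_units)
}

scenario_class1 <- function(art, geom, model, up, s, config) {
  patch <- central_disc(geom, round(s$het_frac * geom$n_units))
  het <- het_override("ffw_e_scale", patch, s$het_scale, "scale")
  ramp <- ramp_spec("p_basal", s$ramp$from, s$ramp$to,
                    s$ramp$t_start, s$ramp$t_end)
  glob <- update_unit_params(up, p_basal = s$ramp$from)
  res <- simulate_sheet(model, glob, het = het, ramps = ramp,
                        noise = noise_spec(up$noise_coupling, config$seed),
                        duration = s$duration, u_stride = 4)
  # per-macrocolumn time of crossing into the active state
  cross <- apply(res$macro_u, 2, function(x) {
    i <- which(x > 0.5)[1]
    if (is.na(i)) NA_real_ else res$t_macro[i]
  })
  frac_in_patch <- vapply(seq_len(geom$n_macros), function(m)
    mean(geom$macro[patch] == m) * length(patch) /
      sum(geom$macro == m), numeric(1))
  patch_macros <- which(frac_in_patch > 0.5)
  onset_patch <- max(cross[patch_macros])
  onset_median <- stats::median(cross, na.rm = TRUE)
  art$results$run <- res
  art$patch <- patch
  art$macro_onsets <- cross
  art <- scenario_contract(art, "patch_leads_global_onset",
    isTRUE(onset_patch < onset_median),
    sprintf("patch macros cross at %.0f ms, sheet median %.0f ms",
            onset_patch, onset_median))
  art
}

scenario_class2a <- function(art, geom, model, up, s, config) {
  mask <- central_disc(geom, s$pulse_n)
  stim <- stimulus_spec("input_pulse", mask, s$pulse_amplitude,
                        s$pulse_onset, s$pulse_duration)
  one <- function(P) {
    res <- simulate_sheet(model, update_unit_params(up, p_basal = P),
                          stimuli = stim,
                          noise = noise_spec(up$noise_coupling, config$seed),
                          duration = s$duration, u_stride = 4)
    list(res = res, rep = detect_recruited_units(res, baseline_mask = mask))
  }
  bi <- one(s$p_bistable); mono <- one(s$p_monostable)
  growing <- all(diff(bi$rep$fraction) >= -1e-9) &&
    utils::tail(bi$rep$fraction_surround, 1) > 0.5
  art$results <- list(bistable = bi$res, monostable = mono$res)
  art$reports <- list(bistable = bi$rep, monostable = mono$rep)
  art$stim_mask <- mask
  art <- scenario_contract(art, "pulse_recruits_bistable_sheet", growing,
    sprintf("bistable surround recruited %.1f%%", bi$rep$final_percent_surround))
  art <- scenario_contract(art, "pulse_dies_in_monostable_sheet",
    mono$rep$final_percent_surround < 10,
    sprintf("monostable surround recruited %.1f%%",
            mono$rep$final_percent_surround))
  art
}

scenario_class2b <- function(art, geom, model, up, s, config) {
  mask <- central_disc(geom, s$micro_n)
  one <- function(P) {
    ramp <- ramp_spec("p_basal", P, s$p_micro, s$ramp_window[1],
                      s$ramp_window[2], mask = mask)
    res <- simulate_sheet(model, update_unit_params(up, p_basal = P),
                          ramps = ramp,
                          noise = noise_spec(up$noise_coupling, config$seed),
                          duration = s$duration, u_stride = 4)
    list(res = res, rep = detect_recruited_units(res, baseline_mask = mask))
  }
  bi <- one(s$p_bistable); mono <- one(s$p_monostable)
  art$results <- list(bistable = bi$res, monostable = mono$res)
  art$reports <- list(bistable = bi$rep, monostable = mono$rep)
  art$micro_mask <- mask
  art <- scenario_contract(art, "microdomain_recruits_bistable_surround",
    bi$rep$final_percent_surround > 50,
    sprintf("bistable surround recruited %.1f%%",
            bi$rep$final_percent_surround))
  art <- scenario_contract(art, "microdomain_isolated_in_monostable_surround",
    mono$rep$final_percent_surround < 10 &&
      mean(mono$rep$recruited[mask]) > 0.5,
    sprintf("monostable surround %.1f%%, microdomain %.0f%%",
            mono$rep$final_percent_surround,
            100 * mean(mono$rep$recruited[mask])))
  art
}

scenario_class3a <- function(art, geom, model, up, s, config) {
  glob <- update_unit_params(up, p_basal = s$p_surround)
  one <- function(nsub) {
    lay <- place_subclusters(geom, s$total_units, nsub,
                             placement_seed = config$seed + 101L)
    ramp <- ramp_spec("p_basal", s$p_surround, s$p_micro, s$ramp_window[1],
                      s$ramp_window[2], mask = lay$all_units)
    res <- simulate_sheet(model, glob, ramps = ramp,
                          noise = noise_spec(up$noise_coupling, config$seed),
                          duration = s$duration, u_stride = 4)
    list(lay = lay, res = res,
         rep = detect_recruited_units(res, baseline_mask = lay$all_units))
  }
  sub <- one(s$n_subclusters); comp <- one(1)
  art$results <- list(subclustered = sub$res, compact = comp$res)
  art$reports <- list(subclustered = sub$rep, compact = comp$rep)
  art$layouts <- list(subclustered = sub$lay, compact = comp$lay)
  art <- scenario_contract(art, "subclusters_recruit_monostable_surround",
    sub$rep$final_percent_surround >
      comp$rep$final_percent_surround + 20 &&
      comp$rep$final_percent_surround < 20,
    sprintf("subclustered %.1f%% vs compact %.1f%%",
            sub$rep$final_percent_surround, comp$rep$final_percent_surround))
  art
}

scenario_class3b <- function(art, geom, model, up, s, config) {
  glob <- update_unit_params(up, p_basal = s$p_surround)
  lay <- place_subclusters(geom, s$n_domains * s$domain_n, s$n_domains,
                           placement_seed = config$seed + 202L)
  het <- het_override("p_basal", lay$all_units, s$p_micro, "absolute")
  stims <- with_seed(config$seed + 303L, lapply(s$stim_times, function(tt) {
    center <- sample.int(geom$n_units, 1)
    stimulus_spec("input_pulse", grow_quasi_disc(geom, center, s$pulse_n),
                  s$pulse_amplitude, tt + 100, s$pulse_duration)
  }))
  res <- simulate_sheet(model, glob, het = het, stimuli = stims,
                        noise = noise_spec(up$noise_coupling, config$seed),
                        duration = s$duration, u_stride = 4)
  rep <- detect_recruited_units(res, baseline_mask = lay$all_units)
  # staged recruitment: partial after the first stimulus, large at the end
  t1 <- s$stim_times[2] - 800
  early <- rep$fraction[which.min(abs(rep$t_window - t1))]
  final <- utils::tail(rep$fraction, 1)
  art$results$run <- res
  art$reports$run <- rep
  art$layout <- lay
  art <- scenario_contract(art, "stimuli_progressively_recruit",
    final > 0.5 && early < 0.5 && early < final - 0.15,
    sprintf("recruited fraction %.2f after the first stimulus, %.2f at end",
            early, final))
  art
}

scenario_counter <- function(art, geom, model, up, s, config) {
  glob <- update_unit_params(up, p_basal = s$p_bistable)
  mask <- central_disc(geom, s$pulse_n)
  stim <- stimulus_spec("input_pulse", mask, s$pulse_amplitude,
                        s$pulse_onset, s$pulse_duration)
  counter_mask <- central_disc(geom, min(geom$n_units,
                                         round(length(mask) *
                                               s$counter_cover_factor)))
  counter <- stimulus_spec("state_reset", counter_mask, 0, s$counter_onset)
  one <- function(stims) {
    res <- simulate_sheet(model, glob, stimuli = stims,
                          noise = noise_spec(up$noise_coupling, config$seed),
                          duration = s$duration, u_stride = 4)
    detect_recruited_units(res, baseline_mask = mask)
  }
  plain <- one(list(stim)); countered <- one(list(stim, counter))
  art$reports <- list(plain = plain, countered = countered)
  art$counter_mask <- counter_mask
  art <- scenario_contract(art, "counter_stimulation_reduces_recruitment",
    countered$active_percent < plain$active_percent,
    sprintf("%.1f%% active with counter vs %.1f%% without",
            countered$active_percent, plain$active_percent))
  art
}

scenario_incision <- function(art, geom, model, up, s, config) {
  glob <- update_unit_params(up, p_basal = s$p_bistable)
  mask <- central_disc(geom, s$micro_n)
  ramp <- ramp_spec("p_basal", s$p_bistable, s$p_micro, s$ramp_window[1],
                    s$ramp_window[2], mask = mask)
  # two full-height vertical cuts enclosing the microdomain column band
  xs <- range(unit_coords(geom, mask)[, "x"])
  h <- geom$n_rows * geom$pitch_um
  # half-pitch offset keeps the cut between unit-centre columns
  margin <- 3.5 * geom$pitch_um
  cut1 <- c(xs[1] - margin, -geom$pitch_um / 2, xs[1] - margin, h)
  cut2 <- c(xs[2] + margin, -geom$pitch_um / 2, xs[2] + margin, h)
  one <- function(cuts) {
    mdl <- if (is.null(cuts)) model else apply_microincision(model, cuts)
    res <- simulate_sheet(mdl, glob, ramps = ramp,
                          noise = noise_spec(up$noise_coupling, config$seed),
                          duration = s$duration, u_stride = 4)
    detect_recruited_units(res, baseline_mask = mask)
  }
  plain <- one(NULL)
  single <- one(rbind(cut1))
  double <- one(rbind(cut1, cut2))
  # units outside the enclosed band
  outside <- which(unit_coords(geom)[, "x"] < cut1[1] |
                     unit_coords(geom)[, "x"] > cut2[1])
  out_frac <- function(rep) 100 * mean(rep$recruited[outside])
  art$reports <- list(plain = plain, single_cut = single,
                      double_cut = double)
  art$cuts <- rbind(cut1, cut2)
  art <- scenario_contract(art, "double_cut_suppresses_outside_recruitment",
    out_frac(double) < 5 && out_frac(plain) > 30,
    sprintf("outside recruitment %.1f%% uncut, %.1f%% single, %.1f%% double",
            out_frac(plain), out_frac(single), out_frac(double)))
  art <- scenario_contract(art, "cuts_strictly_reduce_recruitment",
    double$final_percent < plain$final_percent,
    sprintf("%.1f%% double-cut vs %.1f%% uncut",
            double$final_percent, plain$final_percent))
  art
}

#' @export
print.run_artifact <- function(x, ...) {
  cat(sprintf("<run_artifact> scenario %s (seed %d, scale %g)\n",
              x$scenario, x$config$seed, x$config$geometry_scale))
  if (!is.null(x$contracts)) {
    for (i in seq_len(nrow(x$contracts)))
      cat(sprintf("  [%s] %s: %s\n",
                  if (x$contracts$passed[i]) "ok" else "FAILED",
                  x$contracts$contract[i], x$contracts$detail[i]))
  }
  invisible(x)
}

#' Persist a run artifact
#'
#' Writes macrocolumn traces (CSV), the contracts table (CSV) and a JSON run
#' manifest (scenario, settings, seeds) into \code{dir}.
#'
#' @param artifact a \code{run_artifact}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_run_artifact <- function(artifact, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(artifact$results)) {
    res <- artifact$results[[nm]]
    if (!inherits(res, "simulation_result")) next
    keep <- seq(1, nrow(res$macro_u), by = 5)
    df <- data.frame(t_ms = res$t_macro[keep],
                     res$macro_u[keep, , drop = FALSE])
    names(df) <- c("t_ms", paste0("macro_", seq_len(ncol(res$macro_u))))
    utils::write.csv(df, file.path(dir, paste0("macro_traces_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(artifact$contracts))
    utils::write.csv(artifact$contracts, file.path(dir, "contracts.csv"),
                     row.names = FALSE)
  manifest <- list(scenario = artifact$scenario,
                   seed = artifact$config$seed,
                   geometry_scale = artifact$config$geometry_scale,
                   settings = lapply(artifact$settings, function(x)
                     if (is.numeric(x) || is.character(x)) x else NULL),
                   package_version =
                     as.character(utils::packageVersion("cortexsheet")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Build a seeded test fixture
#'
#' @param kind \code{"small_sheet"} (a 30 x 30 sheet with full standard
#'   connectivity and presets), \code{"planted_wavefront"} (a synthetic
#'   onset-time field with known propagation speed), or
#'   \code{"planted_oscillation"} (multichannel series with known amplitude
#'   and frequency).
#' @param seed integer seed.
#' @param ... kind-specific settings: \code{speed_m_per_s} and
#'   \code{onset_noise_ms} (planted_wavefront); \code{freq_hz},
#'   \code{amplitude}, \code{n_channels}, \code{duration}, \code{dt}
#'   (planted_oscillation); \code{boundary} (small_sheet).
#' @return a list whose shape depends on \code{kind}; every fixture carries
#'   its generating seed and ground truth.
#' @export
make_test_fixture <- function(kind = c("small_sheet", "planted_wavefront",
                                       "planted_oscillation"),
                              seed = 1L, ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  if (kind == "small_sheet") {
    geom <- standard_geometry(1 / 5, boundary = opts$boundary %||% "torus")
    model <- build_connectivity(geom, seed = seed)
    return(list(kind = kind, seed = seed, geom = geom, model = model,
                globals = standard_unit_params()))
  }
  if (kind == "planted_wavefront") {
    speed <- opts$speed_m_per_s %||% 0.5
    noise_ms <- opts$onset_noise_ms %||% 2
    geom <- standard_geometry(1 / 5, boundary = "zero_flux")
    seed_region <- central_disc(geom, 40)
    d <- rep(Inf, geom$n_units)
    for (s in seed_region)
      d <- pmin(d, sheet_distance(geom, s, seq_len(geom$n_units)))
    onset <- with_seed(seed,
      500 + d / (speed * 1000) + stats::rnorm(geom$n_units, 0, noise_ms))
    report <- structure(list(recruited = rep(TRUE, geom$n_units),
                             onset_ms = onset, geom = geom),
                        class = "recruitment_report")
    return(list(kind = kind, seed = seed, geom = geom, report = report,
                seed_region = seed_region, true_speed_m_per_s = speed))
  }
  freq <- opts$freq_hz %||% 12
  amp <- opts$amplitude %||% 0.3
  nch <- opts$n_channels %||% 9
  dur <- opts$duration %||% 4000
  dt <- opts$dt %||% 2
  t <- seq(0, dur, by = dt)
  series <- with_seed(seed, vapply(seq_len(nch), function(ch)
    0.5 + (amp / 2) * sin(2 * pi * freq * t / 1000 +
                          stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(length(t), 0, 0.005), numeric(length(t))))
  list(kind = kind, seed = seed, t_ms = t, series = series,
       true_freq_hz = freq, true_amplitude = amp, dt = dt)
}
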