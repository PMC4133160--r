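#' Packaged standard parameter presets
#'
#' @description
#' `standard_unit_params()` is the standard interictal minicolumn preset.
#' The isolated unit is strongly inhibition-dominated and provably incapable
#' of limit-cycle oscillations for any constant drive P: with sigmoid
#' steepness a and self-excitation c_ee the divergence of the flow is
#' bounded above by (a c_ee / 4 - 1)/tau_e - 1/tau_i < 0 everywhere, so by
#' the Bendixson-Dulac criterion no periodic orbit exists.  Oscillations in
#' the model are a network effect: between-unit coupling raises the
#' effective recurrent excitation of the mean field to the oscillatory
#' range.
#'
#' The default basal input P = -2 places the coupled sheet in the
#' monostable background (interictal) state, near but below the bistable
#' window; see the regime-map functions and the methods vignette for the
#' measured boundaries.
#'
#' @return `standard_unit_params()`: a [unit_params()] object.
#' @export
standard_unit_params <- function() {
  unit_params(c_ee = 6, c_ie = 12, c_ei = 2, c_ii = 1,
              p_basal = -2, q_basal = -3,
              tau_e = 5, tau_i = 10,
              noise_coupling = 0.5,
              sigmoid = sigmoid_params(1, 2.5))
}

#' @rdname standard_unit_params
#' @description
#' `standard_connectivity_params()` is the standard mesoscopic connectivity
#' preset: local connections fall off as a Gaussian (sigma 100 um) with a
#' hard 300 um cutoff; each macrocolumn owns 3 remote patches of radius 5
#' minicolumns placed within 2 mm, shares 1 patch with one direct
#' neighbouring macrocolumn, and every minicolumn draws 10 outgoing remote
#' connections.  Weights are set so that the mean network input raises the
#' effective couplings of the sheet mean field into the oscillatory range
#' (local weight 0.26 on ~23 expected local in-connections, remote weight
#' 0.13 on ~10, self-excitation 6); per-neighbour coupling is weak enough
#' that recruitment fronts pin in the deep background regime.
#'
#' @return `standard_connectivity_params()`: a [connectivity_params()] object.
#' @export
standard_connectivity_params <- function() {
  connectivity_params(sigma_um = 100, local_radius_um = 300,
                      n_patches_per_macro = 3, patch_radius_units = 5,
                      max_patch_distance_um = 2000, n_out_remote = 10,
                      n_shared_patches = 1,
                      w_local = 0.26, w_remote = 0.13, w_self_e = 6)
}

#' @rdname standard_unit_params
#' @description
#' `standard_geometry()` is the full-size sheet: 150 x 150 minicolumns of
#' 50 um pitch (7.5 mm square), tiled into 15 x 15 macrocolumns of 10 x 10
#' minicolumns.  `scale` shrinks the linear size for scans and tests (e.g.
#' `scale = 1/5` gives a 30 x 30 sheet).
#'
#' @param scale linear size factor; the scaled side must stay a multiple of
#'   the macrocolumn edge.
#' @param boundary \code{"torus"} (default, used for constructing
#'   connectivity without edge artefacts) or \code{"zero_flux"}.
#' @return `standard_geometry()`: a [sheet_geometry()] object.
#' @export
standard_geometry <- function(scale = 1, boundary = c("torus", "zero_flux")) {
  boundary <- match.arg(boundary)
  side <- round(150 * scale)
  if (side %% 10 != 0)
    stop("scaled side (", side, ") must be a multiple of the macrocolumn edge (10)")
  sheet_geometry(side, side, macro_edge = 10, pitch_um = 50,
                 boundary = boundary)
}

# canonical basal-input working points of the coupled sheet (see the methods
# vignette for how these were placed relative to the measured regime
# boundaries)
#' Canonical sheet working points of the basal excitatory input P
#'
#' Named reference values of the basal input P used by the scenario drivers:
#' \describe{
#'   \item{deep_background}{well inside the monostable background regime}
#'   \item{interictal}{the standard interictal state: monostable background
#'     near the bistable boundary}
#'   \item{near_bistable}{monostable background, closer still to the
#'     bistable boundary (recruitment-prone surround)}
#'   \item{near_pinning}{lower edge of the bistable window, where
#'     recruitment fronts are close to pinning (used by the intervention
#'     experiments, whose background must stay quiescent for long runs)}
#'   \item{bistable}{inside the bistable background/oscillation window}
#'   \item{oscillatory}{monostable oscillation (seizure state)}
#'   \item{microdomain_target}{ramp target for hyperactive microdomains,
#'     high enough that patches down to ~90 units ignite on their own}
#' }
#' @return named numeric vector.
#' @export
sheet_p_presets <- function() {
  c(deep_background = -3,
    interictal = -2,
    near_bistable = -1.7,
    near_pinning = -1.4,
    bistable = -1.25,
    oscillatory = -0.75,
    microdomain_target = 1)
}
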