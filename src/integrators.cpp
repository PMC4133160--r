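// Fixed-step explicit Euler integrators for the Wilson-Cowan minicolumn and
// the coupled cortical sheet.  Noise is pre-drawn in R (one standard-normal
// value per macrocolumn per step) so that all randomness flows through R's
// RNG and seeds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigm(double x, double a, double theta) {
  return 1.0 / (1.0 + std::exp(-a * (x - theta)));
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_unit(NumericVector par, NumericVector init,
                                int n_steps, double dt,
                                NumericVector noise, NumericVector ext_e) {
  // par: c_ee, c_ie, c_ei, c_ii, P, Q, tau_e, tau_i, B, a, theta
  const double cee = par[0], cie = par[1], cei = par[2], cii = par[3];
  const double P = par[4], Q = par[5], te = par[6], ti = par[7], B = par[8];
  const double a = par[9], th = par[10];
  NumericMatrix out(n_steps + 1, 2);
  double u = init[0], v = init[1];
  out(0, 0) = u; out(0, 1) = v;
  for (int k = 0; k < n_steps; ++k) {
    double ie = cee * u - cie * v + P + B * noise[k] + ext_e[k];
    double ii = cei * u - cii * v + Q;
    double un = u + dt * (-u + sigm(ie, a, th)) / te;
    double vn = v + dt * (-v + sigm(ii, a, th)) / ti;
    u = un; v = vn;
    out(k + 1, 0) = u; out(k + 1, 1) = v;
  }
  return out;
}

// Sheet integrator.
//
// Between-unit coupling is split from within-unit coupling:
//   ee_off, ei_off : sparse (n x n) input-convention matrices of the
//                    off-diagonal (between-unit) E->E and E->I weights, i.e.
//                    (ee_off * u)[i] is the network excitatory input to i.
//   ee_diag,ei_diag: within-unit self-excitation / E->I diagonal weights.
//   w_ie, w_ii     : within-unit I->E, I->I diagonal weights.
// Feed-forward heterogeneity scales (ffw_e/i) multiply the off-diagonal
// input only.  Noise: n_steps x n_macros, broadcast via macro (0-based).
//
// Ramps (prepared per step in R): target 0 = p_basal, 1 = q_basal,
// 2 = ffw_e scale, 3 = ffw_i scale; "value" is the per-step ramped value
// which replaces the targeted quantity inside "mask" (0-based units).
//
// Stimuli: kind 0 = input pulse added to the E input between step_on and
// step_off; kind 1 = reset of u to "amplitude" applied after step_on.
//
// Delays: delay_ee / delay_ei are parallel lists of sparse matrices, one per
// delay bin, applied to u delayed by delay_steps[g] steps; ee_off/ei_off
// must then hold only the undelayed remainder.
// [[Rcpp::export]]
List cpp_simulate_sheet(const arma::sp_mat& ee_off, const arma::sp_mat& ei_off,
                        const arma::vec& ee_diag, const arma::vec& ei_diag,
                        const arma::vec& w_ie, const arma::vec& w_ii,
                        const arma::vec& P0, const arma::vec& Q0,
                        double tau_e, double tau_i,
                        double B, double a, double theta,
                        const arma::vec& ffw_e_scale0,
                        const arma::vec& ffw_i_scale0,
                        const arma::mat& noise, const arma::ivec& macro,
                        int n_macros, int n_steps, double dt,
                        const arma::vec& u0, const arma::vec& v0,
                        List ramps, List stimuli,
                        List delay_ee, List delay_ei,
                        const arma::ivec& delay_steps,
                        int u_stride, bool record_v_units) {
  const arma::uword n = u0.n_elem;
  arma::vec u = u0, v = v0;
  arma::vec P = P0, Q = Q0;
  arma::vec ffe = ffw_e_scale0, ffi = ffw_i_scale0;

  const int n_keep = n_steps / u_stride + 1;
  arma::mat U_keep(n_keep, n, arma::fill::zeros);
  arma::mat V_keep(record_v_units ? n_keep : 1,
                   record_v_units ? n : 1, arma::fill::zeros);
  arma::mat macro_u(n_steps + 1, n_macros, arma::fill::zeros);
  arma::mat macro_v(n_steps + 1, n_macros, arma::fill::zeros);
  arma::vec macro_count(n_macros, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) macro_count[macro[i]] += 1.0;

  const int n_groups = delay_ee.size();
  int max_delay = 0;
  std::vector<arma::sp_mat> gee(n_groups), gei(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    gee[g] = as<arma::sp_mat>(delay_ee[g]);
    gei[g] = as<arma::sp_mat>(delay_ei[g]);
    if (delay_steps[g] > max_delay) max_delay = delay_steps[g];
  }
  arma::mat hist;
  int hist_pos = 0;
  if (n_groups > 0) {
    if (max_delay >= n_steps) stop("delay buffer longer than simulation");
    hist.set_size(n, max_delay + 1);
    for (int c = 0; c <= max_delay; ++c) hist.col(c) = u;
  }

  const int n_ramps = ramps.size();
  std::vector<int> r_target(n_ramps);
  std::vector<arma::uvec> r_mask(n_ramps);
  std::vector<arma::vec> r_value(n_ramps);
  for (int r = 0; r < n_ramps; ++r) {
    List rr = ramps[r];
    r_target[r] = as<int>(rr["target"]);
    r_mask[r] = as<arma::uvec>(rr["mask"]);
    r_value[r] = as<arma::vec>(rr["value"]);
  }
  const int n_stim = stimuli.size();
  std::vector<int> s_kind(n_stim), s_on(n_stim), s_off(n_stim);
  std::vector<double> s_amp(n_stim);
  std::vector<arma::uvec> s_mask(n_stim);
  for (int s = 0; s < n_stim; ++s) {
    List ss = stimuli[s];
    s_kind[s] = as<int>(ss["kind"]);
    s_on[s] = as<int>(ss["step_on"]);
    s_off[s] = as<int>(ss["step_off"]);
    s_amp[s] = as<double>(ss["amplitude"]);
    s_mask[s] = as<arma::uvec>(ss["mask"]);
  }

  auto record_macro = [&](int step) {
    arma::vec su(n_macros, arma::fill::zeros), sv(n_macros, arma::fill::zeros);
    for (arma::uword i = 0; i < n; ++i) {
      su[macro[i]] += u[i];
      sv[macro[i]] += v[i];
    }
    macro_u.row(step) = (su / macro_count).t();
    macro_v.row(step) = (sv / macro_count).t();
  };
  record_macro(0);
  U_keep.row(0) = u.t();
  if (record_v_units) V_keep.row(0) = v.t();
  int keep_idx = 1;

  for (int k = 0; k < n_steps; ++k) {
    for (int r = 0; r < n_ramps; ++r) {
      const double val = r_value[r][k];
      switch (r_target[r]) {
        case 0: P.elem(r_mask[r]).fill(val); break;
        case 1: Q.elem(r_mask[r]).fill(val); break;
        case 2: ffe.elem(r_mask[r]).fill(val); break;
        case 3: ffi.elem(r_mask[r]).fill(val); break;
      }
    }
    arma::vec net_e = ee_off * u;
    arma::vec net_i = ei_off * u;
    for (int g = 0; g < n_groups; ++g) {
      int col = hist_pos - delay_steps[g];
      if (col < 0) col += (max_delay + 1);
      net_e += gee[g] * hist.col(col);
      net_i += gei[g] * hist.col(col);
    }
    net_e %= ffe;
    net_i %= ffi;
    arma::vec in_e = net_e + ee_diag % u - w_ie % v + P;
    arma::vec in_i = net_i + ei_diag % u - w_ii % v + Q;
    for (int s = 0; s < n_stim; ++s)
      if (s_kind[s] == 0 && k >= s_on[s] && k < s_off[s])
        in_e.elem(s_mask[s]) += s_amp[s];
    for (arma::uword i = 0; i < n; ++i) in_e[i] += B * noise(k, macro[i]);
    for (arma::uword i = 0; i < n; ++i) {
      u[i] += dt * (-u[i] + sigm(in_e[i], a, theta)) / tau_e;
      v[i] += dt * (-v[i] + sigm(in_i[i], a, theta)) / tau_i;
    }
    for (int s = 0; s < n_stim; ++s)
      if (s_kind[s] == 1 && k + 1 == s_on[s])
        u.elem(s_mask[s]).fill(s_amp[s]);
    if (n_groups > 0) {
      hist_pos = (hist_pos + 1) % (max_delay + 1);
      hist.col(hist_pos) = u;
    }
    record_macro(k + 1);
    if ((k + 1) % u_stride == 0) {
      U_keep.row(keep_idx) = u.t();
      if (record_v_units) V_keep.row(keep_idx) = v.t();
      ++keep_idx;
    }
  }
  return List::create(_["u"] = U_keep, _["v"] = V_keep,
                      _["macro_u"] = macro_u, _["macro_v"] = macro_v,
                      _["u_final"] = u, _["v_final"] = v);
}
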