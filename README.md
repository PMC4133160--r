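# cortexsheet

Simulation of focal seizure onset on a multiscale model of a cortical
sheet, for computational neuroscientists studying how localised epileptic
rhythms arise, spread and can be suppressed.

The model is a 150 x 150 lattice of cortical minicolumns (50 um pitch,
~7.5 mm of cortex), each a Wilson–Cowan excitatory–inhibitory pair

    tau_e du_i/dt = -u_i + f( [W_EE u]_i - c_IE v_i + P_i + B xi_i(t) )
    tau_i dv_i/dt = -v_i + f( [W_EI u]_i - c_II v_i + Q_i )

with a logistic response f, coupled by dense local Gaussian connectivity
(E->E and feed-forward E->I, hard 300-um cutoff) and remote patchy
excitatory projections organised per 10 x 10-minicolumn macrocolumn; noise
is one standard-normal draw per macrocolumn per 2-ms step, shared by all
its minicolumns.  An isolated minicolumn provably cannot oscillate;
seizure-like high-amplitude rhythms are a network effect, and the sheet's
mean field moves through monostable background, bistable
background/oscillation, monostable oscillation and a permanently firing
upper state as the basal excitatory input P increases.

On this substrate the package provides the full experimental battery:

* **connectivity** — seeded samplers for the three connection types,
  sparse weight-matrix assembly, degree/distance statistics, MatrixMarket
  export, and microincision editing (removal of connections crossing cut
  segments);
* **simulator** — compiled fixed-step stochastic integration with
  parameter ramps, heterogeneity maps, pulse/reset stimuli, optional
  conduction delays, macrocolumn LFP proxies and stimulation-threshold
  probes;
* **regimes** — operational classification of the mean-field state and 2-D
  regime maps;
* **recruitment** — a per-unit seizure-core detector (amplitude, cycle
  count and neighbourhood phase-locking), recruited-fraction time courses,
  Theil–Sen wavefront-speed estimation, random subcluster placement and
  recruitment scans;
* **scenarios** — turn-key drivers for the three onset classes (global
  ramp, pulse to a bistable sheet, oscillatory microdomain, subcluster
  networks, bistable microdomains) and the two interventions
  (counter-stimulation, microincision), each with an explicit dynamical
  contract.

## Worked example

An oscillatory microdomain embedded in a monostable-background surround
stays isolated; the same microdomain in a bistable surround recruits the
whole sheet:

```r
library(cortexsheet)

geom  <- standard_geometry(2/5)              # 60 x 60 sheet for speed
model <- build_connectivity(geom, seed = 11)
p     <- sheet_p_presets()

run <- function(P_surround) {
  mask  <- place_subclusters(geom, 200, 1, placement_seed = 7)$all_units
  ramp  <- ramp_spec("p_basal", P_surround, p[["microdomain_target"]],
                     200, 1000, mask = mask)
  res   <- simulate_sheet(model, update_unit_params(standard_unit_params(),
                                                    p_basal = P_surround),
                          ramps = ramp, noise = noise_spec(0.5, 4),
                          duration = 6000)
  detect_recruited_units(res, baseline_mask = mask)
}

run(p[["interictal"]])   # monostable surround
#> <recruitment_report> 335/3600 units recruited (9.3%; 4.9% of surround)
run(p[["bistable"]])     # bistable surround
#> <recruitment_report> 3291/3600 units recruited (91.4%; 91.9% of surround)
```

The microdomain (200 units) oscillates in both runs, but only the bistable
surround is recruited — the monostable surround confines the seizure core
to a thin fringe.  `plot(report)` draws the recruited-fraction time
course, `plot_sheet_snapshots(res, times)` the activity field.

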