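---
title: "Modelling focal seizure onset on a multiscale cortical sheet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling focal seizure onset on a multiscale cortical sheet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(cortexsheet)
```

## The model

`cortexsheet` simulates a two-dimensional sheet of cortical minicolumns.
Each minicolumn is a Wilson--Cowan pair of excitatory (E) and inhibitory (I)
population activities $u, v \in [0, 1]$:

$$\tau_e \dot u_i = -u_i + f\!\big( [W^{EE} u]_i - c_{IE} v_i + P_i + B\,\xi_i(t) \big),$$
$$\tau_i \dot v_i = -v_i + f\!\big( [W^{EI} u]_i - c_{II} v_i + Q_i \big),$$

with the logistic response $f(x) = 1/(1 + e^{-a (x - \theta)})$.
$W^{EE}$ collects self-excitation on the diagonal, dense local excitatory
connections (Bernoulli per ordered pair, probability falling off as a
Gaussian in distance with a hard cutoff), and remote patchy excitatory
projections organised per macrocolumn; $W^{EI}$ collects the within-unit
E$\to$I constant and local feed-forward inhibition sampled with the same
algorithm and parameters as the local excitatory connections.  I$\to$E and
I$\to$I coupling is strictly within-unit (no long-range inhibition).  Noise
$\xi$ is one standard-normal draw per macrocolumn per 2-ms step, shared by
all minicolumns of the macrocolumn and fed to the excitatory populations
only.

Geometry: 150 x 150 minicolumns of 50 um pitch (a ~7.5 mm square, the scale
of a single ECoG electrode), tiled into 15 x 15 macrocolumns of 10 x 10
minicolumns.  Connectivity is constructed on a torus by default to avoid
edge artefacts; zero-flux (planar) boundaries are available and used where
an experiment calls for them.

## Design of the standard parameter set

The framework above fixes the model's structure -- equations, connectivity
types, noise sharing, solver step -- but not a unique numeric parameter
set, so the packaged preset was designed from dynamical requirements and
then frozen.  The requirements, in order of priority:

1. **An isolated minicolumn must not oscillate for any constant drive
   $P$.**  In the preset the unit's excitatory population is a bistable
   switch (self-excitation $c_{EE} = 6$ with $a = 1$ exceeds the $4/a$
   slope bound, giving an S-shaped nullcline), while its inhibitory
   population is effectively silent in isolation: the within-unit E$\to$I
   coupling (2) plus $Q = -3$ cannot lift the I input near the sigmoid
   offset ($\theta = 2.5$) for any $u \in [0, 1]$.  The isolated unit is
   therefore essentially one-dimensional in $u$, and one-dimensional flows
   cannot oscillate.  `find_unit_fixed_points()` confirms node/saddle
   structure across the documented $P$ sweep.
2. **The coupled sheet must oscillate collectively.**  Between-unit E$\to$I
   input (local weight 0.26 on ~23 expected in-connections) engages
   inhibition only when the surrounding network is active; the delayed
   ($\tau_i = 10$ ms vs $\tau_e = 5$ ms) restoring force then produces a
   ~17 Hz collective rhythm of switching waves.
3. **Recruitment fronts must pin in the deep background.**  Per-neighbour
   coupling is weak relative to the unit's switching barrier, so an ignited
   patch in a sufficiently quiescent surround drives only a thin fringe --
   the discrete-medium propagation failure that keeps microdomains
   spatially isolated.  Closer to the oscillation onset the fronts depin
   and propagate, which is what makes the bistable surround recruitable.
4. **The regime boundaries sit on the canonical working axis.**  The final
   sigmoid offset and $Q$ place the measured boundaries of the full sheet
   at: monostable background for $P \lesssim -1.75$, bistable
   background/oscillation for $P \in [-1.5, -1.1)$, monostable oscillation
   from $P \approx -1$, and the permanently firing upper state well above;
   the canonical ramp $-3 \to -1$ therefore crosses background, bistable
   window and oscillation onset in that order, and the standard interictal
   state is $P = -2$, a node near (but safely below) the bistable window.

Two places where this implementation makes a deliberate protocol choice:

* **Regime probe.**  The bistable oscillatory attractor of the sheet is
  spatially asynchronous (recirculating switching waves).  A whole-sheet,
  fully synchronised reset of $u$ to 1 collapses through one global
  inhibition wave and never reaches that attractor, even at parameters
  where a local pulse demonstrably switches the sheet to sustained
  oscillation.  `classify_regime()` therefore resets $u = 1$ in one half of
  the sheet by default (still a strongly excited initial state, but one
  that breaks the fatal symmetry); the reset mask is an argument.
* **Noise convention.**  Noise enters as $B\,\xi$ per step without
  $\sqrt{dt}$ rescaling, matching the fixed-step usage at the default
  $dt = 2$ ms; $B$ is therefore documented as a $dt$-bound convention and
  the default step is fixed.

## Detectors

`detect_oscillation()` calls a series oscillatory when the post-transient
peak-to-trough amplitude exceeds 0.1 (fractional firing units) and the
dominant spectral frequency lies in 1--30 Hz; the defaults discard the
first 20% of the run.  `detect_recruited_units()` marks a unit recruited
from the first 1-s sliding window (evaluated every 0.3 s) showing
amplitude above 0.1, at least 3 cycles, and phase-locking above 0.8 with
the mean phase of its neighbours within 3 lattice units -- high-amplitude
oscillation synchronous with its neighbourhood up to a phase shift.
Recruited percentages are reported both relative to all units and relative
to the surround (units outside the imposed hyperactive region); scans that
impose a microdomain use the surround normalisation.

`estimate_wavefront_speed()` fits onset time against distance from the seed
region with a Theil--Sen slope (robust to the saltatory jumps introduced by
remote projections) and reports the inverse slope in m/s with the
least-squares $R^2$ as a diagnostic; a flat onset field is reported as
"speed undefined" rather than an arbitrary large number.

## What the synthetic fixtures emulate

`make_test_fixture()` provides the scales used by the test-suite: a 30 x 30
sheet with full standard connectivity (seconds to simulate), a planted
onset-time field with known wavefront speed, and multichannel sinusoids
with known amplitude and frequency.  These exercise the estimators against
planted ground truth; they do not emulate clinical recordings -- no 1/f
background, electrode noise, artefacts, or non-stationarity -- so passing
tests certify the algorithmic pipeline, not agreement with patient data,
against which this kind of model is compared only qualitatively.

## Numerical choices

Integration is explicit fixed-step Euler at $dt = 2$ ms (a half-step
convergence check is part of the test suite).  For $dt \le \min(\tau_e, \tau_i)$ the update is a convex
combination of the state and a sigmoid value, so trajectories remain in
$[0,1]^2$ exactly.  Fixed-point search polishes sign-change grid cells with
damped Newton iteration (deduplication tolerance $10^{-6}$; eigenvalue
real parts within $10^{-8}$ flagged marginal, imaginary parts above
$10^{-8}$ classified as focus).  Propagation delays, when enabled, are
quantised to whole steps on one-pitch distance bins and applied to
off-diagonal input only; infinite speed bypasses the delay path exactly.
Duplicate local+remote connections sum their weights.  Chord-cut
intersection for microincisions uses open-segment crossing (touching an
endpoint does not cut) with minimal-image chords on the torus.

## Problem sizes

The packaged experiments run at the full 150 x 150 scale (the recruitment
scans of the acceptance script simulate ~10 s per condition and average
over seeds).  The test-suite exercises every code path at 30 x 30 and
60 x 60, where each simulation takes seconds; the regime scans default to
a quarter-linear-size sheet, recorded in the scan metadata, with full-size
scans available behind a flag.

## Known limitations

* Recruited percentages depend on detector thresholds; the defaults above
  are the package's own choices and all of them are arguments.
* The parameter preset is one coherent realisation of the required
  dynamical structure, not a transcription of a reference set; quantitative
  agreement with any particular reference scan is expected only up to that
  freedom.
* Regime classification near boundaries can flip with the noise seed;
  boundary-adjacent disagreements are surfaced as `unresolved`, never
  coerced.
* No laminar structure, conductance-based dynamics, adaptive step sizes,
  or anatomically registered connectivity.
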