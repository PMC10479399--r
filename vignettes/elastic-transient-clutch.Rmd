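---
title: "The elastic transient clutch: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The elastic transient clutch: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(talinclutch)
```

# The problem

In migrating cells the lamellipodial F-actin network flows rearward at
10–50 nm/s while integrin-based adhesions stay put. Talin bridges the two:
its N-terminal head binds integrin, its C-terminal rod binds F-actin, and
the rod's thirteen α-helical bundle subdomains unfold reversibly under
piconewton forces. `talinclutch` models a single such linkage — the *elastic
transient clutch* — in two complementary ways, and implements the
single-molecule-speckle (SiMS) analysis used to measure its kinetics,
together with a synthetic-track generator so that the whole analysis
pipeline can be validated end to end without any external data.

# The mechanical model

One bound Talin is a chain of `N + 2` spring segments between a fixed
integrin anchor and an actin-attached end that advances with the retrograde
flow at `v_retro`. The two end segments (the integrin and actin bonds) and
every folded rod subdomain are Hookean, tensile-only springs
(`k_folded = 1e4` pN/µm, rest length 2 nm). An unfolded subdomain is a
freely jointed chain (FJC) of one Kuhn segment (`b = 0.38` nm) per residue
(`n_res = 145`), with force `(kT/b) L^{-1}(l / (b n_res))`; the inverse
Langevin function is evaluated by Newton iteration from a Padé seed to
1e-10. At 300 K, `kT = 4.1419` pN nm.

The chain starts straight at angle `theta0` to the substrate with every
segment at rest, so the anchor-to-actin distance is
`L(t) = sqrt(L0^2 + 2 L0 v t cos(theta0) + v^2 t^2)` with
`L0 = (N + 2) * 2` nm (the two end linkers contribute the same rest length
as the rod subdomains). Given `i` unfolded subdomains, uniform tension and
length conservation determine the segment lengths; this is a monotone 1-D
root problem solved by a safeguarded, warm-started Newton iteration
(`solve_tension()`), with zero tension when the chain is slack.

Kinetics follow Bell's law: each still-folded subdomain unfolds at
`k_unfold0 * exp(F dx_unfold / kT)` and the integrin bond dissociates at
`k_unbind0 * exp(F dx_unbind / kT)` with `k_unbind0 = 0.17` 1/s (the
measured dissociation rate of stationary speckles) and
`dx_unbind = 0.51` nm (calibrated so the model's unbinding-displacement
distribution matches measurement; `calibrate_dx_unbind()` reproduces this
calibration loop). Refolding and actin-side dissociation are not modelled.
A two-state catch–slip variant of the integrin bond
(`catch_slip_params()`) is available; its published parameters give the
same zero-force rate, 0.194/1.142 = 0.170 1/s, and an interior minimum of
the unbinding rate near 11 pN.

**Unfolding parameter defaults.** The unfolding Bell parameters of the rod
subdomains vary between subdomains and experiments and no single published
pair defines them here; the package ships an illustrative uniform default
(`k_unfold0 = 1e-4` 1/s, `dx_unfold = 4` nm, i.e. unfolding becomes
order-1/s near 10 pN, in the range of single-molecule measurements). They
are plain configuration values, not ground truth, and every simulation
surface accepts per-subdomain values (`subdomain_spec()`).

# Two solvers

**Master equation.** `master_equation()` evolves `P_j(t)`, the probability
of still being integrin-bound with `j` of `M` unfoldable subdomains
unfolded, on a discrete time grid: per step, a binomial redistribution over
additional unfolds (per-domain probability `1 - exp(-k dt)`, evaluated at
the start-of-step tension — an explicit scheme) followed by removal of the
unbinding mass; `P_unbound` is the complement, so probability is conserved
to machine precision by construction. The default `dt = 1e-3` s halves to
a <0.1% change in the mean clutch duration. Runs terminate at
`P_unbound > 0.999` by default; the threshold is an argument (the
closed-form checks in the test suite use `1 - 1e-5`, where the truncated
exponential mean is unbiased to 0.01%). `master_equation_het()` solves the
same scheme over the `2^M` identity states needed when subdomains carry
distinct parameters and reduces to the homogeneous solver (to 1e-15) when
they do not. Observables: the unbinding-time/displacement densities
(`x = v t`), the force-at-unbinding histogram (0.5 pN bins by default), the
ensemble mean force, and the work, accumulated as tension × flow-axis
cosine × `v dt` weighted by the state probabilities.

**Pulling simulations.** `run_pulling()` integrates the overdamped
bead–spring chain (`zeta dr/dt = F`) explicitly, with Monte Carlo
unfolding/unbinding driven by accumulated hazards of the *local* segment
tensions against Exp(1) thresholds. The friction `zeta` is not a measured
quantity; the default `1e-4` pN s/nm makes the bead relaxation time
`zeta/k_folded = 1e-5` s — far below every kinetic timescale, so tension is
quasi-statically equilibrated, and far above the default timestep
`dt = 1e-6` s (stability requires `dt k/zeta < 0.5`). Rates are refreshed
every 10 steps; the tension changes on the loading timescale
(~200 pN/s × 1e-5 s = 0.002 pN per refresh), so nothing is lost. Ensemble
runs in the test suite use `zeta = 1e-3`, `dt = 1e-5` — the same
separation of timescales, ten times fewer steps; the dt-halving test
confirms the discretisation does not move the ensemble means. The
finite-compliance variant adds a substrate bead and an actin-network bead
coupled by zero-rest-length springs of stiffness `k3`; at
`k3 = 1e5` pN/µm it reproduces the rigid-anchor ensemble, and at
`k3 ≤ 1e2` pN/µm the work's dependence on the number of unfoldable
subdomains flattens, because the soft anchors stretch instead of the rod.

The two solvers are cross-validated in `test-acceptance.R`: at
`N = M = 12`, `theta0 = 45°`, `v = 20` nm/s, 1200 pulling traces agree with
the master equation within statistical error (and at Kolmogorov–Smirnov
distance < 0.05 on the displacement distribution). The ensemble size is a
runtime choice; the agreement is not size-limited.

# The SiMS analysis side

`classify_tracks()` implements the run-length classification of speckle
trajectories (coarse mode: 2-s frames, 120-s window, runs of >2 sequential
images; fast mode: 100-ms frames, 10-s window, runs of >10 images, plus the
back-and-forth category). The underlying per-frame motion state is the one
genuinely open design choice: no numeric threshold is published for
"directional motion". The package labels each step by the centered
two-frame displacement `(x[k+1] - x[k-1]) / 2` against a threshold of twice
the localization SD (default SD 18.6 nm, the measured scatter of immobile
molecules). The centered span halves the noise variance of the raw step at
the cost of blurring segment boundaries by at most one frame; at 2-s frames
and 30 nm/s it mislabels ~4% of flowing steps instead of ~19% for the raw
step. Both the threshold and the flow axis are arguments. At 100-ms frames
the per-frame flow displacement (~3 nm) is far below the localization
noise, so per-step labelling there is only meaningful for
noise-free/high-SNR fixtures; sub-noise flow onset is the job of
`detect_flow_onset()`, which implements the published rule: origin and SD
from the initial stationary stretch (≥8 frames, refined over the full
pre-detection stretch), detection at the first of three consecutive frames
beyond one SD along flow, and `delta_x` read off the flowing-segment linear
fit at the detection time. Three consecutive 1-SD exceedances (not a single
3-SD crossing) is the adopted reading of the published rule; it reproduces
the published mean clutch duration (1.47 s) when applied to matching
synthetic data.

`km_exponential_rate()` wraps `survival::survfit()`: Kaplan–Meier with
right-censoring, an exponential fitted by weighted least squares on
log-survival (weights = numbers at risk), the closed-form censored MLE
(events / time at risk) reported alongside, and photobleaching correction
by subtracting the per-frame bleach rate (0.0071/frame at 2-s intervals,
i.e. 0.00355 1/s) from the fitted disappearance rate. The bleach rate is
published for the attenuated 2-s imaging only, so the correction is off by
default in fast mode.

`clutch_flux_balance()` solves the steady-state four-state model
(stationary S, clutch C, flowing F, plus the recycling flux X through the
diffusing pool). The three state equations are linearly dependent; two of
them plus the flux definition `X = k2 S - k4 F` determine (C, F, X) given
S, and residuals of all three are verified below 1e-9 — which also makes
the solution manifestly independent of the pairing. With S = 57% and the
published constants this yields C = 4.15%, F = 39.7%, X = 1.57 %/s. The
published F is 38.3%: with the rounded printed constants the system does
not reproduce it exactly, a known closure discrepancy of the published
`k_d`; the package reports what the equations give.

`force_bookkeeping()` propagates the whole-cell arithmetic (concentration ×
cytosol volume × Avogadro → molecules; speckle, region and clutch
subpopulations; per-filament force × filament count → total force;
per-speckle and per-clutch shares) with interval arithmetic for ranged
inputs.

# The synthetic-data generator

`generate_tracks()` simulates each speckle through a continuous-time Markov
chain stationary ⇄ clutch ⇄ flowing with exits to an invisible diffusing
state from S (rate `k1 = 0.170`) and F (`k3 = 0.104`), clutch engagement
and release at the published `k_a = 0.0548`, `k_b = 0.374`, `k_c = 0.680`,
`k_d = 0.0315` (all 1/s). Kinematics depend on the fluorophore tag: an
actin-end (C-terminal) tag advances with the flow during clutch engagement
and snaps back on release to stationary (the back-and-forth phenotype); an
integrin-end (N-terminal) tag holds still during the clutch and jumps
forward by the accumulated stretch when the clutch releases toward flowing.
Positions are sampled at the frame interval with isotropic Gaussian
localization noise (18.6 nm) and truncated by per-frame Bernoulli
photobleaching (0.0071/frame in coarse mode; fast mode is window-limited,
as no unattenuated-illumination bleach rate is published). The probability
that a new speckle appears stationary rather than flowing is derived from
the rates so that the ensemble's state occupancy reproduces the measured
proportions (57% stationary, 4.1% clutch, 39% flowing); the derivation is
an open-system balance and is verified against a linear-solve oracle in the
tests. Clutch-phase kinematics are a kinematic surrogate (straight advance
at `v_retro`), not the chain mechanics; what the generator deliberately
does **not** emulate — non-exponential sojourns, spatial heterogeneity of
the flow field, drift, tracking errors at high density — bounds what
passing tests can say about real data.

# The recovery loop and the internal consistency of the published rates

`recovery_experiment()` closes the loop: generate coarse-mode tracks,
segment them, estimate `k1`–`k4` by censored Kaplan–Meier with bleach
correction, and compare against truth. Two subtleties matter:

* **What is "truth"?** At 2-s frames the clutch state is invisible for an
  integrin-end tag, so an apparent stationary sojourn alternates S ⇄ C
  until the molecule dissociates or the clutch releases forward. The
  apparent exponential rates of that phase-type process
  (`effective_coarse_rates()`, by first-passage analysis, verified against
  direct simulation) are the recoverable quantities: k1 = 0.1616,
  k2 = 0.0336, k3 = 0.1010, k4 = 0.0109 1/s for the published fine-grained
  rates. The published coarse `k4 = 0.00694` is *not* consistent with the
  published `k_a`–`k_d` under this analysis — the same closure discrepancy
  noted above — so recovery is judged against the generator's own effective
  rates.
* **Sampling pathologies.** Restricting kinetics to classification-eligible
  tracks (lifetime ≥ 4 s) left-truncates the sojourns and inflates them by
  `E[T | T > 4] - E[T]`; the recovery therefore uses every track with at
  least one step, subtracts one frame interval from first-segment durations
  (memorylessness) and adds the half-frame midpoint correction. A trailing
  sub-threshold flow run is kept as a truncated switching event, and
  candidate stationary segments inside flowing stretches are validated by
  their net along-flow displacement. At n = 1000 tracks the k4 estimate
  rests on only ~30 switching events, so its sampling error is ~±20% —
  the recovery table reports relative errors with that caveat.

The fast-mode jump-distance (`delta_x`) ensemble emulates the measured
switching events directly: their duration distribution *defines* `k_c` as
a first-order rate, so durations are drawn Exp(`k_c`) (generator `k_b = 0`
for this ensemble only). The detector recovers the published mean clutch
duration (≈1.5 s vs 1.47 s) and hence `k_c`. The *modal* 20-nm bin of the
recovered `delta_x` histogram lands at 20–40 nm rather than the published
40–60 nm: exponential durations with mean 44 nm of stretch put more mass in
20–40 than 40–60 after detection censoring, and the mechanical model's
displacement distribution (under the illustrative unfolding defaults) does
the same. Reproducing a 40–60 nm mode would need a duration distribution
peaked near 1.5 s more sharply than either; the package reports the
histogram as computed.

# Problem sizes and seeds

All stochastic tests are seeded. The test suite uses: 1200 traces for the
solver cross-validation, 300 traces per point for the compliance scan
(M ∈ {0, 12}, k3 ∈ {1e4, 1e2} pN/µm), 1000 coarse + 1000 fast tracks for
the recovery loop (seed 1), a 0.05-nm grid over 0.36–0.66 nm for the
barrier-distance calibration, and dt = 1e-4 s for the quadrature
comparison (the explicit scheme's hazard quadrature is first-order, so
1e-3 s would leave a ~5e-4 discrepancy against the exact integral).

# Known limitations

Planar geometry only; no refolding; no Talin–actin dissociation; no
rebinding after unbinding; the coarse-mode step classifier assumes flow
displacements resolvable above localization noise; the generator's clutch
kinematics are kinematic, not mechanical, unless durations are supplied
from the mechanical solvers; and the published rate constants are mutually
inconsistent at the ~50% level for `k4`/`k_d`, which caps how literally
"recovery of the printed values" can be read.
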