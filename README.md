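# talinclutch

Mechanochemical modelling and single-molecule kinetics of the **Talin
elastic transient clutch** — the short-lived mechanical linkage by which a
single Talin molecule couples the rearward-flowing lamellipodial F-actin
network (10–50 nm/s) to immobile integrin adhesions, transmitting force
while its rod subdomains unfold.

The package is for quantitative cell biologists and biophysicists who want
to (i) simulate a single loaded Talin linkage, (ii) analyse
single-molecule-speckle (SiMS) trajectories for clutch kinetics, or (iii)
test such analysis pipelines on synthetic data with known ground truth.

## The model

A bound Talin is a chain of `N + 2` springs between a fixed integrin anchor
and an actin end moving at the retrograde flow speed *v*. Folded rod
subdomains (and the two end bonds) are Hookean, `F = k (l − l₀)` with
`k = 10⁴ pN/µm`, `l₀ = 2 nm`; an unfolded subdomain is a freely jointed
chain, `F = (k_BT/b) ℒ⁻¹(l / (b·n))` with Kuhn length `b = 0.38 nm` and
`n = 145` residues. Unfolding and integrin unbinding follow Bell's law,
`k(F) = k₀ exp(F Δx / k_BT)`, with `k_unbind,0 = 0.17 s⁻¹` and
`Δx_unbind = 0.51 nm` (a two-state catch–slip bond is available as a
variant). The linkage-state probabilities are evolved by a discrete-time
master equation over the number (or identity) of unfolded subdomains, and
independently by explicit overdamped bead–spring pulling simulations with
Monte Carlo events; the two are cross-validated in the test suite.

On the measurement side, the four speckle states (diffusing, stationary,
clutch, flowing) obey a steady-state flux balance

    −k_a S + k_b C + X = 0
    k_a S + k_d F − (k_b + k_c) C = 0
    k_c C − k_d F − X = 0,   X = k₂ S − k₄ F

solved by `clutch_flux_balance()`; switching rates are estimated from
censored Kaplan–Meier survival curves with photobleaching correction, and
nanometer flow-onset detection recovers clutch durations from
integrin-end-tag jump distances.

## Worked example

```r
library(talinclutch)

# How much of the speckle-state Talin is mechanically engaged?
sol <- clutch_flux_balance(57, list(k_a = 0.0548, k_b = 0.374, k_c = 0.680,
                                    k_d = 0.0315, k_2 = 0.0324, k_4 = 0.00694))
round(c(C = sol$C, F = sol$F, X = sol$X), 3)
#>      C      F      X
#>  4.151 39.747  1.571
```

Only ~4.15% of speckle-state molecules are in the clutch state (and
~39.7% flowing); the net recycling flux through the diffusing pool is
1.57 %/s.

```r
# Does subdomain unfolding help force transmission?
sw <- me_sweep(list(n_unfoldable = c(0, 5, 12)),
               config = chain_config(12, 12, 45, 20))
round(sw[, c("n_unfoldable", "mean_clutch_duration", "mean_work")], 2)
#>   n_unfoldable mean_clutch_duration mean_work
#> 1            0                 1.29    212.66
#> 2            5                 2.25    302.17
#> 3           12                 2.52    308.85
```

Allowing subdomains to unfold nearly doubles the mean clutch duration
(1.29 → 2.52 s) and raises the work done on actin per linkage
(213 → 309 pN·nm), with most of the gain from the first ~5 unfoldable
subdomains.

```r
# One stochastic pulling trace (bead-spring, Monte Carlo events)
tr <- run_pulling(chain_config(12, 12, 45, 20),
                  sim = sim_params(zeta = 1e-3, dt_sim = 1e-5), seed = 9)
c(lifetime_s = tr$unbind_time, work_pN_nm = round(tr$work, 1),
  unfolds = tr$n_unfolds)
#> lifetime_s work_pN_nm    unfolds
#>     2.9519      382.8          4
```

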