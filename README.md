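# laminarbo

Analysis toolkit for **laminar multielectrode recordings of border-ownership
selectivity in primate visual cortex**. It is written for systems
neuroscientists who record spikes and local field potentials with linear
probes (e.g. 32 contacts at 100 µm pitch) inserted orthogonally to the
cortical surface, and who want to ask *where in the cortical microcircuit* —
superficial, granular or deep layers — stimulus selectivity emerges, and
*when*.

The package implements the full chain for border-ownership experiments:

- **Receptive-field mapping** by reverse correlation: per-position z-scored
  spike counts (response window [30, 100] ms against an equal-length
  preceding window), Gaussian smoothing, cRF contours at *z* = 3, and the
  probe-orthogonality metric *D* (dva of receptive-field drift per mm depth
  along a fitted 3-D line).
- **Laminar assignment** from current source density (CSD):
  `CSD(z,t) = −[φ(z+h) − 2φ(z) + φ(z−h)]/h²` on the band-passed
  (3.3–88 Hz, zero-phase) trial-averaged LFP, sink-positive; automatic
  identification of the leading granular sink (50%-of-peak band, overridable),
  and unit depths as the waveform-amplitude-weighted mean over the five
  contacts around the largest waveform.
- **Border-ownership index** for the classic four-condition square/edge
  design (conditions {1,3} vs {2,4} own opposite sides, {1,2} vs {3,4} swap
  contrast polarity):

  `BOI = ((R1 + R3) − (R2 + R4)) / (R1 + R2 + R3 + R4)`

  with the five inclusion criteria (≥1 sp/s; evoked ≠ pre-trial by rank-sum,
  Bonferroni over conditions; ≥6 trials per condition; central edge inside
  the cRF; ≥1 dva clearance from non-central square edges) and a
  label-permutation test (10,000 shuffles within each contrast pair).
- **Time-course machinery**: spike trains convolved with the postsynaptic
  kernel `K(t) = (1 − e^(−t/τg)) · e^(−t/τd)` (τg = 1 ms, τd = 20 ms),
  normalized preferred/non-preferred response functions, the population
  index `B(t) = (R_pref(t) − R_nonpref(t)) / (R_pref(t) + R_nonpref(t))`,
  sign-rank divergence latencies, shuffle-calibrated threshold latencies
  (lowest threshold at which <1% of label-shuffled populations keep a
  20-ms-sustained crossing), BCa bootstrap confidence intervals, one-sided
  bootstrap latency comparisons, and the trial-resampled
  **border-ownership reliability** `BOR = ΣA / (ΣA + ΣB)` in 100 ms sliding
  windows.
- **Orientation statistics** in the doubled-angle domain: Kruskal–Wallis +
  z ≥ 3 selectivity, resultant-vector preferred orientations, aggregate
  (columnar) orientation with a direction-randomization test, the circular
  mean of border-ownership-selective orientations, identity-line distances,
  and preferred-side spans.
- **Columnar clustering** of the preferred side of border ownership with a
  binomial randomization null.
- A **synthetic-session generator** (`ground_truth()`, `sim_bo_session()`,
  `sim_lfp_session()`, `sim_rf_events()`, `sim_orientation_session()`,
  `sim_ring_session()`) that plants all of the above — compartment-specific
  latencies, multiplicative border-ownership modulation, a granular current
  sink with its source flanks, von Mises orientation tuning — so every stage
  is testable with known ground truth.

## Worked example

Simulate a penetration with border-ownership modulation starting earliest in
the deep layers (75 ms, vs 95/100 ms in granular/superficial), run the
selectivity and latency pipeline, and compare compartments:

```r
library(laminarbo)

truth   <- ground_truth(n_units = c(superficial = 30, granular = 40, deep = 50),
                        m = 0.4, seed = 7)
session <- sim_bo_session(truth, n_trials_per_condition = 10, seed = 8)
session
#> <bo_session> synthP008 (synthA)
#>   32 contacts @ 100 um | 40 trials | 120 units | 129949 spikes | LFP: absent

res <- analyze_bo_session(session, n_shuffles = 2000, seed = 9)
head(res[, c("unit_id", "boi", "p", "significant", "side")], 3)
#>   unit_id   boi p significant side
#> 1     u01 0.336 0        TRUE  180
#> 2     u02 0.328 0        TRUE  180
#> 3     u03 0.365 0        TRUE  180

comp <- setNames(truth$units$compartment, truth$units$unit_id)
pops <- bo_populations(session, res, comp)
thr  <- shuffle_threshold(pops$pops, pops$t, n_shuffles = 1000, seed = 10)
thr$threshold
#> [1] 0.202
```

Each unit's BOI is near the planted modulation (0.4, diluted by the
spontaneous rate), every unit passes the permutation test, and the
preferred side (180°, i.e. leftward of the vertical edge) is the planted
columnar side. Threshold latencies of the compartment `B(t)` functions,
their BCa confidence interval and the one-sided bootstrap comparison:

```r
for (nm in c("deep", "granular", "superficial"))
  cat(nm, population_latency(pops$pops[[nm]]$P, pops$pops[[nm]]$N,
                             pops$t, thr$threshold), "ms\n")
#> deep 96 ms
#> granular 116 ms
#> superficial 125 ms

bootstrap_latency_ci(pops$pops$deep$P, pops$pops$deep$N, pops$t,
                     thr$threshold, n_boot = 1000, seed = 11)$ci95
#> [1] 93 99

compare_latencies(pops$pops$deep, pops$pops$granular, pops$t,
                  thr$threshold, n_boot = 1000, seed = 12)$p
#> [1] 0.002
```

The deep compartment's index crosses the shared threshold ~20 ms before the
granular one — the laminar ordering that was planted. (Threshold-crossing
latencies lag the planted modulation *onsets* by the kernel's step
response, ~10–15 ms; latency *differences* between compartments are
unbiased. See the methods vignette.)

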