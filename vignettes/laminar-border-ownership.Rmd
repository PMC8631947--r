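---
title: "Laminar analysis of border-ownership selectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar analysis of border-ownership selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

A border between two surfaces is perceived as *owned* by one of them, and
neurons in extrastriate visual cortex signal that assignment: an identical
local edge in the classical receptive field (cRF) evokes different firing
depending on which side the inducing square lies. `laminarbo` implements the
statistics needed to ask where in the cortical depth — superficial, granular
(input) or deep layers — this selectivity emerges, and with what timing,
from laminar-probe recordings: spike tables per unit and trial, a
four-condition stimulus design (two owning sides × two contrast polarities),
trial-aligned multi-contact LFP, receptive-field mapping streams and
orientation-tuning blocks.

Because raw recordings of this kind are rarely redistributable, the package
pairs every analysis stage with a synthetic-session generator that plants
known ground truth. All calibration and recovery claims in the test suite
are claims about that generator, a point elaborated at the end.

# The measurement model, stage by stage

## Border-ownership index and its permutation null

For average rates $R_1..R_4$ in the [50, 500] ms evoked window (conditions
{1,3} share one owning side, {2,4} the other; {1,2} and {3,4} are the two
contrast-polarity pairs),

$$BOI = \frac{(R_1 + R_3) - (R_2 + R_4)}{R_1 + R_2 + R_3 + R_4} \in [-1, 1].$$

Averaging the two polarities cancels luminance-driven differences, so the
index isolates ownership. Significance comes from shuffling the side labels
*within each polarity pair* (10,000 shuffles by default) and counting
shuffles with $|BOI_{shuffled}| \ge |BOI|$. The p value is reported as the
plain fraction — which can be exactly 0 — with the add-one-corrected value
$(k+1)/(n+1)$ alongside; the plain fraction is the primary definition, the
corrected one the safe lower bound. Five inclusion criteria gate a dataset
into this analysis (≥1 sp/s somewhere; evoked ≠ pre-trial by two-sided
rank-sum with Bonferroni over the four conditions; ≥6 trials per condition;
the central edge intersects the cRF contour; ≥1 dva clearance between the
contour and all non-central square edges). The pre-trial baseline is the
400 ms fixation window rescaled to the evoked-window length — the only
stimulus-free epoch the trial design provides.

## Response functions and latency

Spike trains (0.1 ms resolution) are convolved with the postsynaptic kernel

$$K(t) = (1 - e^{-t/\tau_g})\,e^{-t/\tau_d}, \qquad \tau_g = 1\ \mathrm{ms},\ \tau_d = 20\ \mathrm{ms},$$

deliberately unnormalized (normalization cancels later). Traces are averaged
per condition, then across polarities, and divided by the unit's
cross-condition mean over [50, 500] ms, so the mean of
$(pref + nonpref)/2$ over that window is 1 by construction. The population
index $B(t)$ is the difference of the compartment-mean preferred and
non-preferred functions over their sum, with the denominator floored at
$10^{-6}$ (flagged) so pre-response times stay defined.

Latency is the earliest time at which $B(t)$ stays at or above a threshold
for 20 consecutive milliseconds. The threshold is *calibrated*, not chosen:
preferred/non-preferred labels are shuffled per unit (1000 shuffles), and
the lowest grid value (step 0.001) at which fewer than 1% of shuffled
populations keep a defined latency is found per compartment; the highest
value across compartments is used for all of them, so compartments are
timed against a common yardstick. Because the null maxima shrink with
sample size, the threshold is population-size dependent — which is why a
subsampling control (`subsample_latency()`) is part of the surface.

Confidence intervals resample units with replacement and re-run the whole
pipeline (mean functions → $B(t)$ → threshold crossing); the 95% interval
uses the bias-corrected and accelerated (BCa) percentile method,
implemented in-package (bias correction from the replicate distribution,
acceleration from a leave-one-unit-out jackknife) because replicates with
an undefined latency must be *dropped* — their fraction is reported, and
above 50% undefined the interval is declared undefined rather than
extrapolated. The in-package BCa is cross-checked in the test suite against
`boot::boot.ci` on a smooth statistic. Compartments are compared one-sided:
p is the fraction of bootstrap pairs on which the putatively-later
compartment's latency minus the earlier one's is ≤ 0; tied replicates count
toward that fraction, which makes the test conservative when latencies are
strongly discretized.

**Known bias, by design:** a threshold crossing of a causally smoothed
signal lags the underlying modulation onset. With $\tau_d = 20$ ms and a
calibrated threshold at ~25–40% of the plateau, the lag is ~10–15 ms. The
recovery tests show exactly this: planted onsets of 75/95/100 ms are read
out near 89/110/115 ms, while the *differences* between compartments are
recovered to a couple of milliseconds. Absolute latencies from this
machinery should be interpreted as conservative (late) bounds; comparisons
between populations timed with the same threshold are unbiased.

## Border-ownership reliability (BOR)

BOR asks how reliably single trials vote for the across-trial preferred
side: 10,000 sets of four spike trains (one random trial per condition,
drawn with replacement across sets) are formed, and in each 100 ms window
(1 ms steps, indexed by the window's *right* edge — a conservative latency
convention) a set votes with the unit when
$\mathrm{sgn}[(C_1+C_3)-(C_2+C_4)]$ matches
$S = \mathrm{sgn}[(R_1+R_3)-(R_2+R_4)]$. $BOR = \Sigma A / (\Sigma A +
\Sigma B)$; windows with fewer than 10 spikes across conditions, or with
only tied sets, are undefined. Because $S$ is estimated from the same
trials, BOR under a true null sits slightly above 0.5 at small trial
counts (the vote and the sign share sampling noise); the effect shrinks as
$1/\sqrt{n_{trials}}$ and the calibration checks use large trial counts for
that reason. The population latency applies the same shuffle-calibrated
threshold machinery, with the per-unit null flip $BOR \to 1 - BOR$.

## Current source density and layer assignment

The trial-averaged LFP is band-passed 3.3–88 Hz with a zero-phase
2nd-order Butterworth (forward–backward, reflected padding) — zero phase so
latencies are not shifted — and the CSD is the negative discrete second
spatial difference (sink-positive), edge contacts dropped rather than
extrapolated, depth interpolated to 10 µm. The granular band is the
earliest depth cluster whose sink exceeds 50% of the global sink maximum
within [0, 100] ms; its extent is the contiguous region above 50% of the
sink's peak on the depth profile averaged over ±10 ms around the peak time
(the averaging suppresses single-sample noise in the band edges). The
automatic call requires the peak sink to exceed 8× the pre-stimulus CSD SD;
otherwise the penetration is flagged uninterpretable and excluded from
laminar analyses. A config override (`override = c(top, bottom)`) is always
available, since sink identification is ultimately a judgment call.

Units are placed at the amplitude-weighted mean depth of the five contacts
around their largest waveform and classified relative to the band; units
more than 2 mm below the most superficial contact with multiunit activity
are excluded as possible white matter.

The synthetic LFP is constructed so this chain has an exact oracle: the
planted CSD (Gaussian-in-depth, Gaussian-in-time dipoles — leading granular
sink, deeper source then later sink, superficial return source) is mapped
to potentials by solving the discrete Poisson problem $\phi'' = -C$ with
zero potential at both end contacts, making the second-difference
estimator its exact inverse on interior contacts. One subtlety: the
mandated temporal band-pass removes DC/slow components of the planted
time courses. The filter is linear and commutes exactly with the spatial
second difference, so recovery is asserted against the identically
filtered planted map; depth structure (band centre, edges, latency
ordering) is untouched by this.

## Receptive fields

Reverse-correlation maps z-score the mean spike count in [30, 100] ms after
events at each grid position against counts in an equal-length window
immediately preceding those events (mean subtracted, divided by the SD of
the preceding counts — note: the SD of single counts, not the standard
error, so |z| is a conservative per-position statistic). Positions with
zero baseline SD are undefined. Maps are smoothed with a Gaussian filter
(σ = 1 grid step, NA-aware), contours traced at z = 3 by marching squares,
and the cRF is the largest-area contour with its polygon-area centroid.
The z = 3 guarantee under the null belongs to the *smoothed* map: raw
per-position z values are heavy-tailed at realistic event counts (a dozen
or so events per position) because the SD is estimated from few discrete
counts, and the smoothing is what makes the contour level meaningful.
Rapid event sequences (50–60 ms spacing) make adjacent count windows
overlap; windows are counted independently per event, which leaves
neighbouring baseline windows correlated but unbiased.

Probe orthogonality fits ordinary least squares of azimuth and elevation on
depth over a 2 mm span starting at the most superficial active contact;
$D = \sqrt{b_{az}^2 + b_{el}^2}$ in dva/mm is the drift of the fitted line
per mm depth — 0 for a perfectly orthogonal penetration.

## Orientation statistics

Orientation has period 180°, so all circular statistics double the angle
first. Selectivity is Kruskal–Wallis on evoked counts ([30, 200] ms)
grouped by orientation *and* a z ≥ 3 criterion for the best orientation
against the pre-trial baseline. The preferred orientation is the direction
divided by 2 of the rate-weighted doubled-angle resultant; the aggregate
(columnar) preference is the resultant of unit resultants, tested by
randomizing directions uniformly on the doubled circle (2000 draws,
magnitudes kept). The circular mean of border-ownership-selective
orientations weights doubled orientation vectors by |BOI| over the
significant orientations. The identity-line distance between a unit's
preferred orientation $x$ and that circular mean $y$ is
$|{\rm wrap}_{180}(x - y)|/\sqrt{2}$ with the difference wrapped into
(−90, 90] — the perpendicular distance to the nearest periodic identity
line; pairing is shuffled for the null. Preferred-side spans are measured
in true direction space (period 360°, *not* doubled): the smallest arc
containing all significant ownership directions, contiguous iff < 180°.
Orthogonal preferences cancel exactly in doubled space (90° doubles to
180°), so undefined resultants are flagged rather than silently zero.

## Columnar clustering

Per penetration, each unit contributes its highest-|BOI| selective dataset
per orientation (ties broken deterministically: lower orientation, then
position), the largest subgroup sharing one edge orientation and position
is retained, and the proportion sharing the most common preferred side is
computed for penetrations with ≥4 such units. The mean proportion across
penetrations is compared against 2000 draws of i.i.d. fair-coin sides. For
a 4-unit penetration with unanimous sides the exact null probability is
$2 \cdot 0.5^4 = 0.125$, which the randomization reproduces — a useful
closed-form anchor. The randomization p is slightly conservative when the
proportion statistic is coarse (few, equally sized penetrations), because
ties between the observed and null statistic count toward p; with many or
unequal penetrations the statistic's support is dense and p is uniform
under the null to KS precision.

# The synthetic generator: what it emulates, and what it does not

Each unit is an inhomogeneous Poisson process,

$$r(t) = b + A\,g(t - \ell_{cRF})\,[1 \pm m\,h(t - \ell_{BO})]\,[1 \pm c\,h(t - \ell_{cRF})],$$

with logistic onset envelopes $g, h$ (10 ms 10–90% rise, reaching 10% at
the nominal latency), multiplicative border-ownership modulation $m$ whose
sign follows the match between the trial's owning side and the unit's
preferred side, and contrast-polarity modulation $c$. Spikes are drawn per
1 ms bin, jittered uniformly within the bin and rounded to 0.1 ms. Key
defaults, chosen once as a realistic operating point for extrastriate
cortex and not revisited:

| parameter | default | why |
|---|---|---|
| baseline rate $b$ | 2 sp/s | low spontaneous activity typical of V4 units; keeps the planted $m$ interpretable, since the sustained index is $mA/(A+b)$ |
| evoked amplitude $A$ | 50 sp/s | robust visual drive |
| cRF latencies | granular 48 < deep 50 < superficial 51 ms | feedforward input arrives in the granular layer first |
| BO latencies | deep 75 < granular 95 < superficial 100 ms | the laminar timing structure the analysis is designed to detect |
| $m$ | 0.4 | a sustained index in the 0.4–0.5 range |
| trials/condition | 8 (generator accepts 6–10+) | typical session yield |
| columnar coherence | 1.0 | a fully coherent column; lower it to emulate partial clustering |
| LFP noise | 1/f, SD 0.001 mV | ~2.5% of the peak potential; the second difference amplifies contact noise by $\sqrt{6}/h^2$, so this sits at a realistic CSD SNR (~12) |
| RF mapping | 10,000 events, gain 12, background 30 sp/s | multiunit-scale background and enough events per position (~16) for stable baseline SDs |

Unit depths are planted at least half a contact pitch (0.05 mm) from the
granular-band boundaries and above the 2 mm exclusion depth: closer than
that, compartment assignment is unresolvable by a 100 µm-pitch probe as a
matter of geometry, not of algorithm.

Because the border-ownership modulation multiplies only the evoked term,
the sustained index approaches $mA/(A+b) \approx 0.96\,m$ rather than $m$,
and the full-window [50, 500] ms index is further diluted by the
pre-modulation segment; recovery of the planted $m$ is therefore asserted
on the sustained window [200, 500] ms, where the modulation is fully on.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify about real data: non-Poisson spiking (bursting,
refractoriness), rate correlations between simultaneously recorded units
(every unit is conditionally independent given the stimulus), spike-sorting
contamination, eye-position jitter and microsaccades, adaptation across
trials, biophysically realistic LFP (the forward model is a 1-D Poisson
solve, not a volume conductor), and stimulus-geometry errors. The test
suite shows the *estimators* are correct and calibrated under the stated
model; it does not show the model is the one generating any particular
laboratory's data.

# Numerical conventions and degenerate inputs

- Times in ms relative to stimulus onset; angles in degrees; depth in mm
  increasing downward from the most superficial contact; latency search
  restricted to the [0, 500] ms stimulus epoch on a 1 ms grid.
- Random seeds: every stochastic function takes an explicit `seed`; master
  seeds are expanded by a fixed integer recurrence (`derive_seed`), and all
  functions restore the caller's RNG state.
- $B(t)$ denominator floor $10^{-6}$, flagged where active; BOR undefined
  below 10 window spikes or with all sets tied; zero-SD baselines make
  z-scores undefined (unit excluded, never silently 0); all-zero rates make
  the BOI an error, not a 0.
- Permutation/randomization p values: plain fraction plus add-one
  correction, everywhere, with ties counted toward the null (conservative).
- Ties in clustering dataset selection: lower orientation, then lower
  azimuth/elevation. Ties in the aggregate-orientation and identity tests
  are handled by the same ≥/≤ conventions.
- Problem sizes used by the packaged checks (chosen to exercise the stated
  operating points at desk scale): 2000 null datasets for permutation
  calibration; 200 units for index recovery; 20 replicate simulations at
  (120, 100, 60) units per compartment with 500-replicate bootstraps for the
  laminar latency ordering; 10,000 sets for BOR; 100 simulations for the
  orthogonality and 200 penetrations for the randomization-calibration
  checks.

# Known limitations

- Absolute threshold-crossing latencies carry the kernel's ~10–15 ms
  step-response lag (see above); compare populations, don't read onsets.
- The shuffle-calibrated threshold depends on population size; comparing
  compartments of very different sizes should be accompanied by the
  subsampling control.
- The granular-band 50% rule is one reasonable automation of what is,
  in practice, a visual judgment; the override exists for a reason, and
  uninterpretable CSD maps must be excluded rather than forced.
- Randomization p values are discrete and conservative at small n; the
  add-one-corrected value is the honest floor.
- The per-contact spike-based receptive fields used for the orthogonality
  metric stand in for analog multiunit-envelope maps; only the contour
  centres enter the metric, which is insensitive to that substitution.
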