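---
title: "Modelling brain network ictogenicity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling brain network ictogenicity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Each region of interest (ROI) is a phase oscillator of theta-neuron
(SNIC) type,

$$\dot\theta_i \;=\; (1-\cos\theta_i) + (1+\cos\theta_i)\,I_i(t),$$

with input current

$$I_i(t) \;=\; I_0 + \sigma\,\xi_i(t) +
  \frac{K}{N}\sum_{j\neq i} a_{ji}\,\bigl[1-\cos(\theta_j-\theta^{(s)})\bigr].$$

For $I<0$ the oscillator has a stable rest phase
$\theta^{(s)} = -\arccos\!\bigl((1+I_0)/(1-I_0)\bigr)$ (the negative
branch is the attracting fixed point; the saddle sits at the mirrored
positive angle, which `stable_phase()` documents and the tests verify by
linear stability).  For $I>0$ the phase rotates — the model's seizure
state.  The transition at $I=0$ is a saddle-node on invariant circle
(SNIC) bifurcation, so sub-threshold nodes seize only by noise-driven
escape, and coupling (which is non-negative and grows as neighbours
leave rest) recruits further nodes.

All ROIs share one excitability $I_0$; the network enters only through
the phase-locking-derived adjacency matrix.  **Brain network
ictogenicity (BNI)** is the area under the seizure-time fraction
$P_{sz}(I_0)$ over a fixed excitability window $[\lambda_1,\lambda_2]$,
by trapezoidal quadrature on the simulation grid.  **Node ictogenicity**
is the relative BNI drop after removing one node and its edges,
$\mathrm{NI}^{(i)} = (\mathrm{BNI}_{pre}-\mathrm{BNI}_{post(i)})/\mathrm{BNI}_{pre}$,
and nNI normalises the NI vector to unit sum.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| $K$ | 10 | global coupling gain |
| $\sigma$ | 6 | noise standard deviation |
| $\delta t$ | $10^{-2}$ | Euler step (arbitrary time units) |
| steps | $4\times10^6$ | production trajectory length |
| $[\lambda_1,\lambda_2]$ | $[-1.7,\,-0.5]$ | excitability window, 13-point grid |

The excitability window follows the convention that $\lambda_1$ is low
enough that no network seizes and $\lambda_2$ high enough that seizures
are common; the 13-point spacing of 0.1 is our choice (the grid
resolution is not fixed by the framework).

### Noise discretization — why the "dt" convention is the default

"Stochastic Euler" admits two readings.  The Euler–Maruyama form adds
$(1+\cos\theta)\,\sigma\sqrt{\delta t}\,\zeta_t$ per step; the plainer
"noise as part of the current" form adds
$(1+\cos\theta)\,\sigma\,\delta t\,\zeta_t$.  The two differ only by the
rescaling $\sigma \mapsto \sigma\sqrt{\delta t}$, so both are exposed
through `model_params(noise_scaling=)`.  With the standard
$\sigma = 6$ and $\delta t = 10^{-2}$, however, only the "dt" reading
(equivalent to Euler–Maruyama at $\sigma_{\mathrm{eff}} = 0.6$)
produces the regime the framework describes: a rest state that survives
at $\lambda_1$ and a seizure propensity that is governed by the network.
Under the Euler–Maruyama reading at $\sigma = 6$ the per-step kicks
reach $\approx 1.2$ radians, the rest state boils away, and a coupled
network's $P_{sz}$ curve is almost indistinguishable from that of its
isolated nodes — BNI then cannot discriminate networks, which would
defeat the method.  We therefore default to `noise_scaling = "dt"`.

### Scoring "time in the rotating state"

The framework does not pin down how a sample is attributed to the
seizure state.  Our classifier: the raw indicator
$r_i(t) = \mathbf{1}\{1-\cos(\theta_i(t)-\theta^{(s)}) > 1\}$ (phase
more than $\pi/2$ from rest) is smoothed by a centred moving average
over one time unit ($1/\delta t$ samples, truncated at the edges) and
thresholded strictly at $0.5$.  The smoothing suppresses brief noise
excursions while scoring sustained rotations; window and threshold are
exposed as knobs.  The threshold comparison is implemented on integers
($2\times\mathrm{sum} > \mathrm{len}$), so the streaming C++ scorer and
the R classifier agree bit-for-bit.

One corner is worth stating: a *noiseless* supra-threshold rotation at
small $I>0$ lingers near the SNIC ghost — within $\pi/2$ of the rest
reference — for most of each period (the far-half duty cycle is
$1-\tfrac{2}{\pi}\arctan(1/\sqrt{I})$, about 20% at $I=0.1$), so this
classifier scores it at its duty cycle, not at 1.  In the operating
regime that matters (noise-driven dynamics at $\sigma_{\mathrm{eff}}=0.6$),
escape excursions traverse the far half slowly and rest dwell is near
the fixed point, so the indicator cleanly separates the regimes.  The
tests assert the closed-form duty cycle for the noiseless corner rather
than pretending it scores as 1.

### Seeding and common random numbers

Every node's noise stream is an independent counter-based generator
keyed by the run seed and a hash of the ROI label.  Consequences, both
verified by tests: permuting a network's nodes permutes trajectories
and seizure times (up to floating-point summation order), and removing
a node leaves every other node's noise realization untouched.  Combined
with shared per-grid-point seeds between the pre- and post-removal
sweeps, NI contrasts are fully paired, which is what makes node removal
detectable above Monte-Carlo noise at test scale.  Whether the original
analyses re-used realizations between pre and post is unknown; pairing
is a pure variance-reduction choice and does not bias NI.

After removal the coupling normalization $K/N$ uses the reduced size
$N-1$ by default (the literal model definition); `n_norm = "original"`
keeps the pre-removal $N$.

## The functional-network pipeline

From regional time series to a weighted network: (1) zero-phase
band-pass into the theta band (4–8 Hz) with a 4th-order Butterworth
design applied forward–backward; (2) instantaneous phases from the FFT
analytic signal; (3) one second trimmed at each end before phase
statistics (filter/Hilbert boundary guard, configurable); (4) PLV and
circular mean phase difference per pair from the time-averaged unit
phasor; (5) per-edge significance against 99 pairs of IAAFT surrogates
(both channels independently surrogated per pair), retaining an edge
only if its PLV strictly exceeds the $\lceil(1-\alpha)\,n_{surr}\rceil$-th of the sorted
null values — the 95th of 99 at $\alpha=0.05$; (6) zero-lag rejection
of edges with $|\overline{\Delta\phi}| < 2\pi f_{low}/f_s$ (strictly
less; $0.008\pi$ rad at 4 Hz and 1 kHz); (7) removal of edges whose
direct length $1/\mathrm{PLV}$ strictly exceeds the Dijkstra shortest
path between their endpoints, ties keeping the edge.

Choices the literature leaves open, fixed here and logged in the output
metadata: the filter family and order; the edge-length transform
$1/\mathrm{PLV}$ (any monotone transform preserves ordering but not
additivity along paths, so this is a real choice); the surrogate
threshold convention (strictly greater, one-sided, per edge); IAAFT
iteration budget (at most 100 iterations, stopping early at relative
spectral error below $10^{-4}$ or when an iteration improves the error
by less than 5% — the scheme plateaus, after which further iterations
only shuffle equivalent surrogates); surrogates drawn from the
*band-passed* series with phases taken directly from their analytic
signal (IAAFT preserves the amplitude spectrum, so surrogates stay
band-limited; re-filtering them is redundant work, not a different
null); the circular mean (argument of the mean
phasor, consistent with the PLV) rather than an arithmetic mean of
wrapped differences.  Degenerate inputs fail loudly: constant channels
have no phase, constant series no surrogate.

## Synthetic data: what it emulates and what it does not

The study's EEG is not deposited, so the generator plants the
statistical structure the analysis assumes.  `simulate_roi_signals()`
produces noisy Kuramoto-type phase oscillators with natural frequencies
jittered $\pm 1$ Hz around 6 Hz, coupling proportional to planted
weights (gain 5 rad/s per unit weight), an imposed per-edge phase lag
of $0.02\pi$–$0.1\pi$ rad (so genuine edges survive zero-lag
rejection), phase diffusion of 2 rad/\(\sqrt{s}\), and observation
$\cos(\phi)$ plus white measurement noise (SD 0.2).  These values were
calibrated once so that planted pairs lock partially rather than
rigidly: stronger coupling or weaker jitter drives whole networks into
global synchrony with PLV near 1 everywhere (unlike resting EEG, whose
theta-band PLV typically spans 0.2–0.7), which would make edge
structure unrecoverable in principle.
Defaults emulate the reference recording geometry: 40 ROIs, 20 s at
1 kHz.

Cohorts (`make_group_dataset()`) default to 26 + 21 subjects with
uniform-random 40-node topologies, edge density 0.3 and mean weight 0.5
(drawn uniformly within ±50%), chosen so that node coupling mass places
network escape thresholds inside the excitability window.  The group
effect is a global multiplicative weight scaling $\gamma$ on group B —
chosen because total coupling mass is what the input current
integrates, hence seizure propensity is monotone in it.  This is a
planted property for validating the pipeline, explicitly *not* a claim
about what differs in real AD networks.

What the generator does **not** emulate: sensor-level volume conduction
and source leakage (beyond what the zero-lag mask is designed to catch),
1/f background spectra, non-stationarity across the recording,
amyloid-dependent topological degeneration.  Passing recovery tests
therefore shows the pipeline is correct and sensitive under its own
assumptions, not that it is robust to everything real EEG does.

## Statistics

Group contrasts use the Mann–Whitney U test with midrank ties,
reporting the first-sample U, the tie-corrected normal z (no continuity
correction) as effect size, and an exact p for small untied samples.
Paired designs use the Friedman test (χ² reported; a fully tied matrix
scores χ² = 0, p = 1).  The nNI node test resamples the pooled
participant × ROI entries (destroying any ROI effect), computes per-ROI
medians for each of 10,000 surrogate tables, and pools all surrogate
columns into one null distribution — columns are exchangeable under
pooled resampling, and pooling sharpens the tail at fixed bootstrap
count.  P-values are one-sided by default (high median = seizure
driving; two-sided by flag), use the add-one convention, and are BH
FDR-adjusted.  MVPA uses unregularized logistic regression, stratified
5-fold CV AUC, 20 repetitions; permutation testing (default 1000
permutations, a choice — the original count is unstated) reuses the
identical fold assignments so overfitting cancels between observed and
permuted data.

## Problem sizes used by the tests and the acceptance script

Production-scale trajectories ($4\times10^6$ steps, 40 ROIs) are the
package defaults, but the test suite and `scripts/acceptance.R` run
scaled-down study conditions chosen once: $10^5$ steps per grid point
(5% burn-in), 12-ROI cohorts of 15 + 15 subjects on a 7-point grid for
group contrasts (the coupling-robustness cohort instead spans edge
densities 0.15–0.45, since rank stability across coupling constants is
only meaningful for subjects whose BNIs genuinely differ),
13-point grids elsewhere, and the full 40-ROI / 20 s /
1 kHz geometry with 19 surrogate pairs (the smallest count valid at
$\alpha = 0.05$; the package default stays 99) for the
network-construction recovery check.  At
$10^5$ steps a single-node seizure fraction carries roughly 17%
relative Monte-Carlo error, so the symmetry check on disconnected
identical nodes averages 64 realizations per grid point
(`n_realizations`, default 1) to test the absence of systematic
asymmetry at a meaningful precision rather than measuring seed noise.

## Known limitations

* BNI magnitudes depend on the seizure classifier's window and
  threshold; comparisons are meaningful within one configuration.
* The $P_{sz}$ ceiling under the default classifier stays below 1 in
  the scaled-down regime; BNI is used comparatively, which the group
  analyses and robustness checks rely on.
* The noise convention is a documented interpretation (see above);
  anyone reproducing published magnitudes should check both.
* Exact reproduction of published cohort statistics is impossible
  without the original EEG; the package validates the machinery on
  planted synthetic structure instead.
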