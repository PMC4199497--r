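---
title: "Spectral network analysis of resting-state EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral network analysis of resting-state EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(modspan)
```

# The analysis in one paragraph

`modspan` turns multichannel resting-state EEG into band-wise functional
networks and compares their topology and scalp topography between groups.
Per subject it computes (i) Welch band power contributions, (ii) debiased
weighted phase lag index (dwPLI) connectivity matrices in the delta, theta
and alpha bands, (iii) weighted graph metrics on those matrices thresholded
across a range of connection densities — clustering, characteristic path
length, global efficiency, Louvain modularity, the SD of participation
coefficients, and the topographic *modular span* of the largest module —
and (iv) normalised mutual information (NMI) between the modular structures
of every pair of subjects. A statistics layer runs Welch unequal-variance
t-tests with Bonferroni–Holm correction across bands, and robust
regressions of network metrics on behavioural CRS-R scores. Because no
patient data ship with the package, a synthetic-cohort generator plants the
group structure the pipeline is designed to detect, and the test suite
verifies end-to-end recovery of that structure.

# Preprocessing

Continuous recordings are band-pass filtered to 0.5–45 Hz with a zero-phase
Hamming-window FIR (transition width 25% of the relevant cutoff, filter
length capped by the data length; the constant group delay of the
linear-phase filter is removed exactly). Zero-phase filtering matters
because everything downstream is a phase statistic. Exactly the first
10 minutes are segmented into 60 × 10 s epochs, each baseline-corrected to
its own mean. Artifact screening is fully automated: the log-variance of
every channel (pooled over epochs) and epoch (pooled over channels) is
converted to a robust z-score (median/MAD), and entries above *z* = 4 are
rejected. Rejected epochs are dropped; rejected channels are refilled with
an inverse-distance weighted average of their 4 nearest intact neighbours —
a deliberately simple spatial fill, not a spherical-spline interpolation,
and flagged as such in the provenance log. Average referencing comes last,
after the fill, so the reference is computed from a complete channel set.
An EOG control analysis (1–3 Hz bipolar derivations, per-second SD
normalised by its mean, first-half vs second-half comparison) supports a
check against systematic drowsiness drift.

The variance-normalisation formula and thresholds for "abnormally noisy"
are package choices — the procedure they automate is usually quasi-manual;
defaults err on the permissive side (*z* = 4) because the synthetic data
carry no gross artifacts.

# Spectral power

Welch spectra use 4 s Hamming segments with 50% overlap inside each epoch,
zero-padded so bins are exactly 0.25 Hz wide at 250 Hz. Band power in the
five canonical bands — delta 0–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–40 Hz, treated as half-open `[lo, hi)` intervals so abutting edges never
double-count a bin — is expressed as the percentage of the 0–40 Hz total,
per channel. Temporal variability is the SD across epochs of the
channel-averaged single-epoch contributions, computed with identical Welch
settings per epoch.

# dwPLI connectivity

For channels $a, b$ with epoch-wise short-time Fourier cross-spectra
$X_e = A_a A_b^*$ at one time–frequency bin, write $I_e = \mathrm{Im}(X_e)$.
The debiased weighted phase lag index is

$$\mathrm{dwPLI} \;=\; \frac{\big(\sum_e I_e\big)^2 - \sum_e I_e^2}
{\big(\sum_e |I_e|\big)^2 - \sum_e I_e^2},$$

with value 0 when the denominator vanishes (no imaginary cross-spectral
mass — e.g. identical or strictly zero-lag signals — means no detectable
lagged coupling; each such event is benign and corresponds to a pair the
estimator is designed to discount). The estimator is dimensionless
(rescaling either channel cancels), insensitive to zero-lag
volume-conducted coupling, and debiased for small epoch counts; with
alternating $\pm a$ imaginary parts over $n$ epochs it equals exactly
$-1/(n-1)$, a useful hand check.

The time–frequency grid is a Hanning-tapered STFT. The default
full-resolution grid uses a 2 s window, 0.04 s hop and FFT length 512 at
250 Hz (0.488 Hz bins); the *coarse* grid (`tf_config_coarse()`: 1 s
window, 0.5 s hop, 0.98 Hz bins) is used for simulation studies, where the
planted structure is broad-band enough that the fine grid adds cost but no
information. Per pair and band, the default summary records the **peak**
dwPLI over all bins in the band, following the ambient-connectivity
convention. The peak is an extreme-value statistic: on *uncoupled* data the
maximum of ~100 zero-mean estimates is positive (~0.2 on the coarse grid at
60 epochs), so band matrices have a positive noise floor. This selection
bias is inherent to the convention; a `"mean"` aggregation is provided and
is the right tool when an unbiased null is needed (the zero-lag robustness
checks in the test suite use it). Analysis is restricted to delta, theta
and alpha by default because sensor-space beta/gamma coupling is badly
confounded by EMG in patient populations.

# Graph metrics

Connectivity matrices are proportionally thresholded to retain the top
$\mathrm{round}(d \cdot N(N-1)/2)$ edge weights at densities
$d = 0.50, 0.475, \dots, 0.10$ (17 levels); graphs stay **weighted**
(no binarisation) and ties at the cutoff break by channel-pair
lexicographic order for determinism. Note a subtlety this implies: for a
matrix with many tied weights the retained edge *count* is exact and the
edge *set* is deterministic, so metrics still vary across densities even
when all weights are equal.

On each graph (weights max-normalised per graph):

* **Clustering** — geometric-mean triangle form,
  $C_i = \sum_{jk} (\hat w_{ij}\hat w_{ik}\hat w_{jk})^{1/3} / (k_i(k_i-1))$,
  averaged over nodes; nodes with fewer than two neighbours contribute 0.
* **Characteristic path length / global efficiency** — Dijkstra distances
  on edge lengths $1/\hat w$; $L$ averages over connected ordered pairs only
  (fragment counts are recorded), $E$ averages inverse distances with
  disconnected pairs contributing 0, so fragmentation at sparse densities
  is handled without infinities and the $L$/$E$ contrast is preserved.
* **Louvain modularity** — 50 repetitions per density, each seeded from a
  derived seed (the heuristic randomises its vertex processing order); $Q$
  and every partition-derived quantity are averaged across repetitions,
  never taken from a single "best" partition. Resolution is fixed at 1.
* **Participation SD** — $P_i = 1 - \sum_m (k_{im}/k_i)^2$ with weighted
  degrees; the SD across nodes indexes the presence of a subpopulation of
  inter-modular hubs.
* **Modular span** — for a non-degenerate module $M$ ($n_M \ge 2$),
  $$S(M) = \frac{1}{n_M} \sum_{(i,j) \in M,\; w_{ij} > 0} w_{ij}\, d_{ij},$$
  where $d_{ij}$ are scalp distances normalised so the most distant
  electrode pair is exactly 1. The reported value is the span of the
  largest module (by node count; ties broken by larger intra-modular
  weight). Divison by $n_M$ is the literal "scaled by the size of the
  module" reading; the divisor is configurable because other size
  normalisations (e.g. the number of intra-modular edges) are defensible.
* **NMI** — $2\,\mathrm{MI}/(H_a + H_b)$ between module-label
  distributions. Two single-module partitions are identical (NMI 1); if
  exactly one side has zero entropy, MI and hence NMI are 0. Inter-subject
  NMI matrices pair partitions at matched (density, repetition) indices and
  average over all 17 × 50 of them.

Everything partition-free is computed once per density; all metrics are
finally averaged across the 17 densities with equal weight.

# Group statistics

Group contrasts use Welch's unequal-variance t-test (the reported sign
convention is controls minus patients). Within each metric family the
p-values are Bonferroni–Holm-corrected **across the three analysed bands**
— never across metrics, matching the correction family to the repeated
test actually performed. Clinical association uses iteratively reweighted
least squares with Tukey bisquare weights; $R^2$ is reported as the squared
correlation between fitted and observed responses (a robust fit has no
canonical $R^2$; this convention is stated rather than assumed), the slope
p-value uses the robust standard error with $t_{n-2}$, and a perfect fit
falls back to ordinary least squares since the IRLS scale estimate
degenerates at zero residuals. Imagery-subgroup contrasts are reported
uncorrected, as single planned comparisons.

# The synthetic cohort: what it emulates, and what it does not

The generator produces 91-channel, 250 Hz, 10-minute recordings (60 × 10 s
epochs) on a quasi-uniform spherical-cap montage (Fibonacci lattice over
the upper 60% of a sphere). Sources are amplitude-modulated sinusoids with
per-epoch random phase; channels in a module share the module's rhythm with
fixed per-channel phase offsets (low-discrepancy spread over ±π/2, so
nearly all pairwise lags avoid 0 and π, the two angles dwPLI discounts).
All sources pass through an instantaneous Gaussian volume-conduction kernel
(width 0.12 in normalised scalp distance) on top of per-channel 1/f
background noise — reproducing the zero-lag confound dwPLI exists to
reject.

Coupling strength $\kappa \in [0,1]$ scales source amplitude **and** phase
stability: each channel's offset is jittered per epoch by
$\mathcal N(0, (2.2(1-\kappa))^2)$ radians. The jitter mapping is essential:
dwPLI measures phase-lag *consistency* and saturates with amplitude, so
without it any nonzero coupling would read as a near-perfect network and
the graded "network quality" axis the clinical regression needs would not
exist.

Default regimes (the study conditions; all values chosen as a realistic
operating point and then left alone):

* **Control-like** — one strong long-range alpha regime (10 Hz,
  $\kappa = 0.9$): two modules, each the union of two diametrally opposite
  azimuthal scalp sectors, plus ~10 apex channels that receive *every*
  module's rhythm at reduced gain and act as planted inter-modular hubs
  (they are what gives healthy networks their high participation-SD).
  Strong per-epoch amplitude modulation (SD 0.5) makes control band power
  temporally variable, delta and alpha most visibly.
* **Patient-like** — compact delta (2.5 Hz, $\kappa = 0.9$, 12 patches) and
  theta (6 Hz, $\kappa = 0.8$, 10 patches) regimes; patches hold 5 and 4
  channels alternately, are seeded by farthest-point sampling from a
  per-subject random rotation (idiosyncratic maps), and do **not** tile the
  scalp — channels outside the patches carry only background noise. Sparse
  patches are the operating point at which patient networks are locally
  clustered with strong inter-modular contrast (high clustering and
  participation-SD) while the *largest* Louvain module remains a diffuse
  background module whose span matches the control noise baseline —
  i.e. short-range structure without a modular-span increase. A weak
  long-range alpha remnant with per-subject
  $\kappa \sim U(0.05, 0.7)$ completes the patient regime; that draw is the
  subject's latent network quality.
* **CRS-R model** — $\mathrm{CRS} = \mathrm{round}(6 + 14\kappa_\alpha +
  \mathcal N(0,1))$ clipped to the integer range 7–19 (the observed
  clinical range); patients with synthetic scores ≤ 8 are labelled VS,
  others MCS. The planted $\kappa_\alpha$ spread is calibrated so that the
  regression of pipeline-recovered alpha clustering on CRS-R is
  well-determined ($R^2 \ge 0.5$) under the default noise; the imagery
  flag is an independent random annotation.

What passing tests on this cohort do **not** show: the generator has no
biophysical head model (linear Gaussian mixing is not a BEM forward
solution), no real artifacts (no blinks, saccades, EMG bursts, electrode
pops — which is why the rejection stage is exercised mostly in its
"nothing to reject" regime), stationary module layouts within a recording,
and a single oscillation per band. Effect sizes on real data will be far
smaller than the planted ones; the cohort demonstrates that the pipeline
recovers structure faithfully and with the right sign, not that it would
reach significance at clinical sample sizes.

# Numerical choices and degenerate inputs

* Frequency bands are half-open; the DC bin carries no imaginary power and
  is harmless to dwPLI.
* dwPLI denominator 0 → value 0 (logged implicitly through provenance).
* All-zero graphs yield a single trivial partition with $Q = 0$; isolated
  nodes get participation 0; single-node modules are excluded from span.
* Degenerate all-zero EOG windows: normalised SD defined as 0 and the
  timecourse flagged `degenerate`.
* Proportional-threshold ties: stable lexicographic order.
* Largest-module ties: larger total intra-modular weight.
* Seeds: every randomised operation takes an explicit integer seed;
  multi-part operations derive child seeds (`derive_seeds()`), all below
  2^31, and restore the caller's RNG state.
* Problem sizes in the shipped test-and-analysis runs (chosen as the
  package's simulation-study scale): the full cohort runs 15 + 15 subjects
  at the default 91-channel/60-epoch geometry on the coarse TF grid;
  estimator oracles use 100 two-channel simulations; unit tests use reduced
  channel counts. The full-resolution TF grid is available throughout via
  `tf_config()`.

# Known limitations

Sensor-space only (no source projection); the peak-over-bins convention
carries the documented positive noise floor; inverse-distance channel fill
is cruder than spherical splines and slightly smooths local topography near
rejected channels; the Louvain resolution parameter is fixed at 1, so very
small true modules can be absorbed at dense thresholds; and NMI between
partitions of the same graph family has a small positive baseline because
module size distributions are shared even when structure is not.
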