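---
title: "Methods: neuron size scaling, cell-cycle deconvolution, and behavior metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuron size scaling, cell-cycle deconvolution, and behavior metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyscale)
```

This vignette documents the models, parameter choices, and numerical
decisions behind `ploidyscale`. The package analyzes how neuron size
responds to a ploidy change — concretely, the diploid-versus-triploid
comparison in *Xenopus* tadpole brains, where the triploid genome is
1.5-fold the diploid one — and ships synthetic-data generators that
emulate the statistical structure of each data type so that every
analysis step can be validated by parameter recovery against known truth.

## 1. Geometry: why surface area superscales

Each neuron is decomposed into a spherical cell body and a tree of
tapered tube (conical frustum) segments. For an edge with end radii
$r_1, r_2$ and chord length $l$:

$$V = \frac{\pi l}{3}(r_1^2 + r_1 r_2 + r_2^2), \qquad
A = \pi (r_1 + r_2)\sqrt{l^2 + (r_2 - r_1)^2}.$$

For a cylinder this reduces to $A = 2\sqrt{\pi V l}$: at fixed volume
fold $f_V$, surface area scales as $\sqrt{f_V f_l}$ with the length fold
$f_l$. The study conditions are $f_V = 1.5$ with $f_l = 1.95$, giving a
neurite surface fold $\sqrt{1.5 \times 1.95} \approx 1.71$ —
superscaling relative to the 1.5-fold ploidy reference — while the
sphere's surface subscales at $1.5^{2/3} \approx 1.31$. Scaling
classification (`classify_scaling()`) uses a band of half-width 0.1
around the reference fold by default; the band only labels the fold, it
never feeds back into estimation.

Conventions worth knowing:

* Edges whose parent is a soma node are measured with the child's radius
  at both ends; the soma is modeled separately as a sphere of the root
  radius (multi-node somata use the volume-equivalent sphere). Without
  this the stem frusta would span soma-to-neurite radii and corrupt the
  area budget.
* Branch level is centrifugal order (stems = 1, +1 at each branch
  point). It matches per-level length summaries; Strahler order does not.
* Mean neurite diameter is length-weighted (the unweighted per-segment
  mean is also reported); the length-weighted form is the one consistent
  with the length-by-diameter distribution.
* `max_radius` is the 3-D Euclidean distance from the soma centroid, not
  path distance.
* Sholl profiles count edge crossings of concentric spheres centered on
  the soma centroid, default step 5 um; an edge crosses radius $r$ when
  its endpoint distances straddle it ($\min < r \le \max$), so tangent
  edges count once.
* SWC coordinates are micrometres; column 6 is a radius, not a diameter.

The frustum formulas are verified against numeric quadrature (1000
random edges, $10^{-6}$ relative) and the additivity, isometry, and
rescaling identities are asserted as properties in the test suite.

## 2. The neuron generator and its calibration

`simulate_neuron()` grows a soma sphere plus `n_stems` neurite stems.
Segment lengths are lognormal (mean 12.5 um, CV 0.35); after each
segment the branch bifurcates with probability 0.35, children shrink in
diameter by the Rall-style taper 0.85, and growth stops at centrifugal
order 4 or after 8 segments on a branch. The segment cap is needed
because nothing else terminates an unbranched path (`branch_prob = 0`
must still yield finite trees); 8 segments keeps branch lengths
realistic. Lognormal laws are mean-parameterized throughout
(`meanlog = log(m) - sdlog^2/2`), so expectations match the configured
means exactly and closed-form calibration is possible.

A triploid draw is the deterministic rescaling of the same-seed diploid
draw: soma radius $\times 1.5^{1/3}$, every edge vector $\times 1.95$,
every neurite radius $\times \sqrt{1.5/1.95} \approx 0.877$. This keeps
topology fixed (branching statistics are unchanged between ploidies, as
observed), isolates the scaling math from sampling noise, and enforces
the closure `length_fold x diameter_fold^2 = volume_fold` so neurite and
soma volume share one fold. Independent populations are obtained simply
by using disjoint seeds.

The defaults are calibrated analytically, from the closed-form
expectations of the branching process (no fitting involved). With
bifurcation probability $p$, cap $m$, and maximum order $L$: a branch
carries $E[K] = (1-(1-p)^m)/p$ segments, level $k$ holds
$n_k = (2q)^{k-1}$ branches ($q = 1-(1-p)^m$), expected total length is
$S\,\mu_l E[K] \sum_k n_k$ and expected neurite area
$\pi \mu_l E[K] S \sum_k n_k d_1 \tau^{k-1}$. The defaults give an
expected total neurite length of about 1.4 mm, a length-weighted mean
diameter of 0.84 um (within the 0-3 um range of real reconstructions),
and a mean per-neuron neurite:soma surface ratio of about 5.1 — the
roughly 5:1 surface partition seen in the tadpole forebrain neurons.
(The per-neuron mean ratio sits slightly above the naive aggregate
expectation — Jensen's correction on the ratio against lognormal soma
areas, $e^{3\sigma_{\log}^2}$, and the junction frusta, which carry the
parent branch's larger radius at one end — and the calibration accounts
for both.) That partition is what
makes the implied total-surface fold
$(A_s \cdot 1.31 + A_n \cdot 1.71)/(A_s + A_n) \approx 1.65$, the
package's reproduction target for total surface superscaling.

What the generator does *not* emulate: real reconstruction artifacts
(broken branches, radius quantization), neurite types (axon versus
dendrite), region-dependent morphology, and any correlation between soma
size and tree size. Recovery tests passing on this generator validate
the measurement chain, not those aspects of real data.

## 3. Flow cytometry

`simulate_flow_sample()` builds one dissociated-brain tube: singlet
cells with phase-labeled DNA content (G0/G1 at the G1 mean, G2/M at
twice it, S uniform in between, all times lognormal noise of CV 0.05 —
a typical Hoechst CV), PCNA and pH3 intensities drawn from log10-normal
components tied to the true phase (G0 = PCNA-negative, S =
PCNA-punctate, M = pH3-positive, G1/G2 = PCNA-diffuse), exactly
`bead_count` bead events, doublets (sums of two cells with inflated
FSC-W), and sub-G1 debris. Triploid tubes multiply all DNA means by
`genome_fold = 1.5` and divide the cell count by `count_fold = 1.5` —
the two study conditions. Default phase fractions (G0 0.45, G1 0.25,
S 0.15, G2 0.10, M 0.05) are free choices; all tests are
recovery-based, never asserting these numbers directly.

Gating follows the hierarchy singlets (FSC-W/FSC-A $\le$ 1.3) →
beads (bead channel $\ge 10^4$) → cells (SSC-W/SSC-A $\le$ 1.3, Hoechst
$\ge$ 100). Cutoffs are configuration values calibrated on the
generator; hand-drawn gates in a flow GUI have no portable equivalent.
The partition is exhaustive, disjoint, and idempotent. Absolute counts
use the bead stock (0.52e5 beads per 50 uL, 20 uL added, i.e. 20,800
beads per tube):
$$N = \frac{N_{\text{cells}}}{N_{\text{beads}}} \cdot \frac{1}{N_{\text{brains}}} \cdot \frac{0.52 \times 10^5}{50} \cdot 20.$$
The five QC rules (bead events > 5,000; cell events > 10,000; sample
bead means of FSC-A and Hoechst inside run mean $(1 \pm \text{CV})$;
sample bead CVs below twice the run CV; a ploidy partner in the same
clutch) are evaluated with run statistics over bead events pooled across
the run's samples; a single-sample run is compared against itself and
flagged.

### Dean-Jett-Fox deconvolution

`fit_djf()` fits histogram densities (256 bins up to the 99.9th
percentile, which excludes aggregates) by bounded least squares
(`minpack.lm::nls.lm`) with a G0/G1 peak, a G2/M peak (initialized at
twice the G1 mean but free — no peak constraints, no synchronized-peak
component), and an S component: a second-order polynomial dose density
between the peak means, clamped at zero and broadened dose-wise with
width proportional to the G1 CV. Two numerical choices matter:

* **Kernel shape.** DNA-stain noise is multiplicative with roughly
  constant CV, so the default broadening kernel is a lognormal matched
  in arithmetic mean and sd; the classic additive Gaussian kernels are
  available via `shape = "gaussian"`. On constant-CV data the Gaussian
  kernels leave a systematic positive S-phase bias — the skew of the G1
  peak gets absorbed by the S polynomial — while the matched kernel
  keeps every weight bias below 0.01 at $n = 50{,}000$ (asserted over 20
  seeds in the test suite).
* **Range-restricted areas.** Component weights are the kernel masses
  inside the fitted histogram range. Without this, a spurious G2
  component can slide past the aggregate cut on G2-free data and carry
  invisible weight.

### Marker mixtures and phase combination

`fit_log_mixture()` is a univariate EM on log10 intensities (k = 3 for
PCNA, k = 2 for pH3), initialized at data quantiles, with 20 seeded
restarts (short runs of 60 iterations; the best restart is polished to a
relative log-likelihood tolerance of 1e-8, max 500 iterations). The EM
log-likelihood is asserted non-decreasing in tests, the fit is
cross-checked against an independent mixture implementation, and a fit
is flagged degenerate when a weight collapses below 0.02 or the fitted
density has fewer modes than components. Assignment boundaries are
posterior-equality points between adjacent components.

`classify_phases()` merges the three fits: M from the pH3-positive
weight, G0 from PCNA-negative, S from PCNA-punctate, G2 as the
DNA-content G2/M weight minus M (floored at 0), G1 as the remainder
(clipped and renormalized; a clip beyond 0.05 warns). The exact merging
rule is a package decision — the alternative of sourcing S from the
DNA-content fit sits behind `s_source = "djf"`. The PCNA-diffuse
component genuinely spans G1, G2, and M; the classifier inherits that
ambiguity, which is why G1 is derived as a remainder. Confidence
intervals bootstrap hard event assignments (1000 resamples) rather than
refitting all three models per resample. Cell-only events enter the
DNA-content fit (not beads or all singlets).

## 4. Ratio imaging

The pERK/ERK chain assumes co-registered pairs (elastic registration is
an external, published step and is out of scope): `ratio =
perk / (erk + eps)` with `eps = 1e-6 x max(erk)` guarding the division;
the mask is the Huang threshold of the ERK channel followed by
4-connectivity border flood-fill hole closing; the ratio is zeroed
outside the mask; ROI means are taken over mask∩ROI pixels, and an ROI
with no in-mask pixels is reported missing rather than zero. The Huang
threshold minimizes the Shannon fuzzy entropy over all 256-bin histogram
cuts with memberships $u(g) = 1/(1 + |g - \mu_{\text{class}}|/C)$; the
implementation *is* the exhaustive search, ties break to the first
minimizing cut, and tests require bit-equality with an independent
loop-based implementation on random images. Z-projection defaults to
sum (mean available); the choice cancels in the ratio. Clutch
normalization divides every measurement by the maximum pixel of the
clutch's reference-group average ratio image, making values
scale-invariant per clutch.

## 5. Behavior

Speeds are finite differences of tracked positions; gaps longer than
three median frame intervals break the differencing so tracking dropouts
never become teleport speeds; speeds are floored at 1e-3 mm/s before
geometric averaging (the geometric mean is undefined at zero). The
startle window is the first second after stimulation and the cruising
window the last 60 s of the 2-minute session; summaries are geometric
means and group statistics run on log2 speeds. Activity classes are a
thresholded surrogate for manual scoring: active fraction = share of
samples above 1 mm/s, binned at 0.25/0.75 into still / half-active /
active, with a first-half flag for half-active animals. The bins are
documented defaults, not a claim about the original manual criteria.
The trajectory generator uses a startle mode of 3 s at 20 mm/s and a
cruising mode at 5 mm/s (CV 0.3, 30 Hz); `still_fraction` defaults to 0
because the speed analyses concern swimming animals — still animals are
exercised explicitly in classification tests.

## 6. Reproducibility and problem sizes

Every generator takes an explicit seed and restores the caller's RNG
state; identical (parameters, seed) give identical outputs, byte-for-byte
for SWC files. The pipeline manifest records the seed and a configuration
hash, and every output row carries both. Validation uses populations of
50 neurons per ploidy over five seeds for morphometry folds, samples of
20,000-50,000 events for the deconvolution recovery (20 seeds for the
bias bounds), batches of 6 + 6 tubes for the counting chain, and 12
animals over 5 seeds for behavior recovery — sizes at which recovery
tolerances (±0.02-0.05) sit several standard errors above the estimators'
sampling noise.

## 7. Known limitations

* The soma model is a sphere; real somata are irregular, so absolute
  soma surface is approximate even though fold changes are exact under
  the rescaling model.
* The weighted KS permutation test permutes neuron labels, which is
  conservative when neurons contribute very unequal segment counts.
* The DJF S-phase polynomial cannot represent strongly non-uniform
  S-phase dose distributions.
* The recursive CUSUM test uses the asymptotic linear-boundary crossing
  p-value $2(1 - \Phi(3\lambda) + e^{-4\lambda^2}\Phi(\lambda))$, which
  is anti-conservative below roughly 30 observations.
* Activity classes are threshold surrogates; agreement with manual
  scoring on real videos is untested by construction.
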