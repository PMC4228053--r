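---
title: "Melanopsin metamers and synthetic dLGN cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melanopsin metamers and synthetic dLGN cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melovis)
```

This vignette documents the models behind `melovis`, the parameters that
matter, and the design decisions taken where several defensible choices
existed. The package has two halves: the *stimulus design* half builds
cone-metameric, melanopsin-contrasting spectra by receptor silent
substitution; the *simulation/analysis* half generates synthetic
electrophysiology with planted condition effects and quantifies them with
the estimators a physiology lab would use.

## 1. Photoreceptor model

Pigment spectral sensitivities come from the Govardovskii A1 nomogram
(α-band plus β-band), parameterised only by the peak wavelength λmax and
normalised to 1 at the peak. Defaults for the mouse: SWS cone opsin 360 nm,
melanopsin 480 nm, rod opsin 498 nm, native MWS cone opsin 508 nm, and the
human LWS cone opsin (556 nm) that replaces MWS in the red-cone knock-in
line used for melanopsin-contrast work. These are standard literature
values, configurable per call; tabulated sensitivity curves can be supplied
instead of the nomogram. Pre-receptoral (lens) filtering is off by default
— fluxes are *corneal* — and can be supplied as a transmission function.

α-opic effective photon flux is ∫E(λ)s(λ)dλ, evaluated by the trapezoid
rule on the SPD grid after linear interpolation of the template. Grids are
in nm with inclusive endpoints; no sub-nm resolution is assumed.

## 2. Silent-substitution design

The LED model is three Gaussian primaries (365, 460, 600 nm; FWHM 20 nm,
configurable; measured spectra can be read from CSV). Writing the receptor
matrix $R$ (receptors × primaries, flux per unit drive), every design
requirement is linear in the stacked drive vector:
matched fluxes, isoluminance between spectra, Michelson contrast targets
(linearised as $f_2 = k f_1$, $k = (1+c)/(1-c)$, or $f_2 = f_1/k$ for a
decrement), and flux ratios.

`solve_metamer()` treats isoluminance and contrast constraints as *hard*:
it restricts the solution to their null space (SVD) and resolves the
remaining freedom by weighted least squares over the *soft* targets (flux
profile, ratio targets). Hard constraints therefore hold to machine
precision, not to the residual of a weighting scheme. Drives must lie in
`[0, max_drive]`; if the soft optimum leaves the box, a hinge-penalty
refinement moves it to the nearest in-gamut point *inside* the null space,
and genuinely infeasible systems are returned unclipped with
`feasible = FALSE` and per-constraint residual diagnostics.

### Why the cone contrast is carried by one opsin

Silencing rod *and* melanopsin confines the within-pair flash modulation to
a single spectral-exchange direction (the null space of the 2×3 rod/mel
submatrix). Along that ray the SWS and LWS drives necessarily move with
opposite signs for narrow-band primaries — an exchange that raises LWS
while holding rod and melanopsin fixed must lower SWS. A flash with the
*same signed* contrast on both cone opsins is therefore not realisable, and
since a daylight-like background holds roughly ten times less SWS than LWS
flux, gamut limits decide which opsin can carry a large step.
`design_daylight_mellow()` carries the requested Michelson contrast exactly
on one reference opsin (trying each opsin and polarity and keeping the
first in-gamut design; with defaults this is an SWS decrement) and reports
the other opsin's implied contrast. Michelson contrast is unsigned, so both
polarities realise the nominal value. All quantities reported in a
solution are recomputed from the synthesised spectra, never taken from the
solver's internal algebra.

The built-in daylight profile integrates a 6500 K blackbody photon
spectrum (a daylight-locus stand-in) through the templates and scales it
into the gamut; it reproduces the signature that matters — melanopsin, rod
and LWS fluxes roughly equal and about an order of magnitude above SWS.
With defaults, the design achieves the 10.0× melanopsin background ratio
exactly, a best-effort rod ratio of ~6.7×, and cross-pair cone contrasts
below 1e-14.

## 3. Synthetic units and stimuli

Units are linear–nonlinear–Poisson: a difference-of-Gaussians receptive
field (centre normalised to unit sum; surround of 2× the centre SD, scaled
by a strength $s \in [0,1)$, so full-field drive is $1-s$), an exponential
temporal kernel (τ = 40 ms), half-wave rectification, a multiplicative
cosine direction modulation for drifting gratings whose depth is a
log-frequency Gaussian of the grating temporal frequency, and Poisson
spike generation. Receptive-field half-max widths are drawn from a
right-skewed distribution over 5.6°–23° (Beta(1.2, 4) over the reported
mouse dLGN range; median ≈ 9°) — most centres are small, which also
matters for the spatial-frequency battery: with a 2× surround, only units
with centres below roughly 11° *can* move their preferred SF between the
two lowest grid frequencies, and the prevalence of preference changes in
the cohort (~half the units) is meant to match what dLGN recordings
show.

Stimuli live on a 100°×60°, 1°-pixel screen and are stored as a pattern
bank plus a per-frame index, which keeps hundred-fold cohort simulation
cheap. Conventions worth noting:

* *Inverting gratings*: a "1 Hz" grating inverts phase every 0.5 s (two
  inversions per cycle); the convention is configurable
  (`inversions_per_cycle`). The cohort presents each grating at two
  spatial phases in quadrature and combines responses by RMS — a
  single-phase contrast-reversing grating has position nulls that would
  make measured tuning depend on where a unit's RF happens to sit.
* *Drifting gratings* translate at TF/SF degrees per second; trials last
  one full cycle of the slowest frequency so mean rates are
  direction-balanced for untuned units.
* *Bar white noise*: one black or white bar per frame at a uniformly drawn
  position, for STA mapping.
* *Movie surrogate*: seeded 1/f spatiotemporal noise. It reproduces the
  property the analyses need — rich, reproducible spatiotemporal structure
  — but not the object content or luminance statistics of real footage.

### Reliability

A unit's `reliability` r is implemented as the trial-shared fraction of
drive variance: each trial's drive is $\sqrt{r}\,y + \sqrt{1-r}\,\sigma_y
\xi$ with fresh frame-held Gaussian noise ξ, so r is the expected
trial-to-trial drive correlation. The same r sets the variance $1-r$ of a
log-normal per-trial gain (unit median), which couples amplitude
variability to reliability and yields the amplitude–reliability
correlation pattern seen in flash data. Gain noise alone was rejected:
scaling a whole trial's rate leaves its Pearson correlation with the mean
response almost unchanged (only the Poisson signal-to-noise shifts, a ~0.01
effect on r), so it cannot plant the reproducibility differences the
analyses are meant to detect.

### Cohorts and planted effects

`make_cohort()` simulates a population through the full battery under both
spectral conditions. Wild-type defaults plant, in daylight: a strong
inhibitory surround (0.8 vs 0 in mel-low) in 75% of units — which lowers
full-field flash responses and shifts preferred spatial frequency upward
through the DoG transfer function, not by fiat; direction-selective units
(16% of the population, DSI depth 0.8) whose selectivity peaks at 1 Hz vs
0.2 Hz in mel-low; higher movie reliability (0.9 vs 0.55); and a weaker
shared drive between simultaneously recorded units (0.3 vs 0.6), which
lowers pairwise signal correlation. Flash reliability is higher in mel-low
(0.9 vs 0.55), matching the amplitude effect. Grating reliability is high
in both conditions (0.95 vs 0.75): forty-repeat grating responses are
substantially repeatable in practice, and the planted tuning effects, not
response scatter, should carry the spatial-frequency comparison. None of
these magnitudes is reported by the study being modelled; they are chosen
once as physiologically plausible values and documented here.

The movie sub-population (17 units split 5/4/4/4 across four "animals",
giving exactly 28 within-animal pairs) keeps condition-independent spatial
parameters: 1/f movies are dominated by low spatial frequencies, so a
condition-dependent surround would change movie drive power and confound
the reliability and correlation effects that block exists to plant. For
the same reason each unit's private movie drive is orthogonalised against
the shared reference drive before mixing — without this, the global
structure of 1/f noise correlates every RF drive at 0.2–0.97 and the
shared-drive weight would be invisible. A knockout cohort collapses every
per-condition parameter to its mel-low value, so planted condition
differences are exactly zero.

The ERG generator scales a stereotyped a-wave/b-wave template (normalised
so trough-to-peak is exactly the planted amplitude) by a Naka–Rushton
function of flash contrast (c50 = 0.3, n = 2) and by a gain that relaxes
exponentially (τ = 180 s) toward each condition's asymptote (40 µV mel-low
vs 28 µV daylight).

## 4. Estimators

* **PSTH**: half-open bins from trial onset; rate = counts/(trials×width);
  10 ms bins for flash analysis, 25 ms for correlation measures, 50 ms for
  grating responses.
* **Flash amplitude**: mean baseline-subtracted rate over 200 ms after
  flash onset; baseline from the pre-flash window. Responsiveness
  criterion: smoothed peak > 2 baseline SDs above baseline (the study's
  criterion is unstated; this is configurable).
* **Latency**: smoothed-peak time; population comparisons fit Gaussians to
  latency histograms and use an extra-sum-of-squares F test, attempted
  only when both fits reach R² > 0.8.
* **Reproducibility**: leave-one-out trial-vs-mean Pearson r at 25 ms bins
  (the pairwise-trial variant is equivalent up to a monotone map; the
  leave-one-out form is the default).
* **Inversion-locked modulation**: the event-locked PSTH's signal
  variance, estimated from trial-resolved PSTHs as the across-bin variance
  of the trial-mean minus the between-trial variance over n (noise is
  independent across trials), scaled to a peak-to-trough-equivalent
  $2\sqrt{2\,\mathrm{var}}$. The naive peak-minus-trough is biased upward
  by Poisson noise in proportion to rate, which scrambles preferred-SF
  argmaxes for weak responses.
* **Preferred SF**: grid argmax at the preferred orientation (chosen
  independently per condition as the orientation of the overall maximal
  response); ties break to the lower frequency.
* **Direction selectivity**: DSI = (R_pref − R_null)/(R_pref + R_null)
  with responses floored at zero; a vector-sum index is available behind
  `method = "vector_sum"`. "Direction sensitive" is decided by a
  permutation test (1000 label shuffles, α = 0.05) rather than a fixed DSI
  cutoff; shuffling stops early once the p value is clearly above α,
  which leaves the classification unchanged.
* **STA receptive fields**: signed bar stimulus averaged over a 20–160 ms
  pre-spike lag window, Gaussian fit with offset; diameter is the half-max
  width $2\sigma\sqrt{2\ln 2}$; fits from fewer than 100 spikes are
  flagged low-confidence.
* **Naka–Rushton fits**: Levenberg–Marquardt with Rmax initialised at the
  maximum response, c50 by interpolation at half-max, n = 2, bounded
  c50 ∈ (0, 1], n ∈ (0, 50]; shared-vs-separate condition comparison by
  extra-sum-of-squares F test; per-animal normalisation ("1 = maximum
  recorded for that animal") available before pooling.
* **Condition report**: five comparisons (flash amplitude paired t;
  preferred SF paired Wilcoxon on log2 SF; DS temporal-frequency
  preference paired t on per-unit DSI differences between the extreme
  frequencies over direction-sensitive units; movie autocorrelation paired
  t; signal correlation paired t over pairs), Bonferroni-adjusted.
  The DS prevalence histogram by temporal frequency is reported alongside,
  and is the more robust readout of the speed-preference shift at small
  unit counts.

## 5. Problem sizes and what passing tests show

The default cohort uses 40 units (a 17-unit movie sub-population), 100
flash trials, 40 grating presentations per spatial frequency and
orientation (20 per phase), 10 drifting-grating trials and 50 movie
repeats — trial counts at or near the modelled study's, with a smaller
unit count chosen so that hundred-cohort simulation studies complete on a
laptop. The `make_fixtures("study")` preset mirrors the sampling of the modelled
recordings (272 units, 161 responsive, 200 flash repeats); `"tiny"` runs the whole
battery in a few seconds for testing.

Passing the recovery tests shows that the pipeline detects the planted
effects under the generator's assumptions: Poisson spiking, exponential
temporal integration, circular DoG RFs, stationary condition effects, and
noise structure as described above. Real recordings violate several of
these (spike-sorting errors, non-Poisson variability, eye movements,
slow drift, correlated noise beyond a single shared drive), so the tests
certify the *analysis machinery*, not the biology. The null-control
cohorts certify type-I behaviour of the full battery under the same
assumptions.

## 6. Known limitations

* The nomogram λmax values and the absence of lens filtering are
  documented assumptions; the modelled study states neither.
* Absolute flux levels of the designed spectra reproduce stated ratios and
  contrasts, not calibrated irradiances; LED gamut is a box on linear
  drives with no output nonlinearity.
* Rod attenuation between backgrounds is best-effort (~6.7× at defaults)
  — with three primaries it cannot be pinned independently of melanopsin.
* The movie surrogate and the shared-drive correlation model are
  deliberately minimal; signal-correlation magnitudes are meaningful
  relative to each other, not as predictions of absolute pairwise
  correlations in vivo.
* The signal-correlation comparison treats within-animal pairs as
  independent observations, as the modelled analysis does; pairs sharing a
  unit are in fact correlated, which makes that paired t test mildly
  anticonservative.
* ERG modelling is a template amplitude model: no a-wave physiology,
  oscillatory potentials, or photoreceptor adaptation dynamics.
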