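---
title: "Methods: spectral QUS, texture derivatives and response classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral QUS, texture derivatives and response classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models and
estimators it implements, the assumptions behind them, the numerical
conventions chosen where the field leaves room, and what the synthetic
phantoms do and do not establish. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The scattering model and its analytic ground truth

Soft tissue at diagnostic frequencies behaves, to first order, like a
random collection of sub-resolution scatterers. `qustex` adopts the
simplest member of that family that still has an analytic backscatter
coefficient (BSC): a 2-D field of point scatterers with Poisson-distributed
count, uniform positions and i.i.d. Gamma amplitudes, observed by a
pulse-echo system with a Gaussian amplitude spectrum. Scatterer size enters
through the spherical-Gaussian form factor, so the model BSC is

$$\mathrm{BSC}(f) \;=\; C\,\Big(\tfrac{f}{f_c}\Big)^{4}
  \exp\!\big[-0.827\,(2\pi f/c)^2\,a_{\mathrm{eff}}^2\big],
  \qquad C = n\,\mathbb{E}[a^2],$$

with $n$ the number density (mm^-2^), $a$ the amplitude (echogenicity) and
$a_{\mathrm{eff}}$ the effective Gaussian radius. The constant 0.827 is the
standard Gaussian form-factor constant; it is defined once
(`GAUSS_FORM_FACTOR_CONSTANT`) and shared by the simulator's
`analytic_bsc()` and the estimator, so size recovery is a genuine
round-trip rather than a calibration.

Two deliberate simplifications keep the reference-phantom algebra exact:

* **No frequency-dependent tissue attenuation by default.** An attenuation
  field is stored on the reference phantom (dB/(cm·MHz)) as a hook for real
  data, but the simulator emits none, so normalization cancels the system
  response exactly and any residual error in ASD/AAC is attributable to
  speckle statistics alone.
* **The Rayleigh $f^4$ power factor is omitted from the synthesized echo
  filter.** It is common to sample and reference and cancels identically in
  the spectral ratio; `analytic_bsc()` keeps it on both sides of the
  normalization, so the estimators see a consistent convention while the
  synthesized spectra remain centred on the stated transducer band. This
  also makes the "point scatterers peak at $f_c$" property literally true.

Speed of sound defaults to 1540 m/s, the standard soft-tissue value.

## 2. Spectral estimation

Each sub-ROI window is tapered per scan line (Hann), periodograms are
averaged across lines *in linear power* before conversion to dB (averaging
in dB would introduce a $\psi$-function bias), and the window spectrum is
normalized by the reference phantom's average window spectrum — computed
with the *same* window length and taper, so spectral smearing largely
divides out:

$$S_{\mathrm{norm}}(f)\,[\mathrm{dBr}] = S_{\mathrm{sample}} -
  S_{\mathrm{reference}} + 10\log_{10}\mathrm{BSC}_{\mathrm{ref}}(f).$$

* **MBF / SS / SI** come from an ordinary least-squares line on dBr versus
  MHz over the fixed 4–9 MHz band; `MBF = SI + SS·f_c` holds exactly by
  construction and is property-tested to machine precision. The band is
  *fixed* rather than adaptive (−6 dB tracking) because the acquisition
  protocol states a 4–9 MHz bandwidth; it is configurable.
* **ASD / AAC** come from the linearization
  $\ln \mathrm{BSC} - 4\ln f = \ln C - 0.827 (2\pi/c)^2 a_{\mathrm{eff}}^2 f^2$:
  a linear regression against $f^2$ whose slope maps to
  $a_{\mathrm{eff}}$ and whose intercept maps to
  $\mathrm{AAC} = 10\log_{10} C$. ASD is reported as a *diameter*
  ($2a_{\mathrm{eff}}$, µm). AAC is a relative log-concentration: the
  intercept absorbs constant factors of the frequency normalization, so
  absolute AAC values carry an arbitrary offset, while *differences* are
  exact — a 10× concentration step is recovered as +10 dB, which is what
  the tests assert.
* **Degenerate windows** (all-zero RF → −∞ dB) are flagged, not thrown;
  they propagate as missing map pixels excluded from all statistics.
  A non-negative regression slope (nonphysical size, possible in noisy
  windows with small scatterers) clamps ASD at 1 µm and flags the
  estimate.

## 3. Sub-ROI geometry

Windows are $10\lambda \times 10\lambda$ ($\lambda = c/f_c$; 2.2 mm at
7 MHz), converted to samples via the axial pitch $c/(2f_s)$ (19.25 µm at
40 MHz) and to lines via the line spacing, then rounded to *odd* pixel
counts so each window has a centre pixel. The step per axis is
$\max(1, \mathrm{round}(0.06\,w))$ — the 94% overlap; with the default
geometry this gives steps of 7 samples × 1 line. A window is included when
its centre pixel lies inside the ROI mask (a "fully inside" rule is
available); the centre rule keeps edge behaviour symmetric and was chosen
because the protocol is silent on inclusion.

Parametric maps live on the *step lattice*: neighbouring map pixels are
(step × pitch) apart, recorded as `pixel_mm`. The literature's "15 by 15
pixels" window description implies a display decimation that is not
specified anywhere; this package defines map pixels on the sub-ROI step
lattice and documents the geometry in every exported sidecar instead of
guessing that decimation.

The per-tumour value of each QUS parameter is the unweighted mean over all
valid sub-ROI values pooled across frames — frames with more tumour
cross-section contribute proportionally more windows, which is what
"averaging over all sub-volumes" means here.

## 4. GLCM textures and texture derivatives

* **Quantization**: equal-width bins over the min–max of the map's valid
  pixels, 16 levels. This makes every texture feature invariant to strictly
  increasing affine rescalings of a map (property-tested), i.e. insensitive
  to the arbitrary dBr offsets of relative calibration. Quantization is per
  map per patient; cohort-global normalization is treated as a display
  convention only.
* **GLCM**: symmetric, distance 1, four angles accumulated into one matrix,
  normalized to sum 1. Pairs touching missing pixels are skipped, never
  imputed. The implementation is verified against a brute-force double-loop
  pair counter on hundreds of random grids, including missing values, for
  every (distance, angle, symmetry) combination.
* **Features**: contrast $\sum p_{ij}(i-j)^2$, energy $\sum p_{ij}^2$,
  correlation $\sum (i-\mu_i)(j-\mu_j)p_{ij}/(\sigma_i\sigma_j)$ and
  homogeneity $\sum p_{ij}/(1+|i-j|)$ (the inverse-difference-moment
  variant is exposed as an option). A zero-variance GLCM has correlation
  defined as **1** — the limit of a perfectly correlated constant field —
  with a degeneracy flag. Note that under min–max quantization a
  *homogeneous but speckled* map still spans all grey levels; the
  ENE→1/CON→0 limit is reached only for a literally constant map, and the
  tests assert exactly that.
* **Texture maps**: the same operator slides in a 15-map-pixel
  neighbourhood at step 1 (mirroring the 15-pixel sub-ROI construction;
  the neighbourhood size is not stated anywhere and 15 is the analogy
  default). Positions where fewer than half of the realizable pixel pairs
  are valid are missing. The sliding implementation uses per-level-pair
  summed-area tables and is tested for exact equality against independent
  whole-window GLCMs.
* **Second pass**: the texture-derivative features are *literally* the
  first-pass operator re-applied to the 20 first-pass texture maps
  (20 × 4 = 80), which resolves the source material's internally
  inconsistent description ("using the parametric maps as input" versus a
  texture-of-texture flowchart and the 80-feature count — only the
  texture-map-input reading yields 80). The composition identity is tested
  on a shared fixture. Per-frame texture values are averaged across frames
  with equal weight.

Feature names follow the grammar `BASE[-TEX1[-TEX2]]` with bases
MBF/SS/SI/ASD/AAC and textures CON/ENE/COR/HOM; assembly validates the
grammar and canonical order (5 + 20 + 80 = 105).

## 5. Classification protocol

* **Balanced subsets** (default 7): all minority-class patients plus an
  equal-size majority draw without replacement, one derived RNG stream per
  subset.
* **Forward selection**: greedy on LOOCV accuracy of the target classifier,
  at most 3 features, stopping when no addition *strictly* improves
  accuracy (so one-feature models arise naturally); ties break by
  canonical feature order, making selection deterministic.
* **Selection nesting**: by default selection is repeated inside every
  LOOCV fold (leakage-free; verified by an injected held-out-outlier test).
  A `"subset"` mode selects once per subset before cross-validation — the
  plausibly optimistic legacy protocol — and the mode is recorded in every
  result, because the source protocol's ordering is ambiguous.
* **Classifiers**: FLD with pooled within-class covariance
  (ridge-regularized on singularity); KNN with Euclidean metric on
  fold-standardized features, k = 5 by default (odd 3–9 sensible; the
  protocol never states k); SVM-RBF via an in-package deterministic SMO
  solver with fixed C = 1 and γ = 1/p on standardized features. A
  hyper-parameter grid inside nested selection inside LOOCV would multiply
  the fit count by orders of magnitude for no testable benefit at phantom
  scale, so the grid is a constructor argument rather than a default.
  No R SVM binding is available in the target environment, hence the
  in-package solver; it is exercised by the classic XOR separability test.
* **Positive class = non-responder** (the minority): the clinically
  critical error is missing a treatment failure, and the PPV/NPV asymmetry
  of the published panel matches that orientation.
* **Evaluation**: held-out scores are pooled into a trapezoid-rule ROC; the
  AUC is property-tested against the Mann–Whitney U identity
  $\mathrm{AUC} = U/(n_1 n_0)$ on every evaluation. The confusion panel
  thresholds at each classifier's native decision point (FLD: projected
  midpoint; KNN: 0.5; SVM: 0).
* **Aggregation across subsets**: the default report is the unweighted mean
  of each metric (per-subset panels retained); a pooled-score alternative
  is provided because the source never states which was used.
* **Univariate screen**: Shapiro–Wilk in each class gates (p ≥ 0.05 in
  both) between a classic unpaired t-test and a Mann–Whitney test,
  two-sided, α = 0.05; constant features are skipped and flagged. Type-I
  calibration is tested on null cohorts (flag rate inside the binomial 95%
  band).

## 6. What the synthetic cohort does and does not establish

`generate_cohort()` emulates: per-patient draws of scatterer size and
density from class distributions, an elliptical tumour embedded in a
background medium with different scatterer statistics (so ROI masking
matters), fully developed speckle, optional additive electronic noise, and
1-cm frame spacing. The default classes differ in effective radius
(20–30 µm vs 50–62 µm) — deliberately *disjoint*, representing the
best-case biology where microstructure determines response.

It does **not** emulate: focused-aperture diffraction, elevational beam
width, frequency-dependent attenuation, nonlinear propagation, tumour
heterogeneity, or any of the biological noise that makes the clinical
problem hard. Consequently a green "disjoint classes ⇒ KNN AUC ≥ 0.9"
test establishes that the *pipeline* preserves class information, not that
any clinical effect size is reproduced; and the published clinical panel
(sens 87% / spec 81% / acc 82% / AUC 0.86 for the best model) depends on
patient data this package cannot access and is *not* a package claim.
Within one simulated field a single effective radius applies everywhere
(the echo filter is field-wide), so background scatterers outside the ROI
share the tumour form factor; masking confines analysis to the interior,
where the truth is exact. Two-region phantoms are built in the tests by
summing the RF of two disjoint fields.

## 7. Numerical conventions, in one place

| Quantity | Convention | Default |
|---|---|---|
| Pulse spectrum | Gaussian; −6 dB power width = fractional bandwidth × f_c | 5/7 × 7 MHz → 4–9 MHz |
| Periodogram | Hann per line, linear-power averaging | — |
| Fit band | fixed, inclusive | 4–9 MHz |
| ASD clamp | non-negative slope → 1 µm, flagged | — |
| GLCM | 16 levels, d = 1, 4 angles, symmetric | configurable |
| COR degenerate | 1, flagged | — |
| Sliding window | 15 px, step 1, ≥ 50% valid pairs | configurable |
| Tie-breaks | canonical feature order, first maximum | — |
| Missing values | excluded, never imputed; CSV empty cell | — |
| Seeds | every generator takes one; derived streams stay < 2³¹ | — |

## 8. Known limitations

* The simulator is 2-D and unfocused; absolute BSC levels are relative, so
  AAC is only meaningful as a difference (by design, matching the relative
  dBr calibration of the whole chain).
* Per-window ASD estimates are noisy at small radii (the form-factor decay
  over 4–9 MHz is shallow), and the 1 µm clamp introduces a small downward
  bias there; volume means over thousands of overlapping windows keep the
  sweep-level median error within the tested 15%.
* The SMO solver is adequate for the ≤ 40-sample balanced subsets the
  protocol uses; it is not a general-purpose SVM.
* `run_cohort()` with nested selection over 105 candidates is O(folds ×
  candidates × inner-folds) classifier fits; at clinical scale (n = 34
  subsets) prefer KNN/FLD or `"subset"` selection mode.
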