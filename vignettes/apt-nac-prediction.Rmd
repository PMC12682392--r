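---
title: "Methods: APTw histogram analysis for predicting pCR after neoadjuvant chemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APTw histogram analysis for predicting pCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptnac)
```

## The problem

Fewer than a third of breast-cancer patients given neoadjuvant chemotherapy
(NAC) reach pathologic complete response (pCR), and predicting response
*before* treatment would spare non-responders months of toxic, ineffective
therapy. Amide proton transfer weighted (APTw) CEST MRI probes mobile
protein/peptide content via the exchange of amide protons (resonating
+3.5 ppm from water) with bulk water; proliferative, protein-rich tumors
show elevated APTw signal. `aptnac` implements the full analysis chain for
a pre-treatment prediction study: APTw/ADC/net-enhancement quantification,
whole-tumor first-order histogram features, and the statistical pipeline
that screens those features together with immunohistochemical (IHC) markers
and builds a combined logistic prediction model.

## Quantification model

**Z-spectrum and MTRasym.** Each voxel's Z-spectrum is the saturated water
signal at offsets $\Delta\omega \in \{\pm2.7, \pm3.5, \pm4.3\}$ ppm,
normalised by an unsaturated reference $S_0$ acquired far off-resonance
(−1540 ppm). The APTw metric is the magnetization-transfer-ratio asymmetry
at the amide frequency:

$$\mathrm{MTR_{asym}}(3.5\,\mathrm{ppm}) =
  \frac{S(-3.5) - S(+3.5)}{S_0} \times 100\% .$$

It may legitimately be negative (e.g. where NOE/MT contributions on the
negative side exceed the amide signal).

**B0 correction.** Static-field inhomogeneity shifts the apparent water
frequency, which corrupts the asymmetry; the shift is estimated per voxel
from the least-squares slope of (unwrapped) phase over three echo times
($\Delta f = \mathrm{slope}/2\pi$, converted to ppm by the 127.728 MHz
proton frequency at 3 T). The measured spectrum is then resampled at
(nominal offset + shift), separately on the negative and positive branches,
by 3-point Lagrange (quadratic) interpolation — exact for branch signals
polynomial of degree ≤ 2, and the natural choice with only three samples
per branch. Targets pushed beyond a branch's sampled range are marked `NA`
(never extrapolated), and `NA` propagates to ROI extraction rather than
being zeroed. Voxels with $|\delta| \ge 2$ ppm are flagged unreliable.

A numerical limitation worth stating plainly: quadratic interpolation of a
*peaked* line (water FWHM ≈ 2–3 ppm, amide FWHM ≈ 1.5–3 ppm) is not exact.
With the default phantom line shapes the residual MTRasym error after
correction grows from ≈0.1 pp at a 0.1 ppm shift to ≈0.6 pp at 0.5 ppm —
roughly 7–8× smaller than the uncorrected error at every shift we test,
but not zero. Consequently the package asserts exact recovery only on the
interpolation-exact class (polynomial branches), and asserts strict error
*reduction* (not elimination) for Lorentzian spectra with shifts up to
0.4 ppm.

**ADC and net enhancement.** ADC uses the mono-exponential model
$S(b) = S(0)e^{-b\,\mathrm{ADC}}$ fitted by least squares on $\log S$
versus $b$ (reported in $10^{-3}\,\mathrm{mm^2/s}$); non-positive signals
invalidate the voxel. Net enhancement is the voxel-wise early
post-contrast minus pre-contrast signal.

## Histogram features and reader agreement

ROI samples are the finite map values inside the tumor mask, minus an
exclusion mask for cystic/necrotic/hemorrhagic areas. The first-order
feature vector comprises mean, sample SD, RMS ($\sqrt{\sum x^2/n}$ — the
"root-mean-square deviation" of first-order radiomics; the alternative
reading, = SD, is exposed as the separate `sd` feature), mean absolute
deviation, percentiles $p_1 \dots p_{99}$ with the linear-interpolation
convention $h = (n-1)q + 1$ (the most widespread default; the identity
`iqr = p75 − p25` is exact), and bias-uncorrected skewness and excess
kurtosis. Two readers' feature vectors are averaged element-wise — the
per-patient value used by all downstream statistics — and agreement is
quantified by ICC(2,1), the two-way random-effects absolute-agreement
single-measure form (the stricter conventional choice for interchangeable
readers; > 0.8 is read as good agreement).

## Statistical chain

1. **Normality gate.** Shapiro–Wilk per group (Royston's approximation via
   `stats::shapiro.test`); both groups normal → independent-samples t-test
   (Welch form when the variance-ratio F-test rejects equality at 0.05),
   otherwise Mann–Whitney U with normal approximation and tie correction.
2. **Categorical tests.** 2×2 tables use Pearson's chi-square without
   correction when the minimum expected count is ≥ 5 and the Yates
   continuity correction when it is in [1, 5) — this rule, not an
   always-on correction, is what reproduces the reference statistics
   exactly; below 1 the caller is directed to Fisher's exact test.
   Multi-level factors with sparse cells use a Monte-Carlo Fisher test
   (Patefield margin-fixed sampling, `p = (1+k)/(B+1)`).
3. **Univariate screen.** Variables significant at 0.05 get a univariate
   maximum-likelihood logistic fit reporting β, SE, Wald z (and its
   square, since multivariate tables often print the Wald χ² instead),
   p, OR and the Wald CI $\exp(\beta \pm 1.96\,\mathrm{SE})$. Perfect
   separation and zero cells raise explicit errors rather than returning
   runaway estimates.
4. **Forward-stepwise multivariate fit** over the univariate-significant
   set: the candidate with the smallest likelihood-ratio p enters while
   p < 0.05 (classical default), included terms are re-tested and dropped
   at p > 0.10, ties break lexicographically, collinear duplicates add no
   parameters and are never admitted. If nothing enters, the
   intercept-only model is returned with a warning.
5. **ROC / DeLong.** AUC by the tie-aware Mann–Whitney identity
   (equivalent to trapezoidal integration), SE and CI from DeLong's
   placement-value components; the operating point maximises Youden's J
   with ties resolved to the smallest cutoff and orientation
   "score ≥ cutoff ⇒ pCR", auto-flipped when the raw AUC < 0.5. The
   combined model is scored by its linear predictor and compared against
   each selected predictor with the paired DeLong test. No
   multiple-testing adjustment is applied anywhere; the pipeline reports
   the total number of tests run so readers can judge that choice.

## Synthetic data

**Digital phantom.** Z-spectra are Lorentzian pool superpositions
$Z(\Delta\omega) = 1 - \sum_k A_k\,(w_k/2)^2 / ((w_k/2)^2 +
(\Delta\omega - \delta_k - \delta_{B0})^2)$ — a deliberate simplification
of exchange physics (no Bloch–McConnell integration) that gives a
closed-form oracle for every downstream value. The default scene is a
24×24×8 grid (2×2×4 mm voxels) with an ellipsoidal tumor (water pool
A = 0.80, FWHM 2.6 ppm; amide A = 0.035, FWHM 1.8 ppm; a small negative-
side NOE/MT pool), an optional necrotic core (no amide, high ADC), region
ADCs of 1.8/0.9/2.4 ×10⁻³ mm²/s (background/tumor/core), and a smooth
in-plane polynomial B0 surface. The default scene is shimmed
(zero B0 field) so the baseline round-trip is interpolation-free; B0
amplitudes up to 0.3–0.4 ppm are switched on explicitly where the benefit
of correction is measured. Noise, when enabled, is additive Gaussian on
the saturated signals only ($S_0$ noiseless), keeping the MTRasym noise
model analyzable. Multi-echo phases are generated wrapped, exactly
consistent with the B0 field. Reader variability is emulated by including
each voxel of the erosion–dilation boundary band independently with
probability ½ per reader. What the phantom does *not* emulate: realistic
anatomy, coil sensitivity, Rician magnitude noise, motion, fat signal —
so passing round-trips demonstrate correctness of the quantification
algebra, not robustness to those effects.

**Synthetic cohorts.** Two generative modes, because class-conditional
summary tables and an outcome-generative logistic model describe different
joint distributions: (a) *label-first* — draw pCR at prevalence 43/108,
then IHC categoricals from their class-conditional probabilities and
features from class-conditional normals with exchangeable within-block
correlation ρ = 0.8 (adjacent percentile features are strongly dependent
by construction); features reported as median(IQR) in the reference are
approximated as normal with mean = median and sd = IQR/1.349, a noted
approximation; (b) *logistic-outcome* — covariates drawn marginally, then
pCR ~ Bernoulli(expit(β₀ + βᵀx)), used for coefficient recovery with the
reference multivariate ORs (0.16, 7.25, 1.35) as truth. A third,
voxel-derived option computes each synthetic patient's MTRasym features
from an actual simulated voxel sample, so within-patient percentile
monotonicity and the IQR identity hold exactly. The label-first mode
treats covariates as conditionally independent given the class (beyond
the feature correlation), which overstates joint separability relative to
real cohorts — its pipeline outputs demonstrate mechanics, not expected
clinical AUCs.

## Problem sizes and numerical choices

Simulation-based checks use: coefficient recovery at n = 2000 over 400
replicates (the coverage estimator's SE then sits well inside the margin
between nominal 95% coverage and the 93% threshold being asserted);
combined-model dominance at n = 300 over 100 replicates (chosen for
adequate DeLong power under the strong-effect configuration); phantom
grids of 16³–24³·8 voxels. GLM fits use IRLS with tolerance 1e-10 and up
to 100 iterations; separation is declared when fitted probabilities
degenerate and a coefficient exceeds 10 on the log-odds scale. Monte-Carlo
Fisher tests require ≥ 10⁴ draws. All stochastic outputs are reproducible
from explicit integer seeds.

## Known limitations

- The Lorentzian phantom cannot validate exchange-rate- or
  B1-dependent behaviour; it validates the quantification algebra.
- Quadratic Z-spectrum interpolation leaves a shift-dependent residual on
  peaked lines (quantified above); denser offset sampling would be needed
  to do better, and is out of scope for the 6-offset schedule.
- ADC percentile features in the reference cohort include negative
  values, implying an undocumented standardization in the original
  feature code; this package computes physical ADC and simply mirrors the
  reference's group means/SDs in the generator rather than emulating that
  transformation.
- The stepwise-selected model is reported without cross-validation or
  calibration assessment, matching the analysis it implements; its AUC on
  conditionally-generated synthetic cohorts is optimistic by
  construction.

## A worked phantom example

```{r phantom-example, eval = FALSE}
scene <- phantom_scene(core_radius = 2.5, seed = 101,
                       b0_coef = c(0.05, 0.15, -0.10, 0.02, 0.05, -0.03))
bundle <- simulate_phantom_volumes(scene)
maps <- quantify_phantom(bundle)
readers <- simulate_reader_masks(bundle$mask, jitter_vox = 1, seed = 102)
roi_a <- extract_roi(maps$mtrasym, readers$reader_a, bundle$core_mask,
                     patient_id = "phantom", reader_id = "a")
roi_b <- extract_roi(maps$mtrasym, readers$reader_b, bundle$core_mask,
                     patient_id = "phantom", reader_id = "b")
average_readers(compute_features(roi_a), compute_features(roi_b))
```

The numbered scripts under `analysis/` run this chain end to end —
phantom simulation, quantification, feature extraction with ICC, cohort
generation, and the full statistical pipeline — writing their tables
under `results/`.
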