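---
title: "Voxel-wise normative modelling of individual brain abnormalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise normative modelling of individual brain abnormalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxnorm)
```

## The problem

Group-average analyses of quantitative MRI maps — fractional anisotropy
(FA) and mean diffusivity (MD) from diffusion imaging, cerebral blood
flow (CBF) from arterial spin labelling — cannot say whether *this*
concussed athlete's brain is abnormal, or where. voxnorm implements an
individual-level alternative: fit a *normative* reference distribution
at every voxel from an uninjured control cohort, score a single
subject's co-registered map against it, and threshold the resulting
probability map into a binary abnormality map that can be localized,
compared across timepoints, and summarized across a cohort.

Two complementary analyses are supported:

* **Cross-sectional (CS)** — the subject's post-injury values are scored
  against the distribution of control *baseline values*. Sensitive to
  anything that makes the subject differ from controls, including
  stable, pre-existing anatomical idiosyncrasies.
* **Longitudinal (LNG)** — the subject's *change* map (post-injury minus
  own baseline) is scored against the distribution of control *changes*
  (post-season minus baseline). Subject-stable offsets cancel, so only
  departures from normal longitudinal variability register.

Because FA and MD are strongly subject-stable traits while scan-to-scan
change is comparatively small, the two analyses interrogate nearly
orthogonal components of variance, and their thresholded maps can agree
poorly even when both are correct. The package's synthetic cohort
generator reproduces this mechanism by construction, which is what makes
it testable.

## The normative model

At each masked voxel, control values $X_1,\dots,X_N$ define a weighted
Gaussian kernel mixture

$$\hat f(x) = \sum_{n=1}^{N} w_n\, \phi_h(x - X_n),$$

fitted in two steps.

**Bandwidth.** $h$ is selected per voxel by least-squares leave-one-out
cross-validation: over candidates $h$,

$$CV(h) = \int \hat f^2(x)\,dx \;-\; \frac{2}{N}\sum_{n}
\hat f_{-n}(X_n),$$

where the squared integral has the closed form
$\frac{1}{N^2}\sum_{i,j}\phi_{h\sqrt2}(X_i - X_j)$ (no numerical
quadrature), and the leave-one-out density renormalizes the remaining
$N-1$ kernels. Candidates are 50 log-spaced values between 0.01 and 10
times the voxel's sample SD; exact ties go to the smallest candidate
(fixed for determinism; the smaller, detail-preserving choice). The
count and log spacing are package choices — the bounds admit both very
spiky and nearly-parametric fits, and log spacing resolves the small-$h$
end where $CV(h)$ varies fastest.

**Robust weights.** Kernel weights are fitted by an iteratively
reweighted scheme in the kernel-induced geometry: each control point's
distance to the current mixture,
$d_n^2 = k(0) - 2\,(Kw)_n + w^\top K w$, feeds a Hampel redescending
influence function, and $w_n \propto \psi(d_n)/d_n$, renormalized to
sum to 1, until the largest weight change is below $10^{-6}$ (at most
100 iterations; non-convergence keeps the last iterate with a warning).
CV bandwidth selection uses uniform (pre-robust) weights; the two steps
are not coupled.

The Hampel breakpoints $(a, b, c)$ are taken from the initial
(uniform-weight) distance distribution: $a$ its 90th percentile, $b$ its
99th, and $c = 1.5\times$ its maximum. This was a genuinely open design
choice, and the package resolves it in favour of *null calibration*.
With $N \approx 44$ controls and cross-validated bandwidths, the
kernel-space distance saturates in the tails: the most extreme clean
control and a gross artifact are not reliably separable by any initial
statistic we examined (distances or mixture densities, at the model
bandwidth or at wider scout bandwidths). Aggressive breakpoints that
zero the most distant points therefore amputate genuine support from the
reference mixture and inflate the null tail probabilities several-fold —
fatal for a pipeline whose downstream contract is FDR control. The
defaults keep typical controls at full weight, downweight the top decile
gently and redescend only well beyond the observed range, which
preserves calibration while still guaranteeing that the most outlying
point always receives the smallest weight and that calibration under
contamination is strictly better than with uniform weights. Cohorts with
suspected heavy contamination can pass stricter
`breakpoint_quantiles`/`c_scale` to `normative_kde()`.

**Scoring.** For a new value $x$ the one-tailed cumulative probability
is $P = \sum_n w_n \Phi\!\big((x - X_n)/h\big)$, converted to the
two-tailed extremeness probability $P' = 2\min(P, 1-P)$. Voxels with
degenerate control data (zero variance) are flagged invalid, propagate
`NA`, and are excluded from all counts — never silently filled.

## From probabilities to abnormality maps

Each subject's $P'$ map is thresholded by the Benjamini–Hochberg
step-up procedure at FDR $q = 0.05$, one procedure per
(subject, modality, analysis, timepoint) map — matching the per-map
framing of the analysis; detections are not pooled across subjects.
Plain BH (independence-valid) is used; the mild positive dependence
induced by spatially smooth data is absorbed by the tolerance the
simulation checks allow. Surviving voxels then pass a minimum
cluster-extent filter (3 voxels, 26-connectivity by default;
connectivity is configurable because adjacency conventions differ
between tools) which removes singleton detections. Abnormal voxels are
classified *positive* when $P \ge 0.975$ (high relative to controls)
and *negative* when $P \le 0.025$; an abnormal voxel strictly between
the tails cannot have survived thresholding and raises a consistency
error rather than being silently tolerated.

Downstream summaries: Jaccard overlap $J = |X \cap Y| / |X \cup Y|$
between thresholded maps (CS vs LNG per timepoint, SYM vs RTP per
analysis), with an empty-vs-empty pair recorded as *missing* rather
than 0 — "no abnormality anywhere" is agreement about absence, not
spatial disagreement, and conflating the two would bias pooled medians
downward; paired Wilcoxon signed-rank contrasts of overlap values
(exact for small samples, zero differences dropped); spatial extent and
positive-fraction tables (median and quartiles across subjects);
threshold-robustness sweeps re-thresholding the retained probability
maps under FDR levels 0.005–0.10, uncorrected $P'$ cutoffs 0.005–0.05,
and per-map percentile cutoffs 99.9th–95th (seven evenly spaced points
per scheme; the cluster filter is re-applied in every scheme for
consistency); and atlas-based localization — each map is parcellated
into connected clusters, each cluster is assigned every atlas region it
overlaps, clusters touching only background fall back to the region
with the nearest center of mass (ties to the lowest region id), and
per-region counts tally *maps*, not clusters. CS/LNG concordance of
regional frequencies uses Spearman correlation with a percentile
bootstrap CI over regions (the correlated units), 10,000 resamples by
default.

## The synthetic cohort generator

No imaging data ship with the package, so every stage is exercised on
seeded synthetic cohorts with known ground truth. A subject's value at
voxel $v$ in session $s$ is

$$X_{s}(v) = \mu(v)\,\big(1 + \delta_s(v) + \beta + \varepsilon_{s}(v)\big),$$

where $\mu(v)$ is the modality's mean field, $\delta_s$ a
subject-stable offset field (redrawn per subject, constant across that
subject's sessions), $\beta$ a deterministic longitudinal drift applied
to post-baseline sessions, and $\varepsilon$ fresh session noise. The
total baseline coefficient of variation $c(v)$ splits between offset
and session noise as $\sigma_{\text{off}}^2 + \sigma_{\text{sess}}^2 =
c^2$ with session share $\lambda$:

| modality | median CoV $c$ | drift $\beta$ | change CoV | $\lambda$ |
|---|---|---|---|---|
| FA  | 0.0586 | −0.12% | 7.47 | 0.108 |
| MD  | 0.0423 | +1.41% | 2.26 | 0.533 |
| CBF | 0.443  | −1.87% | 2.99 | 0.089 |

$\lambda$ is derived, not free: the change map has SD
$\sqrt2\,\sigma_{\text{sess}}$ and mean $|\beta|\mu$, so matching the
observed change CoV fixes
$\lambda = |\beta|\cdot \text{CoV}_{\text{chg}} / (\sqrt2\, c)$. This
single constraint makes the generator reproduce simultaneously the
baseline CoV, the drift, and the much larger relative variability of
longitudinal change that motivates treating CS and LNG as distinct
analyses. The per-voxel CoV field is itself sampled from a log-normal
law matched to the modality's median and quartiles.

Further emulated features: a configurable fraction of voxels (default
10%, within the 5–21% non-normality range observed in control cohorts)
receive shifted log-normal noise matched in mean and SD (the skewed law
is a package choice; only the *fraction* of non-Gaussian voxels is
empirically constrained); noise fields are spatially smoothed by a
Gaussian kernel, stated as FWHM in voxels (default 1.5 — FWHM being the
convention in which smoothing kernels are quoted for real maps), with
circular-convolution normalization so the marginal variance is exact;
values are truncated to the modality's valid range; and one seed governs
the cohort, with per-subject sub-streams drawn so that enlarging a
group never perturbs earlier subjects of that group.

**Injections.** Ground-truth abnormalities are spherical (or
exact-$n$-voxel) clusters shifted by a chosen number of control SDs.
Two modes mirror the two analyses: *value* mode adds a stable shift —
scaled by the control baseline SD — to the subject's baseline **and**
post-injury sessions, so it registers cross-sectionally but cancels in
change maps (this reading is forced by the requirement that value-type
effects be invisible to LNG; a shift applied only post-injury would leak
into the change map); *change* mode shifts only the listed post-injury
sessions, scaled by the control change SD. Injection magnitudes are free
experimental parameters — no effect-size scale for real abnormalities is
assumed.

What the generator does **not** emulate: biophysical structure (tensor
geometry, perfusion kinetics), registration error, scanner drift, site
effects, realistic anatomical covariance between voxels, or demographic
modifiers. Passing tests demonstrate the statistical machinery is
correct under the stated generative law; they do not certify behaviour
on real data with those additional features.

## Numerical choices and degenerate inputs

* Masked voxels are stored in ascending raster (column-major linear
  index) order everywhere; all per-voxel arrays align to it.
* Tissue masks use strict inequalities (mean FA > 0.25 for white
  matter, mean CBF > 20 mL/100 g/min for grey matter); MD analyses
  reuse the FA-derived mask, which the caller supplies explicitly.
* Non-finite values inside a mask are a hard load-time error (the
  pipeline starts at cleaned, co-registered maps).
* CoV uses the sample ($N-1$) SD convention; percent change reduces to
  the per-voxel *median* over subjects before summarizing over voxels;
  zero-mean and zero-baseline voxels are excluded with counts reported.
* Mixture CDF values are clamped to $[0,1]$ against summation
  round-off; probability maps from invalid voxels stay `NA` end to end.
* Ranks in representative-slice selection average over ties, final
  ties go to the lowest slice index; an all-empty quartet returns `NA`.
* Wilcoxon contrasts with fewer than 2 complete pairs, correlations on
  constant vectors, and concordance on constant frequency vectors all
  return explicit not-computable signals rather than numbers.

## Problem sizes used by the test-suite and acceptance script

The packaged simulations run at desk scale, chosen to exercise the full
pipeline while completing comfortably on one CPU: FDR-calibration
cohorts use 44 controls and 20 pseudo-concussed subjects on a
$20^3$ mask (CoV 0.06, Gaussian voxels) with 27 known 15-voxel 6-SD
clusters (~5% of the mask), averaged over 20 seeded replicates;
the CS/LNG mechanism cohort uses 12 concussed subjects with six
value-mode and six change-mode clusters at disjoint loci; generator
calibration checks use 44 controls on 5000-voxel masks. Measured under
these conditions: the empirical false-discovery proportion stays within
the nominal level plus the Monte-Carlo/dependence allowance, the median
CS-vs-LNG Jaccard is far below 0.10, and the recovered CoV medians land
within a few percent of their calibration targets.

## Known limitations

* Gaussian-kernel CDFs have lighter-than-true tails beyond the control
  range; extreme quantiles are mildly anti-conservative, which is
  visible as a small excess in the empirical false-discovery proportion
  relative to the nominal BH level. The effect shrinks with $N$.
* The robust weighting is deliberately gentle (see above); it is a
  calibration safeguard, not a contamination screen.
* LSCV bandwidths are variable at $N \approx 44$; per-voxel bandwidths
  should be treated as noisy.
* The percentile sweep applies the cluster filter, one of two defensible
  readings of the thresholding comparison.
* Real atlases are accepted as labelled NIfTI volumes but not bundled;
  the toy Voronoi atlas is a fixture, not an anatomical model.
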