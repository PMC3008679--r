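---
title: "Seed-based Granger causality mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based Granger causality mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restgca)
```

## The analysis problem

`restgca` maps *directed* (effective) connectivity between a seed region and
every voxel of the brain in resting-state BOLD fMRI. Undirected functional
connectivity asks whether two regions fluctuate together; the directed
question asked here is whether one region's past improves the prediction of
another region's present — Granger causality. The motivating application is a
clinical two-group comparison: patients versus matched controls, with an
amygdala seed, followed by correlation of the connectivity estimates with
symptom-severity scores.

## The influence measure

For a seed series $x_t$ and a voxel series $y_t$, both of length $T$, the
package fits two nested autoregressions by ordinary least squares on the same
$T - p$ aligned samples:

* restricted: $y_t = c_0 + \sum_{k=1}^{p} a_k\, y_{t-k} + \varepsilon_t$
* full: $y_t = c_0' + \sum_{k=1}^{p} a_k'\, y_{t-k} + \sum_{k=1}^{p} b_k\, x_{t-k} + \varepsilon'_t$

and reports Geweke's influence measure
$$F_{x \to y} \;=\; \ln\!\frac{\hat\sigma^2_{\text{restricted}}}{\hat\sigma^2_{\text{full}}},$$
with residual variances $\hat\sigma^2 = \mathrm{RSS}/(T-p)$ in both models so
the ratio is well defined. $F_{y \to x}$ swaps the roles of the two series.
Because the models are nested and fitted on identical samples, $F \ge 0$ up
to floating-point noise, and $F$ is invariant to positive rescaling of either
series. Both properties are enforced by tests against a brute-force
normal-equations oracle.

Model order defaults to $p = 1$ and `select_order()` implements the Schwarz
criterion on the bivariate full model, evaluated on a common sample across
candidate orders, to justify that choice on data of this kind.

Design choices worth stating explicitly:

* an intercept is always included, although the series arrive detrended and
  essentially mean-free, so its effect is negligible;
* the analysis is strictly bivariate (seed versus one voxel at a time); no
  conditional or multivariate Granger variant is attempted;
* degenerate voxels (constant series, or collinear with the seed) are set to
  a missing value, excluded from group statistics and counted in QC, rather
  than raising an error mid-map.

## Permutation inference

Significance of a single influence value is assessed by reshuffling the
*target* series with uniform random permutations of the time indices — the
source is untouched — and recomputing $F$ each time (500 draws by default).
The p-value uses the add-one estimator $p = (1 + \#\{F_{\text{null}} \ge
F_{\text{obs}}\})/(n_{\text{perm}}+1)$, which never returns zero. The full
reshuffle destroys *all* temporal structure of the target, not only its
dependence on the source. On strongly autocorrelated (e.g. band-pass
filtered) series this null is therefore anticonservative: the observed $F$
of two independent filtered series sits systematically above the reshuffled
null. This is a known trade-off of the plain permutation scheme (block or
phase-randomized permutations would preserve autocorrelation, and are
deliberately not used here); its practical consequence for group-level masks
is discussed under Limitations.

## Preprocessing

`preprocess_voxelwise()` applies, in order: initial-volume discarding
(default 5, so a 205-volume acquisition keeps 200), optional isotropic
Gaussian smoothing (FWHM 8 mm when enabled; off by default for synthetic
runs), nuisance regression (intercept + 6 rigid-body motion parameters +
white-matter mean + CSF mean), zero-phase frequency-domain band-pass
filtering (0.01–0.08 Hz with a raised-cosine taper of half-width 0.002 Hz),
and linear detrending. Tissue means are extracted from the unsmoothed
post-discard data. The band edges must lie below the Nyquist frequency
$1/(2\,\mathrm{TR})$.

Motion quality control summarizes a trace as the mean frame-to-frame
Euclidean displacement, separately for the three translations (mm) and three
rotation angles (degrees),
$$\frac{1}{L-1}\sum_{i=2}^{L}\sqrt{\Delta x_i^2+\Delta y_i^2+\Delta z_i^2},$$
and excludes a subject when any single parameter strictly exceeds 1.5 mm or
1.5°; a value exactly at the limit is retained. Because motion files
circulate with rotations in both radians and degrees, `read_motion()`
refuses to guess: the unit must be declared (argument or JSON sidecar), and
radians are converted on read. Motion rows correspond to pre-discard
volumes; the first `n_discard` rows are dropped in lockstep with the volumes.

## Group-level mapping

Per subject and seed, `influence_maps()` yields one from-seed and one
to-seed map. Group inference proceeds as:

1. per-group significance versus the permutation null
   (`significance_mask_for_group()`): by default a per-voxel one-sample t of
   the subjects' influence values against the voxel's pooled permutation
   null mean, one-sided, FDR-corrected (Benjamini–Hochberg step-up) at
   $q=0.05$, then filtered to connected components of at least 10 voxels
   (26-neighborhood by default; 6 and 18 are available). A Fisher
   combination of per-subject permutation p-values is available behind a
   flag. Neither rule claims to reproduce any particular in-house original;
   both are stated here so results are interpretable.
2. the analysis mask is the union of the two groups' masks;
3. the group contrast is a voxel-wise pooled-variance two-tailed two-sample
   t within that mask ($\mathrm{df}=n_1+n_2-2$; Welch available behind a
   flag), FDR-corrected over in-mask voxels, with signed direction
   (increased = patients above controls);
4. surviving signed clusters are extracted and each subject's mean influence
   over a cluster is correlated (Pearson, two-tailed) with clinical scores,
   per group, flagged at p < 0.05 *uncorrected* — deliberately lenient, with
   the number of correlations tested annotated in the output table.

The BH step-up is implemented from its definition (largest rank $i$ with
$p_{(i)} \le i\,q/m$) and is tested against both a brute-force
every-cutoff oracle and `stats::p.adjust`.

## The synthetic cohort generator

No public fMRI data accompany the analysis this package operationalizes, so
validation rests on synthetic cohorts with known ground truth. The generator
is deliberately minimal and fully documented:

* **Dynamics.** Regional signals follow a stationary lag-1 vector
  autoregression with Gaussian innovations — the least structured process
  consistent with an order-1 analysis model. Stationarity (spectral radius
  of the transition matrix below 1) is enforced.
* **Timescale.** The default self-coefficient is 0.7 per region. At TR = 2 s
  this matches typical resting-state BOLD lag-1 autocorrelation and, more
  importantly, concentrates signal variance inside the 0.01–0.08 Hz
  analysis band (the in-band fraction is maximal near 0.7), so band-pass
  filtering retains the coupled structure as it does for real BOLD. White or
  fast dynamics would place most variance above the band and the filter
  would delete the very signal under study.
* **Geometry.** Default grid 24 × 24 × 12 voxels with axis-aligned blocks
  for each region plus white-matter and CSF compartments; full
  acquisition-scale grids remain configurable. Every in-block voxel carries
  its node's series plus i.i.d. observation noise (sd 0.3 against unit
  innovations); background voxels are pure noise; nuisance compartments
  carry independent AR(1) series.
* **Cohort structure.** 22 subjects in group A ("SAD") and 21 in group B
  ("HC") by default, 205 volumes at TR = 2 s. Group B adds a configurable
  delta to selected coupling entries. Each subject's realized coupling
  perturbs every structural entry with Gaussian jitter (sd 0.06) —
  between-subject heterogeneity without which coupling–score correlations
  would be undefined. Draws that would break stationarity are redrawn.
* **Clinical scores.** The avoidance-like score is a linear map of the
  subject's realized target coupling plus Gaussian noise; the default slope
  (−60) and noise (4.8 points) give a population coupling–score correlation
  of −0.6 at jitter 0.06. Remaining scores are drawn from group-typical
  normal distributions so the behavioral table is populated.
* **Reproducibility.** All randomness flows from a single master seed;
  per-subject seeds for coupling, innovations, observation noise, motion
  and scores are drawn up front, so any subject regenerates bit-identically
  from the master seed alone.

What the generator does **not** emulate: hemodynamic convolution, spatial
autocorrelation, scanner drift/spike artifacts, anatomical geometry.
Passing tests on these phantoms therefore validate the *estimation and
inference machinery*, not robustness to physiological confounds.

## The validation study

`validation_replicate()` fixes the conditions used by the test suite and the
acceptance script: three regions (seed, a `target` receiving seed influence,
an `itg` region sending influence to the seed), 22 + 21 subjects, the
24 × 24 × 12 grid, 205 volumes. Two relations are planted:

* **Group difference.** Seed→target coupling 0.30 in patients versus 0.08 in
  controls. The near-ablation emulates a directed connection reported as
  present in one group and essentially absent in the other — the kind of
  robust, FDR-surviving difference the group contrast exists to find. Pilot
  simulation at these settings places the per-voxel population two-sample t
  of the influence estimates around 6; smaller standardized differences
  (population t near 4) are exercised separately at the map level in the
  unit tests, where the multiplicity burden is controlled.
* **Clinical relation.** itg→seed coupling 0.35 in both groups, with the
  avoidance score tied negatively to it (population r = −0.6).

The pooled permutation null mean entering the group masks is estimated from
a subsample of subjects (4 subjects × 25 shared-permutation draws): the null
mean is a property of the reshuffled-target distribution and is essentially
common across subjects, so a subsample estimates it accurately at a fraction
of the cost; `run_pipeline()` uses all subjects by default. Null-cohort
false-discovery behavior is measured by random relabelings of cohorts
generated with delta = 0. Problem sizes throughout (20 replicate cohorts, 50
null contrasts, 1000 permutation-calibration pairs at 199 draws) were chosen
as the smallest giving stable Monte-Carlo estimates of the rates under
study.

## Numerical choices

* Band-pass: FFT gain mask with raised-cosine transitions centered on the
  band edges (half-width 0.002 Hz); exactly zero phase; DC always removed.
* Rank-deficient designs: minimum-norm least squares via SVD, with a
  warning; collinear nuisance columns are dropped.
* Constant voxels: passed through as zeros and flagged, never errors.
* Cluster connectivity: 26-neighborhood default, configurable.
* p-values: permutation p uses the add-one estimator; parametric p-values
  come from the t and chi-square distributions.
* Disk format: float32 NIfTI-1 with TR in the header; all computation in
  double precision.

## Known limitations

* **Filtering versus the permutation null.** Band-pass filtering makes every
  series strongly autocorrelated, while the full-reshuffle null destroys
  autocorrelation entirely. The observed influence of two independent
  filtered series therefore exceeds the reshuffled null on average, and
  one-sample group tests against that null flag large portions of the brain
  at conventional FDR levels. The union analysis mask can consequently be
  broad; the group *contrast* (patients versus controls) is unaffected,
  because both groups share the inflation.
* **Zero-phase filtering and directionality.** A zero-phase filter mixes
  future samples into the past, which can blur temporal-precedence evidence.
  Direction-recovery tests on unfiltered series bound what the estimator can
  do; the filtered pipeline trades some of that resolution away.
* **Attenuation of coupling–score correlations.** The influence estimate at
  T = 200 carries irreducible estimation noise that is shared across a
  cluster's voxels (it stems from the realized innovations of the common
  regional signal, so cluster averaging does not remove it). A population
  coupling–score correlation of −0.6 is therefore recovered at noticeably
  smaller magnitude, and with n = 22 the power of a two-tailed
  significance test at the attenuated value is modest. Even with *perfect*
  recovery, the power to reject at $\alpha = 0.05$ with true $\rho = 0.6$
  and $n = 22$ is about 0.86 — sign recovery is reliable, per-replicate
  significance is not. The acceptance script reports the recovery,
  sign-recovery and mean-r values so this attenuation is visible rather
  than hidden.
* **Phantom realism.** Block-structured regions and white observation noise
  are idealizations; anatomical labeling of clusters is out of scope.
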