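---
title: "Twin-based heritability mapping of task functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-based heritability mapping of task functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinconn)
```

twinconn estimates genetic influences on brain phenotypes in the classical
twin design. This vignette is the package's account of the statistical
machinery: the variance-decomposition model and its estimators, the
permutation schemes used for family-wise error control, the task-weighted
connectivity measure, the synthetic cohort generator that stands in for
restricted twin data, and the numerical and design choices that were
genuinely open.

## The ACE model and its twin-design estimators

A phenotype measured on twin pairs is decomposed into additive-genetic
variance $A$, shared-environment variance $C$ and unique-environment (plus
measurement error) variance $E$. Monozygotic (MZ) co-twins share their
additive-genetic score entirely; dizygotic (DZ) co-twins share half of it on
average; both kinds of pair share $C$ fully. The implied twin-pair
correlations are $r_{MZ} = A + C$ and $r_{DZ} = A/2 + C$ (for unit total
variance), and heritability is $h^2 = A/(A + C + E)$.

Two estimators are provided.

**Falconer's contrast** (`falconer_ace()`) works from the pair correlations
directly: $\hat A = 2(r_{MZ} - r_{DZ})$, $\hat C = 2 r_{DZ} - r_{MZ}$,
$\hat E = 1 - r_{MZ}$. It is the natural tool when only summary
correlations are available (for example, printed behavioral results).
Negative $\hat A$ or $\hat C$ are truncated at zero; the raw values are
reported alongside, and $h^2$ is computed from the constrained set without
renormalizing, so a negative raw component cannot inflate the others.

**Squared-pair-differences regression** (`lrsd_ace()`) is the non-iterative
estimator used for element-wise maps, where thousands of phenotype elements
(voxels, regions, connectivity edges) must be fit cheaply. For each pair
$p$ the squared within-pair difference $d_p = (y_{p1} - y_{p2})^2$ has
expectation $2\sigma^2_E$ in MZ pairs and $2\sigma^2_E + \sigma^2_A$ in DZ
pairs, so regressing $d$ on a 0/1 dizygosity indicator identifies
$\hat\sigma^2_E$ (intercept / 2) and $\hat\sigma^2_A$ (slope) in closed
form; $\hat\sigma^2_C$ is recovered by subtracting both from the total
variance pooled across all subjects. Pooling all subjects (rather than pair
means) keeps the total-variance estimate unbiased under exchangeability and
on the same moment scale as the squared differences. Constraints are
applied by truncation, $A$ first, then $C$, with $A$ and $E$ additionally
capped at the total variance so every component lies in
$[0, \hat\sigma^2_P]$; the truncation order is pinned by tests. Optional
covariates (age, sex) are removed by ordinary least squares before fitting,
since squared differences are not invariant to mean structure that differs
across pairs.

Both routes agree asymptotically; the test suite checks
$|\hat h^2_{\text{Falconer}} - \hat h^2_{\text{LR-SD}}| < 0.02$ at 5000 +
5000 pairs.

### Testing $A > 0$ at a boundary

The hypothesis $A = 0$ sits on the boundary of the parameter space, so the
parametric reference distribution for the (squared) one-sided slope
statistic is the mixture $\tfrac12\delta_0 + \tfrac12\chi^2_1$. The package
reports `stat_A` (the regression $t$ truncated at zero) and a p-value of
$\tfrac12 P(\chi^2_1 \ge t^2)$ for positive slopes, with the conventions
$p = 0.5$ at a slope of exactly zero and $p = 1$ for negative slopes. Under
this convention the null p-value distribution is *not* uniform on $(0,1]$ —
it is uniform on $(0, 0.5)$ with the remaining mass at or near 1 — but it
is valid (conservative) at every conventional level, which is what
inference needs; the calibration test checks exactly that, plus uniformity
of $2p$ conditional on a positive slope.

## Permutation inference

**Exchangeability scheme.** The identifying contrast for $A$ is the MZ/DZ
difference in within-pair similarity, so the null is generated by shuffling
zygosity labels across intact pairs (`permute_zygosity()`): pair
memberships, and hence within-pair dependence, are preserved while the
differential genetic sharing is destroyed. MZ and DZ pair counts are
preserved by construction. Alternative schemes (within-pair member flips)
do not break the A-contrast and are not offered.

**Element-wise FWE** (`elementwise_fwe()`) uses the max-statistic method:
each element's observed statistic is referred to the permutation
distribution of the maximum statistic over all elements, with the
$(1+b)/(m+1)$ p-value convention so p-values are never zero and the test is
exact at achievable levels.

**Cluster-extent FWE** (`cluster_fwe()`) thresholds the parametric
boundary-mixture p-values at a cluster-forming level (default
$p < 0.05$), groups supra-threshold elements into connected components
under a user-supplied adjacency, and refers each observed cluster's extent
(element count) to the permutation null of the maximum extent. Cluster mass
is deliberately not offered; extent is the convention the rest of the
package's component machinery shares.

**Power** (`twin_power_curve()`) simulates the same LR-SD test used by the
mapping pipeline (not a structural-equation likelihood ratio) over a grid
of true $A$ values with $C = 0$, and interpolates the smallest $A$ reaching
80% power. Using the pipeline's own test makes the power statement
internally consistent: it describes what *this* analysis chain can detect.
Generic twin-power calculators built on maximum-likelihood model
comparisons can report different crossings for the same design, so the
curve produced here should be read as the operating characteristic of the
implemented test. At 56 MZ + 67 DZ pairs the implemented test's
80%-power crossing computed by `scripts/acceptance.R` lands near
$A \approx 0.65$ (2000 replicates per grid point; seed-to-seed spread
$\approx 0.003$).

## Task-weighted functional connectivity

First-level connectivity is a *weighted* Pearson correlation between node
time series, with per-volume weights equal to the condition's boxcar
convolved with the canonical double-gamma hemodynamic response function
(peak 6 s, undershoot 16 s, unit dispersions, undershoot ratio 1/6,
support $[0, 32]$ s, positive lobe normalized to unit sum). Weights are
rectified at zero because a weighted correlation requires nonnegative
weights; the negative undershoot lobe would otherwise produce negative
weights for volumes just after a trial. Correlations are Fisher-z
transformed with $|r|$ clipped at $1 - 10^{-7}$ so collinear nodes produce
a large finite value rather than infinity.

The surrounding steps are deliberately standard:

* confound regression (`regress_confounds()`): OLS projection onto an
  intercept, the task-mean regressors, the 6 motion parameters and their
  squares, and one-hot scrub regressors for flagged volumes; collinear
  columns are dropped by QR pivoting with a warning.
* band-pass filtering (`bandpass_filter()`): a zero-phase ideal FFT mask on
  $[0.008, 0.09]$ Hz. The ideal mask was chosen over an IIR design because
  it is exactly zero-phase, idempotent (filtering twice changes nothing,
  which the tests pin), and deterministic across platforms.
* spatial smoothing is never applied — local correlations would otherwise
  be inflated spuriously — so no smoothing entry point exists.

The contrast of interest (shock trials versus unreinforced trials) merges
the aversive-cue and shock events into one weight series for the first
condition, because the shock follows the cue with no delay and the two
cannot be separated hemodynamically.

Network-level summaries divide summed edge values between networks $X$ and
$Y$ by $|X| + |Y|$ (and within-network sums by $|X|$), matching the
convention used for group-level figures in task-FC studies.

## The heritable-component (NBS) test

Edge-wise heritability of the per-subject contrast matrices
(`edgewise_h2()`) is computed by applying the LR-SD estimator to every
upper-triangle edge, vectorized so that a permutation replicate costs one
pass of column means. The component test (`nbs_h2_test()`) binarizes the
$h^2$ matrix at a threshold $\tau$ (strictly greater; ties are dropped),
finds the connected component with the most edges (ties broken by node
count, then smallest minimum node id, so results are deterministic), and
refers its edge count to the permutation distribution of the maximum
component size under zygosity shuffling.

The choice of $\tau$ matters more than any other parameter. The null
spread of an edgewise $h^2$ estimate scales like
$\sqrt{16/n_{\text{pairs-per-group}}}$, and once the per-edge
supra-threshold probability exceeds roughly $1/n_{\text{nodes}}$, the
background graph percolates into a giant component that swamps any planted
structure — thresholds that are too low produce "biologically unrealistic"
giant components, and thresholds that are too high shatter real components.
`threshold_sweep()` therefore re-thresholds one shared permutation stream
over an ascending grid (default 0.25–0.32 in steps of 0.01 plus 0.328, the
grid used for the 400-node cohort analysis this package re-implements), so
the sweep is internally consistent and costs a single permutation pass. At
the simulation scale used in the acceptance tests (150 + 150 pairs, 50
nodes, planted 20-edge component with $A = 0.6$) the null sd is
$\approx 0.33$, so the detection test thresholds at $\tau = 0.5$: between
the null bulk and the planted effect, keeping the expected background
supra-threshold count near the sub-percolation regime while retaining
nearly all planted edges.

## Quality control

* **Framewise displacement**: backward differences of the six rigid-body
  parameters, rotations converted to arc length on a 50 mm sphere (the
  standard convention; the screening rule itself only names FD). A subject
  is flagged when strictly more than 50% of volumes have FD strictly above
  0.5 mm — both inequalities strict, pinned by tests.
* **Amplitude outliers**: the scaled-MAD rule
  $|x - \text{median}| > k \cdot 1.4826 \cdot \text{MAD}$ with $k = 3$ by
  default. The phrase "3 times the median standard deviation" in the
  source description is internally inconsistent; the cited robust-outlier
  method is the scaled-MAD rule, which is what is implemented, with $k$
  configurable.
* **Cascade order**: motion, then outliers (each with the co-twin), then
  missing data, with subjects counted at the first stage that triggers;
  finally any widowed twin is removed so only intact pairs remain. Whether
  motion exclusions also remove the co-twin is not specified by the source
  description; the default is yes (it keeps the intact-pair invariant
  stage-local), controlled by `motion_removes_cotwin`.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()`, `simulate_ace_phenotypes()`, `simulate_task_events()`,
`simulate_fc_phenotypes()` and `simulate_roi_timeseries()` generate,
respectively: pair/zygosity structure with same-sex pairs aged 20–60;
phenotypes with exact ACE structure (the DZ genetic score is built as
$\sqrt{0.5}\,a_{\text{pair}} + \sqrt{0.5}\,a_{\text{indiv}}$, which gives
correlation 0.5 exactly and $O(n)$ generation, rather than drawing from a
joint covariance); an aversive-conditioning schedule (16 six-second cues, 8
co-terminating with a 3 s shock, uniform 8–12 s jitter — the source
describes "randomized jittering" without a distribution, so
uniform-continuous is used; habituation trials are not generated); direct
edge-level FC phenotypes for testing the mapping chain; and ROI time series
in which designated node pairs load on a shared latent factor whose
variance follows the task weight series, scaled per subject by an
ACE-structured factor. The boost enters as a correlation modulation, not a
mean shift, so regressing out task means — which the pipeline does — leaves
the planted connectivity intact.

What passing tests on these generators shows: the estimators are unbiased
under the model, the permutation schemes are valid, and planted effects of
realistic size are recovered. What they do not show: robustness to
non-Gaussian BOLD noise, autocorrelated scanner drift, spatially structured
artifacts, zygosity misclassification, or assortative mating — none of
which the generator produces. Results on real cohort data depend on those
ingredients too.

The demonstration dataset (`make_demo_dataset()`) is sized for a laptop
(40 + 40 pairs, 30 nodes) and exists so the full pipeline can be exercised
end-to-end with known ground truth. Its planted effects are deliberately
large (phenotype $A = 0.8$, connectivity boost 3) and its outlier rule
stricter ($k = 5$) so that at this small scale the injected failures are
the *only* QC flags and the planted elements separate cleanly; these are
properties of the demonstration, not defaults of the analysis functions.

## Numerical choices and degenerate inputs

* Fisher-z clipping at $\text{atanh}(1 - 10^{-7})$; zero-variance nodes get
  zero rows/columns with a warning rather than NaNs.
* Zero-variance phenotype elements are reported with $h^2 =$ NA and
  excluded from permutation maxima with a warning.
* Equal-size component ties: more nodes, then smallest minimum node id.
* Binarization uses strict $h^2 > \tau$; values exactly at threshold drop.
* All generators and permutation streams are reproducible from explicit
  integer seeds; the pipeline derives per-stage substreams from one config
  seed keyed by stage name, so disabling one stage never shifts another's
  randomness.
* Permutation p-values use $(1+b)/(m+1)$ and can never be zero.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerance being asserted: twin-correlation convergence at
2000 + 2000 pairs (tolerance ±0.03), estimator recovery at 2000 + 2000
(±0.05), Falconer/LR-SD agreement at 5000 + 5000 (±0.02), null calibration
with 200 replicate datasets of 50 elements at 100 + 100 pairs and 200
permutations, planted-component detection with 50 replicates at 150 + 150
pairs, and the power curve at 2000 replicates per grid point. The full
suite, including the end-to-end demo pipeline, completes in a few minutes
on one CPU.

## Known limitations

* The LR-SD estimator trades efficiency for speed; its power is below a
  maximum-likelihood ACE fit, and the power curve reports the implemented
  test's operating characteristic, not an upper bound for twin designs.
* No ADE or sex-limitation models; no structural-equation fitting.
* The weighted-correlation estimator is a documented stand-in for toolbox
  implementations whose exact weight normalization is unpublished;
  contracts (constant weights reduce to plain correlation, one-hot weights
  restrict to a block) are pinned by tests instead.
* Cluster inference supports extent only, not mass; spatial parametric
  alternatives (random-field theory) are out of scope.
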