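---
title: "Clustering longitudinal multi-region trajectories with trajmix"
author: "trajmix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering longitudinal multi-region trajectories with trajmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmix)
```

## The problem

Cohorts followed with repeated regional measurements — for instance cortical
thickness and subcortical volume from serial structural MRI in an Alzheimer's
disease study — are heterogeneous: different subjects start at different
severity levels and progress at different rates in different regions.
Cross-sectional clustering of a single visit confounds *subtype* (a distinct
spatial pattern) with *stage* (how far along a common pattern a subject is).
trajmix clusters subjects by their whole estimated trajectory — a per-region
intercept (level at the first visit) and slope (change per year) — across all
regions at once, while

* using every available visit of every subject (visits may be irregular and
  incomplete),
* expressing all measurements relative to a healthy control group at the same
  visit, so normal-ageing level and change are removed before clustering,
* adjusting for covariates that should not drive the clusters (age, sex,
  intracranial volume, ...), and
* reporting how certain each subject's cluster membership is instead of
  forcing a hard assignment.

## The model

Write $Y_{ijl}$ for the measurement of subject $i$ in region $j$ at visit
$l$ ($l = 1, \dots, n_{ij}$), after standardization (see below). The
within-subject model is a multivariate linear mixed model,

$$ Y_{ijl} = x_{ijl}^\top \beta_j + z_{ijl}^\top b_{ij} + \varepsilon_{ijl},
\qquad \varepsilon_{ijl} \sim N(0, \phi_j), $$

with $z_{ijl} = (1, t_{il}/12)^\top$ (time in months from the first visit,
so slopes are per year) and $x_{ijl}$ the subject's covariates. Fixed
effects $\beta_j$ and residual variances $\phi_j$ are population parameters,
common to all clusters. The joint random-effect vector
$b_i = (b_{i1}^\top, \dots, b_{iJ}^\top)^\top \in \mathbb{R}^{q}$, $q = 2J$,
carries the subject's per-region intercepts and slopes; cross-region
dependence lives in its covariance. The mixture enters through hierarchical
centering: given the latent cluster $U_i = k$,

$$ b_i \mid U_i = k \sim N(\mu_k, D_k), \qquad P(U_i = k) = w_k , $$

so the cluster means $\mu_k$ *are* the cluster-typical trajectory patterns
and $D_k$ their within-cluster spread. Integrating $b_i$ out gives the
subject's component marginal in closed form,

$$ y_i \mid U_i = k \sim N(X_i \beta + Z_i \mu_k,\;
   Z_i D_k Z_i^\top + \Phi_i), $$

and the mixture marginal $f_i(y_i) = \sum_k w_k f_{ik}(y_i)$, whose
$-2\sum_i \log f_i$ is the deviance used for model comparison.

### Standardization

Raw units differ across regions (millimetres vs cubic millimetres) and all
regions shrink with normal ageing. Patient values are therefore converted to
control-referenced z-scores per region and *per scheduled visit*:
$z = (x - \hat\mu_{jt}^{\,\mathrm{ctrl}}) / \hat\sigma_{jt}^{\,\mathrm{ctrl}}$,
with the control mean and *sample* SD ($n-1$ denominator; control cells are
small) computed at the same nominal visit. Actual acquisition times are
binned to the scheduled visits (default 0/12/24 months) within a +/-3-month
tolerance window; both the schedule and the window are arguments. A value of
$-2$ thus reads "two control SDs below the healthy mean for that region at
that point of follow-up", which is also the display threshold of the fitted
maps. Norms are fit before any patient filtering so the reference is stable.
Covariate-adjusted (e.g. age-regressed) norms are deliberately not offered:
covariate adjustment is the mixture model's job, through $\beta_j$.

### Priors

All priors are conjugate and weakly informative *on the z-score scale*:
$w \sim \mathrm{Dirichlet}(\delta = 1)$; $\mu_k \sim N(0, 100\,I_q)$;
$D_k^{-1} \sim \mathrm{Wishart}(q + 1, I_q)$ (the smallest proper integer
degrees of freedom); $\beta \sim N(0, 10^4)$ per coefficient — large enough
that the posterior SD of the fixed effects should come out far below it,
which is worth checking on any fit — and
$\phi_j \sim \mathrm{InvGamma}(0.01, 0.01)$. All are exposed through
`mmlmm_priors()`. Because the priors assume unit-scale data, `mmlmm()` warns
when handed an unstandardized cohort, and numeric covariates are centered
and scaled internally (profiles supplied to `fitted_maps()` are on the raw
scale; the stored centers/scales are re-applied).

## The sampler

`mmlmm()` runs a systematic-scan Gibbs sampler with conjugate full
conditionals, in the fixed order: allocations $U_i$, weights $w$, random
effects $b_i$, cluster means $\mu_k$, cluster precisions $D_k^{-1}$, fixed
effects $\beta_j$, dispersions $\phi_j$. The allocation update is *collapsed*
— it uses the closed-form component marginals with $b_i$ integrated out, and
$b_i$ is redrawn immediately afterwards — a partially collapsed scheme that
mixes better over cluster membership than conditioning on the current $b_i$.
The expensive steps (component marginals via the matrix determinant
lemma/Woodbury identity in the $q$-dimensional random-effect space, and the
$b_i$ draws) are compiled; all random numbers come from R's RNG, so a chain
is bit-reproducible from `mmlmm_control(seed = )`.

Numerical choices worth knowing:

* Marginal covariances are never formed; the factorization works on
  $D_k^{-1} + Z_i^\top \Phi^{-1} Z_i$, which stays well conditioned on the
  z-scale. A non-positive-definite factorization aborts with the subject and
  component named.
* Empty clusters are allowed during sampling (the Dirichlet prior keeps
  weights positive); components empty in the final classification are simply
  reported, and undersized ones flagged as outlier clusters.
* Categorical draws use the Gumbel-max trick; ties in classification
  probabilities break toward the lowest cluster index, with a warning.

### Initialization

Mixture posteriors are multimodal and a Gibbs chain rarely jumps between
well-separated modes, so the starting point matters. Four strategies are
provided: random allocations (`default`), k-means or Ward hierarchical
clustering of the baseline-visit values (`kmeans_baseline`,
`hierarchical_baseline`), and externally supplied cluster means perturbed by
uniform noise U(-h, h) (`given_means_plus_noise`), the idiom for warm-starting
from a previous (e.g. cross-sectional) solution while still randomizing the
start. Empty initial clusters are re-drawn up to a bounded retry count. In
our simulations the baseline-informed starts reliably find the separated
modes that random starts can miss; comparing chains from several strategies
through the scorecard (below) is the intended workflow, mirroring how the
framework is used in practice.

### Burn-in, thinning, label switching

The reference analysis this framework was built for ran 750,000 iterations
with 250,000 burn-in and thinning 500 (1000 retained draws). The package
default, `mmlmm_control(20000, 5000, 15)`, also retains 1000 draws and is
the scale used throughout the tests and simulations; the heavier schedule is
config-reachable. Retained draws are aligned by pivot relabeling
(`relabel()`): the draw with the smallest deviance is the pivot and every
draw's components are permuted (exhaustively for $K \le 7$, greedily above)
to maximize agreement of the allocation-probability matrices. This is cheap
and adequate for separated components; for heavily overlapping components no
relabeling scheme is fully satisfactory, and averaged probabilities should
be read with care.

## Classification with uncertainty

Soft clustering: $\hat p_{ik}$ is the across-draw mean of the per-draw
allocation probabilities $P(U_i = k \mid y_i, \theta^{(r)})$ (a
sampled-allocation frequency estimator is available as an alternative).
Subjects are labeled by the maximum-probability rule. Two uncertainty layers
follow, in a fixed order:

1. **Outlier clusters.** Clusters with fewer than `min_size` (default 3)
   assigned subjects are too small to interpret as population patterns;
   their members are flagged rather than interpreted.
2. **HPD uncertainty.** For each subject and component, the package computes
   the highest-posterior-density interval (shortest-interval method on the
   empirical draws, default 95% mass) of the membership probability. A
   subject still in play is flagged uncertain when its top component's
   interval overlaps another component's interval — the chain does not
   separate the memberships with confidence. An alternative rule (top
   component's lower HPD bound below a threshold) is selectable; the overlap
   rule is the default because it directly expresses "cannot be assigned to
   any single cluster with high certainty". No operational definition being
   canonical, both are kept and the choice is recorded in the output.

## Model selection

Candidate chains (different $K$, different initializations, different seeds)
are compared on three criteria: posterior mean deviance (fit), the maximum
absolute lag-1 autocorrelation over monitored scalar traces (mixing; the
deviance trace and the weights, which are label-robust after relabeling),
and mean classification certainty. Each criterion is min-max scaled to
[0, 1] across candidates, oriented so 1 is best, and combined as an
unweighted mean (weights are exposed); ties break toward smaller $K$. A
criterion on which all candidates agree contributes 1 to everyone, with a
log message. The quantitative autocorrelation score stands in for the visual
trace inspection a human analyst would add; it is deliberately simple, and
information criteria (DIC/WAIC) are out of scope because the three-part
score is the framework's own selection device.

## Interpretive outputs

* `mds_embed()` applies classical (Torgerson) MDS to Euclidean distances
  between subjects' probability rows — deterministic and exactly
  reproducible, unlike stress-minimizing variants. Subjects belonging
  confidently to the same component collapse toward a corner; mixed subjects
  sit between. Tests compare distance matrices, not raw coordinates, since
  the embedding is unique only up to orthogonal maps.
* `fitted_maps()` evaluates each cluster's fitted z-value per region and
  time at a covariate profile, reporting across-draw medians with first and
  third quartiles as dispersion. `apply_display_mask()` implements the
  display rule that only values strictly below -2 control SDs are shown;
  masking only sets a flag, never alters values. The quartiles are
  across-posterior-draw by default; "dispersion" could equally mean
  across-subject spread within a cluster, so
  `fitted_maps_subject_quartiles()` implements that reading and the export
  records which basis produced the numbers.

## The synthetic cohort generator

`simulation_design()` + `generate_cohort()` produce cohorts with exactly the
model's structure and known ground truth: controls on a linear per-region
mean trajectory with Gaussian noise attending every visit; patients drawn
from $K$ latent clusters via $U_i \sim \mathrm{Cat}(w)$,
$b_i \sim N(\mu_{U_i}, D)$, shared covariate effects, Gaussian residuals,
and attendance thinning of the final visit. Defaults describe the study
conditions the framework targets: 31 controls and 72 patients at 0/12/24
months, 24-month patient attendance 57/72, and three patterns — diffuse
atrophy (intercepts −2.5, slopes −0.5/yr), minimal atrophy (−0.5, −0.1/yr)
and hippocampal sparing (cortical −2.5/−0.5, subcortical −0.5/−0.1) —
weighted (34, 23, 9)/66, with residual SD 0.5 and random-effect SDs 0.4
(intercept) / 0.15 (slope), intercept–slope correlation 0.3 within region
and 0.2 across regions. Where the emulated study prints no value (the
random-effect correlations, the residual SD, covariate effect sizes) the
defaults are one-time choices of what a realistic neuroimaging cohort looks
like on the z-scale, not tuning knobs. A patient left with fewer than two
visits by the attendance draw has attendance re-drawn (logged), keeping
slopes identifiable.

What the generator does *not* emulate: measurement error structure beyond
i.i.d. Gaussian residuals, scanner or site effects, non-linear trajectories,
informative dropout (attendance is independent of severity), and skewed or
heavy-tailed biomarker distributions. Tests passing on these cohorts
therefore demonstrate correctness of the machinery under the model's own
assumptions, not robustness to their violation; the
`cluster_specific_beta` mode exists to probe one such violation
deliberately.

## Verification strategy and problem sizes

The test-suite benchmarks run at sizes chosen to exercise the study
conditions while keeping a full run comfortable on one CPU: conjugate full
conditionals are checked against their analytic Dirichlet / Gaussian /
Wishart / inverse-gamma moments on held-fixed states (a few thousand
replicate draws each); the closed-form marginal likelihood is checked
against brute-force Monte-Carlo integration (10^5 draws) on a
two-region/two-visit instance; the $K = 1$ reduction is checked against
generalized least squares on a 30-subject cohort; and end-to-end recovery
runs $K = 3$, $J = 4$, 120 patients with >= 2-residual-SD separation over
ten seeds at 20,000 iterations each, asserting adjusted Rand index >= 0.9
and approximately nominal 95% credible-interval coverage for the cluster
means. Coverage is assessed against the *induced* truth — the generator's
raw-unit trajectories pushed through the fitted reference norms — because
standardizing against an estimated control mean shifts the target of
inference by the norms' own estimation error; comparing against the raw
design values would mistake that shift for sampler miscalibration.

## Known limitations

* One shared $D$ across clusters in the generator default (the model itself
  allows cluster-specific $D_k$, which the sampler estimates).
* Pivot relabeling can misalign draws when components overlap heavily.
* The collapsed allocation update still explores a multimodal posterior; for
  real analyses run several initializations and compare scorecards rather
  than trusting a single chain.
* Only the Gaussian family is implemented; the `family` notion exists in the
  design to keep the door open for other links, not as a working feature.
* Visit binning assumes a scheduled-visit design; cohorts with genuinely
  continuous acquisition times would need a smooth normative model instead
  of per-visit cells.

## A minimal session

```{r example, eval = FALSE}
design <- simulation_design(n_controls = 31, n_patients = 72, k = 3,
                            n_regions = 4)
sim <- generate_cohort(design, seed = 1)
norms <- fit_reference(sim$cohort)
zc <- to_zscores(filter_min_visits(sim$cohort), norms)

fit <- relabel(mmlmm(zc, k = 3, fixed = ~ age + sex + icv,
                     control = mmlmm_control(seed = 1,
                                             init = "kmeans_baseline")))
summary(fit)
cls <- classify(fit)
cls
truth_recovery_report(sim$truth, cls)$ari

maps <- apply_display_mask(fitted_maps(fit, profile = list(
  age = 75, sex = 1, icv = 1.5e6)))
head(maps)
```
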