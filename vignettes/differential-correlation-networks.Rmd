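---
title: "Differential correlation networks for two-group metabolomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential correlation networks for two-group metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menodcn)
```

This vignette is the package's account of its statistical methods: the
model behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where more than one defensible option existed.

## The differential correlation statistic

For a metabolite pair $(i, j)$ with within-group Pearson correlations
$r_{\text{pre}}$ and $r_{\text{post}}$ estimated from $n_{\text{pre}}$
and $n_{\text{post}}$ samples, the package computes

$$
r_{\text{diff}}(i,j) \;=\; \sqrt{\tfrac{n_{\text{pre}}-3}{2}}\; z_{\text{pre}}(i,j)
\;-\; \sqrt{\tfrac{n_{\text{post}}-3}{2}}\; z_{\text{post}}(i,j),
\qquad z(r) = \tfrac12 \ln\!\frac{1+r}{1-r}.
$$

The Fisher transform variance-stabilises a sample correlation
($\operatorname{Var} z \approx 1/(n-3)$), so each weighted term has
variance $\approx 1/2$ and $r_{\text{diff}}$ is approximately standard
normal under the no-change null *whatever the two group sizes are*. This
is the reason the weight is $\sqrt{(n-3)/2}$ applied per group rather
than a single common factor: with unequal groups ($55$ vs $64$ here) a
common weight would leave the null variance dependent on the sizes. When
the groups are equal the statistic reduces to the familiar
$\sqrt{(n-3)/2}\,(z_1 - z_2)$.

Two conventions are configurable:

* **Direction.** The default reports pre-minus-post;
  `direction = "post_minus_pre"` flips the sign. Both orders are in use
  in the differential-correlation literature and they differ only by the
  reported sign, never by $|r_{\text{diff}}|$ or the p-value.
* **Degenerate correlations.** `fisher_z()` refuses $|r| \ge 1$ rather
  than clamping. A perfect sample correlation means a degenerate input
  (duplicated column, $n=2$ effects) that the caller should see, not a
  value to push through arithmetic.

### Permutation null

Analytic normality of $r_{\text{diff}}$ is only asymptotic and assumes
independent pairs, so significance comes from a permutation test:
the group labels are permuted $B$ times (default $B = 1000$), preserving
the two group sizes, and the two-sided add-one estimator

$$
p = \frac{1 + \#\{b : |r_{\text{diff},b}| \ge |r_{\text{diff,obs}}|\}}{B + 1}
$$

is reported per pair. Its floor is $1/(B+1)$; it never returns 0. One
*shared* set of permutations is used for all pairs: that is what a single
permutation test over a pair family means operationally, and it preserves
the cross-pair dependence structure (at the cost of correlating the
Monte-Carlo noise across pairs — see the note on validation subsampling
below). Permutations relabel the *preprocessed* residual/normalised
values; covariates are not re-adjusted inside the loop, because the
adjustment is group-blind by construction.

Edges are selected at $p \le 0.01$ (inclusive), the conventional
threshold for building the network stage; the within-group correlation
screen instead uses Bonferroni control ($p < \alpha / \binom{m}{2}$,
strict) because there the family is the full pair set of a correlation
matrix and family-wise control is the standard practice.

## Preprocessing chain

The order is fixed and recorded in the preprocessing report:

1. **Measurability filter** (`min_fraction = 0.8`, inclusive): a
   metabolite must be genuinely quantified in at least 80% of samples.
   Below-LOD and missing entries both count against it — both are
   detection failures, and counting censored values as "measured" would
   let a mostly-censored metabolite through on a technicality.
2. **Below-LOD imputation**: half the minimum quantified concentration of
   that metabolite, groups pooled. Simple, standard for targeted panels,
   and deliberately not probabilistic (a left-censored model is out of
   scope and would interact badly with the later residualisation).
3. **Covariate residualisation**: each metabolite is replaced by its OLS
   residual against intercept + age + BMI + physical activity + age of
   menarche, fitted on both groups pooled. Pooled, not per group: the
   adjustment is meant to happen once, prior to any group comparison; a
   per-group fit would absorb part of the group effect itself. Missing
   entries are excluded per fit and stay missing.
4. **Mean imputation**: metabolites missing in $< 5\%$ of samples have
   missing entries filled with the all-sample mean (of the residuals, at
   this point in the chain); metabolites at or above 5% are dropped. The
   imputation sits *after* residualisation so that imputed values are
   neutral (zero) on the scale the correlations see, rather than
   reintroducing covariate structure.
5. **z-normalisation** over all samples pooled, to mean 0, SD 1.

Rerunning the chain on its own output is a no-op up to normalisation
round-off (tolerance $10^{-8}$ in the tests).

`summarize_cohort()` reports per-covariate group means ± SD with a Welch
(unequal-variance) two-sample t-test. The Welch choice is ours; cohort
tables of this kind rarely state their test, and the summary is
descriptive — none of the downstream stages consume these p-values.

## Network stage

Edges at $p \le 0.01$ form an undirected simple graph; nodes are the
incident metabolites. Centralities are computed on the **unweighted**
topology (|r_diff| is kept as an edge attribute for export and plotting
only) because no weighted-path convention is standard for correlation
networks and an unweighted definition keeps the brute-force test oracle
exact:

* degree: raw neighbour count;
* betweenness: shortest-path betweenness, endpoints excluded, computed
  within each connected component and normalised by
  $(N_c-1)(N_c-2)/2$;
* closeness: classical $(N_c-1)/\sum d$ within each component.

Per-component normalisation (rather than whole-graph) keeps both scores
in $[0,1]$ and comparable across the fragmented graphs that a
$p \le 0.01$ edge set typically produces. Hubs are ranked by degree with
betweenness then name as tie-breaks; the bottleneck flag marks the top
decile of betweenness or closeness (both cut-offs configurable — they are
conventions, not estimates). Exports: GraphML and edge-list CSV,
round-trip safe.

## OPLS-DA stage

`fit_oplsda()` implements the NIPALS orthogonal-projection algorithm:
repeatedly extract the class-predictive direction, split off its
class-orthogonal part, deflate, and finally fit one predictive PLS
component on the deflated matrix. With `n_orth = 0` the fit is exactly a
one-component PLS-DA (a test asserts equality against an independently
coded direct PLS). Defaults: one orthogonal component — the usual
starting point for a two-class metabolomics model; model selection of
`n_orth` is deliberately out of scope.

* **VIP** is computed on the predictive component. With a single
  predictive component the general VIP formula collapses to
  $\sqrt{m}\,|w_j|$ with $w$ the unit weight vector, which makes the
  normalisation identity $\overline{\mathrm{VIP}^2} = 1$ exact rather
  than approximate.
* **S-plot** coordinates are $\operatorname{cov}(x_j, t)$ and
  $\operatorname{cor}(x_j, t)$ against the predictive score $t$.
* **Q²** uses 7-fold cross-validation stratified by class (a common
  chemometrics default), $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$ on the
  centred class response, with seeded fold assignment. Stratification
  guarantees both classes in every training split at these group sizes.
* **Screening** passes a metabolite iff VIP $> 1$ (strict) and its
  univariate p-value is $< \alpha/m$ (strict). The univariate test is a
  Welch t-test on the normalised values — configurable in principle, but
  a t-test on z-scored data is the natural default. For $m = 168$,
  $\alpha = 0.05$ the threshold is $2.976\times10^{-4}$; the package also
  reports the 2-significant-digit *truncated* display $2.9\times10^{-4}$,
  since truncation (not rounding) is how such thresholds are usually
  printed.
* **Association**: screened candidates are regressed (their
  covariate-*adjusted*, pre-normalisation values) on the binary group
  indicator; with a binary predictor the OLS slope is exactly the
  adjusted group-mean difference, which makes the estimate directly
  interpretable in concentration-residual units.

## The synthetic-data generator

`generate_study()` defines the study conditions every test and the
acceptance script run under. It emulates a two-group targeted plasma
panel:

* **Group sizes** default to 55 (pre) and 64 (post). (The motivating
  cohort reports 120 participants but group sizes summing to 119; the
  defaults use the stated per-group counts and leave the discrepancy
  alone.)
* **Latent scale.** Metabolite values are generated as correlated
  Gaussians on a log-concentration scale and exponentiated, giving
  positive, right-skewed concentrations spanning roughly 0.1–100 µM.
  Correlations are planted on the latent scale; since the pipeline
  z-normalises (and correlation analysis is scale-free up to the
  log-normal distortion), latent-scale structure is what the analysis
  sees, and ground-truth checks are done there.
* **Shared blocks** (defaults: sizes 12, 10, 8, 6 with within-block
  correlations 0.45–0.6) model "housekeeping" co-regulation — lipid
  classes that correlate identically in both groups, as the large
  cross-group overlap of significant correlations in real panels
  suggests.
* **Planted differential pairs** default to
  $(r_{\text{pre}}, r_{\text{post}}) = (0.7, 0.0), (0.8, 0.1),
  (-0.6, 0.1)$ — strong correlation changes of the magnitude a
  differential network method is meant to detect. Ground truth stores
  these *target* correlations, not the realised sample values: recovery
  is judged against the generative truth.
* **Covariates.** Age differs by group by design (pre
  $\mathcal N(39.4, 9.1^2)$, post $\mathcal N(57.2, 8.5^2)$), so a
  non-zero age slope creates genuine confounding for the adjustment
  stage to remove; BMI, activity and menarche age are group-invariant
  with cohort-level moments. Covariate effects default to zero slopes —
  a clean null — and are switched on explicitly in the tests that probe
  the adjustment.
* **Censoring and missingness.** The lowest 2% of each metabolite is
  flagged below-LOD (rank-based, so the fraction is exact to $1/n$);
  2% of the remaining entries are missing at random. Missingness must
  stay under 5%, matching the downstream imputability bound.
* **Positive definiteness.** Blocks plus planted pairs can produce a
  non-PD target matrix; the generator repairs it by eigenvalue clipping
  at $10^{-6}$ followed by re-normalisation to unit diagonal, records
  that a repair happened, and errors if the repaired matrix deviates
  from the targets by more than 0.05 anywhere — deterministic, simple,
  and target-preserving for mild violations.

What it does **not** emulate: mass-spectrometry peak data, batch or
plate effects, metabolite-specific missingness mechanisms, heavy-tailed
or bimodal abundance distributions, and group differences in metabolite
*levels* (there is deliberately no mean-shift knob — the generator's
subject is correlation structure). Two consequences worth knowing:
passing tests say nothing about robustness to batch structure, and on
default synthetic studies the OPLS-DA stage correctly finds nothing
(cross-validated Q² is negative), because there is no level signal to
predict. Tests of the discriminant stage therefore construct mean-shifted
panels directly.

## Numerical choices and problem sizes

* Exactness tolerances are $10^{-8}$ absolute (normalisation,
  residual-covariate orthogonality), $10^{-6}$ for OPLS-DA orthogonality
  and VIP identities, $10^{-12}$ for closed-form checks.
* Ties in edge ranking break by metabolite name; pair identity is always
  the name-ordered pair, so every unordered pair appears exactly once.
* Permutation p-values are validated for calibration on a no-difference
  panel of 100 independent metabolites at $n = 55/64$, $B = 1000$: the
  $r_{\text{diff}}$ distribution across all pairs is checked for mean
  within $\pm 0.1$ and SD within $[0.9, 1.1]$, while the
  Kolmogorov–Smirnov uniformity and exact-binomial type-I checks use a
  metabolite-disjoint subsample of pairs (~50), because p-values of
  pairs sharing a metabolite or sharing the permutation set are not
  independent and would invalidate the exact interval.
* Planted-pair recovery is measured over 50 replicates of a 20-metabolite
  panel with the default planted pairs at $n = 55/64$, $B = 1000$ — a
  panel size chosen to keep the replicated simulation quick while leaving
  the per-pair power unchanged (power depends on the group sizes and the
  planted correlations, not on how many null metabolites surround them).
* The permutation loop is vectorised over pairs (two correlation-matrix
  evaluations per permutation); a full 168-metabolite panel at
  $B = 1000$ runs in well under a minute on one CPU.

## Known limitations

* The differential statistic inherits Pearson correlation's sensitivity
  to outliers; no robust (rank-based) variant is provided.
* Mean imputation slightly shrinks correlations of metabolites with
  missing entries; at the enforced $<5\%$ missingness the attenuation is
  negligible but it is not corrected for.
* The analytic $N(0,1)$ null for $r_{\text{diff}}$ is used only as a
  cross-check; reported inference is always permutation-based.
* Centrality conventions (per-component normalisation, endpoint
  exclusion) are choices among several in use; rankings are robust to
  them, absolute values are convention-dependent.
* OPLS-DA with one fixed orthogonal component can under- or over-deflate
  for panels whose class-orthogonal variation is not one-dimensional;
  inspect R²X/R²Y and Q² before interpreting VIP.
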