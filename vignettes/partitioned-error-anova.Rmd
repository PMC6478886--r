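---
title: "Partitioned-error repeated-measures ANOVA in a single-error-term GLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned-error repeated-measures ANOVA in a single-error-term GLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peranova)
```

## The problem

Group-level repeated measurements — the same subjects measured under every
combination of one or more within-subject conditions, possibly split into
between-subject groups — are classically analysed with a mixed-measures
ANOVA. Writing the three-way case with within-subject factors $A$
($i = 1,\dots,a$) and $B$ ($j = 1,\dots,b$), a between-subjects factor $C$
($k = 1,\dots,c$), and subjects $l = 1,\dots,n_k$ nested in the groups of
$C$:

$$
y_{ijkl} = \mu + \alpha_i + \beta_j + \gamma_k
  + (\alpha\beta)_{ij} + (\alpha\gamma)_{ik} + (\beta\gamma)_{jk}
  + (\alpha\beta\gamma)_{ijk}
  + S_{l(k)} + (S\alpha)_{il(k)} + (S\beta)_{jl(k)} + \epsilon_{ijkl}
$$

with $S_{l(k)} \sim N(0, \sigma^2_s)$,
$(S\alpha)_{il(k)} \sim N(0, \sigma^2_{s\alpha})$,
$(S\beta)_{jl(k)} \sim N(0, \sigma^2_{s\beta})$ and
$\epsilon \sim N(0, \sigma^2)$. The random subject terms partition the
error into *strata*, and each fixed effect must be tested against the
stratum whose **expected mean square** (EMS) differs from the effect's EMS
only by the effect's own component. In this design that yields four
denominators: $MS_S$, $MS_{SA}$, $MS_{SB}$ and the residual.

Mass-univariate imaging software (and `lm`-style GLM code generally) uses a
*single* error term: whatever is left after the design matrix is fitted.
Testing a between-subjects effect against that residual tests the effect
*plus* the subject variance and inflates the F statistic. The remedy is a
multi-model procedure:

1. derive the EMS for the complete model — the number of distinct error
   strata is the number of sub-models needed;
2. for each sub-model, average the data over the within-subject factors
   *not* tested under that stratum — the stratum's random term then becomes
   perfectly collinear with the residuals and *is* the enforced error term;
3. fit each sub-model and test each effect with estimable contrast weights
   derived from the design-matrix rows.

`peranova` automates all of it.

```{r}
design <- rm_design(within = c(Location = 2, Texture = 3),
                    between = c(Drink = 2), n = c(14, 16))
ems <- derive_ems(design)
ems
plan_models(ems)
```

## EMS derivation and error-term selection

`derive_ems()` implements the classical tabular bookkeeping: a term $U$
contributes to the EMS of a term $T$ when $U$'s subscripts contain $T$'s,
with coefficient equal to the product of the level counts of the indices
absent from $U$; a contribution is struck out when any surplus live index
of $U$ belongs to a fixed factor. Coefficients are kept symbolic (products
of level-count symbols) so the table can be printed and asserted literally,
and evaluated numerically on demand. The fixed-factor strike-out is the
*restricted* mixed-model convention, in which a subject's interaction
effects sum to zero over the levels of the fixed factor; the synthetic-data
generator draws its subject-by-within effects the same way so that
simulated mean squares converge to exactly these expressions
(`monte_carlo_ems_check()` verifies this — the keystone test coupling the
EMS engine, the simulator and the fitting engine).

`select_error_term()` removes the effect's own component from its EMS row
and searches for the unique term whose EMS equals the remainder. If none
exists — e.g. a fixed factor crossed with two random factors — an exact F
does not exist and the function raises a quasi-F error naming the unmatched
components; it never silently substitutes the residual. Quasi-F
construction (Satterthwaite pooling) is deliberately out of scope. If two
strata ever matched, an ambiguity error would be raised; this cannot occur
in the supported designs.

Supported designs (v1): any crossing of fixed within-subject and fixed
between-subject factors with one random subject factor, subject nested in
the between factors, one observation per subject per within-cell, and
arbitrary (possibly unbalanced) group sizes. The EMS derivation runs on the
balanced template — sufficient for identifying error terms — while degrees
of freedom use the actual group sizes. Unbalanced-design EMS coefficients
(Type III expected values) are intentionally not reported.

## Contrasts from design-matrix rows

Overparameterized design matrices (indicator blocks for every level,
fitted by pseudoinverse) make individual parameters non-estimable; only
linear combinations of design-matrix *rows* are estimable. Marginal-mean
weights are therefore built by averaging rows
(`marginal_mean_weights()`), and effect weights by differencing them
(`derive_effect_contrast()`). Weight arithmetic is carried out in exact
rationals (integer numerators over a common denominator), so printed
weights are exactly $\pm1, \tfrac12, \tfrac14, \dots$.

Two diagnostics matter:

* `subject_zero` — whether every subject-block weight is zero. Within
  effects cancel their subject weights; between effects do not, and a
  contrast with non-zero subject weights must not be tested against the
  model residual. `f_test()` refuses such a combination rather than
  returning an inflated statistic. Zeroing the subject weights by hand does
  not help: the result fails `check_estimable()`.
* `required_error` — the stratum whose EMS matches the effect, carried as
  metadata. For simple effects the appropriate stratum is not necessarily
  the omnibus one; a between-group comparison at a fixed within level needs
  a between model on the data subset, which
  `derive_simple_effect_contrast()` reports in its `note`.

For fitting, contrasts are derived from the matrix reduced to unique rows
of the fixed-effect columns (first-occurrence order, subject blocks
removed, zeros re-inserted). Each design cell then contributes exactly one
row regardless of group size, which makes the tests Type III — invariant to
imbalance — without sequential model comparisons. Codings
(overparameterized, treatment, sigma-restricted, cell-means) span the same
row space, so F statistics are coding-invariant; in the constrained codings
the subject blocks remain nested 0/1 indicators and only the fixed factors
change code.

## Fitting and the ANOVA table

`run_partitioned_anova()` (or the formula front-end `peranova()`) executes
the plan: per stratum it averages the data, builds the sub-model (fixed
terms of the retained factors, subject blocks, and subject-by-within blocks
short of the stratum itself), fits by pseudoinverse, and computes each
effect's sum of squares as the contrast quadratic form
$(\mathbf{L}\hat\beta)'[\mathbf{L}(\mathbf{X}'\mathbf{X})^-\mathbf{L}']^{-1}(\mathbf{L}\hat\beta)$.
Missing within-cells are an error, not imputed: the averaging device
requires complete crossings (marginal/sandwich-estimator approaches are the
appropriate alternative for incomplete data).

Averaging divides sums of squares by the number of averaged levels (2, 3
and 6 for the three reduced models of the example design) while leaving
every F ratio unchanged. The assembled table reports SS multiplied back to
the full-decomposition scale so that it matches classical ANOVA software
line by line; the sub-model-scale values are available from
`fit_submodel()`. Numerical choices: pseudoinverse cutoff at machine
epsilon times the leading singular value and matrix dimension;
estimability tolerance $10^{-8}$ on the maximum projection residual; a
residual mean square below $10^{-12}$ of the effect mean square is treated
as zero and the F reported as `Inf`.

`variance_components()` inverts the EMS identities of the error strata
(method of moments), and `simulate()` on a fitted object regenerates
datasets from the estimated components — a quick parametric bootstrap.

## Covariates

With partitioned errors there are as many covariate regression
coefficients as error strata. A covariate is decomposed
(`decompose_covariate()`) into its per-subject mean (between stratum), its
per-within-level subject means (subject-by-factor strata) and its raw
values (residual stratum); columns that coincide after averaging — a
covariate constant over some within factor — are redundant and dropped.
Each sub-model receives every available column, but only the
stratum-matched one is tested there, with 1 numerator df. Covariates are
grand-mean centered by default (`covariate_spec(center=)` switches this
off) so the intercept stays at the grand mean.

Degrees of freedom follow the classical split-block ANCOVA accounting: a
covariate is charged one df at the *subject level* of every stratum in
which it has a slope, so with a fully within-subject covariate the example
design's error df become $(28-1)\times1 = 27$, $27$, $(28-1)\times2 = 54$
and $54$. Note this differs from the rank of the fitted sub-model (which
grows by one per stratum, giving 55 for the two-df strata); the table uses
the split-block convention and additionally stores the rank-based residual
df on the fit object. Covariate-by-within-factor interactions and
covariate-by-group interactions are not generated automatically; whether to
include them is a modelling choice left to the user via extra columns.

## Sphericity

Within-subject F tests are exact only under sphericity — equal variances
of all pairwise differences of the repeated measurements.
`assess_sphericity()` reports those pairwise difference variances,
Mauchly's W with its chi-square approximation, and the Greenhouse–Geisser
and Huynh–Feldt epsilons from the eigenvalues of the pooled within-group
covariance projected onto an orthonormal contrast basis (the Kronecker
interaction basis for multi-factor strata). `adjust_df()` multiplies the
numerator and denominator df of the affected tests by epsilon, which
leaves F unchanged and can only increase the p-value (the correction is
conservative; p is non-increasing in epsilon). Epsilons are computed per
response — per voxel in the image pipeline — rather than pooled over
voxels, an intentional choice favouring exactness over the pooling
shortcut some packages use. Whitening/GLS approaches that would make the
random subject blocks redundant are out of scope and never combined with
the partitioned-error models.

## Images

`load_image_stack()` reads one volume per subject and within-cell (these
should be readily interpretable per-condition summary images), checks
geometry, and masks non-finite voxels. `run_voxelwise()` computes the plan,
sub-model matrices and contrast operators once and sweeps them across all
voxels with matrix algebra; a one-voxel stack reproduces the tabular
analysis to machine precision. Averaged sub-model responses are computed
internally from the loaded stack, so users never supply separately averaged
images. Multiple-comparison control is voxel-wise Benjamini–Hochberg FDR
only; random-field and permutation inference are out of scope.
`write_stat_maps()` emits one NIfTI volume per effect and statistic plus a
JSON sidecar with the design, plan and df.

## What the generator emulates — and what it does not

`simulate_dataset()`/`simulate_images()` produce Gaussian
variance-component data: independent subjects, independent voxels,
spherical (or optionally compound-symmetric / AR(1)) within-subject
covariance, fixed effects that sum to zero over each factor margin.
Defaults in the worked examples mirror the example study's shape — a
2×3×2 mixed design with group sizes 14 and 16 (180 observations), unit
error variance and subject-stratum components of roughly half to one times
it. Real imaging data add spatial smoothness, temporally autocorrelated
first-level noise, heteroscedastic groups and missing cells — none of
which the generator produces. Passing calibration tests here therefore
validates the *algebra and the null distributions under the model's own
assumptions*, not robustness to those violations.

Problem sizes used by the test suite were chosen to make Monte-Carlo
standard errors small relative to the asserted tolerances while keeping
the default run lightweight: 2,000 replicates for type-I calibration and
EMS recovery (99% binomial band half-width ≈ 0.0126 at α = 0.05), an
8×8×8 volume with 30 subjects × 6 cells for the image round trip, and
n = 8–10 per group for the oracle-equivalence checks (tolerance 10⁻⁸ on
relative F error).

## Known limitations

* One random unit factor only; crossed random factors (subjects *and*
  items) are detected and refused, not approximated.
* Complete within-subject crossings are required.
* The split-block ANCOVA df convention (above) is a convention, not a rank
  count; users wanting rank-based df can read them off the fit object.
* Moment estimates of variance components can be negative; they are
  reported as computed.
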