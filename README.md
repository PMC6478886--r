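# peranova

Partitioned-error repeated-measures ANOVA and ANCOVA for tabular and
mass-univariate (voxel-wise) data.

## The problem

Repeated measurements — subjects observed under every level of one or more
within-subject conditions, possibly split into between-subject groups — do
not have a single error term. In the three-way mixed model

```
y_ijkl = mu + alpha_i + beta_j + gamma_k
       + (alpha beta)_ij + (alpha gamma)_ik + (beta gamma)_jk
       + (alpha beta gamma)_ijk
       + S_l(k) + (S alpha)_il(k) + (S beta)_jl(k) + eps_ijkl
```

the random subject terms `S`, `S×A`, `S×B` partition the error into
strata, and each fixed effect must be tested with the mean square whose
**expected mean square (EMS)** differs from the effect's EMS only by the
effect's own component (e.g. the between-group effect against `MS_S`, not
the residual — using the residual tests the effect *plus* the subject
variance and inflates F). GLM software with a single implicit error term —
the situation in standard mass-univariate neuroimaging packages — needs one
sub-model per stratum, with the data averaged over the within-subject
factors not tested in that stratum so that the stratum becomes the model's
residual.

`peranova` implements the whole procedure:

* symbolic EMS derivation and exact error-term selection (with an explicit
  quasi-F refusal when no exact denominator exists);
* the multi-model plan: which factors to average over, which effects each
  sub-model tests, all degrees of freedom (balanced or unbalanced groups);
* estimable Type III contrast weights derived from design-matrix rows in
  exact rational arithmetic, with `subject_zero`/`required_error`
  diagnostics and an estimability check that catches hand-zeroed subject
  weights;
* pseudoinverse fitting of each sub-model and a single assembled ANOVA
  table;
* stratum-decomposed continuous covariates (between- or within-subject);
* Mauchly / Greenhouse–Geisser / Huynh–Feldt sphericity handling;
* a voxel-wise engine over NIfTI image stacks with BH-FDR, plus a seeded
  synthetic-data generator with the model's exact variance-component
  structure.

## Worked example

A 2 (Location, within) × 3 (Texture, within) × 2 (Drink, between) design
with 14 + 16 subjects; data simulated with Location and Texture effects,
subject variance 1, subject-by-within components 0.5 / 0.4, error
variance 1:

```r
library(peranova)

design <- rm_design(within = c(Location = 2, Texture = 3),
                    between = c(Drink = 2), n = c(14, 16))
spec <- sim_spec(design,
  effects  = list(Location = c(-0.3, 0.3), Texture = c(-0.2, 0, 0.2)),
  variance = c(sigma2 = 1, `Subject(Drink)` = 1,
               `Subject(Drink):Location` = 0.5,
               `Subject(Drink):Texture` = 0.4),
  seed = 7)
dat <- simulate_dataset(spec)
fit <- run_partitioned_anova(dat, design)
fit
```

```
Partitioned-error repeated-measures ANOVA
                         Effect        SS df       MS        F         p
                          Drink   0.36290  1  0.36290  0.04299 0.8372460
          Error: Subject(Drink) 236.40000 28  8.44200
                       Location  27.33000  1 27.33000 15.13000 0.0005647
                 Location:Drink   0.04342  1  0.04342  0.02403 0.8779246
 Error: Subject(Drink):Location  50.59000 28  1.80700
                        Texture   4.89600  2  2.44800  1.12000 0.3333467
                  Texture:Drink   1.27400  2  0.63720  0.29160 0.7481819
  Error: Subject(Drink):Texture 122.40000 56  2.18500
               Location:Texture   5.91500  2  2.95800  2.88100 0.0644484
         Location:Texture:Drink   0.27510  2  0.13760  0.13400 0.8748888
                Error: Residual  57.50000 56  1.02700
```

Each effect row is tested against its own error stratum (the `Error:` row
beneath it): Drink against `Subject(Drink)` on (1, 28) df, Location against
`Subject(Drink):Location` on (1, 28), Texture against
`Subject(Drink):Texture` on (2, 56), and the interactions not involving a
single within factor against the residual on (2, 56) — the df column of the
classical ANOVA table for this design. The injected Location effect is
detected (F = 15.13, p ≈ 6e-4); the null Drink effect is not (F = 0.04).
Method-of-moments variance components recover the simulation truth:

```r
round(variance_components(fit), 3)
#>                  sigma2          Subject(Drink) Subject(Drink):Location
#>                   1.027                   1.236                   0.260
#>  Subject(Drink):Texture
#>                   0.579
```

The same analysis runs per voxel on an image stack:

```r
sim <- simulate_images(spec, shape = c(8, 8, 8), effect_mask = mask)
vd  <- load_image_stack(sim$images, sim$obs_table)
res <- run_voxelwise(vd, design, fdr = 0.05)
write_stat_maps(res, "results/maps")
```

See the vignette (`vignettes/partitioned-error-anova.Rmd`) for the model,
the contrast machinery, covariates, sphericity, and the design decisions.

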