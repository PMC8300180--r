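# geoherd

Genomic prediction (GBLUP) with **spatially correlated herd effects**.

In routine genetic evaluation of livestock, the herd (farm / contemporary
group) is modelled as an independent random effect: two farms are treated
as unrelated management units no matter how close they sit on the map. But
nearby farms share climate, terrain and often management, so their
environmental effects are correlated. `geoherd` implements an animal model
in which the covariance of the herd effects is built directly from the
farms' GPS coordinates, and provides everything needed to compare this
model against the traditional alternatives: REML variance-component
estimation, GBLUP prediction, replicated cross-validation with the field's
standard accuracy/reliability metrics, an eigenstructure-based confounding
diagnostic, and a synthetic-data generator that emulates a commercial
beef-cattle population (thousands of animals on ~100+ farms with a heavily
skewed herd-size distribution).

It is aimed at quantitative geneticists and animal breeders who want to
test whether modelling herds as correlated changes their variance
components, heritabilities and breeding-value reliabilities.

## The model

Five model forms are supported, all special cases of

```
y = X b + g + Z eta + eps
```

| Model      | Random terms                                  |
|------------|-----------------------------------------------|
| `GRM`      | `g ~ N(0, G sigma_g2)`                        |
| `FARM`     | `eta ~ N(0, I_F sigma_eta2)`                  |
| `GPS`      | `eta ~ N(0, E sigma_eta2)`                    |
| `GRM_FARM` | `g` and independent `eta`                     |
| `GRM_GPS`  | `g` and spatially correlated `eta`            |

with `eps ~ N(0, I_n sigma_e2)` throughout. `X` carries the fixed effects
(intercept, age in months, sex, contemporary-group size), `Z` is the
animal-to-herd incidence matrix, and `G` is the VanRaden genomic
relationship matrix `W W' / (2 sum p_j (1 - p_j))` computed from
QC-filtered SNP dosages.

The herd covariance kernel `E` is built in three steps from the farm
coordinates: (1) the matrix `D` of pairwise WGS84 geodesic distances
(meters, via `geosphere::distGeo`); (2) standardization
`D* = D / max(D)`; (3) `E_ij = 1 - D*_ij`, so coincident farms have
covariance 1 and the farthest pair 0. A Matérn kernel (smoothness `nu`,
range `rho`) is available as an alternative family; with all herds
observed the two give near-identical herd-effect predictions. Because
`1 - D*` is not automatically positive semi-definite, `ensurePSD()`
clips negative eigenvalues and records the repair.

Variance components are estimated by average-information REML (with
guaranteed-ascent fallback steps and explicit zero-boundary handling),
giving per-model heritability `h2 = sigma_g2 / sigma_y2` and
*environmentability* `e2 = sigma_eta2 / sigma_y2`, where `sigma_y2` sums
exactly the components the model includes. Cross-validation repeatedly
holds out 20% of the animals and reports, per replicate and model:

* `r_pgbv = cor(g_tilde, y_test - X_test b_hat)` and
  `r_eta = cor(Z eta_tilde, y_test - X_test b_hat)` — prediction
  accuracies of breeding values and herd effects;
* reliabilities `R2_pgbv = r_pgbv^2 / h2`, `R2_eta = r_eta^2 / e2`;
* phenotype accuracy `r_y = cor(y_tilde, y_test)`.

Models are compared within metric by Tukey's multiple comparison on
Fisher-z-transformed accuracies (square roots of reliabilities first),
with compact-letter groupings. The `kappaStatistic()` diagnostic checks
for confounding between `G` and the animal-level herd structure
`W_eta = Z E Z'`: `kappa_i = U_eta,i' G U_eta,i` is ~1 everywhere when the
structures are unconfounded and aligns with the herd eigenvalues when they
are not.

## Worked example

```r
library(geoherd)

## a population of 500 animals on 40 farms, herd effects correlated by
## the linear GPS kernel; true components (0.3, 0.2, 0.5)
cfg <- simConfig(nAnimals = 500, nSnps = 1000, nFarms = 40,
                 sigmaG2 = 0.3, sigmaEta2 = 0.2, sigmaE2 = 0.5,
                 herdKernel = "linear_gps", seed = 2024)
dat <- simulateHerdData(cfg)

des <- buildDesign(dat$pheno, entityIds(dat$herdKernel))
fit <- remlFit(des, modelSpec("GRM_GPS", dat$grm, dat$herdKernel))
fit
#> ModelFit: GRM_GPS (converged in 6 iterations)
#>   sigma_g2     0.2809  (SE 0.0806)
#>   sigma_eta2   0.2006  (SE 0.1121)
#>   sigma_e2     0.5477  (SE 0.0750)
#>   REML logLik: -672.6434
round(heritability(fit), 3)
#>       h2       e2 sigma_y2
#>    0.273    0.195    1.029
```

The REML estimates sit on top of the generating values, and `h2`/`e2`
recover the simulated variance fractions (0.3 and 0.2 of a total ~1.0).
Cross-validating three model forms on the same replicate splits:

```r
I_F <- identityKernel(entityIds(dat$herdKernel))
specs <- list(GRM      = modelSpec("GRM", dat$grm),
              GRM_FARM = modelSpec("GRM_FARM", dat$grm, I_F),
              GRM_GPS  = modelSpec("GRM_GPS", dat$grm, dat$herdKernel))
cv <- crossValidate(dat, specs, nReps = 10, seed = 1)
subset(summarizeCV(cv), metric %in% c("h2", "R2_pgbv"))
#>   metric    model      mean letters
#>       h2      GRM 0.2788786       a
#>       h2 GRM_FARM 0.2796118       a
#>       h2  GRM_GPS 0.2758566       a
#>  R2_pgbv      GRM 0.1468600       a
#>  R2_pgbv GRM_FARM 0.1378885       a
#>  R2_pgbv  GRM_GPS 0.1468213       a
```

Models sharing a Tukey letter within a metric are statistically
indistinguishable at alpha = 0.05 — at this desk scale and moderate herd
variance the three models agree; the separation grows with the herd
variance fraction (see the methods vignette). Finally, the confounding
diagnostic:

```r
ks <- kappaStatistic(animalHerdCovariance(des$Z, dat$herdKernel), dat$grm)
round(c(mean_kappa = mean(ks$kappa), alignment = ks$alignment), 3)
#> mean_kappa  alignment
#>      0.998     -0.667
```

`kappa ~ 1` everywhere: the genomic and herd covariance structures are not
confounded, so the variance partition between `g` and `eta` is
identifiable.

A command-line wrapper over the same functions lives at
`inst/scripts/geoherd.R` with subcommands `simulate`, `grm`, `kernel`,
`fit`, `cv` and `diagnose`.

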