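---
title: "Modelling herd effects as spatially correlated in GBLUP: methods and design"
author: "geoherd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling herd effects as spatially correlated in GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoherd)
```

## The model and its assumptions

`geoherd` fits the animal model

$$ y = Xb + g + Z\eta + \varepsilon $$

where $y$ is a vector of $n$ phenotypes, $X$ a fixed-effect design,
$g \sim N(0, G\sigma_g^2)$ the additive genomic values with $G$ the
VanRaden genomic relationship matrix, $\eta$ the herd (farm) effects with
incidence $Z$, and $\varepsilon \sim N(0, I_n\sigma_e^2)$. The five
supported model forms (`GRM`, `FARM`, `GPS`, `GRM_FARM`, `GRM_GPS`) are
obtained by including or dropping $g$ and $\eta$ and by choosing the herd
covariance: $I_F$ (herds independent) or a kernel $E$ derived from farm
GPS coordinates (herds correlated). The random terms are mutually
independent; there is no genotype-by-environment interaction term, no
pedigree information, and a single trait is analysed at a time.

The central premise is that farms close in space share unmeasured
environmental drivers (climate, terrain, local management culture), so
the distance between farms can proxy the correlation of their effects.
The package does not try to predict herd effects for *unobserved*
locations — the kernel correlates herds that all have data — which is why
a simple distance transform is an adequate kernel family and no
geostatistical machinery (kriging, SPDE approximations) is included.

## Kernels

**Linear GPS kernel.** From farm coordinates (decimal degrees, WGS84;
note the package fixes the column order as *latitude, longitude* — many
GIS tools use the opposite) the matrix $D$ of pairwise geodesic distances
in meters is computed with `geosphere::distm(fun = distGeo)`, i.e. on the
WGS84 ellipsoid rather than a sphere. Distances are standardized,
$D^* = D/\max(D)$, and the kernel is $E_{ij} = 1 - D^*_{ij}$: diagonal
exactly 1, farthest pair exactly 0, linear decay in between. The
construction is invariant to a uniform rescaling of all distances.

$1 - D^*$ is not guaranteed positive semi-definite. `ensurePSD()` repairs
it by eigenvalue clipping — the nearest PSD matrix in Frobenius norm —
deterministically, and records whether the repair ran and the most
negative eigenvalue found, so the user can see how far from PSD the raw
kernel was. Clipping was preferred over diagonal jitter because it
perturbs the kernel minimally and does not inflate the diagonal.

**Matérn kernel.** `maternKernel()` implements
$K(d) = \frac{2^{1-\nu}}{\Gamma(\nu)}\big(\sqrt{2\nu}\,d/\rho\big)^\nu
K_\nu\big(\sqrt{2\nu}\,d/\rho\big)$ with $K(0)=1$; $\nu = 1/2$ reduces to
the exponential kernel and the test suite checks this closed form to
machine precision. Defaults are $\nu = 3/2$ and $\rho$ = half the maximum
inter-farm distance — a smoothness that gives once-differentiable fields
(a common geostatistical default) and a range on the scale of the study
region. Since no fitted $(\nu, \rho)$ values are prescribed by the kernel
family itself, analyses that use the Matérn family profile $\rho$ over a
grid by REML log-likelihood; the acceptance checks verify that the
best-$\rho$ Matérn fit and the linear-kernel fit produce herd-effect
predictions correlating above 0.95 when all herds are observed.

**Genomic kernel.** `computeGRM()` uses VanRaden's first method,
$G = WW'/(2\sum_j p_j(1-p_j))$ with $W$ the dosage matrix column-centred
by $2p_j$ and $p_j$ estimated from the current sample (no external base
population is assumed). The citation trail for this construction does not
pin down method 1 vs method 2 (the marker-variance-weighted form); method
1 is implemented as the field's default, and method 2 would be a
straightforward variant. Missing dosages are mean-imputed (set to $2p_j$,
i.e. 0 after centring) — standard practice, adequate at the low
missingness rates that survive QC. QC order is deliberate: individuals
with high missingness are removed *first*, then allele frequencies are
recomputed and low-MAF SNPs dropped, because individual removal shifts
the MAFs the second filter uses.

## REML and BLUP numerics

Variance components maximize the restricted likelihood of
$y \sim N(Xb, \sum_k \theta_k A_k + \theta_e I)$ by
**average-information (AI) REML**: Newton steps with the AI matrix
$\mathrm{AI}_{kl} = \tfrac12 y'PA_kPA_lPy$, score
$-\tfrac12[\mathrm{tr}(PA_k) - y'PA_kPy]$, and
$P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$ formed densely once per
iteration (an $O(n^3)$ Cholesky; the package targets desk scale,
$n \lesssim$ a few thousand). AI-REML was chosen over EM or
derivative-free maximization because it converges in a handful of
iterations and its inverse AI matrix yields approximate standard errors
of the estimates.

Three safeguards make the iteration robust:

* **Line search.** A proposed step is accepted only if the restricted
  log-likelihood does not decrease; otherwise it is halved toward the
  current point (up to 15 times). This gives monotone ascent, which the
  raw AI step does not guarantee far from the optimum.
* **Boundary decay.** A component the AI step drives negative is instead
  divided by 10 each iteration (held fixed during that iteration's line
  search), so it reaches the zero boundary geometrically rather than by
  EM's notoriously slow crawl. A singular AI matrix triggers one plain EM
  step ($\theta_k \mathrel{+}= \theta_k^2/n\,[y'PA_kPy -
  \mathrm{tr}(PA_k)]$), which stays in the parameter space.
* **Boundary polish.** After the loop, any component lingering below
  $10^{-3}\,\mathrm{var}(y)$ is tested against the profiled fit with that
  component fixed at 0; the higher restricted likelihood wins. This
  resolves the flat-ridge geometry near the boundary that defeats both
  plain AI and plain EM, and it is what makes the estimates match a
  brute-force Nelder–Mead maximization to three decimals on tiny
  instances (verified in the tests). Components fixed at zero are
  reported with a boundary flag — zero-boundary estimates are one-sided,
  so their SEs are reported as missing rather than pretending normality.

Convergence is declared when the log-likelihood changes by less than
`tol` (default $10^{-6}$) on an unconstrained step; `maxIter` defaults to
200. Starting values split $\mathrm{var}(y)$ equally across components —
crude, but the line search makes the iteration insensitive to this
choice.

BLUPs use the GLS/conditional-expectation form
$\hat g = \sigma_g^2 G P y$, $\hat\eta = \sigma_\eta^2 E Z' P y$, which
is algebraically identical to solving Henderson's mixed-model equations
but never inverts $G$ or $E$ — important because both kernels are
routinely singular (a centred GRM has rank $\le n-1$; the clipped linear
kernel loses rank by construction). The tests verify the identity against
a dense MME inversion at $10^{-8}$.

**Prediction for held-out animals** extends the training BLUPs by the
conditional mean: $\tilde g_{test} = \sigma_g^2 G_{test,train} P\,
y_{train}$, equal to $G_{test,train} G_{train,train}^{-1}\hat g_{train}$
when the training block is invertible but defined regardless. A test
animal's herd effect is its herd's trained BLUP (the split is by animal,
so herds almost always span both sets); a herd with no training records
automatically gets 0 under the identity kernel and the kernel-regression
extension under a correlated kernel, because both fall out of
$\hat\eta = \sigma_\eta^2 E Z'_{train} P y$. The trained BLUP is used
directly rather than re-shrunken — an interpretive choice, documented
here, matching the view that the herd effect is a property of the farm
estimated on training data. The fixed-effect adjustment of test
phenotypes, $y_{test} - X_{test}\hat b$, uses the training-set $\hat b$.

## Heritability, environmentability and the evaluation metrics

$h^2 = \sigma_g^2/\sigma_y^2$ and $e^2 = \sigma_\eta^2/\sigma_y^2$
(*environmentability*), with $\sigma_y^2$ composed from exactly the
components the model includes ($\sigma_g^2 + \sigma_e^2$ for `GRM`,
$\sigma_\eta^2 + \sigma_e^2$ for `FARM`/`GPS`, all three for the combined
models). This composition means a model that omits a real source of
variance absorbs it elsewhere — the mechanism by which ignoring herd
correlation inflates $h^2$, and the reason reliabilities
$R^2 = r^2/h^2$ rise when the correlated-herd model lowers $h^2$ at
unchanged accuracy.

Reliabilities can exceed 1 in finite samples (when $r^2 > \hat h^2$).
They are reported **raw with a flag** rather than silently truncated:
truncation would hide exactly the replicates where the variance fraction
was underestimated. Replicate-level model comparisons use Tukey's
multiple comparison at $\alpha = 0.05$ on Fisher-$z$ transformed
accuracies (reliabilities are square-rooted first); REML heritabilities
are compared untransformed since they are already treated as
approximately normal. The compact-letter display assigns letters to
maximal sets of mutually non-significant models (exact maximal-clique
enumeration — model counts are small), with Tukey–Kramer standard errors
for unequal replicate counts; p-values are cross-checked against
`stats::TukeyHSD` in the tests. Spearman comparisons of predicted
breeding values use average ranks for ties.

Cross-validation defaults to 100 replicates of an 80/20 split by animal.
All model specs in a run see identical splits, which is what makes the
within-replicate Tukey comparison paired and meaningful, and each
replicate's $R^2$ uses that replicate's own training-fit $\hat h^2$, not
a pooled value. Contemporary-group size enters as a fixed covariate
computed from the *full* data rather than recomputed per training split —
the herd's size is treated as a property of the farm, not of the subset
sampled; this is a documented choice, switchable by editing the
phenotype table. A training split in which a fixed-effect column becomes
constant (e.g. one sex absent) is logged and re-drawn.

## The confounding diagnostic

For eigenvectors $U_{\eta,i}$ of the animal-level herd structure
$W_\eta = ZEZ'$ (or $ZZ'$) and the eigenpairs of $G$,

$$ \kappa_i = \sum_j (U_{\eta,i}' U_{G,j})^2 \lambda_{G,j}
           = U_{\eta,i}' \, G \, U_{\eta,i}. $$

If $\kappa \approx 1$ everywhere, the herd structure's directions carry
average genomic variance — no confounding; if $\kappa$ aligns with
$\lambda_\eta$, the two structures concentrate variance in the same
directions and the variance partition is poorly identified. The
completeness identity $\sum_i \kappa_i = \mathrm{tr}(G)$ holds by
orthonormality and is asserted to $10^{-8}$. Within blocks of tied
$\lambda_\eta$ the individual $\kappa_i$ depend on the arbitrary basis of
the eigenspace, so block sums — which are rotation-invariant — are
reported alongside. No numeric confounding threshold is imposed: the
package reports the $(\lambda_\eta, \kappa)$ scatter and the alignment
correlation and leaves the verdict to the analyst.

## The synthetic-data generator

`simulateHerdData()` generates populations with exactly the structure the
models assume, so that estimation and prediction can be tested by
parameter recovery:

* **Genotypes**: per-SNP allele frequencies drawn from a configurable MAF
  law (default uniform on [0.05, 0.5]), dosages Binomial(2, $p_j$) under
  Hardy–Weinberg equilibrium, optional missingness completely at random.
  There is **no linkage disequilibrium, selection or pedigree
  structure** — the GRM of such a panel is the identity plus noise, so
  passing recovery tests demonstrate correctness of the machinery, not
  performance on realistic LD structure.
* **Farms**: coordinates uniform in a configurable lat/lon rectangle
  (default a compact South-Korea-like region, 34.5–38°N, 126.5–129°E).
  Herd sizes follow either a near-uniform law or `"table1_skewed"`: a
  discretized log-normal fitted once, by least squares on bin
  proportions, to a reference herd-size histogram in which a third of
  herds have ≤5 animals and one herd exceeds a thousand. Draws from the
  fitted law reproduce the small-herd bins; the surplus animals needed to
  reach the configured total are allocated with probability proportional
  to size² — the law's body cannot produce the single mega-herd, so the
  surplus belongs in the extreme tail. Every farm keeps at least one
  animal.
* **Phenotypes**: $g$, $\eta$, $\varepsilon$ drawn from their exact
  multivariate normals (eigendecomposition sampling, so PSD-singular
  kernels are fine), fixed effects from age ~ uniform integers 25–35
  months, sex Bernoulli with a steer fraction of 3810/4168, and
  contemporary-group size equal to the realized herd size (the simulator
  treats herd = contemporary group, as the models do). Default
  coefficients (0, 0.05, 0.5, 0.002) give fixed-effect contrasts of the
  same order as the random variation. The realized $g$, $\eta$,
  $\varepsilon$, $X$ and $b$ are retained as simulation truth; they sum
  to $y$ exactly, and the tests assert this to machine precision.

Default variances (0.3, 0.2, 0.5) put $h^2$ and $e^2$ in the ranges
typical of beef carcass traits (~0.2–0.4 and ~0.05–0.5). The
parameter-recovery and variance-reallocation checks run at 1000 animals
on 50 farms with $(\sigma_g^2, \sigma_\eta^2, \sigma_e^2) = (2, 1, 1)$
over 20 independent populations — large enough for stable Monte-Carlo
means, small enough that the whole acceptance run stays within a few
minutes on one CPU; unit tests use a few hundred animals.

## Known limitations

* Dense $O(n^3)$ algebra bounds practical use to a few thousand animals;
  national-scale evaluation would need sparse or preconditioned solvers.
* The linear GPS kernel is a proxy: it captures *that* nearby farms are
  similar, not *why*; measured climate or management covariates would be
  the next step.
* Single-trait only; no single-step (pedigree + genomic) relationships.
* Reliability definitions assume the training-fit $\hat h^2$ is a fair
  variance fraction; when a component sits on the zero boundary the
  corresponding reliability is undefined and recorded as missing.
* The simulator's genotypes carry no LD, so accuracy *levels* from
  simulations should not be read as forecasts for real panels — only the
  contrasts between model forms transfer.
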