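---
title: "Methods: individual-tree response functions from seed-orchard progeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-tree response functions from seed-orchard progeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, the
numerical choices, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The combined protocol

The package chains two classical methodologies:

1. **Pedigree-based genetic evaluation.** Offspring of a clonal seed
   orchard, phenotyped *in situ* on operational afforestation sites, are
   analysed with a bivariate animal model. The pedigree (reconstructed, in
   practice, from molecular markers — reconstruction itself is out of
   scope) links trees within and across sites, which is what makes the
   additive variance separable from the residual.
2. **Response functions.** Each tree's *predicted* performance, rather than
   its raw phenotype, is regressed on planting-site climate. Prediction
   removes the residual noise and places every tree on a common scale, so
   curves can be fitted for entities as small as a half-sib family.

## 2. The animal model

For traits MAI (mean annual increment, height/age, cm/year) and wood
density,

$$ y = Xb + Za + e, \qquad
   \operatorname{var}(a) = G_0 \otimes A, \qquad
   \operatorname{var}(e) = R_0 \otimes I, $$

with one fixed cell mean per trait-by-site combination. Assumptions worth
stating explicitly:

* **No genotype-by-environment term.** The emulated trial reported a
  non-significant interaction; the model omits it, and `gxe_diagnostic()`
  offers an optional likelihood-ratio check (an iid family-by-site
  variance added to a univariate fit; the exact reduced model used in the
  original report is not public, so this formulation is labelled a guess).
* **Unknown parents are unique unrelated non-inbred founders.** External
  (contaminant) pollen donors enter the pedigree as unknown sires with a
  flag on the offspring. This is the standard tabular-method convention;
  pooling contaminants into genetic groups would be an alternative the data
  cannot distinguish at this scale.
* **Missing trait values drop rows, not trees.** A record contributes only
  its observed-trait rows; the residual covariance is conditioned
  accordingly.

**Kronecker orientation.** Vectors are ordered trait-major (all individuals
for trait 1, then trait 2), so `var(a) = G0 ⊗ A` exactly; this is an
implementation convention with no effect on estimates.

### Fitting

REML is maximized by average-information (AI) Newton steps. Parameters are
the log-Cholesky factors of `G0` and `R0` — iterates stay positive
semi-definite by construction and the gradient criterion is applied on this
scale, where it also vanishes as a variance approaches its zero boundary.
Plain AI steps with a PSD projection crawled on near-boundary iterates in
development, so the step is damped Levenberg–Marquardt style (ridge scaled
by the AI diagonal, grown on rejection, shrunk on acceptance) with a trust
region of 3 in the transformed coordinates. Convergence requires a
log-likelihood change below `1e-6` and a transformed-score norm below
`1e-4`; a persistent stall with a non-zero gradient is reported as boundary
convergence with a warning, and exceeding `max_iter` raises an error of
class `reml_nonconvergence` carrying the iteration trace.

Two likelihood engines implement the same criterion:

* **Eigendecomposition path** (complete data — every tree observed for
  every trait, identical fixed-effect structure per trait): one
  decomposition of the phenotyped block of `A` turns every subsequent
  likelihood, score and AI evaluation into O(n) work on 2×2 blocks. The
  default 1,300-tree bivariate fit takes about a second.
* **Dense path** (arbitrary missingness): the full record covariance is
  assembled from per-parameter derivative matrices (`V` is linear in the
  components). Quadratic memory; intended for modest instances.

The suite proves the two paths agree to machine precision on complete data,
that the univariate reduction of the bivariate code reproduces a univariate
fit, that the optimum matches a brute-force likelihood grid, and that the
balanced one-way special case equals the closed-form ANOVA estimator.

### Derived quantities

`h²` and `r_a` carry delta-method standard errors propagated from the
inverse AI matrix (checked against a parametric bootstrap). Site contrasts
are Wald z-tests on differences of MAI cell means with raw p-values — no
multiplicity correction, deliberately mirroring how such trials report the
"fraction significant at α = 0.05".

## 3. Performance and trimming

`PMAI = overall mean + site effect + BV`. The **overall mean is the
unweighted mean of the site cell means** (so site effects sum to zero);
record-weighted averaging is available via `mean_weights = "record"` since
the convention is genuinely ambiguous in the field. The half-sib **family
key is the maternal parent**: seed-orchard progeny are maternal arrays, and
the dam is always identified, whereas ~8% of sires are external and
unknown. Families on fewer than 6 distinct sites are trimmed (configurable
`min_sites`), evening family representation along the gradient; the
operation is idempotent.

## 4. Climate-variable selection

A bagged CART regression forest (written in-package — the target
environment provides no forest implementation) relates per-site mean PMAI
to the climate table. Hyperparameters are fixed and documented: 500 trees,
`mtry = max(1, ⌊p/3⌋)`, minimum node size 2, per-run seed = base + run
index. Two importance measures are recorded — permutation importance (OOB
MSE increase; one permutation per variable per run, drawn from the seeded
stream so a manual re-permutation reproduces the score exactly) and total
node-impurity decrease — plus a recurrence count: how often a variable
ranks in the top 7 over 20 runs (7 mirrors the number of variables the
motivating analysis retained). Collinear variables are grouped by connected
components of the |r| > 0.85 graph; the gradient variable is the most
recurrent member of the block containing the top-recurrence variable, ties
broken by permutation importance. The "share of variability explained" by
the gradient alone is reported as the OOB R² of a single-variable forest —
one specific operationalization of a loosely defined field statistic, and
labelled as such.

## 5. Response functions

The quadratic `v = β0 + β1 c + β2 c²` is fitted by OLS on centred/scaled
`c` and back-transformed, so the vertex is invariant to affine rescaling of
the climate axis (tested to 1e-8). Adjusted R² uses `1−(1−R²)(n−1)/(n−k)`;
the p-value is the overall F-test (per-coefficient tests are computable but
not used for selection — the curvature-term test would be the alternative
reading of a per-family p-value). Alternatives: linear OLS, and a Gaussian
`A·exp(−(c−m)²/(2s²))` by `nls` (port algorithm) initialized from the
quadratic's vertex and curvature; Gaussian non-convergence is flagged with
`AIC = +Inf` rather than an error. Model comparison uses
`AIC = n·log(RSS/n) + 2(k+1)` (Gaussian-likelihood constant omitted — it
cancels on identical data, which `compare_models()` verifies via a stored
data signature); exact ties break toward the simpler family in the order
linear < quadratic < gaussian.

**"Individual-level" curves are realized at the half-sib family level**: a
per-tree curve is not identifiable from one observation per tree, while a
family ties siblings together across sites. Fits use individual PMAIs (one
point per tree), matching the boxplot-per-site presentation of such
analyses; `site_means = TRUE` fits per-site family means instead.

## 6. The synthetic world

The generator's defaults are a stated world, fixed once:

| parameter | default | why |
|---|---|---|
| parents / sites / offspring | 53 / 21 / 62·21 ≈ 1,302 | the emulated trial's design (genotyped subset) |
| contamination rate | 0.084 | reported external-pollen fraction |
| stand ages | 25–37 y, recycled over sites | reported range |
| MTCM range | −4…0 °C | Alpine-to-lowland winter gradient |
| `G0` diag | 6.3, 0.30 | gives h² = 0.27 / 0.30 with `R0` diag 17.0, 0.70; σ_a(MAI) ≈ 2.5 cm/yr matches the reported parental BV range (−5…6.4) |
| `G0` off-diag | 0.1237 | r_a = 0.09 |
| `R0` off-diag | 0.345 | residual correlation 0.1 — unreported; chosen small and positive |
| population curve | (40.8, −22, −5) | vertex exactly (−2.2 °C, 65 cm/yr) |
| density scale | mean 10, dimensionless | measurement method and units unreported |
| climate noise sd | 0.35 | keeps the 7-variable winter block above |r| = 0.85 |
| decoys | 5 precipitation-like noise variables | exercises the selection stage |

Draw order is documented and single-seeded: pedigree → climate → breeding
values → residuals. Offspring BVs follow `½(BV_sire + BV_dam)` plus a
Mendelian deviation with covariance `½G0` (¾`G0` when a parent is unknown —
the variance an unrelated-founder convention implies). True site effects
lie exactly on the configured quadratic; all noise enters through `a` and
`e`.

An optional `family_optimum_range` gives each maternal family its own
quadratic optimum, evenly spaced over the range (implemented as a per-family
`β1` shift vanishing at the population optimum). This contradicts the
default no-GxE world and exists solely to test whether family-level curve
fitting can rank families by their true optima; it is off by default.

**What a green test does not establish.** The simulator omits spatial
autocorrelation within stands, mortality and selective thinning,
pedigree-reconstruction errors, age-by-site confounding beyond the assigned
ages, and non-quadratic response shapes. Parameter recovery on this world
validates the estimation machinery, not the biological adequacy of the
quadratic model — which field studies themselves treat as a convenient
approximation with a physiologically implausible sharp drop beyond the
optimum.

## 7. Known limitations

* The dense REML path is O(n²) memory and meant for hundreds, not tens of
  thousands, of records; sparse A-inverse machinery (Henderson's rules) is
  deliberately out of scope at desk scale.
* Heritability SEs rely on asymptotic REML theory; on tiny instances (a
  handful of families) estimates can sit on the variance boundary, where
  SEs and the genetic correlation are ill-defined (the code flags these).
* The forest importance ranking operates on ~21 site-level observations;
  it discriminates a strong collinear block from noise, which is all the
  protocol requires of it.
* Contaminant pollen is modelled as fully unknown; with marker data one
  could instead fit genetic groups.
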