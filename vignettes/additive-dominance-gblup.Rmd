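---
title: "Decomposing additive and dominance genetic control with GBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing additive and dominance genetic control with GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblupad)
```

## The problem

Breeding programs for non-domesticated perennials — the motivating case is
the juçara palm, *Euterpe edulis*, evaluated for fruit-production traits —
often work with natural populations of unknown pedigree. Without a
genealogy the classical kinship matrix is unavailable, so pedigree BLUP
degenerates to an identity-kinship model in which individuals are treated
as unrelated: variance components are still estimable from repeated
records, but no information flows between individuals and untested
genotypes cannot be predicted. Genome-wide SNP markers replace the missing
pedigree with realized relationships and, beyond that, allow the genetic
variance to be split into additive and dominance parts — something a
pedigree from a random-mating population of unknown parents could not
support.

`gblupad` implements this analysis end to end: marker QC, the additive and
dominance genomic relationship matrices, REML estimation of multi-kernel
mixed models on unbalanced multi-year phenotypes, derived genetic
parameters, model comparison, and cross-validated predictive ability. A
synthetic-data generator with known truth makes every stage testable.

## Models

For one trait, records $y$ over several years are modeled as

$$y = X\beta + Z_1 g + Z_2 d + \varepsilon,$$

where $X$ is the incidence of the year factor (cell means: one parameter
per observed year, no intercept), $Z$ maps records to individuals (repeated
records of an individual share one genetic effect; there is no
permanent-environment or genotype-by-year term), and

* **BLUP**: a single genetic term with identity kinship,
  $a \sim N(0, I\sigma^2_a)$;
* **GBLUP-A**: $g \sim N(0, G\sigma^2_a)$ with the VanRaden matrix
  $G = WW'/\sum_j 2p_jq_j$, where column $j$ of $W$ is the dosage centered
  by $2p_j$;
* **GBLUP-AD**: adds $d \sim N(0, D\sigma^2_d)$ with the Vitezica matrix
  $D = SS'/(4\sum_j (p_jq_j)^2)$, where $S$ codes genotype classes
  $\{2, 1, 0\}$ as $\{-2q_j^2,\; 2p_jq_j,\; -2p_j^2\}$.

Both kernels use allele frequencies recomputed on the post-QC panel. Under
these scalings the mean diagonal of $G$ and $D$ is near 1 for an
unstructured panel, so $\sigma^2_a$ and $\sigma^2_d$ are on the trait
scale.

Derived parameters follow directly from the estimated components:
$h^2 = \sigma^2_a/\sigma^2_P$, $H^2 = (\sigma^2_a+\sigma^2_d)/\sigma^2_P$,
$d^2 = \sigma^2_d/\sigma^2_P$ with
$\sigma^2_P = \sigma^2_a+\sigma^2_d+\sigma^2_e$;
$RL_{aa} = \sigma^2_{a(AD)}/\sigma^2_{a(A)}$ compares the additive variance
with and without dominance in the model (values well below 1 mean the
additive-only model absorbed dominance); and the theoretical accuracy is
$r = \sqrt{1 - \mathrm{PEV}/\sigma^2_g}$.

## Estimation

Variance components are estimated by average-information REML. Each
likelihood evaluation is reduced from record level ($N$) to individual
level ($q$) with the Woodbury identity
$V^{-1} = (I - ZM^{-1}\Gamma Z')/\sigma^2_e$ and Sylvester's determinant
identity $\log|V| = (N-q)\log\sigma^2_e + \log|M|$, where
$\Gamma = \sum_k \sigma^2_k K_k$ and
$M = \sigma^2_e I + \Gamma Z'Z$. Scores and the average-information matrix
are likewise assembled from $q \times q$ products. Nothing in this path
inverts a kernel, so the (typically singular) $G$ and $D$ are handled
exactly; a diagonal jitter is applied only as a retry when a factorization
fails, never to reported matrices.

Numerical choices:

* **Constraints and boundaries.** Components are constrained non-negative.
  A component that reaches the floor ($10^{-8}\,\mathrm{var}(y)$) with an
  outward-pointing score is pinned (active set) and released if its score
  turns positive; pinned genetic components are reported as exactly 0 with
  a `boundary` flag. A dominance variance of exactly zero is a legitimate
  estimate, not a failure.
* **Updates.** AI steps with step halving (up to 30 halvings, accepting
  only non-decreasing restricted likelihood); an EM-style update is the
  fallback when the AI system is singular. Convergence requires relative
  likelihood change $< 10^{-8}$ and relative component change
  $< 10^{-6}$; non-convergence returns an honest `converged = FALSE`.
* **Constant convention.** The restricted likelihood includes the
  $(N - p)\log 2\pi$ constant, matching `lme4`, so likelihood differences
  (LRT, AIC) are convention-free.
* **Solutions and PEV.** At the optimum, fixed and random solutions are the
  mixed-model-equation solutions obtained kernel-side
  ($\hat u_k = \sigma^2_k K_k Z'Py$), and the per-individual PEV comes from
  the equivalent identity
  $\mathrm{PEV}_k = \sigma^2_k K_k - \sigma^4_k K_k Z'PZ\, K_k$ (diagonal),
  again without $K^{-1}$. Tests verify these against Henderson's equations
  and against a dense-formula likelihood oracle.

## Reporting conventions

Several reporting details are genuinely open choices; the package fixes
them as follows and treats them as part of its definition:

* **$k$ in AIC/BIC** counts only the fixed-effect parameters (the year
  levels), not the variance components:
  $\mathrm{AIC} = 2k - 2LL$, $\mathrm{BIC} = -2LL + k\log v$ with
  $v = N - \mathrm{rank}(X)$. This is non-standard but is the convention
  used by the published analyses this package validates against, and since
  every model for a trait shares the same fixed structure it does not
  change model rankings within a trait.
* **Scalar PEV** per trait and model is the mean over individuals of the
  PEV of the *total* genetic value ($g+d$ for GBLUP-AD, cross-covariances
  included). The published tables print one PEV per trait without defining
  the aggregation; the mean is the default here.
* **$\sigma^2_g$ in the accuracy formula** is the model's total genetic
  variance: $\sigma^2_a$ for single-kernel models,
  $\sigma^2_a + \sigma^2_d$ for GBLUP-AD. If $\mathrm{PEV} > \sigma^2_g$
  the accuracy is clipped to 0 with a warning.
* **Dominance LRT** uses the statistic $2(LL_{AD} - LL_A)$ clipped at zero
  and the boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, i.e.
  $p = \tfrac12 P(\chi^2_1 \ge t)$ (0.5 at $t = 0$). A simulation test at
  the null confirms the 5% size within binomial error.
* **Missing dosages in $S$.** The dominance coding is class-based, so mean
  imputation has no meaning there. $S$ is built from the pre-imputation
  matrix with missing cells coded 0 — the Hardy–Weinberg expectation of
  the centered code — and the count is reported. Post-QC (call rate
  $\ge$ 90%) such cells are rare.
* **Orientation.** Dosage counts the allele with frequency $p$; the
  dosage-0 homozygote gets $S$ code $-2p^2$. $G$ and $D$ are invariant to
  flipping which allele is counted (verified by test), so this choice only
  fixes signs in $W$ and $S$.

## Cross-validation

Folds partition *genotypes* (all years of a genotype are masked together,
preventing leakage across years); 275 genotypes in 5 folds give the
classical 220/55 split. Variance components are re-estimated on each
training set (configurable in principle, but per-fold refit is the
default because it is the honest protocol). Masked individuals are
predicted through the kernel from the joint solutions — equivalently the
conditional expectation given the training BLUPs. Predictive ability is
the per-fold Pearson correlation between predictions and each validation
genotype's across-year phenotype mean, averaged over folds, with the
standard error $\mathrm{sd}/\sqrt{k}$. Identity-kernel BLUP transfers no
information to masked individuals, so its predictions are constant; such
folds score $r = 0$ by convention rather than `NA`, which reproduces the
expected zero predictive ability of pedigree-free BLUP.

## The synthetic-data generator

`sim_config()` defaults emulate the motivating study population: 275
genotypes, 8,112 post-QC SNPs with counted-allele frequencies uniform on
[0.05, 0.5], 2% missing calls, variance components
$(\sigma^2_a, \sigma^2_d, \sigma^2_e) = (0.39, 0.62, 1.27)$ (the
fruit-weight-per-bunch decomposition), year means 3.05/3.45/3.68 for
2018/2019/2021, and a per-year inclusion probability of 0.8 to mimic the
unbalancedness of field phenotyping (the published record counts per trait
are not stated; 0.8 is consistent with the degrees of freedom implied by
the published information criteria).

Genotypes are drawn per marker as Binomial(2, $p_j$) — Hardy–Weinberg
equilibrium with free recombination. Marker effects are i.i.d. normal with
variances $\sigma^2_a/\sum 2p_jq_j$ and $\sigma^2_d/(4\sum(p_jq_j)^2)$ and
act through the same $W$/$S$ codings the kernels use (with realized
frequencies), so the configured variances are exactly the REML estimands
on the realized panel — this is what makes parameter recovery a valid
test. Phenotypes add the year effect and i.i.d. residuals.

What the generator does **not** emulate: linkage disequilibrium, population
structure and relatedness, selection, genotype-by-year interaction,
non-MCAR missingness, and genotyping error. Passing recovery tests on this
generator therefore validates the estimation machinery under the model's
own assumptions; it does not certify behavior under model misspecification
on real data.

## Validation problem sizes

The test suite exercises, among others: parameter recovery at $n = 500$
individuals, $m = 2000$ markers, truth $(0.4, 0.2, 0.4)$, 30 replicates
(mean estimates within 3 Monte-Carlo standard errors; additive-only
$\hat\sigma^2_a$ inflated relative to GBLUP-AD in the majority of
replicates); LRT size at the null with 200 replicates of $n = 300$,
$m = 1000$; dominance-advantage cross-validation at $n = 250$, $m = 800$
with $d^2 = 0.25$ over 15 replicates; and exact-arithmetic reproduction of
the published derived-parameter tables to one unit in the last printed
decimal. Oracles are independent implementations: a dense-formula
restricted likelihood, brute-force double-loop kernels, ridge-regression
marker solutions, and `lme4` for the identity-kernel special case.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 150, n_markers = 600, seed = 42,
                  trait = "FWB")
dat <- simulate_dataset(cfg)

res <- run_analysis(dat$genotypes, dat$phenotypes, cv_k = 5, seed = 1)
res$components        # variance components, h2, H2 per model
res$dominance_ratios  # d2 and RL_aa
res$fit_criteria      # PEV, r, LL, AIC, BIC
res$lrt               # boundary-corrected dominance test
res$cv                # per-fold and mean predictive ability
```

## Limitations

* Single-trait analyses only; no genetic correlations.
* No genotype-by-environment interaction or spatial terms.
* The AIC/BIC parameter count is the fixed-effects convention described
  above; compare with other software accordingly.
* Standard errors of heritabilities are not computed.
* The dense individual-level algebra targets populations up to a few
  thousand genotypes; it is not engineered for biobank scale.
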