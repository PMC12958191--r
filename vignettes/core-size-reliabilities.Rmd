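---
title: "Core size and approximated reliabilities in single-step GBLUP with APY"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core size and approximated reliabilities in single-step GBLUP with APY}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apycore)
```

## The problem

Genetic evaluation programs report, next to each genomic estimated breeding
value (GEBV), its reliability — the squared correlation between true and
estimated breeding value. For a single-trait animal model the reliability of
animal $i$ is

$$\mathrm{rel}_i \;=\; 1 - \frac{\mathrm{PEV}_i}{\sigma_a^2\,(1+F_i)},
\qquad \mathrm{PEV}_i = \sigma_e^2\,[\mathbf{C}^{-1}]_{ii},$$

where $\mathbf{C}$ is the coefficient matrix of Henderson's mixed model
equations (MME) and $F_i$ the pedigree inbreeding coefficient. Direct
inversion of $\mathbf{C}$ is only feasible for small systems; national
single-step GBLUP (ssGBLUP) evaluations with millions of genotyped animals
must approximate reliabilities instead. The approximation studied here works
on the genotyped subset through the APY ("algorithm for proven and young")
sparse inverse of the genomic relationship matrix $\mathbf{G}$, and its cost
is quadratic in the number of *core* animals $n_c$ and linear in the number
of *noncore* animals $n_n$. The package implements, at a desk scale where
every stage can be verified against exact dense computation, the question:
**how much can the APY core be shrunk before the approximated reliabilities
drift away from the benchmark?**

## Models and algorithms

### Relationship matrices

* Pedigree: tabular-method $\mathbf{A}$, inbreeding $F = \mathrm{diag}(\mathbf{A})-1$,
  and the sparse $\mathbf{A}^{-1}$ from Henderson's parent-contribution rules
  with Mendelian sampling variances $d_i = 0.5 - 0.25(F_s + F_d)$ (one-parent
  and founder variants included). The tabular method is exact and doubles as
  the oracle in the tests; it is $O(n^2)$ in memory and intended for desk-scale
  pedigrees (thousands of animals).
* Genomic: $\mathbf{G}_0 = \mathbf{W}\mathbf{W}' / \big(2\sum_j p_j(1-p_j)\big)$
  with $\mathbf{W}$ the gene-content matrix column-centered at the observed
  allele frequencies, blended as
  $\mathbf{G} = \alpha \mathbf{G}_0 + (1-\alpha)\mathbf{A}_{22}$
  (default $\alpha = 0.95$). Monomorphic loci carry no information and are
  dropped with a warning. No mean/scale tuning of G to A22 is applied — the
  blend alone guarantees positive definiteness at these scales.
* Combined: $\mathbf{H}^{-1} = \mathbf{A}^{-1} +
  \begin{bmatrix} 0 & 0 \\ 0 & \tau\mathbf{G}^{-1} - \omega\mathbf{A}_{22}^{-1}\end{bmatrix}$,
  with $\tau = \omega = 1$ by default. With $\mathbf{G} = \mathbf{A}_{22}$ the
  genomic term cancels exactly and pedigree BLUP is recovered — a property the
  test suite asserts to $10^{-8}$.

### APY inverse

Noncore breeding values are conditioned on the core:
$u_n = \mathbf{G}_{nc}\mathbf{G}_{cc}^{-1}u_c + \varepsilon$ with independent
conditional residuals $\mathrm{Var}(\varepsilon_i) = m_{nn,i} =
g_{ii} - \mathbf{g}_{ic}\mathbf{G}_{cc}^{-1}\mathbf{g}_{ci}$. The resulting
inverse has a dense $n_c \times n_c$ core block, dense cross blocks, and a
*diagonal* noncore block — $n_c^2 + 2n_cn_n + n_n$ structural nonzeros. When
the core is the whole genotyped set the APY inverse equals $\mathbf{G}^{-1}$
exactly. The core block is Cholesky-factorized once; a reciprocal-condition
estimate below $10^{-12}$ or a non-positive $m_{nn,i}$ raises an error naming
the animal, because silent near-singularity corrupts every downstream
quantity.

### Core sizing and nested reduction

The benchmark core size is the number of leading eigenvalues of the GRM
(squared singular values of centered $\mathbf{W}$) explaining a target
fraction of variance (default 0.99). The SVD is taken of centered
$\mathbf{W}$, not raw gene content: the raw matrix's spectrum is dominated by
allele-frequency means and does not measure relationship variance. The study
schedule reduces this size through fractions
$\{1, 0.8, 0.6, 0.4, 0.2\}$, mirroring a 25k → 5k published schedule
proportionally. Cores are nested by construction: the largest is drawn
uniformly from the genotyped animals and each smaller core uniformly from the
next larger, so the smallest core's animals belong to every larger core.
Genotyped animals are then classified per comparison as R-core (retained),
F-core (formerly core, dropped by the reduction) and N-core (never core).

### Exact reliabilities

At desk scale the MME coefficient matrix (fixed effects first, then one
equation per animal, phenotyped or not) is inverted through a dense Cholesky
factorization (capped at 20,000 equations) and
$\mathrm{PEV}_i = \sigma_e^2 [\mathbf{C}^{-1}]_{ii}$. The reliability
denominator is $\sigma_a^2(1+F_i)$ with pedigree $F$, applied identically to
exact and approximated flavors so that all comparisons are internally
coherent. A rank-deficient fixed-effect block falls back to a Moore–Penrose
generalized inverse with a warning (breeding values and PEVs are invariant to
the choice of constraint).

### The reliability approximation

The approximation never builds the genotyped block of the MME. Its stages:

1. **Pedigree stage.** Exact pedigree-only reliabilities for all animals
   (at production scale this stage is itself approximated; computing it
   exactly here deliberately isolates the APY-core effects, which are the
   object of study).
2. **Reverse reliability.** Each genotyped animal's reliability is converted
   to the effective number of own records that would reproduce it in
   isolation: $d_i = \lambda\,\mathrm{rel}_i/(1-\mathrm{rel}_i)$ with
   $\lambda = \sigma_e^2/\sigma_a^2$. Reliabilities are capped at
   $1 - 10^{-6}$ so weights stay finite.
3. **Genomic pooling.** The weights enter
   $\mathbf{K} = \lambda\,\mathbf{G}_{\mathrm{APY}}^{-1} + \mathbf{D}$ and only
   $\mathrm{diag}(\mathbf{K}^{-1})$ is needed. Block-sparse inversion
   exploits APY's pattern: step A forms the Schur complement
   $\mathbf{S} = \mathbf{K}_{cc} - \mathbf{K}_{cn}\mathbf{K}_{nn}^{-1}\mathbf{K}_{nc}$
   (cost $\propto n_c^2 n_n$, the first of the two expensive products);
   $\mathbf{S}$ is densely inverted; step B forms
   $\mathbf{V} = \mathbf{S}^{-1}\mathbf{K}_{cn}$ and the noncore diagonal
   $1/k_{ii} + \mathbf{k}_{ci}'\mathbf{v}_i / k_{ii}^2$. These diagonals
   convert to *genomic reliabilities*.
4. **Propagation.** The genomic gain becomes a pseudo-record weight
   $\Delta_i = \max\!\big(0,\; d(\mathrm{rel}^G_i) - d(\mathrm{rel}^{A22}_i)\big)$
   added to animal $i$'s diagonal in the pedigree-only coefficient matrix;
   reliabilities for *all* animals — genotyped and not — are recomputed from
   the updated system's inverse diagonal.

Two design choices in stages 3–4 deserve justification, because the
published description of this algorithm family does not fix them:

* **Double-counting baseline.** The subtracted baseline
  $\mathrm{rel}^{A22}$ is *the same pooling computed with pedigree
  relationships*: $\mathrm{diag}\big((\lambda\mathbf{A}_{22}^{-1} +
  \mathbf{D})^{-1}\big)$ converted to reliabilities. Information that flows
  between genotyped relatives through $\mathbf{A}_{22}$ as well as through
  $\mathbf{G}$ then cancels — the same cancellation
  $\tau\mathbf{G}^{-1} - \omega\mathbf{A}_{22}^{-1}$ performs inside
  $\mathbf{H}^{-1}$. The simpler alternative of subtracting each animal's own
  pedigree reliability (available via `baseline_rel = NULL`) double counts
  family information that reaches an animal through both matrices: on the
  desk-scale study conditions it inflates the mean effective-record gain by a
  factor of about 2.4 and drops the correlation with exact MME reliabilities
  from ~0.98 to ~0.85.
* **Denominator convention.** `genomic_reliabilities()` defaults to the GBLUP
  convention $\mathrm{rel}^G_i = 1 - \lambda[\mathbf{K}^{-1}]_{ii}/g_{ii}$.
  The experiment pipeline passes `denominator = 1 + F` instead, so every
  stage shares the pedigree base-variance convention; mixing $g_{ii}$ in the
  genomic stage with $1+F_i$ elsewhere leaks the sampling variation of
  $\mathrm{diag}(\mathbf{G})$ straight into $\Delta$.

### Randomized matrix multiplication

The sketched variant replaces the step-A product (inner dimension $n_n$) by
uniform column sampling without replacement with importance rescaling
$n_n/k$: an unbiased estimator that is exact at $k = n_n$, reducing the cost
from $O(n_c^2 n_n)$ to $O(n_c^2 k)$; step B then consumes the sketched Schur
factor. (The second expensive product has inner dimension $n_c$, so sampling
over the noncore dimension cannot be applied to it directly.) Column sampling
was chosen over Gaussian projection precisely because $k = n_n$ recovers the
exact product, giving a clean correctness anchor. On the default synthetic
population, sketching at $k = 0.5\,n_n$ collapses the correlation between
sketched and exact-path approximated reliabilities to roughly 0.1–0.35 —
the approximation becomes unusable even though the estimator is unbiased,
because the Schur complement is the *difference* of two large matrices and
sampling noise survives the subtraction.

## The synthetic population

No producer data can be redistributed, so the generator emulates the
statistical structure the method cares about:

* **Pedigree**: `n_founders` unrelated founders plus `n_generations` of
  random mating (pairs drawn without replacement per generation,
  `offspring_per_dam` offspring each), giving overlapping families, inbreeding
  accumulation and a progeny-count distribution.
* **Genotypes**: per-locus founder allele frequencies uniform on `maf_range`
  (emulating MAF-filtered SNP panels), Mendelian gene dropping to descendants;
  unknown parents contribute founder-frequency draws.
* **Phenotypes**: additive animal model $y = \mu + u + e$ with $u = \mathbf{W}a$
  rescaled so the realized additive variance is $h^2$ of a unit total. In
  `binary_1_2` mode the liability is thresholded at the quantile giving the
  target incidence and coded 1/2, and — as in the motivating application — the
  coded values are analyzed with the *linear* model.

Defaults are the study's conditions: about 2,000 pedigree animals
(400 founders, 4 generations), 800 genotyped (40%), 1,000 SNPs,
$h^2 = 0.042$ with binary coding at incidence 0.2 and records on 60% of
animals; the sensitivity setting is $h^2 = 0.30$ (run with a continuous
trait, to separate approximation fidelity from threshold-coding noise). At
this scale the 99%-variance core is roughly 600–650 of 800 genotyped
animals, so the noncore:core ratio is small (~0.3) — the regime of the
*reduced* dataset in the motivating study, whose benchmark ratio was 0.4,
rather than the complete dataset's 64.2.

What the generator does **not** emulate: selection and assortative mating,
genotyping-by-merit bias, overlapping generations, unknown-parent groups,
herd structure beyond one optional categorical fixed effect, and linkage
(loci are dropped independently). Passing tests therefore demonstrate the
algebra and the qualitative core-size behavior, not calibration to any real
cattle population — in particular, with a small noncore:core ratio the
absolute deviations here are closer to the published reduced-dataset table
than to the complete-dataset one.

## Numerical choices

* Mendelian sampling variances from exact tabular inbreeding; no
  approximation of $F$.
* Core Cholesky with reciprocal-condition guard $10^{-12}$; conditional
  variances must exceed $10^{-10}$.
* Reliability cap $1 - 10^{-6}$ before reverse-reliability conversion.
* Dense diag-of-inverse capped at 20,000 equations; beyond that the package
  refuses rather than silently approximating.
* Negative PEV beyond $-10^{-8}$ aborts (assembly bug), small negatives are
  clipped to 0; reliabilities clipped to $[0,1]$.
* MD is `mean(benchmark − candidate)`, and the regression is of the
  benchmark (response) on the candidate (predictor), so overestimation by a
  reduced core shows as negative MD. Ties in OLS with a zero-variance
  candidate are reported as flagged NAs rather than NaNs.
* Fraction-to-count rounding everywhere: `floor(fraction * n)`, minimum 1.

## Problem sizes and replication

The default experiment runs 5 replicate populations (seeds
`sim$seed + 0:4`) of the desk-scale configuration above; statistics of
stochastic properties are asserted on replicate means, mirroring the
replication practice of the motivating study. A full default run takes well
under a minute per replicate on one CPU; all tests and the acceptance script
together stay within a few minutes.

## Known limitations

* The pedigree stage of the approximation is computed exactly, so the
  measured approximation error is attributable to the genomic stage alone;
  production systems approximate the pedigree stage too and will be worse.
* The propagation updates only animal-equation diagonals; fixed-effect
  equations are untouched by pseudo-records.
* Binary traits are analyzed on the observed scale with a linear model (the
  motivating application's choice); no threshold model is provided.
* The tabular pedigree machinery is dense and desk-scale by design.
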