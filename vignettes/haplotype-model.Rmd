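---
title: "The multi-allelic haplotype model: partition, relationships, prediction and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multi-allelic haplotype model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopart)
```

## The model

A haplotype block — a set of tightly linked SNPs — is treated as one locus,
and each distinct phased allele string within it as one allele. A block with
h haplotypes is therefore a multi-allelic locus, and everything classical
quantitative genetics says about a locus applies: under Hardy-Weinberg
equilibrium (HWE), the genotypic value $g_{ij}$ of the unordered genotype
carrying haplotypes $i$ and $j$ partitions as

$$g_{ij} = \mu + a_{ij} + d_{ij},$$

where $\mu$ is the population mean, $a_{ij}$ the breeding value (the sum of
the two allelic effects, the transmissible part) and $d_{ij}$ the dominance
deviation. With allele frequencies $p_i$ and allelic means
$\mu_i = \sum_j p_j g_{ij}$, the $h-1$ independent additive effects against
the most frequent ("reference") allele are
$\alpha_{1k} = \mu_1 - \mu_k$, and the dominance effect of a heterozygote is
$\delta_{kf} = g_{kf} - \tfrac12(g_{kk} + g_{ff})$. A homozygote has no
dominance *effect* but generally a nonzero dominance *value*; the number of
dominance effects equals the number of heterozygous genotypes.

The package's starting point is the closed-form factorization of both value
vectors into coding matrices times effect vectors,
$a = W_\alpha \alpha$ and $d = W_\delta \delta$. The additive coding of
genotype $(i,j)$ for effect allele $k$ is $2p_k$, $-(1-2p_k)$ or
$-2(1-p_k)$ according to whether the genotype carries 0, 1 or 2 copies of
$k$; the dominance coding of $(i,j)$ for effect pair $(k,f)$ has five cases
by allele sharing (two shared; one shared with $i \ne j$, in two symmetric
forms; one shared with $i = j$; none shared). `partition_locus()` computes
the partition both directly from allelic means and through
$W_\alpha \alpha$ / $W_\delta \delta$ and verifies on every call that the
two routes agree — the factorization identity is checked, not assumed.
At $h = 2$ the codes collapse to the familiar bi-allelic SNP codes, so
single-SNP additive/dominance GBLUP is the special case `snp_coding()`.

HWE second moments give the variance partition
$\sigma_g^2 = \sigma_a^2 + \sigma_d^2$, computed as frequency-weighted
second moments of the value vectors.

## Relationship matrices

Stacking one coding row per individual over all blocks gives genome-wide
$W_\alpha$ ($q \times n_\alpha$, $n_\alpha = \sum_i h_i - r$ over $r$
blocks) and $W_\delta$ ($q \times n_\delta$, one column per heterozygote
pair observed in the training population). Scaling by the mean diagonal of
$WW'$, $T = W/\sqrt{k}$, yields relationship matrices
$A = T_\alpha T_\alpha'$ and $D = T_\delta T_\delta'$ whose diagonal
averages exactly 1 by construction. For many unlinked single-SNP loci these
behave like twice the coancestry: mean additive relationship 0.5 for
parent-offspring and full sibs, 0.25 for half sibs, 0 for unrelated pairs;
mean dominance relationship 0.25 for full sibs and 0 otherwise — the package
verifies these on simulated Mendelian pedigrees. For haplotype blocks the
relationships shrink below the single-locus expectations as blocks grow
(haplotype identity requires the whole string to match), so haplotype
relationship matrices are a prediction device, not a kinship estimator.

## Two equivalent solving routes

With phenotypes $y = Xb + Z\sum_i u_i + e$, $u_i = T_i\tau_i$,
$\mathrm{Var}(\tau_i) = \sigma_i^2 I$, $\mathrm{Var}(e) = \sigma_e^2 I$,
the same model can be solved two ways:

- **CE** (conditional expectation): through
  $V = Z(\sum_i \sigma_i^2 S_i)Z' + \sigma_e^2 I$ with $S_i = T_iT_i'$;
  fixed effects by generalized least squares,
  $\hat u_i = \sigma_i^2 S_i Z' P y = S_i \varepsilon_i$ with the regressed
  phenotypes $\varepsilon_i$. No relationship matrix is inverted, so
  singular $S_i$ are fine. The largest object is $q \times q$ — best when
  individuals are few relative to effects.
- **QM** (mixed-model equations): Henderson equations at the effect level
  with ridge blocks $\lambda_i I = (\sigma_e^2/\sigma_i^2) I$, then
  $\hat u_i = T_i\hat\tau_i$. The largest object is
  $(c + n_\alpha + n_\delta)$-square — best when effects are few.

The two give identical $\hat b$ and $\hat u_i$; `gblup(method = "auto")`
picks by comparing $q$ with $c + n_\alpha + n_\delta$. Validation
individuals are predicted either as $S_{01}\varepsilon_i$ (training-validation
relationship block) or as $T_0\hat\tau_i$ (validation coding against the
training catalog); the routes again agree, and the equivalence is exercised
across random datasets in the test suite to $10^{-6}$ relative tolerance.

Variance components are estimated by EM-type REML in both routes: the CE
updates multiply each component by
$y'PZS_iZ'Py / \mathrm{tr}(PZS_iZ')$ (and $\sigma_e^2$ by
$y'PPy/\mathrm{tr}(P)$), whose fixed point solves the REML score equations;
the QM updates are $\hat\tau_i'\hat\tau_i/[t_i - \lambda_i\,
\mathrm{tr}(C^{ii})]$ with $C^{ii}$ the diagonal blocks of the inverse
coefficient matrix after absorbing fixed effects, and
$\hat e'\hat e / \{N - [r - \sum_i \mathrm{tr}(C^{ii})\lambda_i]\}$ for the
residual, with $r$ the rank of the full coefficient matrix. The two update
sequences are algebraically identical, which the tests confirm
per-iteration to $10^{-8}$. One deliberate reading: the effect-count
denominator of the component update uses $t_i$, the number of effects of
term $i$ — the count that makes the update correct for haplotype terms as
well as for SNP terms (for which it equals the marker count). Multiplicative
updates from positive starts keep every component nonnegative; EM is slow
but dependable, and no attempt is made at faster average-information
schemes.

From a converged fit, $h_i^2 = \sigma_i^2/\sigma_y^2$ with
$\sigma_y^2 = \sum_i \sigma_i^2 + \sigma_e^2$, $H^2 = \sum_i h_i^2$, and the
effect-level route additionally yields per-block heritabilities
$h_{ij}^2 = (\hat\tau_{ij}'\hat\tau_{ij}/\hat\tau_i'\hat\tau_i)\,h_i^2$,
whose shares sum to $h_i^2$ exactly.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| block rule | — | exactly one of `n_snps` (SNPs per block), `block_length` (bp), or BED intervals |
| `ref_allele` | most frequent | reference allele per block; ties broken by the lexicographically first haplotype string |
| haplotype frequencies | training-sample counts / 2q | used in all codings; can be supplied explicitly |
| `sigma2`, `sigma2_e` | — | variance components for GBLUP (estimate with `greml()`) |
| `greml_control(tol)` | 1e-8 | max relative change of any component between EM iterations |
| `greml_control(max_iter)` | 10000 | EM iteration cap; non-convergence is flagged, not fatal |
| `greml_control(floor_frac)` | 1e-12 | component floor as a fraction of phenotypic variance, keeps $\lambda_i$ finite |

## Numerical choices

- **Generalized inverses.** Fixed-effect normal matrices (and, on fallback,
  singular mixed-model equations) are inverted by an eigendecomposition
  Moore-Penrose pseudo-inverse with relative cutoff $10^{-10}$; rank
  deficiency is reported, not hidden.
- **Factorized solves.** $V^{-1}$ is applied through a Cholesky
  factorization; the QM coefficient matrix is solved by Cholesky with a
  pseudo-inverse fallback.
- **Spectral fast path.** With a single genetic term and one record per
  individual, EM-GREML diagonalizes $S$ once and runs each iteration in
  $O(q)$; it is exact and is cross-checked against the dense path in the
  tests.
- **Rank in the residual update.** $r$ is the rank of the full
  mixed-model-equation coefficient matrix, computed as the numerical rank
  of $X$ plus the (always full) ridge-regularized random dimension.
- **Ties and determinism.** The reference allele of a block is the most
  frequent haplotype, ties resolved to the string that sorts first; allele
  catalogs are in lexicographic string order; every simulator function
  requires a seed.
- **Degenerate inputs.** Monomorphic blocks and SNPs contribute zero
  columns; an all-zero coding matrix is an error at the relationship step;
  a heterozygote pair with any missing genotypic value has its dominance
  effect flagged missing and its coding column dropped, while the additive
  side proceeds; validation haplotypes absent from the training catalog are
  coded as the reference allele with a warning (their effect carries no
  information from training).

## What the simulator emulates — and what it does not

`simulate_haplotypes()` draws each individual's two haplotypes per block
independently from the block's frequency spectrum: HWE holds by
construction, and blocks are unlinked. `simulate_pedigree()` adds Mendelian
transmission at unlinked SNPs for nuclear and half-sib family designs.
`simulate_phenotypes()` draws iid Gaussian effects with the model's
variances — exactly the second-moment assumptions of the mixed model.

Real data differ in ways the simulator deliberately omits: linkage
disequilibrium between blocks, recombination within blocks, selection,
non-Gaussian effect architectures, inbreeding, and genotyping or phasing
error. Passing tests therefore demonstrate the internal correctness of the
partition, coding, equivalence and estimation machinery under the model's
own assumptions; they do not certify prediction accuracy on any particular
real population.

## Problem sizes used in the checks

The test suite exercises: random loci with 2-8 alleles for the partition
invariants; populations of 10-60 individuals for coding and equivalence
checks (20 random datasets with 2 and 4 random terms for CE/QM agreement);
pedigrees of 100-200 families at 2000-5000 unlinked SNPs for the
relationship expectations (within 3 Monte-Carlo standard errors); and
variance-component recovery at q = 500 with one haplotype additive term,
100 replicates per heritability level (0.2, 0.5, 0.8), requiring the mean
estimate within 2 standard errors of the truth. These sizes were chosen so
the asymptotic properties under test are actually visible at the simulated
scale.

## Known limitations

- Input must be phased; phasing and imputation are upstream tasks.
- No standard errors of variance components and no prediction reliabilities
  are computed (both need observed/average-information machinery that EM
  does not provide).
- EM-REML convergence can be slow near boundary estimates; the iteration
  cap and floor make this safe but a boundary component may simply sit at
  its floor.
- Dominance information vanishes for large blocks (nearly every individual
  is heterozygous, and missing genotypic classes drop pairs) — a practical
  bound on block size when dominance matters.
- Haplotype relationship matrices are not kinship estimates; use single-SNP
  relationships when relatedness itself is the target.
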