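---
title: "Genomic PCA/ICA: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic PCA/ICA: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasdecomp)
```

## The model

A genome-wide association study (GWAS) of one trait yields, for each SNP, a
per-allele effect size $\beta$, its standard error $se$, and a p-value.
When many genetically correlated traits are studied in the same cohort —
the motivating case is thousands of brain imaging-derived phenotypes
(IDPs) — variants acting through a shared biological pathway impose similar
effect patterns across traits. Stacking the per-trait effects into an
$m \times n$ traits-by-SNPs matrix $X$ (raw betas, or $z = \beta/se$)
therefore exposes low-rank structure:

$$X \approx A\,S + E,$$

where the $K$ rows of $S$ ($K \times n$) are *latent genomic factors*
(SNP loadings), the columns of $A$ ($m \times K$) are the corresponding
*trait loadings*, and $E$ is sampling noise. `pca_decompose()` estimates
the subspace by singular value decomposition; `ica_decompose()` rotates the
$K$-dimensional principal subspace by fixed-point negentropy maximisation
(the FastICA iteration with the log-cosh contrast and symmetric
decorrelation), on the premise that genuine genomic factors are sparse,
hence super-Gaussian, in SNP space while noise directions are Gaussian.

Two deliberate departures from generic PCA/ICA practice, both asserted by
tests:

* **No demeaning.** GWAS effect sizes are already centred on zero under the
  null because the effect-allele orientation is arbitrary. The SVD is taken
  on the raw matrix; adding a constant to a SNP column *changes* the
  result, by design.
* **No per-SNP variance normalisation.** The magnitude of an allelic
  effect carries biological information; columns are not scaled to unit
  variance. Scaling a column up makes it dominate its component, by
  design.

### Conventions that fix an otherwise arbitrary output

SVD and ICA are defined only up to sign and order, so the package pins
both: components are ordered by decreasing explained energy (squared norm
of the trait-loading column), and each SNP-loading row is oriented so its
skewness is positive (falling back to making its largest-magnitude entry
positive when skewness vanishes). ICA SNP-loading rows are scaled to exact
unit root-mean-square *without* subtracting the row mean: removing the
mean would break the exact identity
`trait_loadings %*% snp_loadings == rank-K PCA approximation`, because the
offset is a rank-one term outside the component span. For null-centred
GWAS input the row means are negligible, so unit RMS and unit variance
coincide in practice. With these conventions, a fixed seed makes
`ica_decompose()` bit-reproducible, and independent seeds agree after
`align_components()` matching.

`ica_decompose()` defaults: `tol = 1e-6`, `max_iter = 1000`, five random
restarts before a convergence error. Pure-Gaussian input is
non-identifiable and may legitimately end in a convergence error; the
contract is that it never silently returns non-finite loadings.

## LD reduction

Neighbouring SNPs are correlated through linkage disequilibrium (LD), which
would otherwise dominate the cross-SNP covariance the decomposition
exploits. The reduction pipeline is the field's standard recipe:

1. `ld_prune()` — greedy windowed pruning in genomic order at
   $r^2 < 0.3$ (1 Mb window);
2. `min_p_across_traits()` — the per-SNP minimum p across all trait GWASs
   as the clumping significance track;
3. `clump()` — lead selection in ascending min-p (ties by chromosome,
   position) with members claimed at $r^2 > 0.1$ within 1 Mb, leads
   requiring $p < 10^{-5}$;
4. `augment_lead_snps()` — optional union with external lead lists
   (e.g. disease-GWAS loci clumped at their own thresholds).

The traversal order of pruning and the clumping tie-break are not dictated
by any external convention beyond determinism; position-ordered traversal
(PLINK-like) was chosen and both operations are verified against
brute-force transcriptions of the rules in the test suite.
`effective_n_snps()` implements the Li–Ji-family eigenvalue count
$M_{\mathrm{eff}} = M - \sum_i (\lambda_i - 1)\,[\lambda_i > 1]$ as a
post-hoc check that residual LD among leads is negligible; with $r^2$-only
LD sources the correlation sign is taken as positive, which is exact for
block-structured sources and conservative otherwise.

## Reproducibility statistics

Given decompositions of two non-overlapping samples,
`component_correlations()` reports Pearson correlations of SNP-loading
rows with exact-t p-values, Bonferroni-adjusted by the number of unique
comparisons $K_a \times K_b$. `binarize_loadings()` standardizes each row
and thresholds at $> 1$ (one-sided by default, with an `absolute` flag for
the two-sided reading, since the thresholded maps are conventionally
z-scaled and the literal "> 1" is honoured as the default);
`overlap_fisher()` tests tail overlap by the two-sided Fisher exact test,
computed by direct hypergeometric enumeration — exact under the
post-clumping approximation that lead SNPs are independent. The benchmark
is `univariate_reproducibility()`: the per-trait correlation of effect
sizes across samples. `benchmark_report()` assembles everything and flags,
per matched component, whether its cross-sample $|r|$ exceeds the mean
univariate benchmark — the headline comparison for this class of methods.

## The synthetic generator

`simulate_pair()` is first-class, tested code that defines the study
conditions for every end-to-end claim. It emulates a paired
discovery/replication release of one consortium: identical traits and
variants, non-overlapping samples (defaults 22,000 vs 11,000
participants).

* **Factors.** Spike-and-slab SNP loadings: a SNP loads on a factor with
  probability $\pi = 0.02$, with slab scale $\tau = 1$. Sparsity makes the
  factors super-Gaussian, so ICA identifiability holds by construction.
* **Trait loadings.** Traits are partitioned into modality blocks, one per
  factor by default, with mean affinity 1 on the matched block and a 0.15
  floor elsewhere (pervasive pleiotropy). A design caveat discovered while
  validating the generator: the mixing matrix must be full rank, which
  requires at least $K$ distinct blocks — a "global" factor whose trait
  profile is the sum of the block indicators is linearly unidentifiable.
* **LD.** SNPs are laid out in blocks (default 10 SNPs, $r^2 = 0.8$
  within, 0 between; blocks > 2 Mb apart so the 1 Mb clumping window never
  spans two). Marginal loadings are the direct loadings convolved with the
  block correlation ($r = \sqrt{r^2}$), the standard marginal-vs-joint
  relation for GWAS effect sizes; recovery is scored against these
  marginal loadings because that is what summary statistics measure.
* **Noise.** Each sample's betas are the truth plus independent Gaussian
  error with the standard GWAS standard-error shape
  $se \propto 1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})\,N}$. The overall
  scale is set by `noise_sd`, defined as the SE of a MAF = 0.5 SNP in the
  discovery sample. The default `noise_sd = 1.0` was calibrated once so
  that per-trait univariate reproducibility sits near $r \approx 0.08$–
  $0.1$ — the regime reported for imaging GWAS at these sample sizes —
  after accounting for the LD convolution's inflation of marginal signal
  variance. The MAF-dependence makes raw betas heteroscedastic across
  SNPs, which is exactly what the $z$-transform compensates; this is why
  $z$-mode decompositions reproduce slightly better than raw-beta ones, in
  simulation as in practice.
* **Seeds.** A two-seed design separates structure (`seed`) from sampling
  noise (`noise_seed`), so a discovery/replication pair shares its truth
  but not its noise.

What the generator does *not* emulate: realistic allele-frequency spectra,
population structure, relatedness, variable per-trait phenotype variances,
cross-trait residual correlation from shared subjects, and long-range LD.
Passing tests therefore demonstrate internal correctness and the
qualitative behaviour of the method under clean planted structure, not
performance on any real cohort.

## Numerical choices

* Whitening uses the exact SVD of the (uncentered) input; the probabilistic
  PCA noise model used by some ICA pipelines is unnecessary here because
  the output dimension is user-fixed rather than model-selected.
* FastICA convergence is measured per component as
  $1 - |\langle w_{\mathrm{new}}, w_{\mathrm{old}}\rangle|$; symmetric
  decorrelation via SVD keeps the unmixing matrix exactly orthogonal at
  every step.
* `align_components()` solves the assignment problem exactly (shortest
  augmenting path, $O(K^3)$) on the $|r|$ matrix; rectangular cases are
  zero-padded and surplus components stay unmatched.
* Fisher p-values sum hypergeometric point probabilities
  $\le (1+10^{-7})$ times the observed one — the standard two-sided rule.
* The t-SNE embedding (`embed_trait_loadings()`) is the exact $O(m^2)$
  formulation with perplexity calibration by bisection, early exaggeration
  (factor 4, 100 iterations) and momentum switching at iteration 250;
  adequate for trait counts in the thousands and fully deterministic for a
  fixed seed. Perplexity defaults to 30 and must satisfy
  $m > 3\,\mathrm{perplexity}$.
* Degenerate inputs error eagerly and specifically: constant loading rows
  (undefined correlations), zero-variance loading vectors, $K$ out of
  range, $K = 1$ ICA, unknown within-window LD pairs in strict mode.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on simulated
data sized for a single CPU: the default generator configuration
(100 traits × 2,000 SNPs) for reproducibility benchmarks, a well-powered
panel (300 traits × 5,000 SNPs, `noise_sd = 0.1`) for factor recovery and
clumping, and 50 × 500 matrices for decomposition oracles. These sizes
were chosen so the full validation cycle completes in well under a minute
per property while leaving the statistical conclusions unambiguous.

## Known limitations

* The $>1$ binarization threshold is applied to standardized loadings; for
  strongly skewed components the one-sided default and the `absolute` mode
  can disagree materially.
* `effective_n_snps()` with $r^2$-only sources cannot recover correlation
  signs; supply genotype dosages when signed correlations matter.
* Clumping assumes min-p values are comparable across traits, i.e. all
  traits come from comparably powered GWAS — true within one consortium
  release, not across heterogeneous studies.
* The exact t-SNE implementation is $O(m^2)$ in memory and time; it is a
  visualisation aid, not a scalable embedding engine.
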