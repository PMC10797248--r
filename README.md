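# gwasdecomp

Principal and independent genomic components from multi-trait GWAS
summary statistics.

## The problem

A genome-wide association study (GWAS) of a single trait produces
mass-univariate statistics — per-SNP effect sizes (β), standard errors and
p-values. For highly polygenic, pleiotropic phenotype families (the
motivating case is thousands of brain imaging-derived phenotypes, IDPs,
measured in one biobank cohort), variants acting through shared biological
pathways show correlated effect patterns across traits. `gwasdecomp`
exploits that: it stacks per-trait summary statistics into an m × n
traits-by-SNPs effect matrix *X* (raw β, or z = β/se) and decomposes it as

    X ≈ A S

where the K rows of S are latent **genomic factors** (SNP loadings) and
the columns of A are the corresponding **trait loadings**. PCA
(`pca_decompose()`, uncentered SVD) gives variance-ordered orthogonal
components; ICA (`ica_decompose()`, FastICA-style fixed-point negentropy
maximisation within the K-dimensional principal subspace) rotates them
toward sparse, super-Gaussian — hence more interpretable — genomic
sources. Deliberately, there is **no demeaning** (GWAS effects are
null-centred by the arbitrary effect-allele orientation) and **no per-SNP
variance normalisation** (allelic-effect magnitude is biology, not
nuisance).

Around the decomposition the package provides the full working pipeline:

* **gwas_io** — reading/harmonizing summary statistics (allele-swap sign
  flips, −log10 p support), effect-matrix assembly and TSV round trips;
* **clumping** — greedy LD pruning (r² < 0.3), min-p clumping across
  traits (1 Mb window, lead p < 1e−5, member r² > 0.1), external lead-SNP
  augmentation, Li–Ji effective-SNP counts;
* **reproducibility** — cross-sample component correlations (Bonferroni by
  K_a·K_b), Fisher-exact overlap of thresholded loading tails, the
  univariate GWAS benchmark, and optimal component matching
  (`align_components()`);
* **loading_stats / embedding** — normal-CDF loading significance with
  Manhattan-style tables, and a deterministic t-SNE of trait loadings;
* **synthetic** — a paired discovery/replication GWAS simulator with
  planted factors, block LD and MAF-dependent standard errors, used by the
  whole validation suite.

## Worked example

Simulate a paired discovery/replication panel (100 traits × 2,000 SNPs,
five planted factors), decompose both samples at K = 5 and compare
component reproducibility with the univariate benchmark:

```r
library(gwasdecomp)

cfg <- sim_config(seed = 7)
sim <- simulate_pair(cfg)

Xa <- assemble_effect_matrix(sim$tables_a, mode = "z_value")
Xb <- assemble_effect_matrix(sim$tables_b, mode = "z_value")
Xa
#> effect_matrix: 100 traits x 2000 SNPs, mode = z_value

da <- ica_decompose(Xa, 5, seed = 11)
db <- ica_decompose(Xb, 5, seed = 11)
da
#> ICA decomposition: K = 5 (100 traits x 2000 SNPs), variance explained = 16.8%

rep <- benchmark_report(da, db, Xa, Xb)
rep
#> Cross-sample reproducibility report
#>   matched components: 5; mean |r| = 0.555 (max 0.667)
#>   univariate benchmark: mean r = 0.089 (max 0.171, sd 0.034)
#>   components exceeding univariate mean: 5 / 5
```

Reading: each per-trait GWAS reproduces across the two samples at only
r ≈ 0.09 on average (the noisy regime typical of imaging GWAS at these
sample sizes), yet every one of the five matched genomic components
reproduces at |r| = 0.41–0.67 — the decomposition pools the pleiotropic
signal shared across traits and discards trait-specific noise. The
matched pairs, component-correlation matrix, Fisher overlap tests of the
binarized loading tails and per-trait univariate r are all in `rep`.
`recovery_score(da, sim$truth)` additionally scores the components
against the planted factors; `manhattan_table(da, 1)` and
`embed_trait_loadings(da, perplexity = 10, seed = 1)` produce the
per-SNP significance table and the 2-D trait-loading embedding.

A command-line wrapper covering simulate/clump/decompose/reproduce/plot
and a full-pipeline `run` subcommand ships in `inst/cli/gwasdecomp.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "gwasdecomp.R", package = "gwasdecomp"))')" \
    simulate --seed 3 --out-dir sim_out
```

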