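# mprsnet

Module-level polygenic risk scores on imaging-genetics networks.

## The problem

Genome-wide association studies of brain-imaging quantitative traits
(iQTs) — here, amygdala grey-matter density — find individual genes, but
disease mechanisms act through interacting gene *modules*. `mprsnet`
implements a network-based association framework that:

1. maps gene-level iQT association scores, `w(v_i) = -log10(p_i)`, onto a
   protein-protein interaction network as node weights;
2. smooths them by random-walk-with-restart propagation,
   `S = beta (I - (1 - beta) A D^-1)^-1 diag(w)`, and extracts candidate
   trait modules by hierarchical strongly-connected-component clustering
   of `S` with a degree-binned permutation test;
3. scores every individual on every module with a **module-level
   polygenic risk score**,
   `MPRS(M) = sum_{j in M} sum_{k in SNPs(g_j)} beta_jk * SNP_jk`,
   where the SNPs lie within ±20 kb of the module genes and the weights
   `beta_jk` come from disease meta-GWAS summary statistics (allele
   harmonization included);
4. selects disease-relevant modules by case-control t-tests with
   Bonferroni correction over all candidate modules (union rule across
   meta-GWAS weight sources), reporting Cohen's d with confidence
   intervals;
5. validates selected modules by co-expression modularity against random
   same-size modules, tissue specificity (paired t-test), diagnostic
   staging, median-split Kaplan-Meier / log-rank and Cox
   proportional-hazards conversion analysis, hypergeometric gene-set
   enrichment with BH-FDR, and x-m-y causal mediation analysis
   (bootstrap ACME/ADE/proportion mediated).

A synthetic-data generator plants known modules, effect sizes, hazard
ratios and mediation proportions at every layer, so the whole pipeline is
testable end-to-end without any external download. It is intended for
methodologists studying module-level genetic scores and for analysts who
want a transparent, fully seeded reference implementation of this class
of pipeline.

## Worked example

```r
library(mprsnet)

res <- run_demo(out_dir = "demo", seed = 7)
sim <- res$simulation   # synthetic study incl. ground truth
pl  <- res$pipeline     # all stage results

pl$modules[, c("module_id", "size", "perm_p")]
#>   module_id size      perm_p
#> 1  trait.M1   10 0.002496879

length(intersect(pl$modules$genes[[1]],
                 sim$ground_truth$planted_modules[[1]]))
#> [1] 10        # the 10-gene planted module, recovered exactly

subset(pl$adm, select = c(module_id, weight_source, p, cohens_d, significant))
#>  module_id weight_source            p cohens_d significant
#>   trait.M1         meta1 9.152080e-28 1.744448        TRUE
#>   trait.M1         meta2 4.793945e-25 1.635148        TRUE

pl$survival[, c("module_id", "n", "cox_hr_per_sd", "cox_p")]
#>  module_id   n cox_hr_per_sd        cox_p
#>   trait.M1 136      1.576187 0.0008350918

pl$mediation[, c("module_id", "acme", "prop_mediated")]
#>  module_id       acme prop_mediated
#>   trait.M1 0.09624733     0.2848358
```

Reading the numbers: the propagation stage recovers the planted 10-gene
module with permutation p = 2/801 (800 permutations); its risk score
separates synthetic AD from CN far below the Bonferroni threshold (the
diagnosis groups are tails of the latent risk, so their d exceeds the
genotype-level target of 0.5); the Cox model estimates a conversion
hazard ratio of 1.58 per SD of the score in the 136-person MCI cohort
(generator truth 1.3, inside the wide single-cohort interval); and 28%
of the score's effect on diagnosis is estimated as mediated by the
imaging trait (generator truth 0.22, stored in
`demo/data/ground_truth.json`).

All stage tables are also written under `demo/results/` (`modules.tsv`,
`adm.tsv`, `modularity.tsv`, `tissue_specificity.tsv`, `enrichment.tsv`,
`staging.tsv`, `survival.tsv`, `mediation.tsv`, `manifest.json`).

The same pipeline runs on user data via `pipeline_config()` +
`run_pipeline()`; every input is a plain TSV/VCF/GMT file (see the
`io_formats` readers) and positions are 1-based inclusive, PLINK/VCF
style. Real gene-analysis output (e.g. MAGMA) can be supplied directly as
the gene score table; a windowed min-p Bonferroni aggregator is included
as a documented stand-in.

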