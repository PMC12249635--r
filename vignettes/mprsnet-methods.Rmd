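---
title: "Module-level polygenic risk scores on imaging-genetics networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-level polygenic risk scores on imaging-genetics networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprsnet)
```

# The analysis in one paragraph

`mprsnet` connects three layers of evidence about a brain disorder: genetic
association with an imaging quantitative trait (iQT, e.g. amygdala
grey-matter density), the topology of a protein-protein interaction (PPI)
network, and individual-level disease risk. Gene-level iQT association
scores are mapped onto the PPI network as node weights; random-walk
propagation plus hierarchical strongly-connected-component (SCC) clustering
extracts candidate trait modules; each module is then scored per individual
as a module-level polygenic risk score (MPRS) weighted by disease meta-GWAS
effect sizes; modules whose MPRS separates cases from controls after
Bonferroni correction are the disease-relevant modules, which are finally
validated by co-expression modularity, diagnostic staging, conversion
survival, and causal mediation analyses. Everything runs end-to-end on
synthetic data with known ground truth.

# Network propagation

## The diffusion operator

Given the undirected restricted network with adjacency $A$, diagonal degree
matrix $D$ and node weights $w_i = -\log_{10} p_i$, the package forms the
asymmetric similarity matrix

$$ S \;=\; \beta\,\bigl(I - (1-\beta)\,A D^{-1}\bigr)^{-1}\,
   \mathrm{diag}(w_1,\dots,w_n), $$

the insulated heat-diffusion operator of the HotNet family, where $\beta$
is the restart probability of the underlying random walk. $S_{ij}$ reads as
the amount of heat node $i$ holds at equilibrium when node $j$ produces
heat at rate $w_j$; column $j$ sums to $w_j$ (heat conservation), which the
test suite asserts to $10^{-8}$.

A second convention, $S = (\beta I - (1-\beta) A D^{-1})^{-1}
\mathrm{diag}(w)$, is implemented behind `convention = "literal"`. Because
$A D^{-1}$ is column-stochastic with eigenvalue 1, that operator is exactly
singular at $\beta = 0.5$ on every connected graph and ill-conditioned
nearby; the implementation guards it with a condition-number check
(error above $10^{12}$) instead of returning numerical noise. The
`hotnet2` convention is the default because it is invertible for every
$\beta \in (0,1)$ and is the operator the hierarchical-SCC literature
actually uses. The default $\beta = 0.4$ follows HotNet-family practice;
results are not sensitive to moderate changes because the SCC sweep spans
all thresholds of $S$.

## Hierarchical SCC clustering

For a threshold $\delta$, draw directed edge $j \to i$ whenever
$S_{ij} \ge \delta$ and decompose the graph into strongly connected
components. As $\delta$ decreases over the distinct off-diagonal values of
$S$, edges only accumulate, so SCCs only merge: the partitions nest and
form a dendrogram. The sweep is implemented in compiled code (iterative
Tarjan over an incrementally growing edge list), and its correctness is
tested against an independent Floyd–Warshall mutual-reachability oracle.

## Permutation null and cut selection

The null model permutes node weights within degree bins (topology fixed):
nodes are sorted by degree, split into bins, and weights shuffled within
bins, which preserves the empirical degree-weight coupling. Bins are
constrained to hold at least 20 nodes — with smaller bins the permutation
can barely move any weight and the null collapses onto the observed
assignment — so the effective bin count is `min(n_bins, n %/% 20)`,
floored at one bin (a uniform shuffle). Permutations are cheap because the
weight-free kernel $K = \beta (I - (1-\beta) W)^{-1}$ is computed once and
$S_\pi = K\,\mathrm{diag}(w_\pi)$ is a column scaling.

The observed largest-SCC size is a step function of $\delta$ with at most
$n-1$ jumps, and within one step the permutation null only grows as
$\delta$ falls, so each step is best tested at its largest $\delta$:
permutations are therefore evaluated at the jump thresholds only, which
makes the permutation stage $O(n)$ rather than $O(n^2)$ SCC sweeps per
permutation. At each such threshold the largest permuted SCC size yields
an empirical exceedance probability
$\hat p(\delta) = (1 + \#\{\pi : L_\pi(\delta) \ge L_{obs}(\delta)\}) /
(1 + n_{perm})$. The cut $\delta^\*$ is chosen as the threshold with the
**largest observed SCC among thresholds where that SCC is both
significantly large** ($\hat p(\delta) < \alpha$) **and a proper
submodule** (size within $[\text{min\_size}, n/2]$); ties go to the larger
$\delta$. Modules are the SCCs at $\delta^\*$ with at least `min_size`
genes (default 3), each assigned the permutation p-value
$(1 + \#\{\pi : L_\pi(\delta^\*) \ge |M|\})/(1 + n_{perm})$, and retained
at $p < 0.05$. With $n_{perm} = 800$ the smallest attainable p-value is
$1/801$.

Two simpler cut rules were evaluated during design and rejected, and the
reasons are worth recording. Maximizing the standardized deviation
$(L_{obs} - \bar L_\pi)/(\mathrm{sd}(L_\pi) + \varepsilon)$ is dominated by
thresholds in the upper tail of $S$ where the permutation distribution is
nearly degenerate: a two- or three-node core of the true module with
near-zero null variance outscores the fully formed module, so the
selected cut systematically truncates modules. Maximizing the
unstandardized deviation $L_{obs} - \bar L_\pi$ is better behaved but still
prefers partially formed modules whenever the weakest module member joins
late. The exceedance rule selects the most complete module that is still
inconsistent with the null, which is the actual quantity of interest, and
it reduces to the same per-module permutation test used for significance.
The size cap at $n/2$ excludes the regime where the "largest SCC" is the
network itself merging — there the statistic measures global connectivity,
not module structure.

# Module-level polygenic risk score

For module $M$ the score of an individual is

$$ \mathrm{MPRS}(M) = \sum_{j \in M}\ \sum_{k \in \mathrm{SNPs}(g_j)}
   \beta_{jk} \cdot g_{jk}, $$

where $\mathrm{SNPs}(g_j)$ are the meta-GWAS SNPs within ±20 kb of gene
$g_j$ (window inclusive at both ends, positions 1-based), $\beta_{jk}$ the
meta-GWAS effect size and $g_{jk}$ the harmonized dosage of the effect
allele. Three design points:

* **Deduplication.** A SNP inside the windows of two module genes would be
  counted twice by the double sum; the package counts it once because
  double-weighting by annotation overlap is biologically arbitrary.
  `dedup = FALSE` restores the literal double counting for comparison.
* **Harmonization.** Dosages are re-expressed on the effect-allele scale
  ($g \mapsto 2-g$ when the counted allele is the other allele);
  strand-palindromic SNPs (A/T, C/G) are dropped by default because their
  orientation is unresolvable without strand information; non-matching
  allele pairs are dropped; every drop is tallied by reason. The suite
  checks that re-encoding a genotype file on the opposite allele leaves
  all scores unchanged to $10^{-12}$.
* **Missingness.** Per-SNP mean imputation by default (standard PRS
  practice; preserves the population mean score); `drop_individual` and
  `zero` are available.

Scores are reported raw and z-standardized across the analysis sample; the
standardized scale is what the survival analysis uses so hazard ratios are
per standard deviation.

# Disease-relevant module selection

Per candidate module and per meta-GWAS weight source, case and control
score distributions are compared with a two-sample t-test (Welch by
default — group variances are not assumed equal; Student's pooled test is
available) plus Cohen's d with a normal-approximation confidence interval.
The significance threshold is $\alpha/m$ with $m$ the number of candidate
modules pooled across trait sides — not modules × weight sources. Under
the default union rule a module qualifies when it passes the corrected
threshold under at least one weight source; the intersection rule is
stricter and available as an option.

# Validation analyses

**Co-expression modularity.** The module statistic is the mean pairwise
Pearson correlation over module genes in a genes-by-samples expression
matrix; the null is random same-size gene sets from the background network
(1000 by default), with the add-one permutation p. Tissue specificity is a
paired t-test of per-module correlations between the target tissue and a
comparison tissue. Zero-variance genes are excluded pairwise rather than
failing a module.

**Staging.** Welch t-tests between every pair of diagnostic groups
(CN/SMC/EMCI/LMCI/AD), raw p-values (the comparisons are descriptive).

**Conversion survival.** The conversion cohort is the baseline MCI
(EMCI + LMCI) subset. Kaplan–Meier curves and a two-group log-rank test
compare high- vs low-risk groups split at the median MPRS (ties assigned
to the low-risk group so the split is deterministic); a Cox
proportional-hazards model (Efron tie handling — monthly visit times
guarantee ties) estimates the hazard ratio per SD of MPRS adjusting for
age, sex and education. These standard estimators are delegated to the
`survival` package; the tests validate them against a hand-built
risk-table log-rank oracle and recovery of a known simulated hazard ratio.

**Mediation.** The x–m–y model uses the MPRS as exposure, the imaging
trait as mediator and dichotomized diagnosis (CN/SMC = 0, MCI/AD = 1) as
outcome, with age/sex/education covariates: a linear mediator model and a
logistic outcome model, combined by counterfactual simulation on the
probability scale between treatment levels $\bar x \pm \mathrm{sd}(x)$.
Using common mediator noise across treatment levels makes the averaged
decomposition ACME + ADE = total exact (asserted to $10^{-10}$), so the
mediated proportion ACME/total is well-defined. Uncertainty comes from a
nonparametric bootstrap (5000 draws by default) with percentile intervals
and sign-crossing p-values floored at $1/n_{boot}$; bootstrap draws whose
logistic fit does not converge are redrawn, with at most 10% discard.

# The synthetic study design

The generator plants known structure at every layer so each stage has a
parameter-recovery test. Defaults describe one fixed desk-scale study:

* **Network**: 100 genes, one planted 10-gene module with within-module
  edge probability 0.9 on a background of density 0.085, plus a spanning
  scaffold for connectivity. The background density is kept low enough
  that, under the permutation null, the handful of large permuted weights
  do not percolate into large chance components (10 hot nodes at
  adjacency 0.085 stay subcritical), while still allowing degree balance
  with the planted module (below). Edge probabilities between a planted module
  and the rest are reduced so that the *expected total degree of module
  nodes matches the background* (a degree-balanced planted-partition
  design). Without this balance the module is simultaneously the densest
  and the highest-degree region, and any degree-aware permutation null
  either re-concentrates the large weights onto the module (making the
  null indistinguishable from the observation) or, if uniform, makes the
  observed network merge systematically earlier than its permutations.
  Degree balance removes this confound, which is an artifact of
  desk-scale networks — at genome scale (10k+ nodes) hot modules are not
  degree outliers to the same extent.
* **Gene scores**: background p ~ Uniform(0,1); planted genes
  p ~ Beta(0.01, 1), i.e. $-\log_{10} p$ roughly exponential with mean
  ≈ 43. This heavy-tailed, strongly heterogeneous score profile is
  realistic (gene p-values near a true locus span orders of magnitude)
  and is the stress case for module detection: the weakest planted member
  may be indistinguishable from background, in which case no detector can
  recover it and the recovery tests accept the 8–9 strong members.
* **Genotypes**: LD-free SNPs, 3 per gene body plus one at the exact
  −20 kb window boundary; dosages Binomial(2, MAF) with MAF ~ U(0.2, 0.5).
  Case/control allele-frequency shifts at planted-module SNPs are
  calibrated analytically to a target Cohen's d of the true module score
  (default 0.5): $\delta = d \cdot \mathrm{sd(score)} /
  (4 \sum_k |\beta_k|)$, shifting cases by $+\delta\,\mathrm{sign}(\beta_k)$
  and controls by $-\delta\,\mathrm{sign}(\beta_k)$. The suite checks the
  calibration is unbiased (mean realized d within ±0.05 of target).
  About 20% of background SNPs are stored on the flipped allele encoding
  and two are strand-palindromic, so harmonization is exercised on real
  work. A second weight source carries attenuated, noisier effect sizes
  (0.8× plus noise), emulating a partially concordant second
  meta-analysis.
* **Phenotypes**: mediator $m = a x + \varepsilon$, outcome
  $y \sim \mathrm{Bernoulli}(\mathrm{logistic}(c x + b m))$ with defaults
  $a = 0.4$, $b = 0.5$, $c = 0.67$, calibrated against the oracle so the
  true mediated proportion is 0.22 on the probability scale (the exact value is
  computed by an independent $10^6$-draw Monte-Carlo oracle and stored in
  `ground_truth.json` with each dataset). Diagnosis derives from $y$:
  y = 0 → CN/SMC (80/20), y = 1 → EMCI/LMCI/AD by latent-score terciles —
  a deliberately simple severity split used only by the staging tests.
  Conversion times for the MCI subset are Exponential with true log hazard
  ratio log(1.3) per SD of the (within-cohort standardized) score,
  administratively censored at the empirical quantile matching the
  configured censoring rate (default 40%), then rounded up to whole
  months.
* **Expression**: in the target tissue, planted-module genes load
  $\sqrt{\rho}$ on a shared per-sample factor (default $\rho = 0.6$, so
  the expected within-module pairwise correlation is 0.6); all other
  genes, and all genes in other tissues, are independent N(0,1).

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify on real data: linkage disequilibrium and
population structure in genotypes, degree-heavy-tailed PPI topology,
expression covariance beyond a single shared factor, informative censoring,
and measurement error in the imaging trait.

# Numerical choices and degenerate inputs

* p-value floor $10^{-300}$ before $-\log_{10}$, so p = 0 cannot produce
  an infinite node weight.
* Permutation p-values use the add-one rule and can never be 0.
* Two-sample t-test with two zero-variance groups: p = 1 when means are
  equal, p → 0 with an infinite statistic otherwise (documented rather
  than an error, since permutation pipelines can produce constant groups).
* Module detection errors when all off-diagonal similarities are equal
  (no threshold structure), and the pipeline stops with a clear message
  when no module passes the permutation screen.
* Tie rules are deterministic everywhere: cut-selection ties go to the
  larger threshold, component-size ties to the component containing the
  lexicographically smallest gene id, and median-split ties to the
  low-risk group.
* Per-stage seeds are derived from the single global seed by hashing the
  stage name into $[0, 2^{31}-1)$, so stages are reproducible
  independently of each other.

# Problem sizes used by the test suite

The suite favours many small replicates over single large runs: networks
of 20–100 nodes, 49–199 permutations inside end-to-end tests, cohorts of
400–4000 individuals for effect-size and survival recovery, and 49–500
bootstrap draws for mediation. These sizes were chosen so the full suite
exercises every code path with meaningful statistical power while staying
fast enough to run habitually during development; the same generators
scale to larger studies by changing the configuration.

# Known limitations

* The min-p Bonferroni gene score is a deliberately simple stand-in for a
  proper gene-based association test; real gene-analysis output should be
  supplied directly when available.
* The exceedance-based cut selection returns a single global threshold;
  modules that form at very different scales of $S$ are better served by
  consensus procedures over the full hierarchy, which are out of scope.
* Mediation assumes sequential ignorability; no sensitivity analysis is
  provided.
* The dense similarity matrix limits practical network sizes to a few
  thousand nodes; the intended scale here is the restricted, scored
  subnetwork, not the raw interactome.
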