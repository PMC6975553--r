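---
title: "Methods: population structure, mixed-model association and Bayesian multilocus epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure, mixed-model association and Bayesian multilocus epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soyepi)
```

## The problem

Days to flowering (DTF) in soybean is a quantitative trait controlled by a
handful of major loci (the *E* series among them) plus a web of smaller
effects and locus-by-locus interactions. A single-marker genome-wide
association scan finds the additive signals; it is structurally blind to
purely epistatic ones, where only the *joint* genotype of two or more loci
moves the phenotype. `soyepi` implements the full chain of analysis for this
setting on inbred, weakly structured cultivar panels: population-structure
diagnostics, a compressed mixed-linear-model (CMLM) association scan,
biologically filtered candidate marker-set construction, and a Bayesian
partition model searched by MCMC that detects multilocus interactions, each
verified by a classical two-locus regression.

Everything is exercised end-to-end on synthetic data, so the package carries
its own test bed; no external genotype download is needed.

## The synthetic panel

`simulation_spec()` describes a two-subgroup panel emulating an improved
cultivar (IC) vs landrace (LR) split:

* **Divergence.** Ancestral alternate-allele frequencies are drawn uniformly
  on `[maf_floor, 1 - maf_floor]` (default floor 0.05); subgroup frequencies
  come from the Balding–Nichols beta distribution with
  $F_{st} = 0.0581$ by default, the divergence small enough for the two
  subgroups to behave as one population. Subgroup frequencies are truncated
  back to the admitted spectrum, a deliberate simplification that keeps
  every marker's minor-allele frequency above the floor while biasing the
  realized $F_{st}$ by well under the acceptance band (measured ~0.053–0.059
  against the 0.0581 target over seeds).
* **Inbreeding.** Soybean is a strict selfer; per individual and locus, a
  genotype call is with probability $F$ (default 0.971) a *selfed* draw —
  homozygous for one sampled allele — and otherwise a Hardy–Weinberg draw of
  two alleles. The mixture weight equals the method-of-moments expectation
  of $F$, and realized estimates land within ±0.01 of the target at
  $n \ge 200$.
* **Linkage disequilibrium.** Each haplotype is a latent Gaussian AR(1)
  chain along the chromosome with correlation $\exp(-d/\ell)$ over distance
  $d$ ($\ell$ = `ld_decay_scale`, default 100 kb), thresholded at the
  subgroup frequency. This is a first-order copula: it reproduces local,
  distance-decaying LD (mean $r^2 \approx 0.12$ within 100 kb at the
  defaults, decaying towards background beyond) without coalescent realism,
  recombination maps or genotyping error — all out of scope.
* **Phenotype.** `value = subgroup mean + additive effects × dosage +
  interaction cell effects + N(0, residual_sd²)`. Default subgroup means are
  42.16 (IC-like) and 45.86 (LR-like) days. No DTF variance is published for
  the real panel; `residual_sd = 5` days is a fixture choice, flagged as
  such. Planted interactions are full $3^k$ cell-effect tables; the default
  two-locus pattern (`xor_cell_effects()`) adds the effect when exactly one
  marker carries the alternate allele, which has no marginal additive
  component at balanced carrier frequencies — a pure test of non-additive
  detection.

Passing tests on this generator show the analysis machinery is correct and
calibrated under these assumptions; they do not show robustness to features
the generator omits (genotyping error, missingness patterns, coalescent LD
block structure, phenotype-by-environment effects).

What the defaults are for: sample sizes (200 + 200) and marker counts
(2,000) are desk-scale stand-ins for the real 2,662 × 180k panel, chosen so
the whole test suite and the acceptance script run in minutes on one CPU
while leaving every estimator enough data to hit its published target values
to within simulation noise.

## Population-structure statistics

* **IBS.** Identity-by-state between diploids $i, j$ is
  $\frac{1}{M}\sum_m (2 - |g_{im} - g_{jm}|)/2$; `ibs_matrix()` also returns
  $1 - \mathrm{IBS}$ as a distance.
* **K2P.** `k2p_distance()` compares a sample pair only at sites where both
  are homozygous, treating each as a haploid base call; heterozygotes are
  coded as missing and excluded pairwise. With a ~97% homozygous panel this
  loses almost nothing and avoids assigning a transition/transversion class
  to ambiguous heterozygote differences — an interpretation choice, since
  the source protocol does not specify one. From the transition fraction
  $P$ and transversion fraction $Q$,
  $d = -\tfrac12\ln\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)$; saturated pairs are
  capped and flagged.
* **Principal coordinates.** `pca_from_distance()` is classical
  multidimensional scaling (double-centered squared distances, spectral
  decomposition). Whether the original analysis decomposed raw or squared
  distances is unstated; classical MDS is the standard reading of "SVD of a
  distance matrix" and is what is implemented and tested (it reproduces
  Euclidean configurations exactly).
* **BIONJ.** `bionj_tree()` wraps the variance-weighted neighbor-joining
  agglomeration and emits Newick text. Negative branch lengths (a
  finite-sample artifact) are clamped to zero with the deficit moved to the
  parental branch; toggleable via `clamp_negative`.
* **LD decay.** $r^2$ is the squared Pearson correlation of dosage columns
  — a genotype (composite) measure, because phase is unavailable without
  external imputation. Pairs are limited to 500 kb by default and
  summarized within 100 kb and 500 kb.
* **Diversity and differentiation.** Per-site nucleotide diversity is
  $c_{ref} c_{alt} / \binom{2n}{2}$; windows of 100 kb sliding by 10 kb
  divide the site sum by the window length in bp, and truncated trailing
  windows are emitted flagged. $F_{st}$ uses the Weir–Cockerham (1984)
  variance components; a window's (and the genome's) value is
  $\sum a / \sum(a+b+c)$ — the ratio of sums, not the mean of per-site
  ratios, which is the estimator the usual VCF tooling reports. Per-site
  components may be negative; the aggregate is reported as computed.
* **Inbreeding.** Method-of-moments
  $F = (O_{hom} - E_{hom}) / (L - E_{hom})$ over polymorphic sites with the
  small-sample corrected expectation $1 - 2p(1-p)\frac{2n}{2n-1}$.

## The mixed-model scan

`cmlm_gwas()` fits $y = x\beta + Zu + \varepsilon$ with
$u \sim N(0, \sigma_g^2 K)$, $K$ the VanRaden genomic relationship matrix.
Variance components are estimated *once* under the null model by REML on the
spectral decomposition of $K$ — the P3D shortcut the reference tool defaults
to — then every marker is tested by generalized least squares with a
two-sided $t$ test. Choices a user can move:

* `n_pcs` (default 3, matching the three displayed principal components)
  fixed-effect covariates from the genotype PCA.
* `compression_groups`: average-linkage clustering of $K$, with the
  cluster-averaged kinship replacing $K$ (the "compressed" in CMLM).
  Default is no compression — the compression level of the original run is
  unpublished — and `compression_groups = n` provably reproduces the
  uncompressed model.
* `lambda`: fixes $\sigma_g^2/\sigma_e^2$ instead of estimating it;
  `lambda = 0` with an identity $K$ collapses the scan to ordinary least
  squares exactly (tested to 1e-8), which is the scan's main correctness
  anchor.

Significance uses the study's convention: strict $-\log_{10} p > 7$, a round
number chosen above the Bonferroni level ($-\log_{10}(0.05/78{,}427) = 6.2$
at one decimal). Genic assignment is plain interval containment (1-based,
closed) against the gene annotation, replacing an external annotator; a
marker inside overlapping genes counts for each of them.

## Candidate marker set

Homology hits (BLAST tabular) are kept at identity strictly $> 80$% and
alignment length strictly $> 70$ — strict because the source states ">" —
with both bounds relaxable to $\ge$ for sensitivity analysis. The
alignment-length unit is taken at face value in positions even though
translated alignments report amino-acid columns; this is a documented
discrepancy inherited from the filtering recipe. The candidate set is the
id-keyed union of homology-derived genic markers and GWAS-significant genic
markers (`build_marker_set()`), with provenance per marker and
inclusion–exclusion enforced; `summarize_counts()` reproduces the
published-style accounting table where the related row is reported net of
its overlap with the significant row.

## The Bayesian partition model

Candidate markers are partitioned into an *associated block* (markers whose
joint genotype predicts the phenotype), any number of *dependency blocks*
(markers mutually correlated — LD, shared structure — but not linked to the
phenotype), and an independent *background*. The score of a partition is the
log marginal likelihood

$$P(Y \mid X_{assoc}) \prod_{blocks} P(X_{block}),$$

where every block's genotypes (the associated block's included — otherwise
partitions of different shapes would not be comparable) carry a
Dirichlet-multinomial marginal over their joint-genotype cells
(concentration 1 per cell by default), and the phenotype factor is a
conjugate Normal–Inverse-Gamma marginal per joint-genotype cell of the
associated block (defaults $\mu_0 = \bar y$, $\kappa_0 = 1$, $\alpha_0 = 2$,
$\beta_0 = \mathrm{var}(y)$). The trait is continuous here; the source
leaves the phenotype likelihood family implicit, so the conjugate Gaussian
cell model is this package's concretization — for categorical traits the
same partition machinery would take a discretized Dirichlet-multinomial
phenotype factor, and `partition_log_score()` is written so that swap is
local. Empty cells contribute marginal 1; the partition prior is uniform,
with an optional per-marker `size_penalty` to curb large-block artifacts.
`max_block_size` (default 5, the largest published group) guards the $3^k$
cell explosion.

### The sampler

`epistasis_scan()` runs Metropolis–Hastings with five proposal types:
relocate one marker (including opening a fresh dependency block or emptying
one), swap two markers between blocks, toggle a *pair* of markers jointly
between background and associated block, switch a whole block's kind
(associated ↔ fresh dependency block), and merge a dependency block into the
associated block or split a subset back out. Relocate, swap and pair-toggle
are symmetric by construction; kind-switch and merge/split carry explicit
Hastings corrections. The compound moves exist because the landscape has
deep two-step valleys: a purely epistatic pair gains nothing until *both*
members sit in the associated block, and a marker captured by a
tight-LD dependency block is expensive to extract one step at a time.
Detailed balance is verified empirically in the test suite: on 3- and
4-marker toys the retained-sample state frequencies match the exactly
enumerated posterior within 1% total variation (the acceptance bound is 2%).

Posterior probability of a marker set is the fraction of retained
(post burn-in) samples in which exactly that set forms a block, tracked
separately for associated and dependency kinds. Reported *interaction
groups* are associated-kind sets of two or more markers at posterior ≥ 0.5:
dependency blocks appear legitimately on phenotypically null data whenever
markers are in LD, so they are kept in the `sets` table with their kind
rather than reported as interactions. The production-scale convention
(1,000,000 iterations, 990,000 burn-in — i.e. retain the final 1%) is the
`run_config()` default; tests and examples use desk-scale chains (50k–320k
iterations) with the same retained fraction.

In recovery studies, a detection is a reported associated group
*containing* the planted interactors. With local LD in the panel the block
occasionally recruits a hitchhiker marker tightly linked to a true
interactor (or substitutes one); direct score evaluation shows these
supersets genuinely dominate the posterior, so exact-set matching would
penalize the sampler for being right. At the reference settings (n = 400, 30
candidates, 50k iterations, cell effects of two residual SDs) detection is
19/20 seeds with 0/20 false reports on null phenotypes.

### Two-locus verification

`two_locus_test()` is ordinary least squares of $y$ on
$[1, g_a, g_b, g_a g_b]$ with a two-sided $t$ test on the product
coefficient, solved by normal equations and cross-checked against `lm()` in
the tests. `pairwise_p_range()` applies it to all $\binom{k}{2}$ pairs of a
reported group and returns the (min, max) p-value range that accompanies
each group in the output table (`interaction_table()`). Degenerate pairs
(collinear dosages, zero residual variance with a non-zero coefficient) are
excluded with a warning.

## Numerical and convention notes

* Coordinates are 1-based and closed throughout; BED input is shifted on
  read. Windows start at position 1 and advance by the step size.
* Genotype loading rejects missing calls unless the user opts into
  `drop_marker` or `mode_impute`; the original pipeline imputed externally,
  and silently guessing a policy seemed worse than asking.
* Marker order after any load is deterministic: (chromosome, position,
  marker id).
* The MCMC caches per-block score contributions and recomputes only the one
  or two blocks a proposal touches; acceptance uses score differences, so
  log-marginal drift cannot accumulate.
* Dosage values are strictly 0/1/2 after load; all downstream stages rely
  on it.

## Known limitations

* The generator's LD is first-order Markov; long-range haplotype structure
  and recombination hotspots are absent.
* K2P on diploids discards heterozygote-involved comparisons; on an
  outbred panel this would be wasteful and a different convention should be
  used.
* The partition model treats samples as exchangeable: population structure
  enters the GWAS through kinship and PCs but is not modelled inside the
  epistasis score, where it can surface as dependency blocks.
* Production-scale searches over thousands of candidate markers are
  supported in principle but not an acceptance surface here; they need the
  full iteration budget and patience.
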