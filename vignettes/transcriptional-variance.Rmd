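---
title: "Ranking transcriptional variance across studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking transcriptional variance across studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txvar)
```

# The problem

How variable a gene's expression is across individuals — its transcriptional
variance — is a gene-level trait in its own right: some genes are tightly
buffered across essentially all tissues, others respond broadly to
environment and context. `txvar` implements a pipeline for measuring this
trait from panels of bulk RNA-seq studies and asking whether the *ordering*
of genes by variance is conserved across studies, tissues and data sources;
and, if so, what functional and regulatory features track that ordering.

The pipeline has five stages:

1. **Per-study processing** (`run_study_pipeline()`): for each study
   independently, keep control samples and sum technical replicates; filter
   genes on counts-per-million; variance-stabilize; regress out curated
   covariates per gene by OLS; drop outlier samples by robust-PCA
   Mahalanobis distance; report each gene's residual standard deviation (and
   its pre-correction mean).
2. **Cross-study structure** (`build_sd_matrix()`,
   `spearman_correlation_matrix()`, `pcoa()`): assemble the gene-by-study SD
   matrix *D* (union of genes, with missingness), compute the
   study-by-study Spearman correlation of its columns over complete-case
   genes, and embed studies by classical MDS of the `|1 - rho|`
   dissimilarities.
3. **Dyadic model** (`build_dyads()`, `fit_dyadic_model()`): explain the
   Fisher-z study-pair correlations with a Bayesian random-effects model
   that accounts for the non-independence of pairs sharing a study.
4. **Consensus ranks** (`compute_rank()`, `compute_mean_rank()`,
   `compute_tissue_ranks()`): project genes onto the leading eigenvector of
   the across-study correlation structure to obtain one variance rank (and,
   with identical machinery, a mean-expression rank and tissue-level ranks).
5. **Functional statistics** (`assign_deciles()`, `term_decile_profile()`,
   `hypergeometric_enrichment()`, `env_responsiveness_tests()`,
   `env_count_glm()`, `weighted_connectivity()`, `windows_to_genes()`,
   `chromatin_state_proportions()`, `partial_spearman()`): relate the rank
   to annotations, environmental responsiveness, co-expression connectivity,
   nucleotide-diversity-like window tracks and chromatin states.

Everything is testable offline because the package ships a synthetic
multi-study generator with known ground truth (`generate_multistudy_counts()`
and friends).

# The per-study model and its knobs

The unit of analysis is the *residual* SD on a variance-stabilized scale:
counting noise and the mean-variance relation of RNA-seq counts are removed
first so that the SD reflects across-individual biological variability.

* **cpm filter** (`min_cpm_all = 1`, `min_cpm_mean = 5`): a gene must reach
  1 cpm in *every* sample and 5 cpm on average. Library sizes are totals
  over pre-filter genes; the filter is idempotent because removing genes can
  only raise the cpm of the survivors.
* **Variance stabilization**: size factors by median-of-ratios, then the
  closed-form transform for a negative binomial with dispersion trend
  `disp(mu) = a/mu + b`,
  `vst(q) = log2((1 + a + 2bq + 2*sqrt(bq(1 + a + bq))) / (4b))`,
  with `a, b >= 0` fitted by least squares to per-gene method-of-moments
  dispersions. Method-of-moments estimates may be negative (under-Poisson
  genes); they stay in the fit and the coefficients are clamped, with
  `b` floored at 1e-8 so the transform is always defined. Exact numerical
  agreement with any particular external implementation is a non-goal; the
  tested contract is de-trending (on NB data with constant dispersion the
  post-transform Spearman correlation between gene mean and gene SD must
  fall from above 0.8 to below 0.2 in magnitude). A `log2(cpm + 0.5)`
  fallback (`method = "logcpm"`) exists for robustness checks.
* **Covariate correction**: one OLS per gene on an intercept, dummy-coded
  categorical covariates and standardized continuous ones. Aliased columns
  are dropped with a warning rather than an error because heterogeneous
  real metadata routinely produces them. Residual means are identically
  zero, so the reported gene mean is taken from the pre-correction
  variance-stabilized matrix — the residual mean carries no information.
* **Outlier removal** (`quantile = 0.99`): the referenced automatic
  robust-PCA detector is not fully specified, so the package commits to a
  simple deterministic variant: genes centred/scaled by median and MAD,
  samples projected on the top components (enough to explain 70% of
  variance, capped at 10), robust centre = componentwise median, diagonal
  MAD covariance, and removal of samples *strictly above* the empirical
  (linearly interpolated) distance quantile. On continuous distance data
  this removes `floor(n * (1 - quantile))` samples — about 1% at the
  default — which is the behaviour a percentile rule implies.

# The dyadic correlation model

Each pair of studies *i > j* contributes one Fisher-z correlation
`z_ij = atanh(rho_ij)`, modelled as

```
z_ij ~ Normal(mu0 + alpha_i + alpha_j + beta[t_ij] + gamma[so_ij], sigma)
alpha_i ~ Normal(0, sigma_alpha)
```

where `t_ij` is 1 for same-tissue pairs and 2 otherwise, and `so_ij` indexes
the six unordered source pairs, lexicographically over {GTEX, MISC, TCGA}:
GTEX–GTEX = 1, GTEX–MISC = 2, GTEX–TCGA = 3, MISC–MISC = 4, MISC–TCGA = 5,
TCGA–TCGA = 6. Priors: `mu0 ~ N(0, 1)`; `beta, gamma ~ N(0, 0.25)` (SD one
quarter — weakly informative given that z values live roughly in 0 to 1.5);
`sigma, sigma_alpha ~ Exponential(1)`. A sample-size covariate is
deliberately omitted.

**Identifiability.** The intercept, the two `beta` levels and the six
`gamma` levels enter the mean as a sum, so the raw levels are confounded;
only contrasts are interpretable. `summarize_posterior()` therefore reports
`beta[1] - beta[2]` (the tissue-congruence effect) and `gamma[k] - gamma[6]`
alongside the raw draws, and the recovery tests assert coverage of
contrasts, never of levels.

**Sampler.** The location block `(mu0, beta, gamma, alpha)` is jointly
Gaussian given the two scales, so it is drawn exactly from its conditional
(one Cholesky solve per sweep); `log sigma` and `log sigma_alpha` are
updated by adaptive random-walk Metropolis with dual-averaging step-size
tuning during warmup (target acceptance 0.44). This blocked
Metropolis-within-Gibbs converges essentially immediately — split-R-hat is
typically below 1.01 at the default 4 chains x 1000 warmup x 1000 kept
iterations — which is why no external probabilistic-programming dependency
is used. Both scales are floored at 1e-4: on degenerate noise-free input
the residual scale would otherwise collapse and make the Gaussian block
numerically singular. Convergence failure (any R-hat above 1.05) is flagged
with a warning, not an error.

# The consensus rank

`compute_rank()` does, in order: keep genes present in at least half of the
studies (`min_presence = 0.5`); rank-transform each study column (average
ties) and scale to [0, 1]; impute missing cells by iterative truncated-SVD
reconstruction (`n_components = 2`, `tol = 1e-6`, `max_iter = 500`,
initialized at column means, observed cells never touched); eigen-decompose
the study-by-study Spearman correlation of the completed rank matrix;
project each gene's centred rank profile onto the leading eigenvector; and
orient the axis so a higher score means a higher per-study SD rank before
ranking scores 1..M. Imputation happens in rank space, which keeps it
scale-free and bounded.

Numerical notes, all tested:

* The imputation's fixed-point iteration has a geometric but sometimes slow
  tail (rates near 0.99 when the panel is close to rank one); hitting
  `max_iter` yields a warning and the best iterate, whose residual error
  (about 1e-4 on the [0, 1] rank scale) is far below the resolution of a
  rank position. On an *exactly* rank-one panel with `n_components = 2`,
  cells missing within a single column are not identified (a
  column-indicator second component fits all observed cells); realistic
  panels with per-study noise do not have this degeneracy.
* Eigenvector sign is fixed by the orientation rule; an exactly tied leading
  eigenvalue (probability zero on real data) is logged and resolved by the
  deterministic LAPACK ordering with the first-study-positive convention.
* Eigenvector weighting makes the consensus robust in both directions: a
  pure-noise study receives a near-zero loading and an *anti-correlated*
  study receives a negative loading, folding its reversed ordering back in
  as signal. Duplicating a study reweights the consensus slightly, so gene
  order is stable but not bit-identical under duplication.

Tissue ranks restrict to each tissue's studies and their complete-case
genes (no imputation); a single-study tissue inherits that study's own SD
rank. The mean rank runs the identical machinery on the companion matrix of
per-gene means. Tail gene sets ("top/bottom 5%") are always computed as
`floor(fraction * M)` of the M genes actually in a given rank — group sizes
are parameters, never constants.

# Functional statistics

* **Deciles**: `decile = ceiling(10 * rank / M)`; ranks are a permutation so
  assignment is deterministic and decile sizes differ by at most one.
* **Entropy** of a term's decile profile uses natural log, so it lives in
  [0, ln 10]; the reporting base is configurable.
* **Skewness** is Fisher–Pearson g1 of the multiset of decile indices, with
  0 under the zero-variance convention. Mass in low-variance deciles leaves
  a right tail, hence positive skew; mass in high-variance deciles gives
  negative skew. This matches the verbal sign semantics
  (low-variance-biased terms positive). The estimator itself was an open
  choice; g1 was chosen for familiarity and its exact antisymmetry under
  decile reversal, which the tests assert. Note one honest edge case: a
  profile with equal mass in deciles 1 and 2 only is *symmetric*, so its g1
  is exactly 0 despite being "low-biased" in location.
* **Enrichment** is the upper-tail hypergeometric test (verified against
  exhaustive enumeration for every table with a universe up to 60);
  Fisher's exact tests use the standard conditional two-sided definition;
  environment-count models are Poisson GLMs with the background category as
  reference; everything batch-mode is Benjamini–Hochberg adjusted.
* **Connectivity** is the per-gene signed sum of all-pairs Spearman
  correlations surviving BH at 1% FDR (t-approximation; exact permutation
  null for untied data at 10 or fewer samples), averaged over the studies
  in which the gene is expressed. `fdr = 0` means an empty network by
  convention. An absolute-value mode exists for sensitivity analysis. The
  blockwise matrix-product implementation is tested for exact agreement
  with pairwise brute force.
* **Intervals** use BED conventions throughout: 0-based half-open, strand
  ignored for overlap, flank clipping at 0 and the chromosome end. Window
  metrics are unweighted means over any-overlap windows; chromatin-state
  proportions are overlap fractions of the gene region extended by 10 kb.
  Both agree with a per-base scan oracle in the tests.
* **Group state comparisons**: the cited display names a signed-rank test
  for two *unpaired* gene groups, which a signed-rank test cannot be; the
  package defaults to the unpaired Mann–Whitney test and exposes a paired
  mode rather than silently resolving the discrepancy.
* **Partial Spearman** correlations (feature vs variance rank controlling
  for the mean rank) are Pearson correlations of rank residuals, with
  t-approximation p-values on n - 3 degrees of freedom; a feature perfectly
  explained by the control is reported as partial rho 0 rather than the
  correlation of rounding noise.

# The synthetic world

`generate_multistudy_counts()` draws, per study, negative-binomial counts
whose mean is `exp(log_mean + batch + covariate effects)` scaled by a
log-normal library size centred on 1e6 (so cpm thresholds behave as at
realistic depth). Each gene's *variance propensity* is
`consistency * shared + (1 - consistency) * study noise`; it enters as the
standard deviation (0.10 to 0.90 on the natural-log scale, via a probit
ramp) of mean-one log-normal noise multiplying the NB mean — biological
over-dispersion on top of a fixed counting-noise floor
(`dispersion_baseline = 0.05`). Outlier samples get a 4x noise scale.
Defaults are the toy panel used in the acceptance suite: 10 studies x 100
samples x 2000 genes, consistency 0.9, two batch levels, 1% outliers. Gene
log-means are Normal(log 100, 1.5) so that a low tail genuinely fails the
cpm filter and exercises missingness.

The annotation generator samples gene sets with decile-weighted
probabilities (`exp(-0.4 * distance-from-favoured-end)`) against the true
propensity rank; environment responsiveness is 10 binary labels at a 10%
marginal rate whose overlap is controlled by a breadth parameter (draws come
from a shared biased pool with probability `env_breadth`). The genomic
generator lays genes on one synthetic chromosome with gene length twice the
window size and gaps of one window, which guarantees a tiling window touches
at most one gene; the window metric mixes a monotone transform of the
propensity rank (weight `effect`) with uniform noise, and the segmentation
partitions the chromosome with active-state share decreasing in propensity
decile.

What the generator does *not* emulate: read-level artifacts (GC bias,
mapping error), gene-gene correlation structure beyond what the shared
propensity induces, realistic annotation topology, or any characterization
of the true biological process generating inter-individual variance — the
log-normal noise choice is a stand-in, not a claim about data. A green test
therefore establishes that the pipeline recovers the structure this world
contains (and stays calibrated when it contains none), not that it would
recover the structure of any particular real compendium. Scaled-down Monte
Carlo checks widen tolerances proportionally to the larger sampling error
at the smaller n (e.g. the null window-metric correlation bound is 0.2 at
200 genes where a 5000-gene check would use 0.05).

# Known limitations

* The sampler's scale floor (1e-4) makes exactly-zero residual variance
  unreachable; irrelevant for data with any noise.
* PCA imputation is only proven useful at modest missingness concentrated
  away from single columns; the 50% presence rule keeps it in that regime.
* The VST is a self-contained reimplementation; studies processed with a
  different stabilizer should not be mixed into the same SD matrix.
* No across-study normalization is attempted by design — studies are
  processed independently and only their within-study orderings are
  combined.
* Residual mean-variance trend can survive the VST in some studies; the
  pipeline reports it in diagnostics and deliberately applies no further
  correction.
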