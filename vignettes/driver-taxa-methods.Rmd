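---
title: "Identifying driver taxa in paired microbiome cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying driver taxa in paired microbiome cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdrivers)
```

`microdrivers` implements the post-sequencing arm of a paired
before/after-treatment (BT/AT) gut microbiome study: starting from an
ASV-by-sample count table it quantifies diversity shifts, asks whether the
community is assembled by stochastic or deterministic processes, builds
compositionality-aware co-occurrence networks per state, and compares the two
networks node by node to call *driver taxa* — organisms whose interaction
partners rewire and whose centrality grows after treatment. A synthetic
paired-cohort generator with planted structure gives every stage a
ground-truth recovery test. This vignette records the models, the defaults,
and the design choices, in that order of importance.

## The count table and its preprocessing

All stages consume a `count_table`: a non-negative integer ASV-by-sample
matrix plus per-sample metadata (`state` in BT/AT, `subject`, covariates).

**Filtering.** ASVs are kept when they are detected (count > 0) in at least
20% of samples *or* their mean relative abundance exceeds 2.5%
(`filter_asvs`, thresholds and the or/and combination configurable and
logged). Presence means count > 0 with no pseudo-detection threshold: ASV
tables are already denoised, and the filter's purpose is to remove taxa so
sparse that network and null-model stages would only see noise. Filtering is
idempotent and applied to the pooled table before any per-state split.

**Normalization.** Between-sample scaling uses trimmed-mean-of-M-values
(TMM) factors with the canonical trims (30% on log-ratios M, 5% on average
log-abundance A), precision-weighted, rescaled to geometric mean one;
`tmm_normalize` delegates to edgeR and returns counts per million of
effective library size. The test suite checks the factors against an
independent hand implementation of the trimmed weighted mean.

## Diversity

Richness counts detected ASVs; Shannon diversity uses natural logarithms
(the base is a convention choice; it is stated here and in the output
header). Rarefaction curves use the analytic hypergeometric expectation
rather than resampling. Beta diversity is Bray–Curtis on relative
abundances; ordination is classical PCoA (negative eigenvalues reported
unchanged, no Cailliez correction) and NMDS (Kruskal stress-1, best of
`restarts` starts, ASV scores by weighted averaging). Group structure is
tested by PERMANOVA with freely permuted labels — matching an unrestricted
`adonis` call — with an optional `strata` argument for a within-subject
permutation scheme, since the samples are paired; both are exposed because
the unrestricted test is what the field most often reports. The simple
differential-abundance screen is a two-sided Mann–Whitney test per ASV with
Benjamini–Hochberg adjustment; raw and adjusted p are both emitted.

## Community assembly

**Sloan neutral community model.** For each ASV, the observed occupancy
(fraction of samples where it is detected) is compared with the neutral
prediction from its mean relative abundance $\bar p$:

$$\hat F(\bar p) = 1 - I_d\!\left(Nm\,\bar p,\; Nm\,(1-\bar p)\right),$$

the upper tail of a Beta distribution at the detection limit $d$, with $d =
1/\text{mean library size}$ by default (standard practice when depths vary;
configurable). $Nm$ is fitted by Levenberg–Marquardt least squares on the
occupancy scale, initialized from a coarse grid over $10^0..10^5$ so the
optimizer never starts in a flat region. Goodness of fit is
$R^2 = 1 - SSE/SST$ computed on occupancies (never counts). Each ASV is
classed above/within/below the Wilson 95% binomial band of $\hat F$ at
$n$ = number of samples. Two caveats are worth stating: the band is
pointwise, and because $\bar p$ is itself estimated, somewhat fewer than 95%
of ASVs fall within it even on data simulated from the model (about 75–85%
at 50 samples in our tests); and $R^2$ compares occupancy spread, so its
absolute value depends on how much occupancy varies in the cohort. The fit
is performed separately on the BT and the AT table.

**Niche breadth.** Levins' index $B_i = 1/\sum_j (n_{ij}/N_i)^2$ is the
effective number of samples an ASV occupies. Each ASV's $B$ is compared with
its distribution over fixed-marginal count randomizations (vegan's
`quasiswap_count`, preserving row and column totals; the choice of null is
ours — the upstream description says only "random rearrangement"): above the
97.5th percentile is a generalist, below the 2.5th a specialist, otherwise
neutral; degenerate nulls are flagged neutral.

**C-score.** Species-pair segregation of the presence–absence matrix is the
mean number of checkerboard units $(r_i - S_{ij})(r_j - S_{ij})$. The null
preserves both marginals exactly via sequential 2×2 checkerboard swaps
(vegan's compiled `swap` engine; burn-in 5,000 swaps, 100 swaps between the
1,000 saved matrices — standard mixing guidance, configurable). SES =
(obs − null mean)/null sd; positive SES means segregation. Note that
thinning counts *successful* swaps: a matrix with almost no checkerboard
submatrices (e.g., nearly all taxa present everywhere) mixes extremely
slowly, and a matrix with none at all is degenerate and rejected — which is
why the C-score operates on cohorts with realistic patchiness, not on small
saturated toy tables.

## Co-occurrence networks

**SparCC.** Pearson correlations on relative abundances are distorted by
the compositional constraint; SparCC estimates basis correlations from
log-ratio variances. Per outer iteration, fractions are Dirichlet-resampled
from counts (+1 pseudocount), the full log-ratio variance matrix
$T_{ij} = \mathrm{var}\log(x_i/x_j)$ is reduced to basis variances
$\omega_i^2$ under a sparsity assumption by solving a linear system, and
$\rho_{ij} = (\omega_i^2 + \omega_j^2 - T_{ij})/(2\omega_i\omega_j)$.
Strongly correlated pairs (|ρ| > 0.1) are excluded from the system one at a
time for up to 10 rounds, so a few true correlations do not bias everyone
else's variances. The reported matrix is the element-wise median over 20
iterations, clipped to [−1, 1]. These defaults are the method's canon; the
upstream description states none. Edge significance comes from re-running
SparCC on tables whose ASV rows are independently permuted:
$p = (1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\})/(1 + B)$.

A practical warning the tests make explicit: with 25 samples per state the
null distribution of an estimated correlation has standard deviation
≈ 0.2, so a |ρ| > 0.3 threshold admits a substantial number of noise edges
no matter how good the estimator is. The planted-pair and null-calibration
tests therefore run at 200 samples, where the law-of-large-numbers claims
they encode actually hold; cohort-scale networks should be read as dense in
noise, which is also why driver lists at cohort scale are broad.

**Edges, modules, metrics.** Edges require |ρ| > 0.3 (strict) *and*
p < 0.05 (strict); a signed mode that keeps only positive ρ is available
and logged, because the upstream rule is written "ρ > 0.3" but negative
associations are ecologically meaningful. Isolated nodes are dropped.
Modules come from agglomerative greedy modularity maximization on |ρ|
weights; when the best found partition has Q ≤ 0 (no better than the
trivial partition, e.g. on a complete graph) a single module is returned
with Q = 0. Metrics are node/edge counts, average degree 2E/N, density
2E/(N(N−1)), average path length over connected pairs, and mean normalized
betweenness. Networks are built per state on the dominant community (at
most `network_top_n` = 150 most abundant ASVs in the pipeline), the scale
at which published co-occurrence subnetworks of this kind live.

**Indicator species.** IndVal$_{ik}$ = specificity × fidelity, where
specificity is the ASV's mean abundance in state $k$ over the sum of its
state means and fidelity its occurrence fraction within the state;
significance by state-label permutation.

## NetShift-style comparison and driver calls

For every node present in either network, with neighbor sets $A$ (BT) and
$B$ (AT): neighbor counts, shared and AT-exclusive neighbors, neighborhood
Jaccard $|A \cap B|/|A \cup B|$, and the neighbor-shift (NESH) score

$$\mathrm{NESH}(x) = \frac{|B \setminus A|}{|B|}
 + \frac{|B \setminus A|}{|A \cup B|}
 + \frac{|B \setminus A|}{K},$$

case-exclusive neighbors as a fraction of the case neighborhood, of the
union neighborhood, and of a network-level normalizer $K$. $K$ is taken as
the maximum case-exclusive count over all compared nodes, which makes the
third term a comparison against the most-rewired node in this pair of
networks; published per-node tables of this quantity are internally
consistent only up to such a network-level constant, which cannot be
recovered from a table alone, so NESH values are comparable within one
comparison, not across publications. DelBet is the difference in normalized
betweenness (AT − BT, each within its own network; absent nodes contribute
0), with positive values rescaled so their maximum is 1 by default — the
convention under which reported DelBet columns top out at exactly 1.000.
A node is called a **driver** when its NESH score reaches the 0.9 quantile
of all NESH scores *or* its DelBet is positive: the union of "strongly
rewired" and "gained centrality", mirroring how the two published driver
lists are combined. The `common_subnetwork` merge tags every union edge
BT-only/AT-only/both for plotting.

## Classification and covariate regression

**Random forest.** Features are TMM-normalized abundances z-scored per ASV
("standardized abundance"); samples are split 80/20 stratified by state.
Importances are mean decrease in accuracy (out-of-bag permutation
importance) and mean decrease in Gini, each ranked; the top-20 list follows
MDA. ROC and AUC use only the held-out split, with AUC in the
Mann–Whitney rank form (ties count ½), which is invariant to monotone
transforms of the scores.

**Covariate model.** The two-step procedure mirrors the published analysis:
an all-subsets screen on a Gaussian working model of log1p-counts scored by
adjusted R² (subsets up to 15 covariates enumerable; best per size
flagged), then a negative-binomial (NB2, log link) fit of the focal ASV's
counts on the selected covariates. The NB fit is our own iteratively
reweighted least squares with the dispersion from the Pearson chi-square
moment equation, alternated to convergence; it agrees with the ML reference
(`MASS::glm.nb`) to three decimals in the tests and reduces to the Poisson
MLE when the data are equidispersed. Term significance is a case-resampling
bootstrap of the coefficients (9,999 resamples in faithful mode, 999 for
screening): two-sided sign-based p and percentile 95% intervals. The
bootstrap-of-coefficients reading is the direct interpretation of
"significance of N bootstrap estimates"; interval coverage is verified at
0.92–0.98 over 200 simulations in the test suite.

## The synthetic cohort generator

`simulate_paired_cohort` emulates the study design the pipeline targets:
25 subjects × 2 states, library sizes negative-binomially dispersed around
29,319 reads (the dispersion is a free parameter — per-sample depth
variance is not reported upstream — defaulting to size 5, i.e. CV ≈ 0.45),
and a log-normal (sdlog 2) community over ~2,000 ASVs. Planted structure:

* **differential taxa** — a log2 fold change applied multiplicatively in AT;
* **correlation modules** — members load on a shared latent Gaussian factor
  (copula on the whole per-sample log deviation) only in their designated
  state, so `r` is the expressed log-abundance correlation and count
  marginals are preserved; negative `r` alternates loading signs;
* **indicator taxa** — present only in their state, lifted to the
  community's upper quartile so they are detectable;
* **covariate effects** — linear coefficients on the focal ASV's log-mean
  per standardized covariate; covariates follow the questionnaire the
  pipeline models (age uniform 18–70, height/weight Gaussian, education and
  six habit variables Bernoulli/ordinal, constant within subject).

`simulate_neutral_community` draws each sample's composition from a Dirichlet
with concentration $Nm \times$ source community and reads multinomially, so
the NCM fit has a true $Nm$ to recover. Column sums equal the drawn library
sizes exactly, and the seed fully determines the output.

What the generator does **not** emulate: taxonomy and phylogeny, chimeras
and sequencing error (inputs are assumed denoised), realistic zero-inflation
beyond what the log-normal/multinomial hierarchy produces, and longitudinal
drift beyond the single BT→AT contrast. Passing recovery tests therefore
demonstrate that the estimators see the structure they model, not that real
cohorts are this clean.

## Numerical choices and problem sizes

* One master seed fans out to stages by fixed offsets (seed + 1, + 2, …),
  so a single integer reproduces a pipeline run.
* NCM fitting: grid initialization 10^0..10^5 (quarter-decade steps), then
  `nlsLM`; degenerate occupancy (all 0/1) is an error.
* Sequential swap: burn-in 5,000, thin 100; niche nulls: `quasiswap_count`.
* SparCC: 20 iterations (10 in the pipeline default for runtime), +1
  pseudocount, exclusion threshold 0.1, ≤ 10 exclusion rounds; permutation
  edge test with ≥ 20 bootstraps.
* Tie-breaks: TMM reference ties resolve to the first sample; rank ties in
  importances resolve first-come; the modularity Q ≤ 0 collapse is described
  above.
* Test-suite problem sizes are chosen to make the statistical claims sharp
  at desk scale: correlation calibrations at 200 samples, type-I error of
  PERMANOVA over 500 null cohorts of 20 samples, NB bootstrap coverage over
  200 simulations of n = 200 with 999 resamples, NCM recovery over 5 cohorts
  of 50 samples × 300 ASVs, end-to-end driver recovery on a 150-ASV cohort.

## Known limitations

* With 25 paired samples the |ρ| > 0.3 edge rule admits noise edges; driver
  lists at cohort scale are correspondingly broad, and the sharpest use of
  the NetShift comparison is ranking (NESH/DelBet order) rather than the
  binary driver flag.
* The NESH network-level normalizer is a documented choice, not a derivable
  constant; compare NESH within a run only.
* The moment (Pearson) dispersion estimator is not the ML estimator; the
  coefficient estimates agree closely but the dispersion itself can differ
  by ~10% from `glm.nb`'s θ.
* PERMANOVA's unrestricted permutations ignore subject pairing unless
  `strata` is supplied.
* The pipeline fits the NCM to whatever cohort it is given; on cohorts that
  are not neutrally assembled the fitted $Nm$ is a descriptive summary, not
  a migration-rate estimate.
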