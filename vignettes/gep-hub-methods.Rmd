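---
title: "Gene expression programme hubs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene expression programme hubs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gephub)
```

# The analysis this package implements

Longitudinal single-cell studies of inflammatory bowel disease profile gut
biopsies from many patients, sites and timepoints. Beyond cataloguing cell
states, a central question is which *gene expression programmes* (GEPs) —
continuous transcriptional modules that cells use to varying degrees — rise
and fall together across tissue samples, forming coordinated "hubs" of
multicellular inflammatory biology. gephub implements that analysis
end-to-end:

1. quality filtering and TP10K log-normalisation of a cells × genes UMI
   matrix;
2. derivation of GEPs per cell compartment by consensus non-negative matrix
   factorisation (NMF);
3. discovery of hubs of covarying GEPs with a quantile-activity permutation
   test, Benjamini-Hochberg FDR control, and signed-network community
   detection;
4. a composite 0–10 tissue inflammation score with a healthy-derived cutoff,
   two-of-three remission rules for Crohn's disease (CD) and ulcerative
   colitis (UC), and a six-pattern taxonomy of longitudinal abundance
   changes;
5. projection of fixed GEP spectra onto bulk or spatial expression profiles
   by non-negative least squares (NNLS).

Every stage is exercised on synthetic atlases with planted ground truth, so
the pipeline is testable without any external data.

# The synthetic atlas generator

`atlas_config()` / `generate_atlas()` emulate the statistical structure the
downstream methods assume, with every planted quantity returned as ground
truth.

**Programme structure.** Each compartment owns `k_true` GEPs. Spectra are
gene-probability vectors: a uniform background plus a dedicated high-weight
gene block per GEP (blocks are disjoint and exclude the signature genes, so
programme identity and inflammation signal do not confound).

**Sample-level covariation.** Per-sample mean usages are log-normal. On the
log scale, GEP $k$ in sample $s$ receives
$\sigma\left(\sqrt{\rho}\, f_{s,h(k)} + \sqrt{1-\rho}\,\varepsilon_{s,k}\right)$
with a standard-normal factor $f$ shared by all GEPs of hub $h(k)$ and
idiosyncratic noise $\varepsilon$; $\rho$ is
`within_hub_usage_correlation` and $\sigma$ (`usage_sd`, default 0.6) the
overall sample-to-sample variability. Hubs deliberately cut across
compartments so that cross-compartment covariation — the signal the
permutation test targets — is present by construction. With $\rho = 0.7$ and
40 samples the realised correlation of within-hub sample mean usages is
about 0.67 (finite cells and the log-normal transform shrink it slightly
below the latent target).

**Inflammation.** GEPs listed in `inflammation_effect_geps` (by default the
members of hub 1) have mean usage multiplied by
`1 + inflammation_effect_size` in inflamed samples; `signature_genes` are
upregulated `signature_effect_size`-fold there, independently of programme
structure, giving the inflammation score something real to detect.

**Counts.** Per-cell usages are gamma-distributed around the sample means
(shape 4), and counts are drawn by gamma-perturbed multinomial sampling:
a library size is drawn per cell (negative binomial around
`library_size_mean`), gene probabilities proportional to
$W_{\text{true}} H_{\text{true}}$ are jittered by
$\mathrm{Gamma}(\theta,\theta)$ multipliers with
$\theta$ = `noise_dispersion`, and the cell's counts are multinomial given
its library size. This gives negative-binomial-style overdispersion while
the total count of every cell equals its drawn library size *exactly* —
conservation that a plain independent-gene NB draw cannot guarantee — and
approaches the Poisson-multinomial limit as $\theta \to \infty$.

**What the generator does not emulate:** batch effects, doublets, ambient
RNA, spatial coordinates, realistic gene-gene correlation beyond programme
structure, or clinically realistic index distributions (remission labels are
assigned by configuration; the remission classifiers are tested on explicit
index fixtures instead). Passing tests therefore demonstrate correctness of
the algorithms under the planted model, not robustness to every artefact of
real data.

# Quality control and normalisation

`filter_cells()` removes cells expressing fewer than 500 genes or with a
mitochondrial fraction above 60%; both removal conditions are strict
inequalities, so a cell at exactly 500 genes or exactly 60% is retained.
`filter_genes()` keeps genes detected in at least 3 cells. Filters are
applied cells-then-genes and are idempotent. `normalize_tp10k_log()` scales
each cell to 10,000 counts and applies $\log(1+x)$; `pseudobulk()` sums
counts per sample.

# Consensus NMF

`factorize_once()` minimises $\lVert X - WH\rVert_F$ with non-negative
factors by hierarchical alternating least squares (HALS) with several inner
sweeps per cached cross-product; the solver is recorded in the model object.
`consensus_factorize()` pools L2-normalised spectra from `n_restarts`
seeded restarts, drops outlier components whose nearest-neighbour distance
exceeds a threshold — by default the 95th percentile of nearest-neighbour
distances, a reproducible stand-in for inspecting the distance histogram —
clusters survivors by seeded k-means, takes per-cluster medians as consensus
spectra, and refits every cell's usage against the fixed consensus by NNLS
(active-set).

**Choosing k.** `select_k()` reports the mean silhouette of pooled restart
spectra against their consensus clusters and the Frobenius error per
candidate `k`. A subtlety discovered during development dictates the
selection rule: with a convergent solver, restarts agree essentially
perfectly for *every* `k` at or below the true programme count (a merged
programme is merged the same way every time), so silhouettes sit at the
ceiling throughout and a literal argmax would always return the smallest
candidate. Selection therefore treats every `k` within `silhouette_tol`
(default 0.02) of the best silhouette as equally stable and picks the
smallest reconstruction error among them, ties to smaller `k`. This makes
both stated criteria — stability *and* error minimisation — consequential.
Biological interpretability of top-weighted genes is deliberately not
automated; the diagnostics table and `top_genes()` (150 genes per programme
by default, 50 for shared-gene displays) support human review.

`gep_gene_scores()` regresses z-scored expression of every gene jointly on
all usage columns (multiple least squares, no intercept), the standard way
of ranking programme-associated genes.

# Hub discovery

**Activity.** `activity_quantiles()` summarises each GEP per sample by five
empirical quantiles (0.25, 0.5, 0.75, 0.95, 0.99; linear interpolation) of
its usage over the sample's cells of the GEP's own compartment. Samples
with fewer than 10 such cells are flagged; samples with none are missing.

**Test statistic.** For each GEP pair, Pearson correlations across samples
are computed per quantile, Fisher-transformed
($\mathrm{atanh}$, clipped at $|r| = 1-10^{-7}$ so degenerate perfect
correlations stay finite), and averaged into a single statistic. The five
quantile correlations enter jointly through this mean; zero-variance
quantiles are excluded with a note.

**Permutation null.** `permutation_null()` shuffles the cells' sample
identities within each compartment stratum (cell type is kept constant, and
per-sample cell counts are preserved exactly), recomputes quantile
activities and the statistic, and repeats `n_perm` times (10,000 at study
scale; smaller for the packaged fixtures, stated below). The two-sided
p-value is twice the smaller of the counts of permuted statistics at or
above / at or below the observed value, divided by the number of
permutations and floored at `2/n_perm` (the minimum resolvable two-sided
value — zero p-values never occur). The adjusted correlation is the mean
observed minus mean permuted correlation, on the correlation scale; the
Fisher scale is used only for testing and edge weights. All tested pairs
form one BH family at FDR 10%.

**A calibration caveat worth knowing.** The null hypothesis of this design
is *exchangeability of cells across samples within a compartment*. Under
that null, p-values are super-uniform by construction (measured fraction at
or below 0.05: 0.038 over 200 pairs). If, however, individual GEPs carry
independent per-sample latent variability — no covariation, but real
sample effects — the observed correlations have heavier tails than the
cell-resampling null and the test over-rejects (measured: 0.148 at nominal
0.05 with `usage_sd = 0.6`). This is intrinsic to the published design, not
an implementation artefact; in practice it means the FDR-controlled edge
list should be read as "sample-level structure beyond cell sampling", and
weak edges treated with care. The hub detection below is designed to be
robust to such weak spurious edges.

**Signed network and hubs.** Significant edges, weighted by the signed mean
Fisher-z, form a network on which `detect_hubs()` operates in three stages:

1. *Resolution sweep.* Signed modularity (positive-part modularity minus
   negative-part modularity, each with its own configuration-null strength
   term, jointly normalised) is optimised by a seeded greedy
   local-move-plus-merge search at 40 log-spaced resolutions in
   $[0.001, 0.2]$.
2. *Consensus.* Node pairs co-clustered in at least $\tau = 0.2$ of the
   resolutions are linked; connected components of the link graph form the
   base partition. Because such low resolutions barely penalise merging,
   this consensus errs deliberately towards coarse hubs.
3. *Iterative splitting.* Every hub larger than three nodes is a candidate:
   a split is proposed by signed-modularity partitioning of the hub's
   subgraph at unit resolution (the standard null strength) and accepted
   only if it strictly improves the signed modularity of the full solution,
   evaluated at resolution 1; accepted splits are revisited until nothing
   improves. Three-node hubs are never split. This is the step that refines
   the deliberately coarse consensus: proposing splits with the same
   low-resolution sweep would never propose anything (verified during
   development — planted-hub recovery then plateaus at ARI ≈ 0.5), whereas
   the unit-resolution proposal recovers planted partitions exactly while
   leaving genuinely cohesive hubs (e.g. positive cliques) intact.

The resulting partition is deterministic given the seed and invariant to
node relabelling on clearly structured graphs.

**Inflammatory labelling.** `gep_inflammation_enrichment()` models each
GEP's per-sample mean quantile activity with a linear mixed model (fixed
effects: inflammation status, age, sex, site, disease duration, timepoint;
random intercept per patient; constant covariates dropped automatically;
OLS fallback with a warning if the mixed fit fails), BH-adjusts across
GEPs, and calls a GEP enriched when significant with a positive coefficient.
`label_inflammatory()` flags a hub when *strictly more than half* of its
members are enriched — a hub of four with two enriched members is not
inflammatory.

# Inflammation score, remission, and abundance patterns

`inflammation_score()` computes a single-sample rank-based running-sum
enrichment of a signature per sample: genes are ranked within the sample,
in-signature steps are weighted by $\mathrm{rank}^{0.25}$ (the exponent is
an exposed parameter), and the score integrates the difference between the
weighted in-signature and uniform out-of-signature cumulative curves. Raw
scores are min–max scaled to $[0, 10]$ across the scored cohort — scores
are therefore comparable only within a cohort, and whether to scale within
a disease subset is the caller's choice of input — and the cutoff is the
maximum score among healthy samples. The score depends on expression only
through within-sample ranks, hence is invariant to any monotone per-sample
transform.

Remission at follow-up is two-of-three: for CD, HBI < 5, no macroscopic
ulcers, Nancy ≤ 1; for UC, SSCAI ≤ 2, UCEIS ≤ 1, Nancy ≤ 1. Escalation to
another biologic forces nonremission regardless of indices. Both
classifiers are monotone: worsening an index never flips nonremission to
remission.

`classify_pattern()` maps the categorical outcomes of baseline and
longitudinal abundance tests to six patterns. The source taxonomy is
descriptive, so a fixed precedence order (3, 1, 4, 5, 6, 2 —
baseline-difference rules first, then concordant, then discordant changes)
and an `unclassified` fallback make the table total and deterministic; the
overlap between "decreases in remission only" (pattern 1) and "decreases in
nonremission, unchanged or decreased in remission" (pattern 2) when both
groups decrease is resolved in favour of pattern 2 by that order.
`abundance_change_test()` supplies the inputs with a binomial mixed model of
state membership (random intercept per patient; linear model on proportions
as fallback) and BH adjustment across states.

# Projection onto bulk and spatial profiles

`project_geps()` holds the spectra strictly fixed and solves a non-negative
least squares problem per sample on the shared genes. Fixing H (rather than
warm-starting a free factorisation) is deliberate: projection must not
alter programme identity. Negative input entries are clamped to zero with a
logged count; the expression scale of the input (RPKM, Q3, pseudobulk
TP10K, ...) is recorded, not changed, and projected usages are returned raw
with an optional per-sample sum-to-one renormalisation flag.
`summarise_projection_by_group()` compares usages across sample groups by
Kruskal–Wallis with BH correction across programmes and pairwise Wilcoxon
rank-sum follow-up only for significant programmes.

# Numerical choices and degenerate inputs

* Quantiles: type-7 linear interpolation throughout.
* Fisher transform clipped at $|r| = 1 - 10^{-7}$.
* Permutation p floored at `2/n_perm`; ties count towards both tails.
* NNLS: active-set (`pracma::lsqnonneg`) per cell/sample; all-zero samples
  get zero usages with a warning.
* HALS reseeds dead components from a random direction; convergence is
  declared on a relative error change below `tol` (checked every 10
  sweeps).
* k-means on pooled spectra is seeded; an empty consensus cluster (possible
  when outlier filtering removes too much) raises an error advising
  threshold relaxation.
* Rank-deficient usage matrices abort gene scoring with the collinear
  programmes named; constant activities and single-group strata are flagged
  untestable rather than tested.

# Problem sizes used in the packaged validation

The test-suite and acceptance fixtures run at desk scale, chosen so the full
validation completes in minutes while leaving each method enough data to
show its behaviour: planted-hub recovery uses 40 samples × 3 compartments ×
100 cells with 12 GEPs in 3 hubs and 1,000 permutations; null calibration
uses 200 GEP pairs at 1,000 permutations; consensus-NMF recovery uses 2,000
cells × 500 genes with k = 4 planted programmes, candidate range 2–7 and 10
restarts; the exhaustive permutation oracle uses 4 samples × 2 cells where
all 2,520 within-stratum relabellings are enumerable. Study-scale defaults
(10,000 permutations, more restarts) remain the documented defaults of the
corresponding functions.

# Known limitations

* The permutation test over-rejects when GEPs carry independent per-sample
  latent noise (see the calibration caveat above); hub membership is robust
  to the resulting weak edges, but edge lists near the FDR boundary are
  optimistic.
* Consensus stability cannot distinguish candidate programme counts below
  the true one; the error term in `select_k()` does that work, and the
  final choice of k remains a human decision in real analyses.
* The inflammation score is cohort-relative by construction.
* Batch correction, doublet detection, clustering/annotation, differential
  expression, and gene-set overrepresentation are out of scope; the package
  expects inputs already curated to that level.
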