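---
title: "Linking CpG methylation to gene regulation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking CpG methylation to gene regulation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most cis-regulatory elements (CREs) — enhancers, silencers, insulators —
lie far from the genes they control, and their activity is reflected in
the DNA methylation state of the CpG sites they contain. Given paired
methylation and expression profiles across many samples and many
biological contexts (e.g. tumour cohorts), this package reconstructs a
regulatory network linking methylation of candidate elements to the
expression of protein-coding genes within 1 Mb of each transcription
start site (TSS), ranks elements by an aggregate *regulatory potential*,
and calls *hubs*: elements whose methylation is associated with the
expression of several genes at once.

```{r, eval = FALSE}
library(methnet)
fx <- smoke_fixture(seed = 7)
res <- methnet_pipeline(fx$genes, fx$probes, fx$methylation,
                        fx$expression, fx$samples, seed = 7)
```

## From probes to candidate associations

Array probes within 200 bp of each other (complete linkage, inclusive
bound) are collapsed into *probe clusters* and their beta values
averaged; a cluster is treated as one candidate element. In one
dimension the globally nearest pair of complete-linkage clusters is
always an adjacent pair, so the implementation merges adjacent spans
nearest-first (ties toward the leftmost coordinate), which is exactly
textbook complete linkage but runs in near-linear time after splitting
at gaps wider than the diameter. Termination of the merge loop implies
maximality: no two neighbouring output clusters could be merged without
exceeding the diameter.

Every gene is then connected to all clusters whose midpoint lies within
1 Mb of its TSS. Distances are signed and strand-oriented (negative =
upstream of the TSS in the gene's reading direction). Coordinates are
0-based half-open throughout (BED convention, GTF converted on read);
the TSS of a minus-strand gene is `end - 1` of its body.

## The per-context expression model

For each gene $g$ and context $k$ we fit

$$y_{gi} = \beta_{g0}(z_i) + \sum_{c \in N(g)} \beta_{gc} x_{ic} + \varepsilon_{gi}$$

where $x_{ic}$ is the beta value of cluster $c$ in sample $i$ and
$\beta_{g0}(z)$ an unpenalized sample-type intercept (one-hot with
"normal" as reference; contexts with a single sample type get a single
intercept). The cluster coefficients carry an elastic-net penalty
$\lambda(\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2)$. Genes whose
per-context population standard deviation of expression is below 1 are
not modelled (inclusive boundary: sd exactly 1 is kept). Cluster rows
with more than 20% missing betas in a context are dropped; remaining
missing cells are mean-imputed per cluster, because the penalized
solver needs complete design matrices.

**Penalty selection.** $\alpha$ runs over $\{0.1, \dots, 1.0\}$ and is
chosen at the minimum mean 10-fold CV error; folds are shared across
$\alpha$ and seeded deterministically from the gene and context labels,
so fits are reproducible and independent of gene order. Within the
winning path, $\lambda$ follows the one-standard-error rule. By default
the fit is *relaxed*: cross-validation also scores the least-squares
refit on each active set (relaxation mixing $\gamma \in \{0, 1\}$) and
the 1-SE rule picks between the penalized and refitted solutions. This
matters for the quality of the recovered network: pure minimum-CV
selection is known to over-select, and on the package's planted
benchmark it yields a consensus precision near 0.25; the plain 1-SE
rule reaches about 0.66; the relaxed 1-SE fit reaches 0.95–1.0 while
keeping recall at 0.9–1.0. The relaxed refit also debiases the retained
coefficients, which downstream scores consume as magnitudes. Users who
want the textbook elastic-net solution — the one satisfying the
elastic-net KKT conditions at the selected penalty, as the test suite
verifies — can set `relax = FALSE`.

$R^2$ is cross-validated ($1 - \mathrm{CV\,MSE}/\mathrm{Var}(y)$), not
in-sample: it is the honest generalization measure, and it is floored
at zero when used as an aggregation weight so that failing models
simply drop out of the average.

## Consensus, score, potential, hubs

Coefficients are averaged across contexts where the gene was modelled,
weighted by $\max(R^2_k, 0)$, with zero coefficients included in the
average; the number of contexts with a nonzero coefficient is kept as a
robustness count. Negative consensus coefficients are *activating*
(methylation gain lowers expression), positive *repressing*.

Each retained association receives the score

$$b_{gc} = \log\frac{|\beta_{gc}|}{\sum_{c'}|\beta_{gc'}|} + \log k_g,$$

the information gain over a naive model in which all $k_g$ candidate
neighbours contribute equally $1/k_g$. The denominator runs over the
gene's retained consensus edges (zero coefficients cannot contribute),
while $k_g$ stays the full candidate count. Natural logarithms are used
throughout; the choice of base only shifts scores by a constant factor
and the distance detrending removes constants anyway. The identity
$\sum_c e^{b_{gc}} = k_g$ holds per gene and is asserted in the tests.

Because proximity alone predicts association strength in an
element-agnostic way, a penalized spline of $b_{gc}$ on $|d_{gc}|$
(univariate additive model, smoothness by GCV) is subtracted, and the
*regulatory potential* of a cluster is the sum of its distance-adjusted
scores, $b_c = \sum_g (b_{gc} - f(|d_{gc}|))$. Total potential is
conserved: clusters with no retained edge contribute zero.

**Hub calling.** Potentials are sorted in decreasing order and the
elbow of the curve is found with an *iterated* chord rule: the rank
maximizing the deviation below the chord joining the first and last
point becomes the new right chord anchor, iterating until the index
stabilizes. A single chord pass systematically overshoots on long-tailed
curves — on a curve with 20 planted values at 10 over a standard-normal
background, the single-pass maximum lands near rank 40 because the
normal order statistics bow far below the chord — whereas the iterated
rule converges to the population boundary exactly. The rule is
parameter-free, deterministic, and translation-equivariant; ties break
toward the smaller hub set. Degenerate curves (all equal, straight
ramps) are flagged and yield at most one hub.

## Characterization analyses

*Distance-rank profiles* rank each gene's outside-gene-body clusters by
distance within CpG-island and non-island classes (−1 = nearest
upstream, +1 = nearest downstream) and report the mean consensus
coefficient (candidate edges without an association count as zero — the
contrast between island and non-island behaviour depends on including
them) and the association probability per rank. Gene-body clusters are
summarized separately.

*Enrichment models* are ordinary least squares of potential on category
indicators: ChromHMM state labels (each cluster takes its
most-overlapped state, ties by a fixed priority list, "Low Signal" as
baseline), TF-binding indicators (one joint regression so co-binding
factors compete; intercept = unbound chromatin; all-zero factors are
dropped with a warning, perfectly collinear factors are dropped
lexicographically), and loop-count quartiles of 2.5 kb bins (zero-loop
bins as reference stratum). Benjamini–Hochberg adjustment is applied
within each family; BH is the package-wide default wherever an adjusted
p-value is reported.

*Survival.* For each element passing the methylation-variance filter
(bottom 25% excluded; all hubs plus a seeded random complement are
tested), a stratified varying-slope proportional-hazards model
`Surv(os_time, os_event) ~ beta * strata(context)` estimates the pooled
log-hazard per unit beta and per-context deviations. The covariate is
the raw beta in [0, 1]. Contexts with fewer than two events are dropped
per element; an element whose model cannot be fitted at all (e.g. all
samples censored) is reported with missing estimates.

## Chromatin-loop validation

An association of length ≥ 10 kb overlaps a loop when one anchor
intersects the cluster span and the other intersects the gene's
promoter (TSS ± 2.5 kb — the assay is promoter-capture, and the gene
body would be too permissive an interval); anchor order is immaterial.
Overlap ratios are reported in score deciles. For hub prediction, the
genome is tiled at the anchor resolution (5 kb), bin potential is the
sum of contained cluster potentials, and bins with at least a threshold
number of anchored loops are positives of a ROC analysis of bin
potential; the AUC uses grouped-tie threshold sweeping with trapezoidal
integration, which equals the midrank Mann–Whitney U statistic (the
tests assert this identity against an independent rank computation).

## Perturb-seq deconvolution

Guide effects are estimated jointly — most cells carry several guides —
by per-gene least squares of log-normalized expression on the binary
cell-by-guide design with empirical-Bayes variance moderation across
genes (limma), BH adjustment across all (guide, gene) pairs, and a
0.05 adjusted-p threshold. A targeted region *validates* when one of
its guides hits one of its network-predicted target genes; significant
effects on non-predicted genes are reported but do not count. The null
for the validated-region count permutes each design column
independently, preserving every guide's cell count and thereby the
per-guide confidence-interval widths; the empirical p-value uses the
add-one correction, so it is bounded below by $1/(1+\text{reps})$.
Genes enter the analysis when their TSS is within 1 Mb of a targeted
region and their mean normalized expression exceeds $2 \times 10^{-4}$
(on the per-cell proportion scale; the default normalization is
counts-per-total × 10⁴, log1p).

## The synthetic fixture and what it does (not) show

All tests run on generated data with planted truth. The default smoke
fixture is one 10 Mb chromosome, 20 genes in 3 gene-dense clumps, 400
probes in short bursts (one burst at every TSS, the rest uniform),
3 contexts × 150 samples (half tumour, half normal, tumour shift 1),
3 true edges per gene with $|\beta| \in [1, 2.5]$ and noise sd 0.5, and
3 planted promoter-proximal hubs regulating ≥ 5 genes each. Genes are
clumped because with 20 genes spread uniformly over 10 Mb no 1 Mb
window contains 6 genes, making a 5-target hub geometrically
impossible; clumping mirrors the gene-dense loci of real genomes.
Methylation is a per-cluster mixture of low/high logit-normal states
(mixing probability uniform on [0.35, 0.65]), member probes copy their
cluster value, and survival times are exponential with hazard driven by
the planted hubs and censoring rates that are proportional to each
sample's hazard (making censoring non-informative given covariates and
fixing the expected event fraction at one minus the censoring rate).

Loops are planted with deterministic per-score-bin quotas increasing
linearly from 0 to 100% across 10 equal-count score bins (interpolated
toward a flat 50% as `enrichment_strength` drops to 0). Quotas rather
than Bernoulli draws make the planted enrichment noise-free, so the
monotonicity of decile overlap ratios is a property of the method, not
of sampling luck; strictly increasing integer quotas need at least ~9
eligible associations per bin, and the generator warns below that.

The generator reproduces the model the pipeline fits. Passing tests
therefore demonstrate correctness of the estimation and scoring
machinery — not robustness to model misspecification. Real data differ
in ways the fixture does not emulate: correlated neighbouring clusters,
non-linear and threshold effects, batch structure, cell-type
heterogeneity, and copy-number confounding of both expression and
methylation. Problem sizes (20 genes, ~100 clusters, 450 samples, 2000
cells, 1000 permutations) were chosen so the full pipeline and test
suite run on a laptop core in minutes.

## Numerical choices and degenerate inputs

* Beta values outside [0, 1] are an input error naming the offending
  cell; matrices with ragged rows are rejected with a line number.
* Trans-chromosomal loop rows are parsed but excluded from all overlap
  statistics (the network is cis by construction).
* The spline basis dimension adapts to the number of distinct
  distances; fewer than 4 distinct values collapse the trend to a
  constant, and the residual mean is zero by least squares either way.
* Guides observed in fewer than 5 cells are dropped (their effect is
  not estimable with useful precision); duplicated (perfectly
  collinear) guide columns keep the smallest index.
* With fewer samples than CV folds, the fold count shrinks with a
  warning (never below 3).
* Elbow ties break toward the smaller hub set; an all-equal potential
  vector yields no hubs and a warning rather than an arbitrary cut.

## Limitations

The linear additive model reads each cluster's contribution
independently; synergy between neighbouring elements, and any
methylation effect not reflected in average beta, are invisible to it.
Associations are correlational — the perturbation and loop-overlap
layers exist precisely to add causal and physical support. Hub calling
depends on the shape of the sorted-potential curve; when the curve has
no clear bend the elbow is flagged degenerate and downstream analyses
should treat the hub set with suspicion.
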