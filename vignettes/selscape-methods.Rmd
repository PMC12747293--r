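---
title: "selscape: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{selscape: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`selscape` implements a genome-wide selection-landscape analysis for
prokaryotic lineages: maximum-likelihood dN/dS estimation under a codon
model, additive decomposition of log dN/dS into lineage-specific and
gene-specific constraints, splittable-lineage heterogeneity testing, gene
gain/loss flux estimation, and a correlation layer with bootstrap
confidence intervals. This vignette documents the models and their
assumptions, the tunable parameters with their defaults, what the synthetic
generators emulate, and the numerical decisions taken where the procedures
leave latitude. It states no empirical result that the package's test suite
or acceptance script does not itself compute.

## The codon model

The substitution model is a Goldman–Yang-style Markov process on the 61
sense codons of the standard genetic code. Codon pairs differing at more
than one position have instantaneous rate 0; a single-nucleotide change
from codon *i* to codon *j* has rate

\[ q_{ij} = \pi_j \,\kappa^{[\text{transition}]}\, \omega^{[\text{nonsynonymous}]} , \]

with `omega` the dN/dS ratio, `kappa` the transition/transversion rate
ratio, and `pi` the codon equilibrium frequencies. The generator is scaled
so that the expected substitution rate at equilibrium is 1 per *nucleotide*
site (3 per codon), so branch lengths are interpreted as substitutions per
nucleotide site — matching trees estimated from nucleotide columns of codon
alignments. The approximate mutation count of an alignment is then
`tree_length × nucleotide_columns`, which is the quantity thresholded by
the retention filter (≥ 32 per family; ≥ 70% of a lineage's families must
pass). Whether "number of sites" should count nucleotide or codon columns
is genuinely ambiguous in the source procedure; we chose nucleotide
columns, which makes the normalization of the rate matrix and the filter
consistent with each other.

Codon frequencies default to equal (1/61). The simulator and estimator use
the same model, which keeps recovery experiments internally consistent;
frequency estimation and among-site rate variation (gamma mixtures) are
deliberate non-goals — the latter roughly triples likelihood cost and the
recovery experiment does not require it.

### Likelihood and optimization

`estimate_dnds_ml()` maximizes the Felsenstein pruning likelihood on a
fixed topology over three parameters: `omega` in [1e-4, 20], `kappa` in
[1e-2, 1e2], and a single global branch-length scale in [1e-3, 1e3]
(per-branch optimization is an extension point; a global scale matches the
phylogeny-aware intent at desk scale). Optimization is L-BFGS-B on
log-transformed parameters, convergence tolerance ~1e-8 in log-likelihood.
The first start is deterministic (`omega = 0.5, kappa = 2, scale = 1`); two
seeded perturbed restarts guard against boundary traps but only run when
the first fit ends at a parameter bound or fails to converge — once an
interior optimum has converged cleanly, additional starts would re-find it.
Estimates within tolerance of a bound are flagged (`boundary_flag`) and
excluded from downstream matrices, mirroring the distrust of dN/dS
estimates pinned at uninformative values.

Reversibility is exploited numerically: with equilibrium frequencies `pi`,
the generator is symmetrized by `diag(sqrt(pi))`, eigendecomposed once per
parameter evaluation, and transition matrices for all branches follow by
exponentiating eigenvalues. Conditional likelihoods are rescaled per node
only when underflow actually threatens (entries below 1e-150), which for
desk-scale trees is never and saves half the evaluation time.

The independent cross-check is a Nei–Gojobori (1986) counting estimator:
synonymous/nonsynonymous site counts per codon, equal-pathway averaging
over orderings for codons differing at 2–3 positions (pathways through stop
codons excluded), and Jukes–Cantor correction. It is used in tests to
confirm that the two estimator families rank gene alignments consistently,
never as a substitute for the likelihood estimator.

## Decomposition of selection constraints

Per-lineage per-gene log dN/dS values are modeled as
`r[L,G] = F_L + R_G + e[G,L]`. Starting from zero, each backfitting
iteration adds the mean residual over a lineage's observed genes to `F_L`,
then the mean residual over a gene's observed lineages to `R_G`; both
updates are exact coordinate minimizations, so the objective
`E = Σ e²` never increases (asserted at every iteration). Iteration stops
when the change in `E` falls below `tol = 1e-6` or after
`max_iter = 1000` iterations.

The model is identified only up to a constant shifted between `F` and `R`.
We fix the gauge `mean(R) = 0` after convergence (the shift is absorbed
into `F`), which makes `F_L` interpretable as the lineage's mean log dN/dS
scale and `exp(F_L)` as its multiplicative constraint factor, comparable
across lineages. Zero initialization alone would select a data-dependent
solution; an explicit gauge makes results invariant to convergence details.
On complete matrices the converged solution equals row/column-mean ANOVA
estimates; on incomplete matrices it equals the normal-equations
least-squares solution — both are enforced in the test suite against
independent solvers (to equivalence tolerance 1e-6, which requires running
the backfit to a tighter internal tolerance than the 1e-6 *objective
change* default; the default is kept because it reproduces the source
procedure, and the equivalence test documents what the algorithm converges
to, not what one iteration budget achieves).

Outlier handling is made concrete as: standardize residuals by their sample
standard deviation, remove cells whose two-sided normal tail probability is
below `alpha / N` (Bonferroni over the `N` observed cells, `alpha = 0.05`),
refit once. The underlying description ("unlikely residuals under a normal
approximation") fixes neither the cutoff nor the iteration count; a single
Bonferroni-controlled pass is transparent, has ≈ `alpha` expected false
removals per matrix, and avoids the masking/over-removal ambiguities of
iterated deletion. Removals that would empty a row or column are skipped
and logged. Fits whose residual standard deviation is below 1e-8 are
treated as exact and trigger no removal (otherwise roundoff residuals would
be flagged).

Per-functional-class refits drop, per class, lineages with fewer than 10
observed genes in that class, and report pairwise Spearman concordance of
the class-specific `F` vectors over shared lineages.

## Splittable lineages

"Phylogenetic depth" is defined as the maximum root-to-tip path length of a
(sub)tree — simple, monotone in branch lengths, and consistent with common
usage for clades; mean depth or total subtree length are defensible
alternatives the source text does not disambiguate. A split edge qualifies
when both resulting subtrees have depth strictly greater than
`min_depth = 0.2` and at least `min_tips = 20` tips. "Maximizing the number
of genomes on both subtrees" is operationalized as max–min (maximize the
smaller tip count), the only reading under which "both" binds; ties break
deterministically by edge order. The remainder subtree keeps its path
length to the original root as a root edge, so branch-length totals are
conserved exactly across a split: `len(A) + cut + len(B) = len(tree)`.

Subtree unreliability: a subtree whose per-gene dN/dS estimates are more
than 30% equal to 1 (tolerance 1e-6) is flagged. Heterogeneity between
subtree constraints `F_A`, `F_B` uses the fold-difference measure
`max(exp(F_A−F_B), exp(F_B−F_A)) − 1`, flagged when strictly above 0.4
(a >40% difference).

The subtree bootstrap resamples codon *columns* with replacement (taxon
resampling would break the tree correspondence; the resampling unit is an
open question in the source procedure), re-estimates dN/dS on the subtree,
and reports the proportion of replicates exceeding the full-tree estimate.
Replicate RNG streams derive from `(seed, gene_id, replicate)`, and columns
are canonicalized (sorted lexicographically — sites are exchangeable under
the model) before resampling, so results are invariant to both evaluation
order and input column order.

## Gene flux

Ancestral presence/absence states come from two-pass Fitch parsimony:
up-pass state sets (intersection when non-empty, else union), down-pass
resolution inheriting the parent's state, root ambiguity resolved to
"present". Parsimony is a transparent, oracle-verifiable stand-in for
likelihood-based stochastic mapping; externally computed (e.g.
probabilistic) reconstructions can be ingested instead, binarized at 0.5
with the boundary mapping to present. Flux counting is method-agnostic:
per branch per family, child state minus parent state, positive differences
summed as gains and negative as losses, totals normalized by total tree
length, flux ratio = gain rate / loss rate. No change is counted above the
root (it has no parent branch). When no losses occurred the ratio is
undefined and reported as `NA` with an explicit flag rather than an error,
since downstream correlation stages can simply drop such lineages.

## Correlation layer

Spearman's rho is the Pearson correlation of midranks; p-values use the
t-approximation with n−2 degrees of freedom (the "asymptotic p-value"). An
exact permutation p-value is available for n ≤ 8 (the permutation count
beyond that is not worth pure-R enumeration; the asymptotic value is the
default everywhere).

BCa intervals resample `(x_i, y_i)` pairs jointly — the statistic is a
paired correlation, so the pair is the exchangeable unit. The bias
correction `z0` uses the strictly-less-than convention with half-weight for
ties, clamped away from 0 and 1 by half a bootstrap mass; the acceleration
`a` is the jackknife third-moment estimate; degenerate bootstrap
distributions collapse the interval to the point value. Failing resamples
(e.g. constant vectors) are redrawn, with an error if more than 10% fail.
Defaults: 1000 replicates, 95% level.

The subsampling null draws `subsample_size = 19` observations *without
replacement* within each of `n_draws = 10000` draws — it mimics drawing a
pseudo-group of the small clade's size from the large clade, which is a
subsampling question, not a bootstrap question. Per-node correlations
compute Spearman over the descendant tips of every internal node with
strictly more than 15 descendants; smaller nodes are reported as absent.

## Synthetic data: what it does and does not emulate

The generators produce the statistical structure the analysis assumes:

- `random_tree()`: coalescent-topology random trees with branch lengths
  rescaled to an exact total — shape-agnostic fixtures with exact
  total-length control, not a model of any real taxon sample.
- `generate_dnds_matrix()`: exactly additive lineage and gene factors plus
  Gaussian residuals, uniform-at-random missingness (the analysis does not
  model missingness, so uniform is the neutral choice), and sign-symmetric
  fixed-shift outliers. Defaults — `sd_F = sd_R = 0.5`, `residual_sd =
  0.3`, lineage-factor mean −1.5 (median dN/dS ≈ 0.2, typical of purifying
  selection) — give planted structure comfortably above the residual noise
  while leaving recovery nontrivial.
- Codon alignments evolve by exact Gillespie sampling per branch, which
  also yields true event counts for expectation oracles.
- Presence/absence histories evolve under the two-state gain/loss process,
  again by waiting-time sampling, returning true internal states.
- `generate_lineage_covariates()`: a Gaussian copula on the normal scores
  of the planted factors, with the Pearson coupling `2 sin(pi rho_s / 6)`
  that corresponds to the requested Spearman rho, mapped through a
  lognormal marginal (median 3 Mb, roughly 0.1–12 Mb — the span of real
  prokaryotic genome sizes).

What the generators do **not** emulate: phylogenetic autocorrelation of
lineage factors along the lineage tree (factors are i.i.d.), non-uniform
missingness (real gene×lineage tables are missing systematically, by gene
dispensability), horizontal transfer and rate heterogeneity in the gain/
loss process, and codon-frequency or among-site rate variation. A green
test therefore establishes that the algorithms recover the structure they
assume, at realistic sizes and noise levels — not that the assumptions hold
for any particular empirical dataset.

## Degenerate inputs and edge policies

- Alignments with fewer than two variable codon columns are rejected as
  degenerate rather than returning a boundary estimate.
- Codons with no synonymous single-step neighbor (ATG, TGG) are absorbing
  under `omega = 0`; the simulator handles zero-rate states explicitly.
- `dS = 0` makes the NG86 ratio undefined (`NA`), as does synonymous
  saturation beyond the Jukes–Cantor domain (proportion ≥ 3/4).
- Masks that would empty a matrix row or column are rejected (generation
  retries a bounded number of times; outlier removal skips such cells).
- All generators save and restore the caller's RNG state; every stage seed
  in the pipeline derives deterministically from the master seed, so a
  rerun with the same configuration is byte-identical.

## Known limitations

Single global branch scale (no per-branch re-estimation); equal codon
frequencies; no gamma rate variation; parsimony (not probabilistic)
ancestral states by default; polytomies are supported in flux counting but
split detection treats only binary resolutions of deep structure; the exact
permutation p-value is limited to n ≤ 8. Each is an extension point rather
than a structural obstacle.
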