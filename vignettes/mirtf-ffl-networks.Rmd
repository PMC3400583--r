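---
title: "Constructing miRNA-TF feed-forward-loop regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing miRNA-TF feed-forward-loop regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtfnet)
```

## The model

Transcription factors (TFs) and microRNAs (miRNAs) are the two main classes
of gene-regulatory molecules in animals: TFs act at promoters, miRNAs act
post-transcriptionally at 3' UTRs. When a TF and a miRNA jointly control the
same target, and additionally regulate one another, they form a mixed
transcriptional/post-transcriptional **feed-forward loop (FFL)** — one of the
most over-represented motifs in mammalian regulatory networks. `mirtfnet`
discovers these motifs in a typed edge set over three node classes (genes,
miRNAs, TFs) and five relation kinds (TF-gene, TF-miRNA, miRNA-gene,
miRNA-TF, gene-gene coexpression), and assembles the significant motifs into
an analysable regulatory network.

A **3-node FFL** is a triple (TF, miRNA, gene) in which both regulators
target the gene and at least one regulator regulates the other. The
regulator-regulator pattern fixes the class, and the three classes are
mutually exclusive:

| class | TF→miRNA | miRNA→TF |
|---|---|---|
| TF-FFL | present | absent |
| miRNA-FFL | absent | present |
| composite-FFL | present | present |

A **4-node FFL** replaces the single target with a coexpressed gene pair
{g1, g2}: under some labeling, TF→g1 and miRNA→g2 must be present, and at
least one of TF→g2 / miRNA→g1 must also be present. The extra coexpression
constraint lets the motif recruit targets whose individual regulator edges
are too sparse to form 3-node loops.

Because two regulators can share targets by chance, candidate (TF, miRNA)
pairs are screened with a **cumulative hypergeometric co-targeting test**:
with `m` genes targeted by the miRNA, `n` regulated by the TF, `x` jointly
targeted, and `Total` genes in the common target universe, the p-value is
the upper tail P(X ≥ x) for X ~ Hypergeometric(Total, m, n). P-values are
adjusted by Benjamini-Hochberg FDR and pairs with q < 0.05 (strict) are
retained. FFLs of surviving pairs that share a (TF, miRNA) regulation are
merged into one record per pair — a TF, a miRNA, and the list of joint
targets — and the merged records are expanded and unioned into the final
network, with per-edge provenance back to the contributing merged FFLs.

## Choice of the test universe

The co-targeting universe is the intersection of all genes targeted by any
miRNA and all genes regulated by any TF. When genome-wide background target
maps are supplied, `Total`, `m`, `n` and `x` are computed on those maps,
because the test asks whether the *global* targeting profiles of the two
regulators overlap more than chance; when no background is given the
analysis edge set itself is used, which makes the universe disease-specific
and the test conservative on small inputs. Both choices are logged at run
time. Genes that are themselves TFs count as part of the gene universe when
regulated at their promoters; the regulator-side test is restricted to
gene-class targets.

## Upstream edge prediction stages

**miRNA targets.** TargetScan-style prediction tables are filtered by
conservation (a site present in human, mouse, rat and dog by default) and by
total context score. Context scores are negative, with more negative
meaning stronger predicted repression, so the filter keeps records with
score ≤ −0.30, boundary inclusive. The −0.30 rule is read as a magnitude
statement: keeping only scores numerically above −0.30 would retain exactly
the *weakest* sites, contradicting the goal of high-confidence regulation.
The comparator is exposed
(`comparator = "ge"`) for users who want the literal reading.

**TF binding sites.** Promoter windows (default −1500/+500 around the TSS,
with the −1000/+500 variant available since both conventions are in use)
are scanned with position weight matrices using an information-weighted
similarity score: `score = (Current − Min) / (Max − Min)` where `Current`
sums `I(i) · f(i, b_i)` over positions, `f` are smoothed column frequencies,
and `I(i) = Σ_b f ln(4 f)` is the per-column information weight. The core
score applies the same formula to the 5 consecutive most informative
columns (leftmost on ties). Defaults follow the stringent published
practice: core ≥ 1.00, matrix ≥ 0.95, and a (TF, node) edge is emitted only
if the pair has at least one hit in every required species (human, mouse,
rat). Cross-species conservation is tested at pair level, not positional
overlap, since orthologous promoters are supplied independently per
species. Windows containing N are skipped rather than scored. The
pseudocount (default 0.25) is added to *normalised* column frequencies so
that scores are invariant to rescaling a count matrix — matrices from
different sources are often scaled differently. Published per-matrix
false-positive-minimising cutoff profiles are proprietary, so per-matrix
cutoff overrides are accepted instead.

**Coexpression.** Gene-gene edges come from all-pairs mutual information
(MI). The estimator bins the *ranks* of each vector into equal-frequency
bins (`round(n^(1/3))` bins by default), making the estimate exactly
invariant under strictly monotone transforms and robust to outliers; it is
validated against the closed-form Gaussian value −½ ln(1 − ρ²). The
significance threshold is calibrated on a permutation null: because the
estimator depends only on ranks, MI between two independent random
permutations *is* the exact null, sampled 10⁵ times by default. The working
significance level of 10⁻⁷ sits far beyond any desk-scale empirical
quantile, so the right tail is extrapolated by fitting an exponential to
the exceedances over the null's 99th percentile (a standard peaks-over-
threshold approximation); fully empirical calibration is available via
`exact_tail = TRUE` for reachable levels. Indirect edges are pruned by the
data-processing inequality: in every triangle the weakest edge is removed
when it is below `min(other two) × (1 − 0.15)`. Marking is done in a first
pass against pre-pruning weights and deletion in a second, so the result is
order-independent and idempotent — in-place variants can depend on edge
order. No claim of bit-compatibility with kernel-density MI implementations
is made; the estimator is a documented substitute validated by its oracle.

## Network analyses

Topology analyses run on the undirected simple projection (direction
ignored, parallel relations collapsed to one adjacency); a flag restores
relation-multiplicity counting. Dual gene/TF nodes are represented once,
under the gene role. Hubs are called per class by a top-quantile rule:
cutoff = the smallest degree among the top 20% of the class by degree,
hubs = nodes at or above the cutoff whose degree also strictly exceeds the
class median (the guard returns no hubs for degenerate all-equal classes).
The published hub-selection procedure is not algorithmically specified, so
this rule is this package's own and no attempt is made to reproduce the
published per-class cutoffs. Communities use clique percolation: k-cliques
(k = 3 by default) are adjacent when sharing k − 1 nodes, and communities
are node unions of the connected components of that adjacency; with k = 2
this degrades to ordinary connected components, which is asserted in the
tests. Seed-gene subnetworks keep exactly the merged FFLs whose TF, miRNA
or any target intersects the seed set. Feedback loops are reciprocal
TF↔miRNA regulations — the defining feature of composite FFLs.

## Synthetic data: what it does and does not emulate

Every pipeline input has a seeded generator with recorded ground truth:

- `gen_regulome()` plants FFLs of requested class and arity, then adds
  background edges at per-relation densities. Each plant takes its own
  (TF, miRNA) pair and dedicated target genes, so with zero background the
  enumerators must return exactly the planted loops — an exact recovery
  oracle. Background edges may create incidental FFLs or lawfully upgrade
  a planted pair's class (adding the reciprocal regulator edge turns a
  TF-FFL pair composite); recovery metrics therefore count planted members
  regardless of final class. One subtlety is intrinsic to the motif
  definitions: a 4-node plant's mandatory-plus-optional edges always
  contain one 3-node loop, so 3-node enumeration over a 4-node plant is
  expected to find it.
- `gen_expression()` draws root genes standard normal and children as
  parent + Gaussian noise along a dependency forest, giving a known
  conditional-independence structure for the MI/DPI stage.
- `gen_promoters()` embeds a PWM consensus at known offsets in uniform
  background sequence.
- `gen_annotations()` gives every id a private term and designated pairs a
  shared term with a controlled probability.

These generators emulate edge sparsity, planted structure and noise — not
the biology: no real degree distributions, no expression covariance of
tumor cohorts, no sequence composition bias, no miRNA site biology. Passing
tests therefore demonstrate algorithmic correctness on known truth, not
predictive accuracy on real regulomes.

## Numerical and design choices

- Hypergeometric and Fisher p-values are computed by explicit log-binomial
  term summation and checked against enumeration oracles to 10⁻¹²;
  `phyper`/`fisher.test` serve as independent cross-checks, not the
  implementation.
- Empirical permutation p-values use the add-one correction
  (r + 1)/(N + 1), so they are never exactly zero.
- The one-sided Kolmogorov-Smirnov statistic is D⁺ = sup(F_b − F_a) on
  right-continuous ECDFs with the asymptotic p-value
  exp(−2 D² n_a n_b/(n_a + n_b)); identical samples give exactly (0, 1).
- The across-miRNA summary of the target-enrichment permutation test is a
  paired t-test of observed counts against per-miRNA null means — one
  plausible reading of an under-specified published comparison; the
  per-miRNA empirical p-values are the primary output.
- The significance filter uses strict inequality (q < α); a pair with
  q exactly α is excluded.
- Merged-FFL tables imported without member-edge detail (`import_merged_ffls`)
  are expanded by the canonical template (first gene of a 4-node pair in
  the TF slot, required edges only), a documented lower bound on the edge
  set when constituent detail is unavailable.
- GO semantic-similarity scores are consumed as precomputed tables; the
  resampling null pools all random pairs across iterations (a per-iteration
  mode is available).
- The annotation-sharing relation is non-empty term-set intersection;
  exact-match mode is configurable.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on synthetic data at
sizes chosen to make each oracle comparison exhaustive and each stochastic
check well-powered: enumeration oracles on 100 random stores of ≤ 12 nodes,
clique-percolation oracles on ≤ 15 nodes, hypergeometric/Fisher enumeration
up to universes of 60, the Gaussian MI oracle at n = 10,000, chain-pruning
replicates at n = 1,500–2,000 samples, tree-recovery at 20 genes ×
1,000 samples, and a planted regulome of 20 TFs × 15 miRNAs × 80 genes at
5% background density for the end-to-end run. Null calibration of the MI
threshold uses 2×10⁴–10⁵ permutation draws depending on the requested
level.

## Limitations

- Identifier matching is case-sensitive and exact; symbol aliasing and
  orthology mapping are out of scope (per-species promoters must be keyed
  by the same node id).
- The hub rule is a quantile heuristic, not a fitted degree-distribution
  model; published per-class hub lists are not reproduced.
- The hypergeometric screen is run once per (TF, miRNA) pair on the
  configured universe, not separately per arity.
- Promoter extraction from genome assemblies, TargetScan's internal site
  prediction, TRANSFAC database content, and cross-platform expression
  unification are upstream of this package: it consumes their outputs in
  plain-text form.
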