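---
title: "Methods: network-based mechanistic analysis of IVIg response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based mechanistic analysis of IVIg response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ivignet)
```

## The scientific question

Pooled intravenous immunoglobulin (IVIg) is a multi-target therapeutic used
across a heterogeneous set of autoimmune and inflammatory diseases, with
clinical benefit that ranges from well established to absent. ivignet
implements a systems-biology workflow for asking *why*: it relates the
molecular definition of each disease — its set of effector proteins and its
curated pathophysiological processes — to the drug's protein-target profile,
through the topology of a protein–protein interaction network.

Diseases are grouped into four clinical response clusters: `DB` (definitely
beneficial), `PB` (probably beneficial), `MPB` (may provide benefit), and
`UPB` (unlikely to provide benefit). The packaged panel
(`ivig_disease_panel()`) transcribes the published 26-disease
characterization (7 DB, 6 PB, 9 MPB, 4 UPB) with each disease's processes
coded into five immune-system groups: 1 B cell-mediated, 2 T cell-mediated,
3 innate immunity/inflammation, 4 complement, 5 other. The full per-disease
effector lists are not redistributed, so the panel carries the published
effector *counts*; protein-level stages run on generated panels or
user-supplied tables with explicit effector columns.

## Cluster statistics

`build_frequency_table()` reports, per cluster and process group, the
percentage of the cluster's diseases annotated with at least one process of
that group. Presence/absence is the counting unit — a disease with three
innate-immunity processes counts once for group 3 — because the quantity of
interest is the fraction of *conditions* associated with a process class,
not process multiplicity.

`test_independence()` computes Pearson's chi-squared on the
cluster-by-group presence table (degrees of freedom
$(n_\text{clusters}-1)(n_\text{groups}-1) = 12$ for the full panel).
Individual cells are additionally tested with a 2×2 chi-squared of (this
cluster vs the rest) × (group present vs absent) over diseases, without
continuity correction. The per-cell method was a genuinely open design
point — displays of this kind mark single cells without stating how — and
the 2×2 partition was chosen because it asks exactly the question a marked
cell answers ("is this cluster unusual for this process group?"). The 20
per-cell tests are uncorrected by default to match common practice in such
tables; `cell_fdr = TRUE` applies Benjamini–Hochberg instead. Under
label-shuffled null panels the per-cell flag rate stays at its nominal
level (this is property-tested).

## Protein-overlap similarity and the cluster tree

For two cluster protein sets $C_1, C_2$ with overlap $O = |C_1 \cap C_2|$,
the similarity is

$$ S(C_1, C_2) \;=\; 100 \times \frac{O/|C_1| + O/|C_2|}{2}, $$

the arithmetic mean of the two overlap proportions, in percent. It is
symmetric, 100 exactly when the sets are equal, and 0 exactly when they are
disjoint.

`build_similarity_tree()` builds a strict binary tree by repeatedly merging
the pair of (groups of) clusters with maximal similarity. Two linkage rules
are implemented because the published description admits both readings:

* `"union"` (default): a merged node's protein set is the union of its
  children and similarities to it are *recomputed* on that union. Chosen as
  the default because branch percentages described as applying to "groups of
  clusters" are most naturally a property of the merged set itself.
* `"average"`: classical average linkage over leaf-pair similarities.

Equal similarities are broken lexicographically on the pair label, which
makes the topology invariant to input order (property-tested). The tree
serializes to Newick with branch similarities as internal node labels
(`as_phylo_tree()` returns an `ape` phylogeny).

`venn_partition()` produces the three compartments analyzed downstream:
`only_db` (DB-exclusive effectors), `db_without_upb` (DB effectors absent
from UPB — the compartment expected to carry response-relevant biology),
and `only_upb`.

## Pathway enrichment

`hypergeometric_enrich()` performs an over-representation test: with
universe size $N$, pathway size $K$, effective query size $n$ and overlap
$k$, $p = P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$. Only the
upper tail is tested because the question is whether effector compartments
*over*-represent a pathway. `bh_correct()` applies the Benjamini–Hochberg
step-up rule $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$ and flags pathways at
$q < 0.05$ by default.

The universe defaults to the union of all pathway members (the reference
database's own gene space), not the network: enrichment asks about effector
lists against the reference database, and the network plays no role in the
test itself. Because universe choice is consequential and not dictated by
anything in the problem, it is an explicit argument of `read_gene_sets()`.
Enlarging the universe with proteins in neither query nor pathways can only
shrink p-values; that monotonicity is property-tested.

`pathway_similarity_graph()` connects enriched pathways whose member sets
are mutually close on the network, using the symmetric Hausdorff distance
over shortest-path hops:
$d(P,Q) = \max(\max_p \min_q d(p,q),\; \max_q \min_p d(p,q))$, with an edge
when $d <$ threshold (strictly). Note that under raw hop counts a threshold
of 1 admits only distance 0, i.e. pathways with identical network coverage
— the strict reading is close to degenerate. A normalized metric (hops
divided by network diameter) is therefore provided
(`metric = "normalized"`); the hop metric with the strict threshold remains
the default so that the conventional parameterization is reproduced
verbatim, and the choice is surfaced rather than silently resolved.

## The mechanistic scorer

The core of the package is a stratified bagged ensemble of small multilayer
perceptrons that scores the relationship between a drug's target set $T$
and a disease's effector set $E$ on a protein network.

**Features.** Each $(T, E)$ pair maps to nine topological features:
minimum hop distance from $T$ to $E$; mean and median over targets of each
target's minimum distance to $E$; fraction of targets within 2 hops;
Jaccard overlap $|T \cap E| / |T \cup E|$; $\log(1 + |T|)$;
$\log(1 + |E|)$; $\log(1 + \overline{\deg}(T))$; and a random-walk
proximity — a personalized PageRank with restart probability 0.15 on the
effector set, summed over the targets. Distances between disconnected
components are imputed as network diameter + 1 so every feature is finite.
The literature on this family of models names only "topological measures";
this nine-feature set is the package's concrete choice, designed to cover
proximity, overlap and size effects, and it is fixed per run (the feature
names are stored on the fitted object).

**Stratification.** Drugs are stratified by target count, because
distance-derived features behave very differently for a 1-target drug than
for a 40-target one. Default stratum boundaries are the target-count
quartiles of the training drugs (no boundaries are prescribed anywhere);
single-class strata merge into their nearest neighbor with a warning.
Prediction routes each query to the stratum covering its mapped target
count and averages only that stratum's kept members (asserted by a test
that recomputes the score from the stratum's members by hand).

**Members and selection.** Each member draws a balanced Monte-Carlo
subsample — the same number of related and unrelated pairs, a fraction
(default 0.8) of the minority class — and trains a one-hidden-layer
perceptron with a single sigmoid output node and a hidden size drawn
uniformly from 7–11. Members are ranked by out-of-subsample accuracy (the
selection metric is unstated in the reference architecture;
out-of-subsample accuracy is the natural bagging choice) with ties broken
by member index, and the best 75% per stratum are kept:
$\lceil 0.75 \times m_s \rceil$ members of $m_s$ trained. The packaged
benchmark trains 40 members — the architecture is identical at 1000, only
the averaging is coarser — and the member count is a single config field.

**Optimizer.** `optimizer = "second_order_least_squares"` (default) fits
each member by quasi-Newton (BFGS) minimization of the squared-error loss,
honoring the second-order least-squares character of Levenberg–Marquardt
fitting without reimplementing that exact routine; the contract that
matters for the ensemble is convergence to a good local optimum of a
least-squares objective, not the step rule. `optimizer = "gradient"`
switches members to the cross-entropy loss.

**Calibration and categories.** `calibrate()` maps scores to empirical
p-values on held-out pairs: $p(s)$ is the fraction of known *unrelated*
calibration pairs scoring $\ge s$ — an empirical false-positive rate,
non-increasing in $s$ by construction. The published wording ("probability
that the result is a true positive") is ambiguous between an FPR, a
positive predictive value and a permutation p; the FPR was chosen because
it needs no prevalence assumption and is monotone by construction. Scores
then map to the published categories: strong (score > 78, p < 0.05),
medium-strong (> 71, p < 0.1), medium (> 38, p < 0.25), low otherwise —
a score of exactly 38 is low. The `+++`/`++`/`+`/`-` glyphs reproduce the
published display convention (`score_grid()`, `plot_score_grid()`).

**Evaluation.** `evaluate_ensemble()` reports accuracy at a score
threshold of 50 (ties predict "related") and the Mann–Whitney rank AUC,
computed only on pairs whose drugs have *all* targets on the network —
the convention under which the reference model reports its headline
accuracy. Grouped-target scoring (`score_functional_group()`) treats a
functional group's targets as a pseudo-drug; whether the original grouped
scores were pseudo-drugs or aggregated singleton scores is unstated, and
the pseudo-drug reading was chosen because the ensemble is defined on
target *sets*.

## The synthetic benchmark

Every stage is testable offline through seeded generators
(`synthetic_config()` and friends). The defaults are the package's
reference conditions: a 300-node preferential-attachment network, a
26-disease panel split 7/6/9/4 like the real one (with DB diseases
guaranteed B-cell and complement processes and MPB/UPB diseases guaranteed
an innate-immunity process, mirroring the observed dependency pattern), 400
drug-indication pairs at 50% positives, and 50 pathways of size 8–40, half
planted on disease neighborhoods and half uniform decoys.

The planted signal is topological: positive pairs sample their targets
within `proximity_radius` (2) hops of the disease's effector neighborhood;
negative pairs sample targets at least `proximity_radius + 2` hops from
every effector of the paired disease. Effector sets themselves are
connected balls around a seed node plus 10% uniform noise. The attachment
parameter defaults to `m = 1` (a preferential-attachment tree): the
distance-separated negative scheme needs a graph whose diameter comfortably
exceeds the separation, and at `m = 2` a 300-node scale-free graph has
diameter ≈ 7, leaving essentially no nodes 4+ hops from a noisy 15–60
protein effector set. Sparser attachment (diameter ≈ 17) is the
mathematically coherent regime for the construction; `attachment_m` remains
configurable for denser networks with larger node counts.

What the generator does *not* emulate: the true size or degree distribution
of a curated interactome, correlated annotation structure between pathways,
literature-curation bias in effector lists, or any pharmacology beyond
topological proximity. A high benchmark AUC therefore demonstrates that the
pipeline recovers a planted topological signal deterministically — not that
the scorer's predictions on real disease data are accurate at any
particular level.

Benchmark problem sizes used by the test suite and the acceptance script —
300 nodes, 400 pairs, 40 members, 20 generator seeds, 20 label
permutations per seed — were fixed once as a balance between statistical
stability of the medians and a test suite a contributor can run routinely.

## Numerical and reproducibility choices

* One master seed governs every stage; each sub-generator and each ensemble
  member derives its own stream from (seed, tag), so adding a stage never
  perturbs another stage's draws. Re-running any generator or the whole
  pipeline with the same configuration is byte-identical (tested on the
  serialized report).
* Infinite hop distances are imputed as diameter + 1; feature
  standardization uses training-set mean/sd with zero sd mapped to 1.
* All identifier comparisons are case-insensitive on trimmed, upper-cased
  symbols; gene symbols are canonical, UniProt accessions are carried as
  annotation.
* The published "HLA class I and II (includes 21 proteins)" target entry is
  expanded to 21 explicit identifiers (the five HLA proteins named in the
  published score grid first, placeholders after) because the scorer
  operates on explicit protein sets.
* Dual-arrow effect annotations are stored as `both` rather than resolved.
* Indirect targets are shipped as annotation (`scorable = FALSE`) and never
  scored; the published score grid is a comparison fixture, not a training
  or tuning input.

## Known limitations

The published headline numbers tied to proprietary inputs — the
target-by-disease score percentages, the training-corpus accuracy, and the
exact enriched-pathway counts — are out of reach by construction: they
depend on a proprietary protein network, a curated drug–indication corpus,
and reference-database snapshots. The package reproduces the method, the
published arithmetic quantities (frequencies, cardinalities, the similarity
worked example, degrees of freedom), and the behavior of every stage under
controlled synthetic conditions; it deliberately does not attempt to
imitate the proprietary numbers.
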