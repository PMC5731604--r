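---
title: "Disease module separation and missing common-gene prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease module separation and missing common-gene prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modsep)
```

## The model

Two diseases that co-occur more often than chance (high comorbidity relative
risk, RR) frequently share part of their genetic architecture.  On a
protein-protein interactome `G`, the genes associated with diseases A and B
form two gene sets `G_A` and `G_B`; how topologically entangled these sets
are is measured by the **module separation**

$$S_{AB} = \langle d_{AB} \rangle - \frac{\langle d_{AA}\rangle + \langle d_{BB}\rangle}{2},$$

where all distances are unweighted shortest-path hop counts.  In the
standard (*nearest*) form, $\langle d_{AA}\rangle$ averages, over the genes
of A, each gene's distance to its nearest *other* A-gene, and
$\langle d_{AB}\rangle$ averages each gene's distance to the nearest gene of
the opposite set, counted once from each side; a gene belonging to both sets
contributes 0 from each side.  Negative $S_{AB}$ means the two
neighbourhoods interpenetrate.  The *all-pair-average* variant $S_{<AB>}$
replaces every nearest distance by the mean over all distinct gene pairs.

A disease's **module** is the largest connected component (LCC) of the
subgraph its genes induce; real disease gene sets are mostly scattered, with
only a minority of genes inside the LCC, so the module is the structured
core of the set.

## Predicting missing common genes

If a comorbid pair shows a larger separation than its comorbidity would
suggest, some genes common to both diseases may simply not be annotated yet.
The package formulates their recovery as minimizing separation: for every
candidate `x` in the symmetric difference of the two sets,

$$s(x) = S_{AB} - S_{AB}[+x],$$

where $S_{AB}[+x]$ is the separation with `x` added to *both* sets.  The
candidate minimizing $S_{AB}[+x]$ (equivalently maximizing $s(x)$) is the
predicted missing common gene; `rank_candidates()` evaluates every candidate
exhaustively.  `best_subset()` generalizes the argmin to all
$\binom{n}{k}$ size-`k` candidate subsets (guarded by an evaluation budget,
default 2,000,000 — no heuristic search is attempted), and
`iterative_recovery()` applies the single-gene argmin sequentially, moving
the winner into both sets before re-ranking; the sequential list and the
jointly optimal subset may legitimately differ.

Scores may optionally be normalized by the base separation
(`normalize = TRUE`), which is undefined for $S_{AB} = 0$.

## Set-based and module-based scoring

Every scoring function can compare either the raw gene sets or the extracted
modules (`use_modules`).  The distinction matters greatly for candidate
evaluation:

* **Set-based** ($S_{AB}$ over the full sets): every candidate changes the
  averages.  The change is dominated by terms that reward genes *far* from
  the opposite set (their large within-set entry depresses
  $S_{AB}[+x]$ through the $-\langle d_{BB}\rangle/2$ term) and genes deep
  inside a compact cluster (which collapse their neighbours' nearest
  cross-distances).  Genuine bridging genes gain little, so set-based
  candidate scores carry almost no usable signal — which is exactly the
  behaviour reported for the all-pair-average variant.
* **Module-based**: separations are computed between the LCC modules,
  re-extracted after the candidate is added.  A candidate that does not
  attach to either module leaves both LCCs unchanged and scores exactly 0;
  a true common gene attaches to both modules, contributes two zero
  cross-distances, and reduces the separation.  This gate is what makes the
  nearest-distance pipeline discriminating.

The cross-validation defaults therefore mirror the two reported pipelines:
`method = "nearest"` scores against modules, while
`method = "all_pair_average"` scores the full sets (the literal "all
distinct A-B gene pairs" reading).  Both choices can be overridden through
`use_modules`.

## Cross-validation design

`make_cv_split()` reserves up to `n_pos` known common genes (default 10, the
study convention) as positives and up to `n_neg` non-common genes as
negatives, drawn balanced from the two sides of the symmetric difference.
Reserved positives are removed from **both** working sets, so scoring them
genuinely re-discovers missing common genes; negatives stay in their single
set and are only labeled.  An earlier design that kept each held-out
positive on one randomly chosen side was implemented and rejected: with the
positive retained on one side, the score terms described above systematically
favour non-bridging genes, and recovery falls below chance.  Scoring genes
from outside the current sets is legitimate — the same mechanics serve
de-novo prediction.

`roc_auc()` is the rank-based Mann-Whitney statistic (ties credited 0.5);
`choose_threshold()` returns the observed score whose cutoff maximizes
TPR − FPR, resolving ties toward the higher threshold, and
`precision_recall()` applies the `score >= threshold` convention with
precision 0 when nothing is predicted positive.  `evaluate_pair()` composes
the steps into one record; `evaluate_pairs()` iterates a pairs table,
skipping pairs with no common genes or with all genes common (the reasons
are kept in the `"skipped"` attribute).  `stratified_report()` summarizes
records overall, by RR bin (left-closed `[0,1), [1,2), [2,3), >=3` —
inclusivity is a convention choice) and by common-gene-count bin
(`[0,5), [5,10), [10,15), >=15`).

The **randomized-common-gene baseline** (`randomize_common_genes()`)
replaces a pair's shared genes with an equal number of uniform random
interactome genes outside the pair, preserving set sizes, overlap count and
the interactome topology.  Whether a pair's split is drawn once or averaged
over several draws is configurable (`repeats`, default 1); the base
separation is always computed on the working sets of the current split.

## The synthetic benchmark

`generate_graph()` grows a connected preferential-attachment graph: a
clique on `attachment` nodes, then each new node links to `attachment`
distinct existing nodes with probability proportional to degree, giving
exactly `attachment * (n_nodes - attachment) + choose(attachment, 2)` edges
and a heavy-tailed degree distribution.  Defaults (500 nodes,
`attachment = 2`) give a sparse hub-rich substrate.

`plant_pair()` emulates a comorbid disease pair:

* each disease receives a connected **core** grown by a random walk with
  restart (`locality` = restart probability, default 0.7; higher is more
  compact).  The second core's walk never absorbs the first core or its
  direct neighbours, keeping the cores at least two hops apart;
* the `n_shared` common genes are sampled from the **connector pool** —
  nodes adjacent to members of both cores — so the planted common genes
  bridge the two neighbourhoods, the defining topological property the
  predictor exploits;
* a `scatter` fraction (default 0.3) of each disease's exclusive genes is
  placed as uniform random singletons, mirroring the majority of real
  disease genes that fall outside the LCC (real modules can be as small as
  11 of 69 associated genes);
* planting retries deterministically with fresh seeds when the connector
  pool is too small, and errors after 50 attempts.

`make_benchmark()` plants `n_pairs` independent pairs on one graph, draws a
synthetic RR per pair from a log-normal distribution (meanlog 0.5, sdlog 1,
spanning the stratification bins; metadata only, never used in scoring) and
optionally writes `graph.tsv`, `assoc.tsv`, `pairs.tsv` — byte-identical
for identical configurations.

### What the benchmark does and does not show

The generator plants an idealized, fully recoverable signal: every common
gene is a true bridge and every negative is either a core member (which the
module gate scores 0) or a scattered singleton.  Recovery on this benchmark
is therefore essentially perfect (mean AUROC ~1.0 at the default study
conditions of 50 pairs, 25 genes per disease, 8 shared, 10 held-out
positives and negatives), the randomized baseline sits near 0.5, and the
set-based all-pair variant stays near chance.  Passing shows the machinery
preserves these qualitative contrasts; it does not certify performance on
real interactomes, where annotation noise, incomplete edges and ambiguous
overlap make all three numbers less extreme.  Generator variants in which
some "negatives" were themselves planted as bridges were rejected: such
genes are legitimate missing-common-gene candidates, so labeling them
negative poisons the ground truth rather than adding realism.

## Numerical choices

* Distances are unweighted breadth-first hop counts; every distance is a
  non-negative integer before averaging.
* Unreachable pairs are excluded from averages, the affected genes recorded
  (`excluded_a`, `excluded_b`); an error is raised only when an average
  would be empty.  Within-distances require sets of at least 2 genes.
* All tie-breaks (component choice, ranking, subsets) are lexicographic on
  gene ids with radix (byte) ordering, independent of the locale.
* Gene identifiers are opaque strings; numeric ids are never parsed.
* BFS distance matrices over `G_A` and `G_B` are computed once per pair and
  shared across candidate evaluations; cached and uncached evaluations are
  the same code path, hence bit-identical.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so every split, benchmark and CLI run is reproducible; CLI reruns with the
  same arguments are byte-identical.

## Problem sizes

The shipped tests and the acceptance script use 500-node interactomes with
50 planted pairs for cross-validation experiments, 100-200 random graphs of
up to 30 nodes for oracle-equivalence checks, and 1,000 random score
vectors for the ROC machinery — sizes chosen so the full suite documents
the method's behaviour in about two minutes on one CPU.

## Known limitations

* No identifier translation, no edge confidence weights, no weighted or
  diffusion-based distances, and no z-score significance of `S_AB` against
  degree-preserving rewiring.
* The subset optimizer is exhaustive by design; `k` is a user parameter (no
  model-selection rule exists for it).
* The percolation-based module-significance threshold used with real
  catalogues is dataset-specific; `qualifies_as_module()` provides a
  configurable minimum size (default 2) and minimum LCC fraction (default
  off) instead.
* The synthetic generator does not fit the human interactome's degree
  sequence; it reproduces qualitative structure only.
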