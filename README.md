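# modsep

Network-medicine tools for **disease module separation** and the prediction
of **missing common genes** of comorbid disease pairs on a protein–protein
interactome.

Diseases that co-occur (high comorbidity relative risk, RR) tend to share
genes, and their associated gene sets sit close together on the
interactome.  For gene sets `G_A` and `G_B` mapped onto an interactome,
the module separation is

    S_AB = <d_AB> − (<d_AA> + <d_BB>) / 2

with unweighted shortest-path distances: `<d_AA>` averages each A-gene's
distance to its nearest other A-gene, and `<d_AB>` each gene's distance to
the nearest gene of the opposite set (a gene in both sets contributes 0
from each side).  Negative `S_AB` means the two modules overlap
topologically.  If an apparently comorbid pair shows a large separation,
common genes may be missing from the annotation; `modsep` recovers them by
exhaustively minimizing `S_AB[+x]`, the separation after candidate `x`
(a gene associated with exactly one of the diseases) is marked as shared,
ranking candidates by the prediction score `s(x) = S_AB − S_AB[+x]`.

The package provides:

* readers/writers for interactome edge lists, disease–gene association
  tables and disease-pair tables (`load_interactome()`,
  `load_associations()`, `load_pairs()`);
* disease-module extraction (largest connected component) and module-size
  checks (`largest_connected_component()`, `module_fraction()`);
* set-based and module-based separation in nearest and all-pair-average
  flavours, plus the Jaccard overlap (`separation()`, `jaccard()`);
* exhaustive single-gene ranking, optimal k-subset search and sequential
  multi-gene recovery (`rank_candidates()`, `best_subset()`,
  `iterative_recovery()`);
* seeded cross-validation with ROC scoring, ROC-curve threshold selection,
  precision/recall, a randomized-common-gene baseline and stratified
  reporting by RR and overlap size (`evaluate_pairs()`,
  `stratified_report()`);
* a synthetic benchmark generator that plants bridging common genes between
  walk-grown disease cores on a preferential-attachment interactome
  (`make_benchmark()`);
* a command line (`inst/cli/modsep`) wiring all of the above.

## Worked example

The five-node path interactome `1–2–3–4–5` with disease A = {1, 2} and
disease B = {4, 5}:

```r
library(modsep)
g <- igraph::make_graph(~ 1-2, 2-3, 3-4, 4-5)

separation(g, c("1", "2"), c("4", "5"))
#> Module separation (nearest)
#>   <d_AA> = 1.0000   <d_BB> = 1.0000   <d_AB> = 2.5000
#>   S_AB   = 1.5000

rank_candidates(g, c("1", "2"), c("4", "5"))
#> Candidate ranking (nearest): base S_AB = 1.5000, 4 candidates
#>   gene   side   s_ab_plus    score
#> 1    1 A_only -0.13333333 1.633333
#> 2    5 B_only -0.13333333 1.633333
#> 3    2 A_only  0.03333333 1.466667
#> 4    4 B_only  0.03333333 1.466667
```

The two within-set averages are 1 hop; the four nearest cross-distances
(3, 2, 2, 3) average 2.5, so `S_AB = 1.5` — the modules are separated.
Marking the end genes 1 or 5 as shared closes the gap the most
(`S_AB[+x] = −0.133`, score 1.63), so they top the ranking.

The same numbers from the shell:

```sh
inst/cli/modsep separation --graph g.tsv --assoc a.tsv --disease-a DA --disease-b DB
```

A full synthetic study — generate a benchmark, cross-validate the
prediction and summarize by comorbidity — takes a few lines:

```r
bench <- make_benchmark(n_pairs = 50, config = synthetic_config(seed = 42), seed = 42)
records <- evaluate_pairs(bench$graph, bench$assoc, bench$pairs, seed = 42)
mean(records$roc_score)   # held-out common genes recovered essentially perfectly
stratified_report(records)
```

## Documentation

The methods vignette (`vignettes/module-separation-methods.Rmd`) describes
the model, the cross-validation design, the set-based versus module-based
scoring distinction, the synthetic generator's geometry and the numerical
conventions in detail.
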