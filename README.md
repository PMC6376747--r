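# codeviews

Filtering, summarization, and comparison of aggregated health data sets
coded with hierarchical terminologies (ICD-9-CM, ICD-10-CM, MeSH, or any
generic parent–child edge list).

## The problem

An institution's coded extract is a long table of `code, frequency` pairs —
thousands of ICD codes with usage counts and no visible structure. The
structure that answers real questions ("which disease classes dominate?",
"which specific codes drive a class?", "how do two cohorts differ?") lives
in the terminology hierarchy. `codeviews` rolls the frequencies up that
hierarchy, filters the result, and extracts compact annotated subgraphs.

For a data set with frequencies *f<sub>c</sub>* over a terminology DAG:

- **NC** (node count): `NC(c) = f_c`, the raw usage frequency of code *c*.
- **CC** (class count): `CC(c) = Σ NC(d)` over the **distinct** proper
  descendants *d* of *c* (optionally plus `NC(c)` itself with
  `include_self = TRUE`). A node reachable along several paths of a
  poly-hierarchy counts once.
- **Ratio**: `CC(child) / CC(parent)` per edge — the child's contribution
  to its parent's class; always in [0, 1], undefined (absent) when the
  parent's CC is 0.

On top of the metrics: threshold / top-k / top-percent filters and their
combinations, a threshold-tuning preview, systematic two-data-set
comparison (difference of CC proportions, optional chi-square + BH
q-values), and ancestor-closed summary views with a red (high) to green
(low) color scale, exported as Graphviz DOT, GraphML, and CSV.

## Worked example

Two printed ICD-10-CM rows — `E11.9` (type 2 diabetes without
complications) used 4559 times and `I10` (essential hypertension) 3000
times — are enough to exercise the whole pipeline, because the ICD
hierarchy is induced from code syntax alone (the parent of `E11.9` is its
prefix `E11`):

```r
library(codeviews)

h  <- build_icd_hierarchy(c("E11.9", "I10"), "ICD10")
ds <- coded_dataset(c(E11.9 = 4559, I10 = 3000), scheme = "ICD10")
m  <- node_metrics(ds, h, include_self = TRUE)
m$cc
#>   E11 E11.9   I10
#>  4559  4559  3000
m$ratio
#>   child parent ratio
#> 1 E11.9    E11     1
```

The category `E11` inherits its child's entire class (CC 4559, ratio 1),
and `I10`, a category-level root, keeps its own 3000. Validation applies
the inclusive minimum sizes (patient count ≥ 100 when declared, event
count ≥ 1000):

```r
validate_dataset(ds)
#> <validation_report> 0 error record(s); size OK
#>   2 distinct codes, 7559 events (freq min/median/max: 3000/3779.5/4559)
```

Selecting the top 2 codes by CC and building the ancestor-closed view:

```r
sel <- select_top(m, "CC", "count", 2)
sel$codes
#> [1] "E11"   "E11.9"
v <- assign_colors(build_summary_view(h, m, sel), key = "CC")
cat(export_view_csv(v))
#> code,label,nc,cc,max_ratio,selected
#> E11,E11,0,4559,,TRUE
#> E11.9,E11.9,4559,4559,1.00000000,TRUE
```

`export_dot(v)` emits the same view as deterministic Graphviz DOT
(`render_view(v, "view.png")` rasterizes it when `dot` is installed).

## Command line

```sh
Rscript inst/cli/codeviews.R analyze --input data.csv --scheme ICD10 \
    --algorithm top_cc_pct --value 5 --include-self --out results/
Rscript inst/cli/codeviews.R compare --input a.csv --input-b b.csv \
    --scheme ICD10 --with-tests --out results/
Rscript inst/cli/codeviews.R generate --n-nodes 200 --n-events 20000 --seed 7 --out fixtures/
```

Subcommands `validate`, `preview`, `analyze`, `compare`, `generate`; exit
codes 0 (ok), 2 (validation failure), 3 (config error), 4 (I/O error).

## Package layout

- `R/normalize.R`, `R/hierarchy.R` — code syntax rules; ICD / MeSH /
  generic hierarchy construction and reachability queries.
- `R/dataset.R` — CSV reading, validation and corrections workflow,
  profiles.
- `R/analytics.R` — NC / CC / ratio and the filtering algorithms.
- `R/comparison.R` — two-data-set systematic comparison.
- `R/views.R` — summary/comparison views, colors, DOT/GraphML/CSV export.
- `R/synthetic.R` — seeded random hierarchy and Zipf data set generators.
- `R/pipeline.R`, `inst/cli/codeviews.R` — end-to-end workflow and CLI.

See `vignettes/methods.Rmd` for the full account of the model, parameter
choices, and limitations.
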