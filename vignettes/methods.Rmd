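---
title: "Hierarchical rollup, filtering, and comparison of coded data sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical rollup, filtering, and comparison of coded data sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codeviews)
```

## The problem

Health care institutions hold large aggregated data sets in which clinical
events are coded with hierarchical terminologies — ICD-9-CM and ICD-10-CM
diagnoses, or MeSH descriptors in the literature — together with a usage
frequency per code. Such a table is easy to store and hard to read: tens of
thousands of codes, no visible structure, and the structure that matters
(which broad disease classes dominate, which specific codes drive a class,
how two cohorts differ) lives in the terminology hierarchy, not in the
table. `codeviews` rolls frequencies up that hierarchy, filters the result
down to the nodes worth looking at, and extracts compact annotated
subgraphs that can be rendered with Graphviz.

The input contract is deliberately minimal: a two-column CSV of
`code,frequency`, plus the terminology structure. No person-level data is
involved at any point; the package works entirely on aggregated counts.

## Terminology model

A terminology is a rooted directed acyclic graph of codes with
parent-to-child edges. Three sources are supported:

* **ICD-9-CM / ICD-10-CM.** These are mono-hierarchies whose structure is
  recoverable from code syntax: the parent of a code is its longest proper
  prefix that is itself a syntactically valid code (`250.00` → `250.0` →
  `250`; `E11.9` → `E11`), and three-character category codes are roots.
  `build_icd_hierarchy()` adds all implied prefix ancestors, so the
  hierarchy induced from a data set's own codes is always upward-closed.
  Chapter and block range groupings above the category level (e.g. the
  ICD-10 chapter spanning `E00`–`E89`) are intentionally not modeled: they
  are not derivable from code syntax, and an explicit edge-list file can
  supply them when needed.
* **MeSH.** A poly-hierarchy: each descriptor carries one or more dotted
  tree numbers (`C04.557.337`), and the parent position of a tree number is
  the tree number with its final segment removed. A descriptor with several
  tree numbers therefore has several parents. When a parent position maps
  to no known descriptor — common in partial extracts — the package
  synthesizes a placeholder node (named by the position and flagged in the
  hierarchy's `placeholders` field) rather than failing; `missing = "error"`
  turns this into a hard error.
* **Generic edge lists.** A TSV of `parent, child, label` rows for any other
  hierarchical coding system. Self-loops and cycles are rejected at load
  time, with one offending cycle named.

All reachability queries use distinct-set semantics: a node reachable along
several paths of a poly-hierarchy counts once. This choice is what keeps
the class-count rollup free of double-counting.

## The metrics

For a data set $D$ with event total $N = \sum_c f_c$ and a hierarchy $H$:

* **NC (node count).** $\mathrm{NC}(c) = f_c$, the raw usage frequency; 0
  for hierarchy nodes absent from the data set. $\sum_c \mathrm{NC}(c) = N$.
* **CC (class count).**
  $\mathrm{CC}(c) = \sum_{d \in \mathrm{desc}(c)} \mathrm{NC}(d)$, the sum
  over the *distinct* proper descendants of $c$. The `include_self` flag
  adds $\mathrm{NC}(c)$ itself. The default follows the descendant-only
  sum literally, so leaves have CC 0; the self-inclusive convention is the
  one under which the root of a tree carries the full event total, and
  several natural uses ("the most frequently used codes") read that way,
  so both are first-class and every computation records which was used.
* **Ratio.** For each edge $(p, c)$ with $\mathrm{CC}(p) > 0$:
  $\mathrm{ratio}(c, p) = \mathrm{CC}(c) / \mathrm{CC}(p)$, the child's
  contribution to its parent's class. Because a child's class is a subset
  of its parent's, every ratio lies in $[0, 1]$; edges whose parent has
  CC 0 carry no ratio at all rather than a 0/0 artifact.

Implementation note: CC is computed from the reachability relation of the
DAG (finite positive path length), evaluated as a boolean matrix-vector
product. This is exact for poly-hierarchies and is cross-checked in the
test suite against an independent naive per-node DFS-and-sum oracle on
hundreds of random DAGs, under both `include_self` conventions.

```{r metrics}
h <- build_icd_hierarchy(c("E11.9", "I10"), "ICD10")
ds <- coded_dataset(c(E11.9 = 4559, I10 = 3000), scheme = "ICD10")
m <- node_metrics(ds, h, include_self = TRUE)
m$cc
m$ratio
```

## Filtering algorithms

All filters return a `node_selection` and are freely combinable:

* `select_threshold(metrics, key, t)` — nodes with NC or CC $\ge t$
  (inclusive, so `t = 0` selects everything).
* `select_top(metrics, key, mode, value)` — top-$k$ by NC or CC. The
  candidate pool is restricted to nodes with a *positive* metric, so
  structural ancestors with zero counts never crowd the ranking. In percent
  mode $k = \lceil \mathrm{value}/100 \times |\mathrm{pool}| \rceil$; the
  ceiling guarantees the selection is never smaller than the requested
  fraction. Ties at the cutoff break lexicographically by code, making
  repeated runs bit-identical.
* `select_ratio(metrics, t)` — children with at least one incident edge of
  ratio $\ge t$ (the *any-parent* rule in poly-hierarchies; per-edge values
  are retained for per-parent analysis).
* `combine_selections(list, mode)` — union (default) or intersection,
  implementing the combination filters such as "most frequent codes plus
  largest contributors".

`preview_distribution()` supports threshold tuning before committing to a
filter: it reports the sorted nonzero metric values, their quantiles, and
a ladder of candidate thresholds with the number of surviving nodes at
each. The default ladder is 10 evenly spaced values over the nonzero
range; any explicit ladder can be passed instead.

## Data set validation

A data set is acceptable when it is coded in a supported hierarchical
terminology with a frequency per code, and when it meets the minimum
sizes: a declared patient count of at least 100 (checked only when the
user supplies one — a frequency table alone cannot determine it) and an
event total of at least 1000. Both bounds are inclusive; the boundary
cases 99/100 and 999/1000 are pinned in the test suite. Undersized inputs
block analysis by default and can be admitted explicitly with
`allow_small` so small worked examples remain runnable.

Row-level problems never abort a read: unparseable rows are retained as
parse issues, and `validate_dataset()` reports error records — negative
frequency, duplicate code (first occurrence kept, later ones flagged
rather than silently summed), unknown code relative to the hierarchy —
each with exactly one primary reason, in that order of precedence.
`apply_corrections()` consumes revise/delete decisions against those
records; deleting all error records always re-validates clean. A zero
frequency is accepted as a valid degenerate entry.

## Two-data-set comparison

`compare_datasets()` compares CC against CC node by node over a shared
hierarchy, for every node with positive CC in either data set. Since the
two data sets generally differ in total events, the effect measure is the
difference of CC *proportions*, each CC normalized by its own data set's
event total: $\delta(c) = \mathrm{CC}_A(c)/N_A - \mathrm{CC}_B(c)/N_B$,
ranked by $|\delta|$. The measure is antisymmetric by construction —
swapping the arguments negates every delta and preserves every score —
and a self-comparison is identically zero.

Optionally each node receives a continuity-corrected chi-square test on
the 2×2 table (node events vs remaining events, per data set) with
Benjamini–Hochberg adjustment across all tested nodes. The choice of test
and adjustment is this package's design decision; degenerate tables (a
node carrying an entire data set) yield `NA` statistics rather than a
fabricated value. Nodes absent from one side keep a CC of 0 there so
one-sided signals stay visible.

## Summary views

`build_summary_view()` closes a selection upward — every ancestor of a
selected node joins the view, descendants are never pulled in — and takes
the induced subgraph: exactly the source edges with both endpoints in the
view. Ancestor-only closure is what makes the view a faithful "table of
contents" for the selection: each chosen code is shown in its full
hierarchical context without dragging in siblings or children.

`assign_colors()` maps the chosen key (CC, NC, or comparison score) to a
red-to-green scale: the maximum value is pure red, the minimum pure
green, and intermediate values are interpolated linearly channel-wise in
RGB. A log option (`log1p`) spreads heavy-tailed CC distributions that
would otherwise color almost everything green; constant-valued views map
uniformly to green. The numeric form of the mapping is this package's
choice — only the red-high/green-low direction is fixed by convention.

Serialization is deterministic (nodes and edges emitted in sorted order,
fixed number formatting), so identical inputs yield byte-identical DOT,
GraphML, and CSV artifacts — a property the acceptance checks verify
end-to-end. PNG/SVG rendering is delegated to an external Graphviz `dot`
binary when one is on the PATH (`render_view()`); image encoding is not
part of the computational contract, so the core guarantees stop at
DOT/GraphML/CSV.

Comparison views reuse the same machinery with the score as the coloring
key and the signed delta in the tooltip.

## Synthetic data generator

Because real coded extracts cannot be redistributed, the package ships a
seeded generator used by the tests and the acceptance script. It emulates
two features that matter for this analysis: *hierarchical shape* (a rooted
tree grown by preferential attachment with a bounded branching factor,
optionally turned into a poly-hierarchy by adding lateral cross edges that
never create a cycle — a cross edge only targets a node that is neither an
ancestor nor a descendant of its source) and *heavy-tailed code usage* (a
Zipf distribution over a random node ordering, exponent 1.2 by default,
the regime commonly observed for clinical code usage; frequencies are
drawn multinomially so they sum exactly to the configured event total).

Defaults (60 nodes, branching ≤ 4, 2000 events) are small enough for
property suites of hundreds of instances; the acceptance script uses 200
nodes and 20 000 events as its study scale. All generation is
integer-based R RNG under an explicit seed, so identical configurations
are identical across platforms, and the generator restores the caller's
RNG state.

What the generator does *not* emulate: real ICD/MeSH code syntax (generic
`N0001`-style codes suffice for structural testing), realistic depth
profiles of ICD chapters, correlation between a code's depth and its
frequency, and coding errors. Passing tests therefore demonstrate the
algorithms' correctness on DAG-shaped data with skewed counts, not
fidelity to any particular institution's case mix.

## Numerical and degenerate-input choices

* Frequencies and counts are exact integers throughout; ratios and
  proportions are the only reals. Exported reals use fixed 8-decimal
  formatting to keep artifacts byte-stable.
* Division guards: ratio keys are absent (not zero) when the parent CC is
  0; comparisons refuse zero-event data sets since proportions would be
  undefined.
* Ties: every ranking breaks ties lexicographically by code.
* Empty inputs are legal everywhere they can be: empty code lists produce
  empty hierarchies, empty data sets produce all-zero NC maps, empty
  selections produce empty (but syntactically valid) views and artifacts.
* Percent-mode $k$ uses the ceiling; count mode caps at the pool size.

## Command-line workflow

The single-shot CLI (`inst/cli/codeviews.R`) mirrors the analytic
workflow: `validate` → `preview` (threshold ladder) → `analyze` (one of
the ten algorithms: `nc`, `cc`, `ratio`, `top_nc`, `top_cc`, `top_nc_pct`,
`top_cc_pct`, `nc_plus_ratio`, `cc_plus_ratio`, `compare`) → artifacts
(validation report CSV, profile JSON, metrics CSV, view DOT/GraphML/CSV,
comparison CSV), plus `generate` for synthetic fixtures. Exit codes: 0
success, 2 validation failure, 3 configuration error, 4 I/O error. It is
a thin wrapper over `run_config()`/`run_pipeline()`, which are the
recommended programmatic interface.

## Known limitations

* ICD hierarchies derived from code syntax stop at three-character
  categories; chapters/blocks require an explicit edge list.
* Terminology versions are opaque metadata; there is no year-resolution or
  cross-version mapping logic.
* Comparison is strictly pairwise; no paired or longitudinal designs.
* The chi-square test treats events as independent draws, which aggregated
  frequency tables cannot guarantee; the q-values are a screening aid, not
  confirmatory inference.
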