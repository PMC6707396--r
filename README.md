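# linksetr

Network extension with versioned linksets, headless and reproducible.

A common step in network biology is to take a network you already have — a
protein–protein interaction network, a list of differentially expressed
genes, any attributed graph — and pull in curated knowledge around it:
which compounds target these proteins, which diseases are associated with
these genes, which pathways contain them. `linksetr` implements this
*network extension* operation around a simple exchange format, the
**linkset**: a named, versioned collection of directed, interaction-typed
links between identified entities, stored in an XGMML dialect. Linksets can
describe anything pairwise — compound→gene (`targets`), pathway→gene
(`containsGene`), gene→disease (`associatedWith`), even author→article —
so the same machinery serves drug–target annotation, pathway analysis and
non-biological graphs alike.

The package is aimed at computational biologists who want these workflows
scripted rather than clicked: every operation is an R function with a
deterministic result, and a command-line interface covers the full
pipeline.

## The extension model

Given a network *N*, a list of linksets *L₁…Lₖ*, a node attribute
`idAttribute` and a direction *d* ∈ {SOURCES, TARGETS, BOTH}, each linkset
edge *s → t* with relation *i* is handled as follows:

- a linkset entity **matches** a network node when one of its canonical
  `system:value` identifiers equals the node's `idAttribute` value, or —
  for bare attribute values such as a `"display name"` of `MECP2` — when
  the value part of an identifier equals it (exact, case-sensitive);
- under **TARGETS**, if *s* matches an original node, the target *t* is
  ensured (reusing a matching original node, else adding a node keyed by
  *t*'s identifier) and the edge is added; **SOURCES** is the mirror image
  (matched targets gain their upstream sources); **BOTH** applies both;
- matching is evaluated against the *input* node set only, so chained
  tiers (authors → articles → journals) require two sequential calls;
- an edge asserted by several linksets is stored once; its **overlap** —
  the number of distinct linksets asserting the same directed
  `(source, target, interaction)` triple — supports `filter_overlap(n)`,
  which keeps only extensions backed by at least *n* resources.

Everything the engine adds is marked with fixed `ctl.*` provenance
attributes (`provenance_keys()`), so reports, filtering and styling are
recomputable from the network alone, and the original subgraph is never
modified.

## Worked example

`usecase_fixtures()` writes three miniature scenario trees; scenario 1 is a
small protein–protein interaction network plus a compound–target and a
gene–disease linkset:

```r
library(linksetr)

dir <- file.path(tempdir(), "uc")
usecase_fixtures(dir)

ppi <- read_network(file.path(dir, "scenario1", "ppi.graphml"))
ppi
#> <network> ppi (directed): 6 nodes, 5 edges

ext <- extend_network(
  ppi,
  list(read_linkset(file.path(dir, "scenario1", "compounds.xgmml")),
       read_linkset(file.path(dir, "scenario1", "diseases.xgmml"))),
  id_attribute = "display name")
ext
#> <extension> direction=BOTH, id attribute='display name'
#> Extension report
#>    linkset version matched nodes+ edges+
#>  compounds     1.0       3      3      4
#>   diseases     1.0       3      2      3
#>   totals: 5 nodes added, 7 edges added, 5 network nodes matched
```

Read: the compound linkset matched 3 network proteins and added 3 compound
nodes with 4 `targets` edges; the disease linkset matched 3 proteins and
added 2 disease nodes with 3 `associatedWith` edges. Nodes shared between
linksets would be added once but attributed to both. `tidy(ext)` returns
the per-linkset table, `glance(ext)` the totals:

```r
glance(ext)
#> # A tibble: 1 × 5
#>   nodes_added edges_added network_nodes_matched n_linksets overlap_threshold
#>         <int>       <int>                 <int>      <int>             <int>
#> 1           5           7                     5          2                NA
```

Since no interaction here is asserted by both linksets, requiring support
from two resources removes all 7 extension edges and the 5 nodes they
brought in — the original network is untouched:

```r
filter_overlap(ext, 2)$counts
#> $edges_affected
#> [1] 7
#> $nodes_removed
#> [1] 5
```

`apply_layout()` (seeded force-directed placement), `apply_style()` (gray
ellipses for original nodes, per-linkset colours and per-type shapes for
additions) and `autoplot()` render the result; `write_network()` exports
GraphML/XGMML losslessly. The same pipeline runs from the shell:

```sh
inst/cli/linksetr extend --network ppi.graphml \
    --linksets compounds.xgmml --linksets diseases.xgmml \
    --id-attribute "display name" --out extended.graphml --report report.json
inst/cli/linksetr report --network extended.graphml
```

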