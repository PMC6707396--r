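---
title: "Extending networks with linksets: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extending networks with linksets: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linksetr)
```

## The model

`linksetr` treats prior knowledge as *linksets*: named, versioned
collections of directed, typed links between identified entities. A
linkset node carries a primary canonical identifier (`system:value`), an
optional set of further identifiers, a label and an entity type; a linkset
edge is a `(source, target, interaction)` triple with a datasource. The
triple is the unit of identity — the same directed, typed assertion made
by two resources is *the same interaction*, which is what makes
cross-resource support counting meaningful. Duplicate triples within one
linkset are a validation error rather than being silently collapsed, so
provenance counts stay exact.

Extension grafts linkset edges onto a user network wherever one endpoint
matches an existing node. The operation is deliberately conservative:

* pre-existing nodes and edges are never modified; a candidate edge whose
  triple already exists in the input network is skipped entirely;
* matching is evaluated against the input node set only, so a single call
  never chains through its own additions — multi-tier growth
  (authors → articles, then articles → journals) is an explicit two-step
  workflow;
* everything added carries fixed provenance attributes
  (`provenance_keys()`), making every downstream step — reporting,
  overlap filtering, styling — a pure function of the network.

## Matching

The `id_attribute` names the network node attribute compared against
linkset identifiers. Two regimes coexist:

* an attribute value containing `":"` is treated as a canonical
  identifier and compared only canonically;
* a bare value (a `"display name"` like `MECP2`) matches any linkset
  identifier whose value part equals it.

The bare fallback exists because real workflows match on display names,
which are unprefixed; restricting it to the network side prevents a
canonical attribute value from accidentally matching an identifier of a
different system that shares the local part. Comparison is exact and
case-sensitive throughout: graphical tools are ambiguous on this point,
and a documented strict rule beats a guessed lenient one (`MECP2` the
human gene symbol and `Mecp2` the mouse symbol are different strings on
purpose). Identifier harmonization, when needed, is an explicit step:
`map_linkset_identifiers()` applies a local two-column cross-reference
table (`from`/`to` CURIEs), adding all mapped identifiers (one-to-many
mappings included, flagged in the report) and optionally dropping
unmapped entities. A local table rather than a live mapping service keeps
runs offline and reproducible.

## Direction

`direction` controls which side of a linkset edge must match: `TARGETS`
extends matched sources downstream, `SOURCES` gives matched targets their
upstream entities (a gene list acquiring pathway→gene annotations), and
`BOTH` — the default, since mixed collections like compound→gene plus
gene→disease need both — is exactly the union of the two. That union
identity, together with idempotence of re-extension and monotonicity of
the original subgraph, is enforced by property tests against a brute-force
oracle and a constructive ground truth (below).

When the far endpoint of a matched edge itself matches an existing node,
the edge connects the two existing nodes and nothing is added; an added
node is keyed by its canonical identifier, prefixed `ctl:` in the rare
case that key already exists in the network, because silently fusing
distinct entities would corrupt both topology and counts.

## Overlap filtering

`ctl.overlap` on an extension edge counts the distinct linksets asserting
its triple. `filter_overlap(n)` keeps extensions with support ≥ *n*;
`n = 1` is a no-op by construction. Removal also drops added nodes left
isolated, and never touches original content. We count overlap on the
*directed* triple; whether an undirected pair would be more faithful to
any particular upstream resource is unknowable in general, and the
directed choice is at least consistent with linkset edges being directed.
A caveat follows: sequential extension calls cannot accumulate overlap
across calls (the second call sees the first call's edge as pre-existing),
so overlap filtering is meaningful within one `extend_network()` call.

## Reports

`summarize_extension()` recomputes the per-linkset ledger purely from
provenance attributes, so it is independent of the call that produced the
network and reflects any filtering since. `network_nodes_matched` is
therefore defined as the distinct pre-existing nodes incident to at least
one of the linkset's extension edges — the anchoring nodes — rather than
"nodes that matched anything", which is not recoverable from attributes.
`extend_network()` builds its own report the same way and appends explicit
zero rows for provided linksets that contributed nothing.

## Formats

The linkset XGMML dialect is fixed bit-exactly so files are
byte-reproducible: graph-level `att`s `name`/`version`/`date`/`url`, node
`att`s `identifiers` (rendered `[id1,id2,...]`, lexically sorted, no
spaces) and `type`, edge `att`s `interaction` and `datasource`; nodes are
written sorted by identifier, edges by triple. Unknown `att`s are
preserved in an `extras` field, so foreign files round-trip. Networks
travel as GraphML or an XGMML network dialect (both lossless, including
list attributes and layout coordinates) or SIF (topology only, with a
warning). GraphML has no list type, so list attributes are declared with a
`list="true"` marker on the `<key>` and rendered comma-joined in
brackets — list items must not contain commas, which holds for the
`"name (version)"` attribution strings the engine writes. Numeric
attributes are written with 17 significant digits so doubles survive
round-trips exactly. TSV inputs (interaction tables, mapping tables, node
attribute tables) are UTF-8, unquoted, with `#` comments skipped.

`build_linkset_from_tsv()` resolves conflicting labels or types for the
same identifier by taking the lexicographic minimum, which makes the
result invariant to row order — a property the suite checks by shuffling.

## Synthetic fixtures and what they do (not) show

`generate_fixtures()` emits a seeded family — network (GraphML), linksets
(XGMML), their TSV sources, a mapping table — together with a *ground
truth* computed constructively from the planted edges, never by running
the engine. Engine tests against it are therefore genuine oracle tests,
and a second, independently coded brute-force oracle in the test suite
triangulates both. Identifier systems are synthetic (`gx` for
network-matchable entities, `ux` for outside entities, `hx` for mapping
targets) to avoid implying real database content.

Defaults describe a mid-sized annotation task: 100 network nodes, 3
linksets of 100 edges, 30% of linkset edges touching the network — the
match side drawn source/target/both at 0.45/0.45/0.10 so every direction
is exercised. The overlap-histogram mode plants an exact support
structure (e.g. 40 edges in one linkset, 25 in two, 10 in all three) for
filter tests. The test suite runs 100 such fixtures with seed-derived
dimensions up to 200 nodes and 3×150 edges, and 50 round-trip fixtures;
these sizes give minute-scale suites while still covering every rule
combinatorially. Fixtures are deliberately *not* realistic biology: no
scale-free topology, no hub structure, no identifier noise. Passing tests
demonstrate the correctness of matching, direction, dedup, overlap and
serialization logic — not robustness to dirty real-world identifiers,
which the mapping step exists to address.

A fixed limitation inherited from the fixture design: network keys are
`n001…n999`, so generated networks cap at 999 nodes. Real networks read
from files have no such limit.

## Layout, style, CLI

The layout is Fruchterman–Reingold (via igraph) under an explicit seed
with a fixed iteration count (default 100), then translated into the
positive quadrant and scaled *down* (never up) when the bounding box
exceeds 1000 units. Scaling small graphs up to fill the canvas would
erase relative-distance information — on a two-node graph it would map
any layout to the same picture — so normalization only bounds, and a
single node sits at the origin. Coordinates are rounded to 6 decimals for
stable serialization.

Styling is a pure attribute assignment: original nodes gray ellipses,
added nodes coloured by contributing linkset from a fixed 12-colour
palette assigned in lexical tag order (cycling with a warning beyond 12)
and shaped by entity type (compound→diamond, disease→octagon,
pathway→rectangle, default round-rectangle); a node attributed to several
linksets takes the lexically first tag's colour. The legend travels as a
plain table next to the style columns, so any viewer can reproduce the
figure without a tool-specific style file.

The CLI (`ctl_cli()`, wrapped by `inst/cli/linksetr`) exposes the whole
pipeline with conventional exit codes (0 success, 1 data error, 2 usage
error), logs to standard error, accepts repeated `--linksets` flags plus
a `--linkset-dir` whose `*.xgmml` files are appended in lexical order,
and takes a JSON `--config` supplying defaults that explicit flags
override. With seeds fixed, every output file is byte-identical across
reruns — the acceptance script verifies exactly that.

## Known limitations

* Identifier equality is purely lexical; no registry-aware normalization
  of system prefixes or case conventions.
* Overlap does not accumulate across sequential extension calls.
* SIF export discards attributes by design.
* The layout's force constants are igraph's defaults; only seed and
  iteration count are exposed.
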