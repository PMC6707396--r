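# Deterministic per-seed fixture dimensions used by the property-style and
# acceptance suites: arbitrary but fixed arithmetic over the seed, bounded by
# 200 network nodes, 3 linksets and 500 edges per linkset.
acceptance_spec <- function(seed) {
  fixture_spec(
    seed = seed,
    n_network_nodes = 20 + (seed * 7) %% 181,
    n_linksets = 1 + seed %% 3,
    edges_per_linkset = 20 + (seed * 13) %% 131,
    match_fraction = 0.1 + (seed %% 9) / 10
  )
}

make_fixture <- function(seed, ...) {
  spec <- if (length(list(...)) > 0) fixture_spec(seed = seed, ...) else {
    acceptance_spec(seed)
  }
  generate_fixtures(spec, withr::local_tempdir(.local_envir = parent.frame()))
}

gt_additions <- function(fx, direction) {
  gt <- fx$ground_truth$directions[[direction]]
  list(added_node_keys = gt$added_node_keys,
       added_edges = as.data.frame(gt$added_edges))
}

# small in-memory linkset builder for terse test cases
tiny_linkset <- function(name, edges, types = NULL, version = "1.0") {
  ids <- unique(c(edges$source, edges$target))
  nodes <- tibble::tibble(
    node_id = ids,
    label = toupper(sub("^[^:]*:", "", ids)),
    node_type = if (is.null(types)) "unknown" else unname(types[ids])
  )
  linkset(name, version, date = "2020-01-01", nodes = nodes, edges = edges)
}
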