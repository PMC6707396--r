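#' Build the identifier match index for a network
#'
#' Matching between network nodes and linkset entities is attribute-based:
#' each node's `id_attribute` value (scalar or list) is indexed either
#' canonically — when it contains a `":"` it is treated as a full
#' `"system:value"` identifier — or as a bare value (e.g. a `"display name"`
#' of `"MECP2"`). A linkset entity hits the index if any of its canonical
#' identifiers is present canonically, or if the value part of any of its
#' identifiers equals a bare indexed value. The bare fallback applies only on
#' the linkset side: a network value containing `":"` is never matched
#' against bare value parts. Comparison is exact and case-sensitive.
#'
#' Nodes lacking the attribute are simply absent from the index.
#'
#' @param net A [network()].
#' @param id_attribute Node attribute name to match on.
#' @return A `match_index` object (lookup environments for canonical and
#'   bare values).
#' @export
build_match_index <- function(net, id_attribute) {
  if (!nzchar(id_attribute %||% "")) abort("id_attribute must be non-empty")
  canonical <- new.env(parent = emptyenv())
  bare <- new.env(parent = emptyenv())
  vals <- node_attr_values(net, id_attribute)
  n_indexed <- 0L
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (is.null(v)) next
    v <- as.character(v)
    v <- v[!is.na(v) & nzchar(v)]
    if (length(v) == 0) next
    n_indexed <- n_indexed + 1L
    key <- net$nodes$key[i]
    for (x in v) {
      env <- if (is_curie(x)) canonical else bare
      env[[x]] <- c(env[[x]], key)
    }
  }
  structure(list(canonical = canonical, bare = bare,
                 id_attribute = id_attribute, n_indexed = n_indexed),
            class = "match_index")
}

# Network node keys matching a linkset entity's identifier set.
match_keys <- function(index, identifiers) {
  hits <- character()
  for (id in identifiers) {
    hits <- c(hits, index$canonical[[id]], index$bare[[id_value(id)]])
  }
  sort(unique(hits))
}

#' Extend a network with linkset interactions
#'
#' The core operation: every linkset edge `s -> t` with relation `i` is
#' tested against the *input* network's nodes via [build_match_index()].
#' Under `direction = "TARGETS"`, if `s` matches an original network node the
#' target `t` is ensured (reusing a matching original node when one exists,
#' otherwise adding a node keyed by `t`'s canonical identifier) and the edge
#' is added; `"SOURCES"` is the mirror image (matched targets acquire their
#' upstream sources, e.g. gene nodes gaining pathway nodes); `"BOTH"`
#' (default) applies both rules. Nodes added during the call are never
#' re-matched within the same call — chained tiers require sequential calls.
#'
#' Added nodes carry `ctl.added = TRUE`, `ctl.type`, a label, the
#' `id_attribute` set to the canonical identifier, and `ctl.linksets` listing
#' every contributing `"name (version)"`. Added edges carry `ctl.linkset`
#' (all contributing linksets), `ctl.interaction`, and `ctl.overlap` — the
#' number of distinct linksets asserting the same directed
#' `(source, target, interaction)` triple; an edge asserted by several
#' linksets is stored once. Pre-existing nodes and edges are never modified,
#' and a candidate edge whose triple already exists in the input network is
#' skipped.
#'
#' @param net A [network()].
#' @param linksets A [linkset()] or list of linksets, applied in order.
#' @param id_attribute Network node attribute matched against linkset
#'   identifiers (e.g. `"display name"`, `"shared name"`).
#' @param direction `"BOTH"` (default), `"SOURCES"` or `"TARGETS"`.
#' @param linkset_dir Optional directory; every `*.xgmml` file in it,
#'   lexically sorted, is appended after the explicit linksets.
#' @return A `ctl_extension` object with fields `$network` (the extended
#'   network) and `$report` (an [extension report][summarize_extension]);
#'   [generics::tidy()] gives the per-linkset ledger, [generics::glance()]
#'   the totals.
#' @examples
#' net <- network(nodes = tibble::tibble(key = "g1", `shared name` = "gx:1"))
#' ls <- linkset("demo", "1.0",
#'   nodes = tibble::tibble(node_id = c("px:1", "gx:1"),
#'                          node_type = c("pathway", "gene")),
#'   edges = tibble::tibble(source = "px:1", target = "gx:1",
#'                          interaction = "partOf"))
#' ext <- extend_network(net, ls, id_attribute = "shared name",
#'                       direction = "SOURCES")
#' generics::tidy(ext)
#' @export
extend_network <- function(net, linksets, id_attribute,
                           direction = c("BOTH", "SOURCES", "TARGETS"),
                           linkset_dir = NULL) {
  direction <- match.arg(toupper(direction[1]), c("BOTH", "SOURCES", "TARGETS"))
  if (inherits(linksets, "linkset")) linksets <- list(linksets)
  if (!is.null(linkset_dir)) {
    files <- sort(list.files(linkset_dir, pattern = "\\.xgmml$",
                             full.names = TRUE))
    linksets <- c(linksets, purrr::map(files, read_linkset))
  }
  if (length(linksets) == 0) abort("at least one linkset is required")
  purrr::walk(linksets, stop_if_invalid_linkset)

  index <- build_match_index(net, id_attribute)
  if (index$n_indexed == 0) {
    warn(sprintf("no network node carries attribute '%s'; nothing to match",
                 id_attribute))
  }
  existing_triples <- edge_triples(net$edges)
  existing_keys <- net$nodes$key

  # accumulators keyed by canonical id / edge triple
  new_nodes <- list()   # canonical id -> list(label, type, linksets)
  new_edges <- list()   # triple -> list(source, target, interaction, linksets)

  for (ls in linksets) {
    tag <- linkset_tag(ls)
    node_tbl <- ls$nodes
    node_lookup <- setNames(seq_len(nrow(node_tbl)), node_tbl$node_id)
    smatch <- purrr::map(node_tbl$identifiers, ~ match_keys(index, .x))

    ensure_node <- function(id) {
      # resolve a linkset endpoint to network keys: matched original nodes
      # win; otherwise an added node keyed by the canonical identifier
      row <- node_lookup[[id]]
      keys <- smatch[[row]]
      if (length(keys) > 0) return(keys)
      node_key <- if (id %in% existing_keys) paste0("ctl:", id) else id
      prev <- new_nodes[[id]]
      if (is.null(prev)) {
        new_nodes[[id]] <<- list(key = node_key, label = node_tbl$label[row],
                                 type = node_tbl$node_type[row],
                                 linksets = tag)
      } else {
        new_nodes[[id]]$linksets <<- unique(c(prev$linksets, tag))
      }
      new_nodes[[id]]$key
    }
    add_candidate <- function(src_keys, tgt_keys, interaction) {
      for (sk in src_keys) for (tk in tgt_keys) {
        triple <- paste(sk, tk, interaction, sep = "\r")
        if (triple %in% existing_triples) next
        prev <- new_edges[[triple]]
        if (is.null(prev)) {
          new_edges[[triple]] <<- list(source = sk, target = tk,
                                       interaction = interaction,
                                       linksets = tag)
        } else {
          new_edges[[triple]]$linksets <<- unique(c(prev$linksets, tag))
        }
      }
    }

    for (r in seq_len(nrow(ls$edges))) {
      s <- ls$edges$source[r]; t <- ls$edges$target[r]
      inter <- ls$edges$interaction[r]
      s_hit <- smatch[[node_lookup[[s]]]]
      t_hit <- smatch[[node_lookup[[t]]]]
      if (direction %in% c("TARGETS", "BOTH") && length(s_hit) > 0) {
        add_candidate(s_hit, ensure_node(t), inter)
      }
      if (direction %in% c("SOURCES", "BOTH") && length(t_hit) > 0) {
        add_candidate(ensure_node(s), t_hit, inter)
      }
    }
  }

  net_out <- materialize_extension(net, new_nodes, new_edges, id_attribute)
  report <- extension_report_for(net_out, linksets)
  structure(list(network = net_out, report = report,
                 direction = direction, id_attribute = id_attribute),
            class = "ctl_extension")
}

materialize_extension <- function(net, new_nodes, new_edges, id_attribute) {
  pk <- provenance_keys()
  if (length(new_nodes) > 0) {
    ids <- sort(names(new_nodes))
    add <- tibble(
      key = unname(purrr::map_chr(new_nodes[ids], "key")),
      label = unname(purrr::map_chr(new_nodes[ids], "label"))
    )
    add[[id_attribute]] <- ids
    add[[pk[["added"]]]] <- TRUE
    add[[pk[["type"]]]] <- unname(purrr::map_chr(new_nodes[ids], "type"))
    add[[pk[["linksets"]]]] <- unname(purrr::map(new_nodes[ids],
                                                 ~ sort(.x$linksets)))
    net$nodes <- bind_rows(net$nodes, add)
  }
  if (length(new_edges) > 0) {
    triples <- sort(names(new_edges))
    add <- tibble(
      source = unname(purrr::map_chr(new_edges[triples], "source")),
      target = unname(purrr::map_chr(new_edges[triples], "target")),
      interaction = unname(purrr::map_chr(new_edges[triples], "interaction"))
    )
    add[[pk[["linkset"]]]] <- unname(purrr::map(new_edges[triples],
                                                ~ sort(.x$linksets)))
    add[[pk[["interaction"]]]] <- add$interaction
    add[[pk[["overlap"]]]] <- unname(purrr::map_int(new_edges[triples],
                                                    ~ length(.x$linksets)))
    net$edges <- bind_rows(net$edges, add)
  }
  # normalize list-column gaps (bind_rows leaves NULL) to empty vectors so
  # attribute round-trips compare cleanly
  for (col in c(pk[["linksets"]])) {
    if (col %in% names(net$nodes)) {
      net$nodes[[col]] <- purrr::map(net$nodes[[col]], ~ .x %||% character())
    }
  }
  if (pk[["linkset"]] %in% names(net$edges)) {
    net$edges[[pk[["linkset"]]]] <- purrr::map(net$edges[[pk[["linkset"]]]],
                                               ~ .x %||% character())
  }
  net
}

#' @export
print.ctl_extension <- function(x, ...) {
  cat(sprintf("<extension> direction=%s, id attribute='%s'\n",
              x$direction, x$id_attribute))
  print(x$report)
  invisible(x)
}

#' Strip everything the extension engine added
#'
#' Removes added nodes, extension edges and all `ctl.*` attribute columns,
#' recovering the original network. Useful for checking that extension never
#' mutates pre-existing content.
#'
#' @param net An extended [network()].
#' @return The network without extension material.
#' @export
strip_extension <- function(net) {
  pk <- provenance_keys()
  if (pk[["added"]] %in% names(net$nodes)) {
    added <- purrr::map_lgl(net$nodes[[pk[["added"]]]], isTRUE)
    net$nodes <- net$nodes[!added, ]
  }
  if (pk[["overlap"]] %in% names(net$edges)) {
    ext <- !is.na(net$edges[[pk[["overlap"]]]])
    net$edges <- net$edges[!ext, ]
  }
  net$nodes <- net$nodes[setdiff(names(net$nodes), unname(pk))]
  net$edges <- net$edges[setdiff(names(net$edges), unname(pk))]
  drop_all_na <- function(tbl) {
    keep <- purrr::map_lgl(tbl, function(col) {
      if (is.list(col)) !all(purrr::map_lgl(col, ~ is.null(.x) || length(.x) == 0))
      else !all(is.na(col))
    })
    keep[c("key", "source", "target", "interaction")[
      c("key", "source", "target", "interaction") %in% names(tbl)]] <- TRUE
    tbl[names(tbl)[keep]]
  }
  net$nodes <- drop_all_na(net$nodes)
  net$edges <- drop_all_na(net$edges)
  net
}
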