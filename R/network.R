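#' Create a network
#'
#' The user-side graph that gets extended. Nodes and edges are plain tibbles:
#' one row per node with a unique `key` column plus one column per attribute
#' (list columns allowed for multi-valued attributes), and one row per edge
#' with `source`, `target`, `interaction` plus attribute columns. Networks are
#' directed by default; linkset edges are always directed, and the
#' SOURCES/TARGETS direction semantics of [extend_network()] are only
#' meaningful on directed edges.
#'
#' @param nodes Data frame with a `key` column (unique) and attribute columns.
#' @param edges Data frame with `source`, `target` (keys present in `nodes`),
#'   `interaction`, and attribute columns. `(source, target, interaction)`
#'   triples must be unique.
#' @param name Network name.
#' @param directed Logical; kept for format round-trips.
#' @return An object of class `ctl_network`.
#' @examples
#' net <- network(nodes = tibble::tibble(key = c("a", "b"),
#'                                       `display name` = c("A", "B")),
#'                edges = tibble::tibble(source = "a", target = "b",
#'                                       interaction = "pp"))
#' net
#' @export
network <- function(nodes = NULL, edges = NULL, name = "network",
                    directed = TRUE) {
  if (is.null(nodes)) nodes <- tibble(key = character())
  nodes <- as_tibble(nodes)
  if (!"key" %in% names(nodes)) abort("network nodes need a 'key' column")
  nodes$key <- as.character(nodes$key)
  if (anyDuplicated(nodes$key)) {
    abort(sprintf("duplicate node key: %s",
                  nodes$key[duplicated(nodes$key)][1]))
  }
  if (is.null(edges)) {
    edges <- tibble(source = character(), target = character(),
                    interaction = character())
  }
  edges <- as_tibble(edges)
  for (col in c("source", "target")) {
    if (!col %in% names(edges)) abort(sprintf("edges need a '%s' column", col))
    edges[[col]] <- as.character(edges[[col]])
  }
  if (!"interaction" %in% names(edges)) edges$interaction <- "interacts"
  missing_ep <- setdiff(c(edges$source, edges$target), nodes$key)
  if (length(missing_ep) > 0) {
    abort(sprintf("edge endpoint not in node set: %s", missing_ep[1]))
  }
  tr <- edge_triples(edges)
  if (anyDuplicated(tr)) {
    abort(sprintf("duplicate edge triple: %s", tr[duplicated(tr)][1]))
  }
  edges <- edges[c("source", "target", "interaction",
                   setdiff(names(edges), c("source", "target", "interaction")))]
  structure(list(name = as.character(name), directed = isTRUE(directed),
                 nodes = nodes, edges = edges),
            class = "ctl_network")
}

edge_triples <- function(edges) {
  paste(edges$source, edges$target, edges$interaction, sep = "\r")
}

#' @export
print.ctl_network <- function(x, ...) {
  cat(sprintf("<network> %s (%s): %d nodes, %d edges\n", x$name,
              if (x$directed) "directed" else "undirected",
              nrow(x$nodes), nrow(x$edges)))
  pk <- provenance_keys()
  if (pk[["added"]] %in% names(x$nodes)) {
    added <- sum(purrr::map_lgl(x$nodes[[pk[["added"]]]], isTRUE))
    ext <- if (pk[["overlap"]] %in% names(x$edges)) {
      sum(!is.na(x$edges[[pk[["overlap"]]]]))
    } else 0L
    cat(sprintf("  extension: %d added nodes, %d extension edges\n",
                added, ext))
  }
  invisible(x)
}

# Fetch one node attribute as a list (scalar values wrapped), NULL-safe.
node_attr_values <- function(net, attribute) {
  if (!attribute %in% names(net$nodes)) return(rep(list(NULL), nrow(net$nodes)))
  col <- net$nodes[[attribute]]
  if (is.list(col)) col else as.list(col)
}

#' Degrees of network nodes
#'
#' @param net A [network()].
#' @return Tibble with columns `key` and `degree` (in + out, over all edges).
#' @keywords internal
node_degrees <- function(net) {
  inc <- c(net$edges$source, net$edges$target)
  cnt <- table(factor(inc, levels = net$nodes$key))
  tibble(key = net$nodes$key, degree = as.integer(cnt))
}

#' Convert a network to an igraph object
#'
#' Used by the layout step and handy for interoperability; scalar node/edge
#' attributes are carried across, list attributes are collapsed to
#' comma-joined strings.
#'
#' @param net A [network()].
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  nd <- net$nodes
  names(nd)[names(nd) == "key"] <- "name"
  nd <- collapse_list_cols(nd)
  ed <- collapse_list_cols(net$edges)
  names(ed)[names(ed) == "source"] <- "from"
  names(ed)[names(ed) == "target"] <- "to"
  igraph::graph_from_data_frame(ed, directed = net$directed, vertices = nd)
}

collapse_list_cols <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- purrr::map_chr(df[[nm]], function(v) {
        if (is.null(v) || length(v) == 0) NA_character_
        else paste(as.character(v), collapse = ",")
      })
    }
  }
  df
}
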