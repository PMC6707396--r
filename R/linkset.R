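#' Create a linkset
#'
#' A linkset is a named, versioned collection of directed, interaction-typed
#' links between identified entities (genes, compounds, pathways, diseases,
#' articles, ...). Linksets are the unit of prior knowledge that
#' [extend_network()] grafts onto a user network; they are stored on disk in
#' an XGMML dialect (see [read_linkset()] / [write_linkset()]).
#'
#' @param name Linkset name (non-empty).
#' @param version Version string of the underlying resource release.
#' @param nodes A data frame with columns `node_id` (canonical
#'   `"system:value"` identifier, unique), `label`, `node_type` (e.g.
#'   `"gene"`, `"compound"`), and optionally `identifiers` (a list column of
#'   canonical identifier vectors; `node_id` is added to it automatically).
#' @param edges A data frame with columns `source`, `target` (both canonical
#'   identifiers of nodes present in `nodes`), `interaction` (relation type,
#'   e.g. `"targets"`), and optionally `datasource`.
#' @param date ISO-8601 date string of the linkset build.
#' @param url Optional source URL.
#' @return An object of class `linkset` with tibble fields `$nodes` and
#'   `$edges` plus the metadata fields above.
#' @seealso [validate_linkset()], [build_linkset_from_tsv()]
#' @examples
#' ls <- linkset(
#'   name = "demo", version = "1.0",
#'   nodes = tibble::tibble(
#'     node_id = c("gx:1", "px:1"),
#'     label = c("G1", "P1"),
#'     node_type = c("gene", "pathway")
#'   ),
#'   edges = tibble::tibble(source = "px:1", target = "gx:1",
#'                          interaction = "partOf")
#' )
#' validate_linkset(ls)
#' @export
linkset <- function(name, version = "0", nodes = NULL, edges = NULL,
                    date = as.character(Sys.Date()), url = NA_character_) {
  nodes <- normalize_linkset_nodes(nodes)
  edges <- normalize_linkset_edges(edges)
  structure(
    list(name = as.character(name), version = as.character(version),
         date = as.character(date), url = as.character(url),
         nodes = nodes, edges = edges),
    class = "linkset"
  )
}

normalize_linkset_nodes <- function(nodes) {
  if (is.null(nodes) || nrow(as_tibble(nodes)) == 0) {
    return(tibble(node_id = character(), label = character(),
                  node_type = character(), identifiers = list(),
                  extras = list()))
  }
  nodes <- as_tibble(nodes)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$node_id
  if (!"node_type" %in% names(nodes)) nodes$node_type <- "unknown"
  if (!"identifiers" %in% names(nodes)) nodes$identifiers <- list(character())
  if (!"extras" %in% names(nodes)) nodes$extras <- list(character())
  nodes$identifiers <- purrr::map2(nodes$identifiers, nodes$node_id,
                                   ~ sort(unique(c(as.character(.x), .y))))
  nodes[c("node_id", "label", "node_type", "identifiers", "extras")]
}

normalize_linkset_edges <- function(edges) {
  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    return(tibble(source = character(), target = character(),
                  interaction = character(), datasource = character(),
                  extras = list()))
  }
  edges <- as_tibble(edges)
  if (!"interaction" %in% names(edges)) edges$interaction <- "association"
  if (!"datasource" %in% names(edges)) edges$datasource <- NA_character_
  if (!"extras" %in% names(edges)) edges$extras <- list(character())
  edges[c("source", "target", "interaction", "datasource", "extras")]
}

#' @export
print.linkset <- function(x, ...) {
  cat(sprintf("<linkset> %s (%s), %s\n", x$name, x$version, x$date))
  cat(sprintf("  %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    tab <- sort(table(x$edges$interaction), decreasing = TRUE)
    cat("  interactions:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a linkset
#'
#' Checks every structural invariant of the linkset model and reports
#' violations instead of raising: non-empty name, well-formed canonical
#' identifiers, unique `node_id`s, `node_id` contained in each node's
#' identifier set, non-empty node types, no dangling edge endpoints, and no
#' duplicate `(source, target, interaction)` triples. Duplicate edges are a
#' validation error rather than being silently deduplicated, so that
#' provenance counts stay exact.
#'
#' @param ls A [linkset()].
#' @return A tibble with columns `severity`, `message`, `location`; zero rows
#'   if and only if the linkset is valid.
#' @examples
#' bad <- linkset("b", nodes = tibble::tibble(node_id = "gx:1"),
#'                edges = tibble::tibble(source = "gx:1", target = "x:9",
#'                                       interaction = "targets"))
#' validate_linkset(bad)
#' @export
validate_linkset <- function(ls) {
  issues <- list()
  add <- function(severity, message, location) {
    issues[[length(issues) + 1]] <<- tibble(severity = severity,
                                            message = message,
                                            location = location)
  }
  if (!inherits(ls, "linkset")) {
    add("error", "not a linkset object", "object")
    return(bind_rows(issues))
  }
  if (!nzchar(ls$name %||% "")) add("error", "linkset name is empty", "graph")
  if (!is.data.frame(ls$nodes) || !is.data.frame(ls$edges)) {
    add("error", "malformed linkset object: missing node/edge tables", "object")
    return(bind_rows(issues))
  }

  n <- ls$nodes
  dup_ids <- unique(n$node_id[duplicated(n$node_id)])
  for (d in dup_ids) add("error", "duplicate node_id", d)
  bad_sys <- n$node_id[!is_curie(n$node_id) |
                         grepl("^[[:space:]]*:", n$node_id) |
                         grepl("[[:space:]]", id_system(n$node_id)) |
                         !nzchar(id_system(n$node_id)) |
                         !nzchar(id_value(n$node_id))]
  for (b in unique(bad_sys)) add("error", "malformed canonical identifier", b)
  if (nrow(n) > 0) {
    miss_self <- n$node_id[!purrr::map2_lgl(n$identifiers, n$node_id,
                                            ~ .y %in% .x)]
    for (m in miss_self) add("error", "node_id missing from identifiers", m)
    empty_type <- n$node_id[is.na(n$node_type) | !nzchar(n$node_type)]
    for (m in empty_type) add("error", "empty node_type", m)
  }

  e <- ls$edges
  if (nrow(e) > 0) {
    known <- n$node_id
    for (m in unique(e$source[!e$source %in% known])) {
      add("error", "dangling endpoint (source)", m)
    }
    for (m in unique(e$target[!e$target %in% known])) {
      add("error", "dangling endpoint (target)", m)
    }
    triple <- paste(e$source, e$target, e$interaction, sep = "\r")
    for (d in unique(triple[duplicated(triple)])) {
      add("error", "duplicate (source, target, interaction) edge",
          gsub("\r", " ", d))
    }
  }
  if (length(issues) == 0) {
    return(tibble(severity = character(), message = character(),
                  location = character()))
  }
  bind_rows(issues)
}

stop_if_invalid_linkset <- function(ls, context = "linkset") {
  iss <- validate_linkset(ls)
  if (nrow(iss) > 0) {
    abort(sprintf("invalid %s: %s [%s]", context,
                  iss$message[1], iss$location[1]))
  }
  invisible(ls)
}

# Attribution string used in ctl.linkset / ctl.linksets provenance values.
linkset_tag <- function(ls) sprintf("%s (%s)", ls$name, ls$version)

#' Provenance attribute names
#'
#' The extension engine writes its provenance under a fixed set of attribute
#' names so that downstream steps ([filter_overlap()], [summarize_extension()],
#' [apply_style()]) and external tools can recognize added material. Node
#' attributes: `ctl.added` (logical), `ctl.type` (entity type string),
#' `ctl.linksets` (list of `"name (version)"` attributions). Edge attributes:
#' `ctl.linkset` (list of attributions), `ctl.interaction`, `ctl.overlap`
#' (number of distinct linksets asserting the interaction, >= 1), `ctl.hidden`
#' (logical, set by [filter_overlap()] in hide mode).
#'
#' @return Named character vector of the seven attribute names.
#' @examples
#' provenance_keys()
#' @export
provenance_keys <- function() {
  c(added = "ctl.added", type = "ctl.type", linksets = "ctl.linksets",
    linkset = "ctl.linkset", interaction = "ctl.interaction",
    overlap = "ctl.overlap", hidden = "ctl.hidden")
}
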