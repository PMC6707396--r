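#' Read a linkset from an XGMML file
#'
#' Parses the XGMML linkset dialect written by [write_linkset()]: a `graph`
#' element carrying graph-level `att`s `name`, `version`, `date` and
#' optionally `url`; `node` elements with `id` (canonical identifier) and
#' `label`, child `att`s `identifiers` (bracketed, comma-joined, lexically
#' sorted) and `type`; `edge` elements with `source`, `target` and child
#' `att`s `interaction` and `datasource`. Unknown node/edge `att`s are
#' tolerated and preserved in an `extras` field so foreign files round-trip.
#'
#' A node without an `identifiers` att gets its `id` as sole identifier.
#' Malformed XML, a missing graph-level `name`, or an edge referencing an
#' absent node are fatal.
#'
#' @param path Path to an XGMML linkset file.
#' @return A [linkset()].
#' @seealso [write_linkset()], [validate_linkset()]
#' @export
read_linkset <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("XML parse error in %s: %s", path, conditionMessage(e)))
  })
  graph <- xml2::xml_find_first(doc, "/*[local-name()='graph']")
  if (is.na(xml2::xml_name(graph))) {
    abort(sprintf("%s: root element is not <graph>", path))
  }
  gatts <- read_att_children(graph)
  if (!"name" %in% names(gatts)) {
    abort(sprintf("%s: missing graph-level 'name' att", path))
  }

  node_els <- xml2::xml_find_all(graph, "./*[local-name()='node']")
  nodes <- purrr::map(node_els, function(el) {
    id <- xml2::xml_attr(el, "id")
    atts <- read_att_children(el)
    ids <- if ("identifiers" %in% names(atts)) {
      parse_id_set(atts[["identifiers"]])
    } else id
    extras <- atts[setdiff(names(atts), c("identifiers", "type"))]
    tibble(node_id = id,
           label = xml2::xml_attr(el, "label") %||% id,
           node_type = vget(atts, "type", "unknown"),
           identifiers = list(sort(unique(c(ids, id)))),
           extras = list(extras))
  })
  nodes <- if (length(nodes) > 0) bind_rows(nodes) else NULL

  edge_els <- xml2::xml_find_all(graph, "./*[local-name()='edge']")
  edges <- purrr::map(edge_els, function(el) {
    atts <- read_att_children(el)
    extras <- atts[setdiff(names(atts), c("interaction", "datasource"))]
    tibble(source = xml2::xml_attr(el, "source"),
           target = xml2::xml_attr(el, "target"),
           interaction = vget(atts, "interaction", "association"),
           datasource = vget(atts, "datasource"),
           extras = list(extras))
  })
  edges <- if (length(edges) > 0) bind_rows(edges) else NULL

  ls <- linkset(name = vget(gatts, "name"),
                version = vget(gatts, "version", "0"),
                date = vget(gatts, "date"),
                url = vget(gatts, "url"),
                nodes = nodes, edges = edges)
  dangling <- setdiff(c(ls$edges$source, ls$edges$target), ls$nodes$node_id)
  if (length(dangling) > 0) {
    abort(sprintf("%s: edge references absent node '%s'", path, dangling[1]))
  }
  ls
}

read_att_children <- function(el) {
  atts <- xml2::xml_find_all(el, "./*[local-name()='att']")
  setNames(xml2::xml_attr(atts, "value"), xml2::xml_attr(atts, "name"))
}

# named-vector lookup that tolerates absent names
vget <- function(v, nm, default = NA_character_) {
  if (nm %in% names(v)) unname(v[[nm]]) else default
}

#' Write a linkset to an XGMML file
#'
#' Emits the dialect described in [read_linkset()] with deterministic element
#' ordering (nodes sorted by `node_id`, edges by `(source, target,
#' interaction)`), so identical linksets produce byte-identical files and
#' `read_linkset(write_linkset(ls))` recovers `ls` up to canonical ordering.
#' The linkset is validated first; the first violation aborts the write.
#'
#' @param ls A valid [linkset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_linkset <- function(ls, path) {
  stop_if_invalid_linkset(ls)
  ls <- canonicalize_linkset(ls)
  doc <- xml2::xml_new_root("graph", label = ls$name, directed = "1")
  add_att <- function(parent, name, value) {
    xml2::xml_add_child(parent, "att", name = name, type = "string",
                        value = value)
  }
  add_att(doc, "name", ls$name)
  add_att(doc, "version", ls$version)
  add_att(doc, "date", ls$date)
  if (!is.na(ls$url)) add_att(doc, "url", ls$url)

  purrr::pwalk(ls$nodes, function(node_id, label, node_type, identifiers,
                                  extras) {
    el <- xml2::xml_add_child(doc, "node", id = node_id, label = label)
    add_att(el, "identifiers", render_id_set(identifiers))
    add_att(el, "type", node_type)
    for (nm in sort(names(extras))) add_att(el, nm, extras[[nm]])
  })
  purrr::pwalk(ls$edges, function(source, target, interaction, datasource,
                                  extras) {
    el <- xml2::xml_add_child(doc, "edge", source = source, target = target,
                              label = sprintf("%s (%s) %s", source,
                                              interaction, target))
    add_att(el, "interaction", interaction)
    if (!is.na(datasource)) add_att(el, "datasource", datasource)
    for (nm in sort(names(extras))) add_att(el, nm, extras[[nm]])
  })
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Canonical ordering of a linkset
#'
#' Sorts nodes by `node_id`, edges by `(source, target, interaction)`, and
#' each node's identifier set lexically. Two linksets with equal canonical
#' forms are considered equal throughout the package.
#'
#' @param ls A [linkset()].
#' @return The reordered linkset.
#' @export
canonicalize_linkset <- function(ls) {
  ls$nodes <- arrange(ls$nodes, node_id)
  ls$nodes$identifiers <- purrr::map(ls$nodes$identifiers,
                                     ~ sort(unique(.x)))
  ls$edges <- arrange(ls$edges, source, target, interaction)
  ls
}

#' Column mapping for building linksets from tab-delimited tables
#'
#' Describes how the columns of a tab-delimited interaction table map onto
#' linkset fields, plus the linkset metadata to stamp on the result.
#'
#' @param source_id,target_id Column names holding the two endpoint
#'   identifiers (canonical `"system:value"` strings, or bare values combined
#'   with `source_system` / `target_system`).
#' @param source_label,target_label Optional label columns (default: the id).
#' @param source_type,target_type Either a column name present in the table
#'   header or, if not a column, a fixed type string applied to every row.
#' @param interaction Optional column for the relation type; rows lacking it
#'   get `default_interaction`.
#' @param datasource Optional column naming the asserting resource.
#' @param name,version,date Linkset metadata.
#' @param source_system,target_system Identifier system prefixes applied to
#'   bare (un-prefixed) id values.
#' @param default_interaction Relation type used when no interaction column
#'   is configured (default `"association"`).
#' @return A `linkset_tsv_config` list understood by
#'   [build_linkset_from_tsv()].
#' @export
linkset_tsv_config <- function(source_id, target_id,
                               source_label = NULL, target_label = NULL,
                               source_type = "unknown",
                               target_type = "unknown",
                               interaction = NULL, datasource = NULL,
                               name = "linkset", version = "0",
                               date = as.character(Sys.Date()),
                               source_system = NULL, target_system = NULL,
                               default_interaction = "association") {
  structure(list(source_id = source_id, target_id = target_id,
                 source_label = source_label, target_label = target_label,
                 source_type = source_type, target_type = target_type,
                 interaction = interaction, datasource = datasource,
                 name = name, version = version, date = date,
                 source_system = source_system,
                 target_system = target_system,
                 default_interaction = default_interaction),
            class = "linkset_tsv_config")
}

#' Build a linkset from a tab-delimited interaction table
#'
#' Converts a TSV of pairwise interactions into a [linkset()]: one edge per
#' retained row, endpoint nodes deduplicated by identifier. The TSV dialect is
#' UTF-8, tab-separated, no quoting, with `#`-prefixed comment lines skipped.
#' Rows with a missing or un-prefixable identifier are dropped (reason
#' `"missing id"`), as are exact repeats of an already-seen
#' `(source, target, interaction)` triple (reason `"duplicate edge"`). When
#' the same identifier occurs with several labels or types, the
#' lexicographically smallest wins, which makes the result independent of row
#' order.
#'
#' @param tsv_path Path to the table.
#' @param config A [linkset_tsv_config()].
#' @return A list with elements `linkset` and `report`; the report holds
#'   `rows_total`, `rows_retained`, `rows_dropped` and a `drop_reasons`
#'   tibble.
#' @export
build_linkset_from_tsv <- function(tsv_path, config) {
  stopifnot(inherits(config, "linkset_tsv_config"))
  tab <- read_plain_tsv(tsv_path)
  for (col in c(config$source_id, config$target_id)) {
    if (!col %in% names(tab)) {
      abort(sprintf("%s: required column '%s' not in header", tsv_path, col))
    }
  }
  n_total <- nrow(tab)

  get_col <- function(col, default) {
    if (!is.null(col) && col %in% names(tab)) tab[[col]] else rep(default, n_total)
  }
  qualify <- function(ids, system) {
    ids <- ifelse(is.na(ids) | !nzchar(ids), NA_character_, ids)
    bare <- !is.na(ids) & !is_curie(ids)
    if (any(bare)) {
      if (is.null(system)) ids[bare] <- NA_character_
      else ids[bare] <- paste0(system, ":", ids[bare])
    }
    ids
  }
  sid <- qualify(get_col(config$source_id, NA), config$source_system)
  tid <- qualify(get_col(config$target_id, NA), config$target_system)
  rows <- tibble(
    sid = sid, tid = tid,
    slab = dplyr::coalesce(as.character(get_col(config$source_label, NA)), sid),
    tlab = dplyr::coalesce(as.character(get_col(config$target_label, NA)), tid),
    stype = type_col(tab, config$source_type, n_total),
    ttype = type_col(tab, config$target_type, n_total),
    interaction = dplyr::coalesce(
      as.character(get_col(config$interaction, NA)),
      config$default_interaction),
    datasource = dplyr::coalesce(as.character(get_col(config$datasource, NA)),
                                 config$name)
  )

  missing_id <- is.na(rows$sid) | is.na(rows$tid)
  kept <- rows[!missing_id, ]
  dup <- duplicated(paste(kept$sid, kept$tid, kept$interaction, sep = "\r"))
  retained <- kept[!dup, ]

  nodes <- bind_rows(
    tibble(node_id = retained$sid, label = retained$slab,
           node_type = retained$stype),
    tibble(node_id = retained$tid, label = retained$tlab,
           node_type = retained$ttype)
  ) |>
    group_by(node_id) |>
    summarise(label = min(label), node_type = min(node_type),
              .groups = "drop")

  ls <- linkset(name = config$name, version = config$version,
                date = config$date, nodes = nodes,
                edges = select(retained, source = sid, target = tid,
                               interaction, datasource))
  drop_reasons <- tibble(
    reason = c("missing id", "duplicate edge"),
    n = c(sum(missing_id), sum(dup))
  ) |> filter(n > 0)
  list(linkset = canonicalize_linkset(ls),
       report = list(rows_total = n_total, rows_retained = nrow(retained),
                     rows_dropped = n_total - nrow(retained),
                     drop_reasons = drop_reasons))
}

type_col <- function(tab, spec, n) {
  if (!is.null(spec) && spec %in% names(tab)) as.character(tab[[spec]])
  else rep(spec %||% "unknown", n)
}

read_plain_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  readr::read_delim(path, delim = "\t", quote = "", comment = "#",
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
}

#' Read an identifier mapping table
#'
#' A local two-column cross-reference table standing in for an identifier
#' mapping service: TSV with header `from<TAB>to`, both columns canonical
#' `"system:value"` strings. One `from` may map to several `to` rows; all are
#' retained.
#'
#' @param path Path to the TSV file.
#' @return Tibble with character columns `from` and `to`.
#' @export
read_mapping_table <- function(path) {
  tab <- read_plain_tsv(path)
  if (!all(c("from", "to") %in% names(tab))) {
    abort(sprintf("%s: mapping table needs 'from' and 'to' columns", path))
  }
  tibble(from = tab$from, to = tab$to)
}

#' Add cross-referenced identifiers to a linkset
#'
#' For every node, looks up each of its identifiers in the mapping table and
#' adds all mapped identifiers whose system equals `target_system`. Under
#' `policy = "drop-unmapped"`, nodes for which no mapping was found are
#' removed together with their edges; under `"keep-unmapped"` (an identity
#' table is then a no-op) they are kept unchanged. One-to-many mappings are
#' all added and flagged in the report.
#'
#' @param ls A valid [linkset()].
#' @param table Mapping table as returned by [read_mapping_table()].
#' @param target_system Identifier system to import (e.g. `"ncbigene"`).
#' @param policy `"keep-unmapped"` (default) or `"drop-unmapped"`.
#' @return List with elements `linkset` and `report` (`nodes_total`,
#'   `nodes_mapped`, `nodes_unmapped`, `ambiguous` tibble).
#' @export
map_linkset_identifiers <- function(ls, table, target_system,
                                    policy = c("keep-unmapped",
                                               "drop-unmapped")) {
  policy <- match.arg(policy)
  stop_if_invalid_linkset(ls)
  tab <- filter(as_tibble(table), id_system(to) == target_system)

  hits <- purrr::map(ls$nodes$identifiers,
                     function(ids) sort(unique(tab$to[tab$from %in% ids])))
  n_hits <- lengths(hits)
  ls$nodes$identifiers <- purrr::map2(ls$nodes$identifiers, hits,
                                      ~ sort(unique(c(.x, .y))))
  ambiguous <- tibble(node_id = ls$nodes$node_id, n_mapped = n_hits) |>
    filter(n_mapped > 1)
  report <- list(nodes_total = nrow(ls$nodes),
                 nodes_mapped = sum(n_hits > 0),
                 nodes_unmapped = sum(n_hits == 0),
                 ambiguous = ambiguous)

  if (policy == "drop-unmapped") {
    keep <- ls$nodes$node_id[n_hits > 0]
    ls$nodes <- filter(ls$nodes, node_id %in% keep)
    ls$edges <- filter(ls$edges, source %in% keep & target %in% keep)
  }
  list(linkset = ls, report = report)
}
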