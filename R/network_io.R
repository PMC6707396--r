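#' Read a network from a standard graph file
#'
#' Supported formats: GraphML (attributed, lossless), the XGMML network
#' dialect written by [write_network()], SIF (`source interaction target`,
#' whitespace- or tab-separated, single-token lines declare isolated nodes),
#' and a tab-separated edge list with header `source`, `interaction`,
#' `target` (rows with empty interaction and target declare isolated nodes).
#'
#' After reading, `"shared name"` and `"display name"` attributes are
#' synthesized from the node label (or the node id when there is no label)
#' whenever absent, so that identifier matching on those attributes always
#' has a value to work with.
#'
#' @param path Input file.
#' @param format One of `"graphml"`, `"xgmml"`, `"sif"`, `"tsv"`; inferred
#'   from the file extension when omitted.
#' @return A [network()].
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  format <- format %||% infer_format(path)
  net <- switch(format,
    graphml = read_graphml(path),
    xgmml = read_xgmml_network(path),
    sif = read_sif(path),
    tsv = read_tsv_edgelist(path),
    abort(sprintf("unknown network format: %s", format))
  )
  ensure_name_attrs(net)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         graphml = "graphml", xgmml = "xgmml", sif = "sif",
         tsv = "tsv", txt = "tsv",
         abort(sprintf("cannot infer network format from '%s'", path)))
}

ensure_name_attrs <- function(net) {
  base <- if ("label" %in% names(net$nodes)) {
    dplyr::coalesce(as.character(net$nodes$label), net$nodes$key)
  } else net$nodes$key
  for (attr in c("shared name", "display name")) {
    if (!attr %in% names(net$nodes)) net$nodes[[attr]] <- base
  }
  net
}

#' Write a network to a graph file
#'
#' GraphML and XGMML carry every node and edge attribute, including the
#' `ctl.*` provenance and `x`/`y` layout coordinates, with deterministic
#' element ordering (attribute declarations sorted by name, nodes by key,
#' edges by `(source, target, interaction)`), so repeated writes of the same
#' network are byte-identical. SIF keeps only the topology; attributes are
#' dropped with a warning.
#'
#' List-valued attributes are rendered `"[a,b]"` (comma-joined); list items
#' must therefore not contain commas. In GraphML the declaring `<key>` is
#' marked with `list="true"`; in XGMML a native `type="list"` att is used.
#' Numeric attributes are written with 17 significant digits, so
#' doubles survive a round-trip exactly.
#'
#' @param net A [network()].
#' @param path Output file.
#' @param format `"graphml"`, `"xgmml"` or `"sif"`; inferred from the
#'   extension when omitted.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = NULL) {
  format <- format %||% infer_format(path)
  switch(format,
    graphml = write_graphml(net, path),
    xgmml = write_xgmml_network(net, path),
    sif = write_sif(net, path),
    abort(sprintf("unknown network format: %s", format))
  )
  invisible(path)
}

canonical_network <- function(net) {
  attr_cols <- sort(setdiff(names(net$nodes), "key"))
  net$nodes <- arrange(net$nodes[c("key", attr_cols)], key)
  ecols <- sort(setdiff(names(net$edges), c("source", "target", "interaction")))
  net$edges <- arrange(net$edges[c("source", "target", "interaction", ecols)],
                       source, target, interaction)
  net
}

# ---- GraphML ---------------------------------------------------------------

graphml_type <- function(col) {
  if (is.list(col)) "list"
  else if (is.logical(col)) "boolean"
  else if (is.integer(col)) "int"
  else if (is.numeric(col)) "double"
  else "string"
}

render_scalar <- function(v) {
  if (is.null(v) || length(v) == 0 || (length(v) == 1 && is.na(v))) {
    return(NA_character_)
  }
  if (is.logical(v)) tolower(as.character(v))
  else if (is.numeric(v)) format(v, digits = 17, trim = TRUE, scientific = FALSE)
  else as.character(v)
}

render_attr <- function(v, type) {
  if (type == "list") {
    v <- unlist(v)
    if (is.null(v) || length(v) == 0) return(NA_character_)
    paste0("[", paste(as.character(v), collapse = ","), "]")
  } else {
    render_scalar(v)
  }
}

parse_attr_values <- function(values, type) {
  switch(type,
         boolean = as.logical(toupper(values)),
         int = as.integer(values),
         long = as.integer(values),
         double = as.numeric(values),
         float = as.numeric(values),
         list = purrr::map(values, function(v) {
           if (is.na(v)) character() else parse_id_set(v)
         }),
         values)
}

write_graphml <- function(net, path) {
  net <- canonical_network(net)
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")

  node_attrs <- setdiff(names(net$nodes), "key")
  edge_attrs <- setdiff(names(net$edges), c("source", "target"))
  keymap <- list(node = character(), edge = character())
  i <- 0
  for (dom in c("node", "edge")) {
    attrs <- if (dom == "node") node_attrs else edge_attrs
    tbl <- if (dom == "node") net$nodes else net$edges
    for (a in attrs) {
      kid <- sprintf("k%d", i); i <- i + 1
      type <- graphml_type(tbl[[a]])
      el <- xml2::xml_add_child(doc, "key", id = kid, "for" = dom,
                                "attr.name" = a,
                                "attr.type" = if (type == "list") "string" else type)
      if (type == "list") xml2::xml_set_attr(el, "list", "true")
      keymap[[dom]][a] <- kid
    }
  }

  g <- xml2::xml_add_child(doc, "graph", id = net$name,
                           edgedefault = if (net$directed) "directed"
                                         else "undirected")
  for (r in seq_len(nrow(net$nodes))) {
    el <- xml2::xml_add_child(g, "node", id = net$nodes$key[r])
    row <- purrr::map(net$nodes[r, node_attrs, drop = FALSE], ~ .x[[1]])
    for (a in node_attrs) {
      s <- render_attr(row[[a]], graphml_type(net$nodes[[a]]))
      if (!is.na(s)) {
        d <- xml2::xml_add_child(el, "data", key = keymap$node[a])
        xml2::xml_set_text(d, s)
      }
    }
  }
  for (r in seq_len(nrow(net$edges))) {
    el <- xml2::xml_add_child(g, "edge", source = net$edges$source[r],
                              target = net$edges$target[r])
    row <- purrr::map(net$edges[r, edge_attrs, drop = FALSE], ~ .x[[1]])
    for (a in edge_attrs) {
      s <- render_attr(row[[a]], graphml_type(net$edges[[a]]))
      if (!is.na(s)) {
        d <- xml2::xml_add_child(el, "data", key = keymap$edge[a])
        xml2::xml_set_text(d, s)
      }
    }
  }
  xml2::write_xml(doc, path)
}


read_graphml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("XML parse error in %s: %s", path, conditionMessage(e)))
  })
  keys <- xml2::xml_find_all(doc, "//*[local-name()='key']")
  keytab <- tibble(
    id = xml2::xml_attr(keys, "id"),
    domain = xml2::xml_attr(keys, "for"),
    name = xml2::xml_attr(keys, "attr.name"),
    type = ifelse(!is.na(xml2::xml_attr(keys, "list")) &
                    xml2::xml_attr(keys, "list") == "true",
                  "list", xml2::xml_attr(keys, "attr.type"))
  )
  g <- xml2::xml_find_first(doc, "//*[local-name()='graph']")
  directed <- !identical(xml2::xml_attr(g, "edgedefault"), "undirected")
  name <- xml2::xml_attr(g, "id") %||% "network"

  read_elements <- function(tag, id_attrs, domain) {
    els <- xml2::xml_find_all(g, sprintf("./*[local-name()='%s']", tag))
    ktab <- keytab[keytab$domain == domain, ]
    rows <- purrr::map(els, function(el) {
      out <- as.list(setNames(
        purrr::map_chr(id_attrs, ~ xml2::xml_attr(el, .x)), id_attrs))
      data <- xml2::xml_find_all(el, "./*[local-name()='data']")
      vals <- setNames(xml2::xml_text(data), xml2::xml_attr(data, "key"))
      out$.data <- vals
      out
    })
    list(rows = rows, ktab = ktab)
  }

  build_tbl <- function(parsed, id_attrs) {
    rows <- parsed$rows; ktab <- parsed$ktab
    base <- purrr::map(id_attrs, function(a) {
      purrr::map_chr(rows, ~ .x[[a]] %||% NA_character_)
    })
    tbl <- as_tibble(setNames(base, id_attrs),
                     .name_repair = "minimal")
    if (length(rows) == 0) {
      for (a in id_attrs) tbl[[a]] <- character()
    }
    for (r in seq_len(nrow(ktab))) {
      kid <- ktab$id[r]
      raw <- purrr::map_chr(rows, ~ unname(.x$.data[kid]) %||% NA_character_)
      tbl[[ktab$name[r]]] <- parse_attr_values(raw, ktab$type[r])
    }
    tbl
  }

  nodes <- build_tbl(read_elements("node", "id", "node"), "id")
  names(nodes)[names(nodes) == "id"] <- "key"
  edges <- build_tbl(read_elements("edge", c("source", "target"), "edge"),
                     c("source", "target"))
  if (!"interaction" %in% names(edges)) {
    edges$interaction <- rep("interacts", nrow(edges))
  }
  network(nodes = nodes, edges = edges, name = name, directed = directed)
}

# ---- XGMML network ---------------------------------------------------------

xgmml_att_type <- function(col) {
  if (is.list(col)) "list"
  else if (is.logical(col)) "boolean"
  else if (is.integer(col)) "integer"
  else if (is.numeric(col)) "real"
  else "string"
}

write_xgmml_network <- function(net, path) {
  net <- canonical_network(net)
  doc <- xml2::xml_new_root("graph", label = net$name,
                            directed = if (net$directed) "1" else "0")
  emit_atts <- function(parent, row, cols, tbl) {
    for (a in cols) {
      type <- xgmml_att_type(tbl[[a]])
      v <- row[[a]]
      if (type == "list") {
        items <- unlist(v)
        if (length(items) == 0) next
        lst <- xml2::xml_add_child(parent, "att", name = a, type = "list")
        for (it in items) {
          xml2::xml_add_child(lst, "att", type = "string",
                              value = as.character(it))
        }
      } else {
        s <- render_scalar(v)
        if (!is.na(s)) {
          xml2::xml_add_child(parent, "att", name = a, type = type, value = s)
        }
      }
    }
  }
  node_attrs <- setdiff(names(net$nodes), "key")
  for (r in seq_len(nrow(net$nodes))) {
    lab <- if ("label" %in% node_attrs) net$nodes$label[r] else net$nodes$key[r]
    el <- xml2::xml_add_child(doc, "node", id = net$nodes$key[r],
                              label = as.character(lab))
    row <- purrr::map(net$nodes[r, node_attrs, drop = FALSE], ~ .x[[1]])
    emit_atts(el, row, node_attrs, net$nodes)
  }
  edge_attrs <- setdiff(names(net$edges), c("source", "target"))
  for (r in seq_len(nrow(net$edges))) {
    el <- xml2::xml_add_child(doc, "edge", source = net$edges$source[r],
                              target = net$edges$target[r])
    row <- purrr::map(net$edges[r, edge_attrs, drop = FALSE], ~ .x[[1]])
    emit_atts(el, row, edge_attrs, net$edges)
  }
  xml2::write_xml(doc, path)
}

read_xgmml_network <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("XML parse error in %s: %s", path, conditionMessage(e)))
  })
  g <- xml2::xml_find_first(doc, "/*[local-name()='graph']")
  name <- xml2::xml_attr(g, "label") %||% "network"
  directed <- !identical(xml2::xml_attr(g, "directed"), "0")

  parse_atts <- function(el) {
    atts <- xml2::xml_find_all(el, "./*[local-name()='att']")
    out <- list()
    for (a in atts) {
      nm <- xml2::xml_attr(a, "name")
      ty <- xml2::xml_attr(a, "type") %||% "string"
      if (identical(ty, "list")) {
        items <- xml2::xml_find_all(a, "./*[local-name()='att']")
        out[[nm]] <- list(value = xml2::xml_attr(items, "value"),
                          type = "list")
      } else {
        out[[nm]] <- list(value = xml2::xml_attr(a, "value"), type = ty)
      }
    }
    out
  }
  typed_scalar <- function(v, ty) {
    switch(ty,
           boolean = as.logical(toupper(v)),
           integer = as.integer(v),
           real = as.numeric(v),
           v)
  }

  node_els <- xml2::xml_find_all(g, "./*[local-name()='node']")
  node_rows <- purrr::map(node_els, function(el) {
    c(list(key = xml2::xml_attr(el, "id"),
           label = xml2::xml_attr(el, "label")), parse_atts(el))
  })
  edge_els <- xml2::xml_find_all(g, "./*[local-name()='edge']")
  edge_rows <- purrr::map(edge_els, function(el) {
    c(list(source = xml2::xml_attr(el, "source"),
           target = xml2::xml_attr(el, "target")), parse_atts(el))
  })

  assemble <- function(rows, fixed) {
    if (length(rows) == 0) {
      return(as_tibble(setNames(rep(list(character()), length(fixed)), fixed)))
    }
    attr_names <- sort(unique(unlist(purrr::map(rows,
                                                ~ setdiff(names(.x), fixed)))))
    tbl <- as_tibble(setNames(
      purrr::map(fixed, function(f) purrr::map_chr(rows, ~ .x[[f]] %||%
                                                     NA_character_)),
      fixed))
    for (a in attr_names) {
      cells <- purrr::map(rows, ~ .x[[a]])
      types <- unique(unlist(purrr::map(cells, ~ .x$type)))
      type <- if (length(types) == 0) "string" else types[1]
      if (type == "list") {
        tbl[[a]] <- purrr::map(cells, ~ if (is.null(.x)) character()
                               else .x$value)
      } else {
        raw <- purrr::map_chr(cells, ~ if (is.null(.x)) NA_character_
                              else .x$value)
        tbl[[a]] <- typed_scalar(raw, type)
      }
    }
    tbl
  }
  nodes <- assemble(node_rows, c("key", "label"))
  edges <- assemble(edge_rows, c("source", "target"))
  if (!"interaction" %in% names(edges)) {
    edges$interaction <- rep("interacts", nrow(edges))
  }
  network(nodes = nodes, edges = edges, name = name, directed = directed)
}

# ---- SIF / TSV edge list ---------------------------------------------------

write_sif <- function(net, path) {
  has_attrs <- length(setdiff(names(net$nodes), c("key"))) > 0 ||
    length(setdiff(names(net$edges), c("source", "target", "interaction"))) > 0
  if (has_attrs) {
    warn("SIF keeps topology only; node/edge attributes are dropped")
  }
  net <- canonical_network(net)
  lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$interaction,
                   net$edges$target)
  isolated <- setdiff(net$nodes$key, c(net$edges$source, net$edges$target))
  writeLines(c(lines, sort(isolated)), path)
}

read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nodes <- character()
  edges <- list()
  for (i in seq_along(lines)) {
    toks <- if (grepl("\t", lines[i], fixed = TRUE)) {
      strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    } else {
      strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    }
    toks <- toks[nzchar(toks)]
    if (length(toks) == 1) {
      nodes <- c(nodes, toks)
    } else if (length(toks) == 2) {
      warn(sprintf("%s line %d: expected interaction column, row skipped",
                   path, i))
    } else {
      for (tgt in toks[3:length(toks)]) {
        edges[[length(edges) + 1]] <- tibble(source = toks[1],
                                             interaction = toks[2],
                                             target = tgt)
      }
      nodes <- c(nodes, toks[1], toks[3:length(toks)])
    }
  }
  edges <- if (length(edges) > 0) distinct(bind_rows(edges)) else NULL
  network(nodes = tibble(key = unique(nodes)), edges = edges,
          name = tools::file_path_sans_ext(basename(path)))
}

read_tsv_edgelist <- function(path) {
  tab <- read_plain_tsv(path)
  for (col in c("source", "interaction", "target")) {
    if (!col %in% names(tab)) {
      abort(sprintf("%s: edge list needs a '%s' column", path, col))
    }
  }
  blank <- function(v) is.na(v) | !nzchar(v)
  isolated <- blank(tab$interaction) & blank(tab$target)
  edges <- tab[!isolated, c("source", "interaction", "target")]
  nodes <- unique(c(tab$source, edges$target))
  network(nodes = tibble(key = nodes), edges = edges,
          name = tools::file_path_sans_ext(basename(path)))
}

# ---- node attribute tables -------------------------------------------------

#' Merge a node attribute table into a network
#'
#' Joins a TSV table (e.g. log2 fold changes per gene) onto network nodes:
#' rows whose `key_column` value equals a node's `key_attribute` value add
#' one attribute per remaining column. Column values are type-guessed
#' (numbers become numeric). Duplicate keys in the table keep the last row,
#' with a warning. Nodes and edges are never added or removed.
#'
#' @param net A [network()].
#' @param table_path Path to a TSV file with a header row.
#' @param key_column Column in the table holding the join key.
#' @param key_attribute Node attribute compared against `key_column`
#'   (default `"shared name"`).
#' @return List with elements `network` and `report` (`rows_total`,
#'   `rows_matched`, `rows_unmatched`, `nodes_untouched`).
#' @export
merge_node_table <- function(net, table_path, key_column,
                             key_attribute = "shared name") {
  tab <- read_plain_tsv(table_path)
  if (!key_column %in% names(tab)) {
    abort(sprintf("%s: key column '%s' not in header", table_path, key_column))
  }
  if (anyDuplicated(tab[[key_column]])) {
    warn(sprintf("duplicate keys in %s: last row wins", basename(table_path)))
    tab <- tab[!duplicated(tab[[key_column]], fromLast = TRUE), ]
  }
  for (nm in setdiff(names(tab), key_column)) {
    tab[[nm]] <- readr::parse_guess(tab[[nm]], guess_integer = TRUE)
  }

  attr_vals <- node_attr_values(net, key_attribute)
  match_row <- purrr::map_int(attr_vals, function(v) {
    if (is.null(v) || all(is.na(v))) return(NA_integer_)
    hit <- which(tab[[key_column]] %in% as.character(v))
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
  for (nm in setdiff(names(tab), key_column)) {
    col <- tab[[nm]][match_row]
    if (nm %in% names(net$nodes)) {
      net$nodes[[nm]] <- ifelse(is.na(match_row), net$nodes[[nm]], col)
    } else {
      net$nodes[[nm]] <- col
    }
  }
  matched_rows <- unique(match_row[!is.na(match_row)])
  report <- list(rows_total = nrow(tab),
                 rows_matched = length(matched_rows),
                 rows_unmatched = nrow(tab) - length(matched_rows),
                 nodes_untouched = sum(is.na(match_row)))
  list(network = net, report = report)
}
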