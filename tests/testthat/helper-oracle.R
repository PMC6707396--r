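# Brute-force extension oracle, deliberately independent of the engine:
# straight scans over node tables, no match index, no shared helpers beyond
# the public data layout.

oracle_node_match <- function(net, id_attribute, identifiers) {
  if (!id_attribute %in% names(net$nodes)) return(character())
  col <- net$nodes[[id_attribute]]
  bare_parts <- sub("^[^:]*:", "", identifiers)
  value_hit <- function(vals) {
    vals <- as.character(unlist(vals))
    vals <- vals[!is.na(vals) & nzchar(vals)]
    if (length(vals) == 0) return(FALSE)
    curie <- grepl(":", vals, fixed = TRUE)
    any(vals[curie] %in% identifiers) || any(vals[!curie] %in% bare_parts)
  }
  hit <- if (is.list(col)) {
    vapply(col, value_hit, TRUE)
  } else {
    curie <- grepl(":", col, fixed = TRUE) & !is.na(col)
    (curie & col %in% identifiers) |
      (!curie & !is.na(col) & col %in% bare_parts)
  }
  unique(net$nodes$key[hit])
}

oracle_extend <- function(net, linksets, id_attribute, direction) {
  if (inherits(linksets, "linkset")) linksets <- list(linksets)
  orig_triples <- paste(net$edges$source, net$edges$target,
                        net$edges$interaction, sep = "\r")
  edge_tags <- list()
  node_used <- character()
  for (ls in linksets) {
    tag <- sprintf("%s (%s)", ls$name, ls$version)
    matched <- lapply(ls$nodes$identifiers, function(ids) {
      oracle_node_match(net, id_attribute, ids)
    })
    names(matched) <- ls$nodes$node_id
    resolve <- function(id) {
      m <- matched[[id]]
      if (length(m) > 0) return(list(keys = m, added = NULL))
      k <- if (id %in% net$nodes$key) paste0("ctl:", id) else id
      list(keys = k, added = k)
    }
    for (r in seq_len(nrow(ls$edges))) {
      s <- ls$edges$source[r]
      t <- ls$edges$target[r]
      inter <- ls$edges$interaction[r]
      cands <- list()
      if (direction %in% c("TARGETS", "BOTH") &&
            length(matched[[s]]) > 0) {
        tr <- resolve(t)
        for (a in matched[[s]]) for (b in tr$keys) {
          cands[[length(cands) + 1]] <- list(a = a, b = b, added = tr$added)
        }
      }
      if (direction %in% c("SOURCES", "BOTH") &&
            length(matched[[t]]) > 0) {
        sr <- resolve(s)
        for (a in sr$keys) for (b in matched[[t]]) {
          cands[[length(cands) + 1]] <- list(a = a, b = b, added = sr$added)
        }
      }
      for (cd in cands) {
        triple <- paste(cd$a, cd$b, inter, sep = "\r")
        if (triple %in% orig_triples) next
        edge_tags[[triple]] <- unique(c(edge_tags[[triple]], tag))
        if (!is.null(cd$added)) node_used <- c(node_used, cd$added)
      }
    }
  }
  triples <- names(edge_tags)
  if (is.null(triples)) triples <- character()
  parts <- strsplit(triples, "\r", fixed = TRUE)
  ed <- tibble::tibble(
    source = vapply(parts, `[`, "", 1),
    target = vapply(parts, `[`, "", 2),
    interaction = vapply(parts, `[`, "", 3),
    overlap = vapply(edge_tags, length, 0L, USE.NAMES = FALSE)
  )
  ed <- ed[order(ed$source, ed$target, ed$interaction), ]
  list(added_node_keys = sort(unique(node_used)), added_edges = ed)
}

# extract the engine's additions in the oracle's shape
engine_added <- function(net) {
  pk <- provenance_keys()
  added <- vapply(net$nodes[[pk[["added"]]]] %||% rep(list(NULL),
                                                      nrow(net$nodes)),
                  isTRUE, TRUE)
  ov <- net$edges[[pk[["overlap"]]]]
  if (is.null(ov)) ov <- rep(NA_integer_, nrow(net$edges))
  ed <- net$edges[!is.na(ov), c("source", "target", "interaction")]
  ed$overlap <- as.integer(ov[!is.na(ov)])
  ed <- ed[order(ed$source, ed$target, ed$interaction), ]
  list(added_node_keys = sort(net$nodes$key[added]),
       added_edges = ed)
}

expect_same_additions <- function(got, want) {
  expect_identical(got$added_node_keys, want$added_node_keys)
  expect_identical(as.data.frame(got$added_edges),
                   as.data.frame(want$added_edges))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
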