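parse_tag <- function(tag) {
  m <- regmatches(tag, regexec("^(.*) \\(([^()]*)\\)$", tag))[[1]]
  if (length(m) == 3) c(name = m[2], version = m[3])
  else c(name = tag, version = NA_character_)
}

#' Summarize the extension state of a network
#'
#' Recomputes the per-linkset extension ledger purely from the `ctl.*`
#' provenance attributes on the network — the headless counterpart of the
#' result panel. Because it only reads attributes, it is idempotent and
#' independent of the [extend_network()] call that produced them: running it
#' after [filter_overlap()] reflects the filtered state.
#'
#' Per linkset it reports `nodes_added` (added nodes attributed to it),
#' `edges_added` (extension edges it asserts), and `network_nodes_matched`
#' (distinct pre-existing nodes incident to at least one of its extension
#' edges). Totals count each shared node/edge once.
#'
#' @param net A [network()], typically extended.
#' @return An `extension_report` object; `tidy()` returns the per-linkset
#'   tibble, `glance()` the totals.
#' @export
summarize_extension <- function(net) {
  pk <- provenance_keys()
  nodes <- net$nodes
  edges <- net$edges
  added <- if (pk[["added"]] %in% names(nodes)) {
    purrr::map_lgl(nodes[[pk[["added"]]]], isTRUE)
  } else rep(FALSE, nrow(nodes))
  added_keys <- nodes$key[added]

  node_tags <- if (pk[["linksets"]] %in% names(nodes)) {
    nodes[[pk[["linksets"]]]]
  } else rep(list(character()), nrow(nodes))
  edge_tags <- if (pk[["linkset"]] %in% names(edges)) {
    edges[[pk[["linkset"]]]]
  } else rep(list(character()), nrow(edges))
  is_ext <- if (pk[["overlap"]] %in% names(edges)) {
    !is.na(edges[[pk[["overlap"]]]])
  } else rep(FALSE, nrow(edges))

  tags <- sort(unique(c(unlist(node_tags), unlist(edge_tags))))
  per <- purrr::map(tags, function(tag) {
    has_node <- purrr::map_lgl(node_tags, ~ tag %in% .x)
    has_edge <- is_ext & purrr::map_lgl(edge_tags, ~ tag %in% .x)
    endpoints <- unique(c(edges$source[has_edge], edges$target[has_edge]))
    nv <- parse_tag(tag)
    tibble(linkset = unname(nv["name"]), version = unname(nv["version"]),
           network_nodes_matched = length(setdiff(endpoints, added_keys)),
           nodes_added = sum(has_node & added),
           edges_added = sum(has_edge))
  })
  per <- if (length(per) > 0) bind_rows(per) else {
    tibble(linkset = character(), version = character(),
           network_nodes_matched = integer(), nodes_added = integer(),
           edges_added = integer())
  }
  all_endpoints <- unique(c(edges$source[is_ext], edges$target[is_ext]))
  totals <- list(
    nodes_added = sum(added),
    edges_added = sum(is_ext),
    network_nodes_matched = length(setdiff(all_endpoints, added_keys))
  )
  structure(list(per_linkset = per, totals = totals,
                 overlap_threshold = net$overlap_threshold %||% NA_integer_),
            class = "extension_report")
}

# extend()'s own report: summarize the result, then list provided linksets
# that contributed nothing as explicit zero rows, in call order.
extension_report_for <- function(net, linksets) {
  rep <- summarize_extension(net)
  provided <- tibble(
    linkset = purrr::map_chr(linksets, "name"),
    version = purrr::map_chr(linksets, "version")
  ) |> distinct()
  missing <- anti_join(provided, rep$per_linkset,
                       by = c("linkset", "version"))
  if (nrow(missing) > 0) {
    missing <- mutate(missing, network_nodes_matched = 0L, nodes_added = 0L,
                      edges_added = 0L)
    rep$per_linkset <- bind_rows(rep$per_linkset, missing)
  }
  ord <- match(paste(rep$per_linkset$linkset, rep$per_linkset$version),
               paste(provided$linkset, provided$version))
  rep$per_linkset <- rep$per_linkset[order(ord), ]
  rep
}

#' @export
print.extension_report <- function(x, ...) {
  cat("Extension report\n")
  if (nrow(x$per_linkset) == 0) {
    cat("  no extension material\n")
  } else {
    df <- as.data.frame(x$per_linkset)
    names(df) <- c("linkset", "version", "matched", "nodes+", "edges+")
    print(df, row.names = FALSE)
  }
  cat(sprintf("  totals: %d nodes added, %d edges added, %d network nodes matched\n",
              x$totals$nodes_added, x$totals$edges_added,
              x$totals$network_nodes_matched))
  if (!is.na(x$overlap_threshold)) {
    cat(sprintf("  overlap filter applied: support >= %d\n",
                x$overlap_threshold))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname summarize_extension
#' @param x An `extension_report` or `ctl_extension` object.
#' @param ... Unused.
#' @method tidy extension_report
#' @export
tidy.extension_report <- function(x, ...) x$per_linkset

#' @rdname summarize_extension
#' @method glance extension_report
#' @export
glance.extension_report <- function(x, ...) {
  tibble(nodes_added = x$totals$nodes_added,
         edges_added = x$totals$edges_added,
         network_nodes_matched = x$totals$network_nodes_matched,
         n_linksets = nrow(x$per_linkset),
         overlap_threshold = x$overlap_threshold)
}

#' @rdname summarize_extension
#' @method tidy ctl_extension
#' @export
tidy.ctl_extension <- function(x, ...) tidy(x$report)

#' @rdname summarize_extension
#' @method glance ctl_extension
#' @export
glance.ctl_extension <- function(x, ...) glance(x$report)

#' Serialize an extension report
#'
#' @param x An `extension_report`.
#' @param path Output file; format by extension (`.json` structured,
#'   anything else plain text).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "ctl_extension")) x <- x$report
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(linksets = x$per_linkset, totals = x$totals,
           overlap_threshold = x$overlap_threshold),
      path, auto_unbox = TRUE, na = "null", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    sink(con); print(x); sink()
  }
  invisible(path)
}

#' Filter extension edges by cross-linkset support
#'
#' Keeps only the added interactions supported by at least `n` distinct
#' linksets. Extension edges (those carrying `ctl.overlap`) with support
#' below `n` are removed, or merely flagged `ctl.hidden = TRUE` in hide
#' mode. Under removal, added nodes (`ctl.added`) left without any incident
#' edge are removed as well. Pre-existing network content is never touched,
#' and `n = 1` is a no-op.
#'
#' @param net A [network()] or the result of [extend_network()].
#' @param n Minimum number of supporting linksets (>= 1).
#' @param mode `"remove"` (default, headless behaviour) or `"hide"`.
#' @return List with elements `network` and `counts`
#'   (`edges_affected`, `nodes_removed`).
#' @export
filter_overlap <- function(net, n, mode = c("remove", "hide")) {
  mode <- match.arg(mode)
  if (inherits(net, "ctl_extension")) net <- net$network
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    abort("overlap threshold n must be an integer >= 1")
  }
  n <- as.integer(n)
  pk <- provenance_keys()
  overlap <- if (pk[["overlap"]] %in% names(net$edges)) {
    net$edges[[pk[["overlap"]]]]
  } else rep(NA_integer_, nrow(net$edges))
  affected <- !is.na(overlap) & overlap < n

  nodes_removed <- 0L
  if (mode == "hide") {
    hidden <- rep(NA, nrow(net$edges))
    hidden[!is.na(overlap)] <- FALSE
    hidden[affected] <- TRUE
    net$edges[[pk[["hidden"]]]] <- hidden
  } else {
    net$edges <- net$edges[!affected, ]
    if (pk[["added"]] %in% names(net$nodes)) {
      deg <- node_degrees(net)
      added <- purrr::map_lgl(net$nodes[[pk[["added"]]]], isTRUE)
      drop <- added & deg$degree == 0
      nodes_removed <- sum(drop)
      net$nodes <- net$nodes[!drop, ]
    }
  }
  net$overlap_threshold <- n
  list(network = net,
       counts = list(edges_affected = sum(affected),
                     nodes_removed = nodes_removed))
}
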