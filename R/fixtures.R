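#' Describe a synthetic fixture family
#'
#' Parameters for [generate_fixtures()]: a seeded random family of one
#' network plus a set of linksets with a controlled fraction of linkset
#' edges touching the network, or — when `overlap_histogram` is given — a
#' planted cross-linkset support structure. Identifier systems are synthetic
#' (`gx` for network-matchable entities, `ux` for entities outside the
#' network) so fixtures never imply real database content.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_network_nodes Number of network nodes (max 999).
#' @param n_linksets Number of linksets to emit.
#' @param edges_per_linkset Edges per linkset (ignored in histogram mode).
#' @param match_fraction Proportion of linkset edges with at least one
#'   endpoint matching a network node.
#' @param overlap_histogram Optional named vector mapping support level to
#'   planted edge count, e.g. `c("1" = 40, "2" = 25, "3" = 10)`; levels must
#'   not exceed `n_linksets`.
#' @param node_type_vocabulary Types assigned to non-network entities.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_network_nodes = 100, n_linksets = 3,
                         edges_per_linkset = 100, match_fraction = 0.3,
                         overlap_histogram = NULL,
                         node_type_vocabulary = c("compound", "pathway",
                                                  "disease")) {
  stopifnot(n_network_nodes >= 1, n_network_nodes <= 999, n_linksets >= 1,
            match_fraction >= 0, match_fraction <= 1)
  if (!is.null(overlap_histogram)) {
    lv <- as.integer(names(overlap_histogram))
    if (any(is.na(lv)) || any(lv < 1) || max(lv) > n_linksets) {
      abort("unsatisfiable overlap histogram: support levels must be 1..n_linksets")
    }
  }
  structure(list(seed = as.integer(seed), n_network_nodes = n_network_nodes,
                 n_linksets = n_linksets,
                 edges_per_linkset = edges_per_linkset,
                 match_fraction = match_fraction,
                 overlap_histogram = overlap_histogram,
                 node_type_vocabulary = node_type_vocabulary),
            class = "fixture_spec")
}

fx_net_key <- function(id) sprintf("n%03d", as.integer(id_value(id)))
fx_gx <- function(i) sprintf("gx:%04d", i)

# deterministic type for an entity id, independent of generation order
fx_type_for <- function(id, vocab) {
  if (id_system(id) == "gx") return("gene")
  vocab[(sum(utf8ToInt(id)) %% length(vocab)) + 1]
}

#' Generate a deterministic fixture tree with constructive ground truth
#'
#' Writes `network.graphml`, one `linkset_XX.xgmml` and matching
#' `linkset_XX.tsv` source table per linkset, and `mapping.tsv` (a synthetic
#' `gx` to `hx` identifier cross-reference covering 60% of network
#' entities) under `out_dir`. The same spec always produces byte-identical
#' files.
#'
#' The returned ground truth — the extension outcome expected for each
#' direction, plus the cross-linkset overlap histogram — is computed
#' constructively from the planted edges while generating, never by running
#' the extension engine, so it can serve as an independent oracle in tests.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list: `network`, `linksets`, `planted` (tibble of
#'   planted linkset edges with match flags), `ground_truth` (per direction:
#'   `added_node_keys`, `added_edges` with `overlap`, `per_linkset` counts),
#'   `mapping_covered` (gx ids present in the mapping table), `paths`.
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed, generate_fixtures_impl(spec, out_dir))
}

generate_fixtures_impl <- function(spec, out_dir) {
  n <- spec$n_network_nodes
  net_ids <- fx_gx(seq_len(n))
  nodes <- tibble(key = fx_net_key(net_ids),
                  label = sprintf("G%d", seq_len(n)),
                  `shared name` = net_ids,
                  `display name` = sprintf("G%d", seq_len(n)))
  # sprinkle some internal wiring; interaction "pp" is reserved for it
  n_int <- max(1L, n %/% 2L)
  seen <- character()
  src <- character(); tgt <- character()
  while (length(src) < n_int) {
    a <- sample.int(n, 1); b <- sample.int(n, 1)
    if (a == b) next
    tr <- paste(a, b)
    if (tr %in% seen) next
    seen <- c(seen, tr)
    src <- c(src, fx_net_key(net_ids[a])); tgt <- c(tgt, fx_net_key(net_ids[b]))
  }
  net <- network(nodes = nodes,
                 edges = tibble(source = src, target = tgt,
                                interaction = "pp"),
                 name = sprintf("fixture-net-seed%d", spec$seed))

  planted <- if (is.null(spec$overlap_histogram)) {
    plant_random_edges(spec, n)
  } else {
    plant_histogram_edges(spec, n)
  }

  linksets <- purrr::map(seq_len(spec$n_linksets), function(j) {
    ed <- filter(planted, linkset == j)
    ids <- unique(c(ed$source, ed$target))
    linkset(
      name = sprintf("LS%02d", j), version = sprintf("%d.0", j),
      date = "2020-01-01",
      nodes = tibble(node_id = ids,
                     label = toupper(id_value(ids)),
                     node_type = purrr::map_chr(ids, fx_type_for,
                                                vocab = spec$node_type_vocabulary)),
      edges = select(ed, source, target, interaction) |>
        mutate(datasource = sprintf("LS%02d", j))
    )
  })

  paths <- list(network = file.path(out_dir, "network.graphml"),
                linksets = file.path(out_dir,
                                     sprintf("linkset_%02d.xgmml",
                                             seq_len(spec$n_linksets))),
                tsv = file.path(out_dir,
                                sprintf("linkset_%02d.tsv",
                                        seq_len(spec$n_linksets))),
                mapping = file.path(out_dir, "mapping.tsv"))
  write_network(net, paths$network)
  purrr::walk2(linksets, paths$linksets, write_linkset)
  purrr::walk2(linksets, paths$tsv, write_linkset_tsv)

  covered <- sort(sample(net_ids, size = floor(0.6 * n)))
  readr::write_tsv(tibble(from = covered,
                          to = paste0("hx:", id_value(covered))),
                   paths$mapping, progress = FALSE)

  gt <- compute_ground_truth(planted, linksets)
  invisible(list(network = net, linksets = linksets, planted = planted,
                 ground_truth = gt, mapping_covered = covered,
                 paths = paths))
}

write_linkset_tsv <- function(ls, path) {
  idx <- setNames(seq_len(nrow(ls$nodes)), ls$nodes$node_id)
  tab <- tibble(
    source_id = ls$edges$source,
    source_label = ls$nodes$label[idx[ls$edges$source]],
    source_type = ls$nodes$node_type[idx[ls$edges$source]],
    target_id = ls$edges$target,
    target_label = ls$nodes$label[idx[ls$edges$target]],
    target_type = ls$nodes$node_type[idx[ls$edges$target]],
    interaction = ls$edges$interaction
  )
  readr::write_tsv(tab, path, progress = FALSE)
}

fx_interactions <- c("targets", "partOf", "association")

plant_random_edges <- function(spec, n) {
  rows <- list()
  for (j in seq_len(spec$n_linksets)) {
    seen <- character()
    ux_counter <- 0L
    fresh_ux <- function() {
      ux_counter <<- ux_counter + 1L
      sprintf("ux:l%02de%03d", j, ux_counter)
    }
    k <- 0L
    while (k < spec$edges_per_linkset) {
      matched <- stats::runif(1) < spec$match_fraction
      side <- if (matched) {
        sample(c("s", "t", "both"), 1, prob = c(0.45, 0.45, 0.1))
      } else "none"
      s <- if (side %in% c("s", "both")) fx_gx(sample.int(n, 1)) else fresh_ux()
      t <- if (side %in% c("t", "both")) fx_gx(sample.int(n, 1)) else fresh_ux()
      inter <- sample(fx_interactions, 1)
      tr <- paste(s, t, inter)
      if (s == t || tr %in% seen) next
      seen <- c(seen, tr)
      k <- k + 1L
      rows[[length(rows) + 1]] <- tibble(
        linkset = j, source = s, target = t, interaction = inter,
        s_matched = side %in% c("s", "both"),
        t_matched = side %in% c("t", "both"))
    }
  }
  bind_rows(rows)
}

plant_histogram_edges <- function(spec, n) {
  rows <- list()
  idx <- 0L
  for (lvl in as.integer(names(spec$overlap_histogram))) {
    cnt <- spec$overlap_histogram[[as.character(lvl)]]
    for (i in seq_len(cnt)) {
      idx <- idx + 1L
      s <- fx_gx(sample.int(n, 1))
      t <- sprintf("ux:h%04d", idx)
      members <- sort(sample.int(spec$n_linksets, lvl))
      for (j in members) {
        rows[[length(rows) + 1]] <- tibble(
          linkset = j, source = s, target = t, interaction = "targets",
          s_matched = TRUE, t_matched = FALSE)
      }
    }
  }
  bind_rows(rows)
}

# Constructive expectation: set arithmetic over the planted edges and their
# match flags. The extension engine is deliberately never called here.
compute_ground_truth <- function(planted, linksets) {
  tags <- purrr::map_chr(linksets, linkset_tag)
  per_direction <- purrr::map(c(SOURCES = "SOURCES", TARGETS = "TARGETS",
                                BOTH = "BOTH"), function(dir) {
    edge_support <- list()
    node_tags <- list()
    for (r in seq_len(nrow(planted))) {
      row <- planted[r, ]
      tag <- tags[[row$linkset]]
      use_t <- dir %in% c("TARGETS", "BOTH") && row$s_matched
      use_s <- dir %in% c("SOURCES", "BOTH") && row$t_matched
      if (use_t || use_s) {
        sk <- if (row$s_matched) fx_net_key(row$source) else row$source
        tk <- if (row$t_matched) fx_net_key(row$target) else row$target
        tr <- paste(sk, tk, row$interaction, sep = "\r")
        edge_support[[tr]] <- unique(c(edge_support[[tr]], tag))
        if (!row$s_matched && use_s) {
          node_tags[[row$source]] <- unique(c(node_tags[[row$source]], tag))
        }
        if (!row$t_matched && use_t) {
          node_tags[[row$target]] <- unique(c(node_tags[[row$target]], tag))
        }
      }
    }
    triples <- names(edge_support) %||% character()
    parts <- strsplit(triples, "\r", fixed = TRUE)
    added_edges <- tibble(
      source = purrr::map_chr(parts, 1, .default = NA),
      target = purrr::map_chr(parts, 2, .default = NA),
      interaction = purrr::map_chr(parts, 3, .default = NA),
      overlap = purrr::map_int(edge_support, length) |> unname()
    ) |> arrange(source, target, interaction)
    per_linkset <- purrr::map(tags, function(tag) {
      has_edge <- purrr::map_lgl(edge_support, ~ tag %in% .x)
      eps <- unique(unlist(purrr::map(parts[has_edge], ~ .x[1:2])))
      original <- eps[grepl("^n[0-9]{3}$", eps)]
      tibble(tag = tag,
             nodes_added = sum(purrr::map_lgl(node_tags, ~ tag %in% .x)),
             edges_added = sum(has_edge),
             network_nodes_matched = length(original))
    }) |> bind_rows()
    list(added_node_keys = sort(names(node_tags) %||% character()),
         added_edges = added_edges,
         per_linkset = per_linkset)
  })
  hist_both <- table(per_direction$BOTH$added_edges$overlap)
  list(directions = per_direction,
       overlap_histogram = setNames(as.integer(hist_both), names(hist_both)))
}
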