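#' Miniature end-to-end scenario fixtures
#'
#' Writes three small, fully deterministic scenario trees under `out_dir`,
#' one per canonical workflow shape:
#'
#' * `scenario1/`: a small protein-protein interaction network
#'   (`ppi.graphml`) plus two linksets of different entity types —
#'   `compounds.xgmml` (compound `targets` gene) and `diseases.xgmml`
#'   (gene `associatedWith` disease) — extended together with the default
#'   `BOTH` direction on `"display name"`.
#' * `scenario2/`: a node-only gene list (`genes.tsv`), a `log2fc.tsv`
#'   attribute table for [merge_node_table()], and `pathways.xgmml`
#'   (pathway `containsGene` gene) used with `direction = "SOURCES"` so gene
#'   nodes acquire their upstream pathway annotations.
#' * `scenario3/`: five seed author nodes (`authors.tsv`) and two chained
#'   linksets — `publications.xgmml` (author `authorOf` article) and
#'   `journals.xgmml` (article `publishedIn` journal) — exercised as a
#'   two-step extension: articles appear after the first call, journals only
#'   after a second call on the already-extended network.
#'
#' @param out_dir Output directory.
#' @return Invisible named list of scenario directories.
#' @export
usecase_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d1 <- file.path(out_dir, "scenario1")
  d2 <- file.path(out_dir, "scenario2")
  d3 <- file.path(out_dir, "scenario3")
  purrr::walk(c(d1, d2, d3), dir.create, showWarnings = FALSE)

  # -- scenario 1: PPI + compound / disease linksets -------------------------
  genes <- sprintf("GENE-%s", LETTERS[1:6])
  ppi <- network(
    nodes = tibble(key = sprintf("p%d", 1:6), label = genes,
                   `display name` = genes, `shared name` = genes),
    edges = tibble(source = sprintf("p%d", c(1, 1, 2, 3, 4)),
                   target = sprintf("p%d", c(2, 3, 4, 5, 6)),
                   interaction = "pp"),
    name = "ppi")
  write_network(ppi, file.path(d1, "ppi.graphml"))

  gene_nodes <- tibble(node_id = paste0("sym:", genes), label = genes,
                       node_type = "gene")
  compounds <- linkset(
    "compounds", "1.0", date = "2020-01-01",
    nodes = bind_rows(gene_nodes[1:4, ],
                      tibble(node_id = sprintf("cx:%04d", 1:3),
                             label = sprintf("CPD-%d", 1:3),
                             node_type = "compound")),
    edges = tibble(source = sprintf("cx:%04d", c(1, 1, 2, 3)),
                   target = paste0("sym:", genes[c(1, 2, 2, 4)]),
                   interaction = "targets", datasource = "compounds"))
  write_linkset(compounds, file.path(d1, "compounds.xgmml"))

  diseases <- linkset(
    "diseases", "1.0", date = "2020-01-01",
    nodes = bind_rows(gene_nodes[c(1, 3, 5), ],
                      tibble(node_id = sprintf("dx:%04d", 1:2),
                             label = sprintf("DIS-%d", 1:2),
                             node_type = "disease")),
    edges = tibble(source = paste0("sym:", genes[c(1, 3, 5)]),
                   target = sprintf("dx:%04d", c(1, 1, 2)),
                   interaction = "associatedWith", datasource = "diseases"))
  write_linkset(diseases, file.path(d1, "diseases.xgmml"))

  # -- scenario 2: gene list + log2fc table + pathway linkset ----------------
  deg <- sprintf("MG%02d", 1:5)
  readr::write_tsv(tibble(source = deg, interaction = "", target = ""),
                   file.path(d2, "genes.tsv"), progress = FALSE)
  readr::write_tsv(tibble(gene = deg[c(1, 2, 4)],
                          log2fc = c(1.8, -2.1, 1.2)),
                   file.path(d2, "log2fc.tsv"), progress = FALSE)
  pathways <- linkset(
    "pathways", "1.0", date = "2020-01-01",
    nodes = bind_rows(tibble(node_id = paste0("sym:", deg[c(1, 2, 4)]),
                             label = deg[c(1, 2, 4)], node_type = "gene"),
                      tibble(node_id = sprintf("px:%04d", 1:2),
                             label = sprintf("PW-%d", 1:2),
                             node_type = "pathway")),
    edges = tibble(source = sprintf("px:%04d", c(1, 1, 2)),
                   target = paste0("sym:", deg[c(1, 2, 4)]),
                   interaction = "containsGene", datasource = "pathways"))
  write_linkset(pathways, file.path(d2, "pathways.xgmml"))

  # -- scenario 3: authors -> articles -> journals, two-step -----------------
  authors <- sprintf("AUTHOR-%d", 1:5)
  readr::write_tsv(tibble(source = authors, interaction = "", target = ""),
                   file.path(d3, "authors.tsv"), progress = FALSE)
  art <- sprintf("ax:%04d", 1:6)
  author_nodes <- tibble(node_id = paste0("person:", authors),
                         label = authors, node_type = "author")
  article_nodes <- tibble(node_id = art, label = sprintf("ARTICLE-%d", 1:6),
                          node_type = "article")
  publications <- linkset(
    "publications", "1.0", date = "2020-01-01",
    nodes = bind_rows(author_nodes, article_nodes),
    edges = tibble(
      source = paste0("person:", authors[c(1, 1, 2, 2, 3, 4, 5, 5)]),
      target = art[c(1, 2, 2, 3, 4, 5, 5, 6)],
      interaction = "authorOf", datasource = "publications"))
  write_linkset(publications, file.path(d3, "publications.xgmml"))

  journals <- linkset(
    "journals", "1.0", date = "2020-01-01",
    nodes = bind_rows(article_nodes,
                      tibble(node_id = sprintf("jx:%04d", 1:3),
                             label = sprintf("JOURNAL-%d", 1:3),
                             node_type = "journal")),
    edges = tibble(source = art,
                   target = sprintf("jx:%04d", c(1, 1, 2, 2, 3, 3)),
                   interaction = "publishedIn", datasource = "journals"))
  write_linkset(journals, file.path(d3, "journals.xgmml"))

  invisible(list(scenario1 = d1, scenario2 = d2, scenario3 = d3))
}
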