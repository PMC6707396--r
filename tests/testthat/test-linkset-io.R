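demo_linkset <- function() {
  linkset(
    "demo", "2.1", date = "2020-06-01", url = "https://example.org/demo",
    nodes = tibble::tibble(
      node_id = c("ncbigene:4204", "ensembl:ENSG1", "cx:7"),
      label = c("MECP2", "GENE1", "CPD7"),
      node_type = c("gene", "gene", "compound"),
      identifiers = list(c("ncbigene:4204", "ensembl:ENSG00000169057"),
                         character(), character())
    ),
    edges = tibble::tibble(source = c("cx:7", "cx:7"),
                           target = c("ncbigene:4204", "ensembl:ENSG1"),
                           interaction = "targets", datasource = "demo-db")
  )
}

linkset_equal <- function(a, b) {
  a <- canonicalize_linkset(a); b <- canonicalize_linkset(b)
  expect_identical(a[c("name", "version", "date", "url")],
                   b[c("name", "version", "date", "url")])
  expect_identical(as.data.frame(a$nodes[c("node_id", "label", "node_type")]),
                   as.data.frame(b$nodes[c("node_id", "label", "node_type")]))
  expect_identical(a$nodes$identifiers, b$nodes$identifiers)
  expect_identical(
    as.data.frame(a$edges[c("source", "target", "interaction", "datasource")]),
    as.data.frame(b$edges[c("source", "target", "interaction", "datasource")]))
}

test_that("linkset XGMML round-trips losslessly and byte-deterministically", {
  ls <- demo_linkset()
  p1 <- withr::local_tempfile(fileext = ".xgmml")
  p2 <- withr::local_tempfile(fileext = ".xgmml")
  write_linkset(ls, p1)
  back <- read_linkset(p1)
  linkset_equal(ls, back)
  expect_identical(nrow(validate_linkset(back)), 0L)
  write_linkset(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  # fixed rendering rule for multi-identifier nodes: sorted, no spaces
  txt <- paste(readLines(p1), collapse = "\n")
  expect_match(txt, "[ensembl:ENSG00000169057,ncbigene:4204]", fixed = TRUE)
})

test_that("an empty-edge linkset writes a valid file with zero edges", {
  ls <- linkset("lonely", "1.0", date = "2020-01-01",
                nodes = tibble::tibble(node_id = "gx:1", node_type = "gene"))
  p <- withr::local_tempfile(fileext = ".xgmml")
  write_linkset(ls, p)
  back <- read_linkset(p)
  expect_identical(nrow(back$edges), 0L)
  expect_identical(back$nodes$node_id, "gx:1")
})

test_that("a node without an identifiers att falls back to its id", {
  p <- withr::local_tempfile(fileext = ".xgmml")
  writeLines(c(
    '<graph label="min" directed="1">',
    '<att name="name" type="string" value="min"/>',
    '<node id="gx:9" label="G9"><att name="type" type="string" value="gene"/></node>',
    '</graph>'), p)
  ls <- read_linkset(p)
  expect_identical(ls$nodes$identifiers[[1]], "gx:9")
})

test_that("unknown atts survive a round-trip in the extras field", {
  p <- withr::local_tempfile(fileext = ".xgmml")
  writeLines(c(
    '<graph label="x" directed="1">',
    '<att name="name" type="string" value="x"/>',
    '<node id="gx:1" label="G1">',
    '<att name="type" type="string" value="gene"/>',
    '<att name="organism" type="string" value="Mus musculus"/>',
    '</node>',
    '</graph>'), p)
  ls <- read_linkset(p)
  expect_identical(unname(ls$nodes$extras[[1]]["organism"]), "Mus musculus")
  p2 <- withr::local_tempfile(fileext = ".xgmml")
  write_linkset(ls, p2)
  expect_match(paste(readLines(p2), collapse = ""), 'value="Mus musculus"')
})

test_that("malformed files fail loudly", {
  bad <- withr::local_tempfile(fileext = ".xgmml")
  writeLines("<graph><unclosed>", bad)
  expect_error(read_linkset(bad), "parse error")

  noname <- withr::local_tempfile(fileext = ".xgmml")
  writeLines('<graph label="g"><node id="gx:1"/></graph>', noname)
  expect_error(read_linkset(noname), "missing graph-level 'name'")

  dangling <- withr::local_tempfile(fileext = ".xgmml")
  writeLines(c('<graph label="g"><att name="name" type="string" value="g"/>',
               '<node id="gx:1"/>',
               '<edge source="gx:1" target="x:1">',
               '<att name="interaction" type="string" value="t"/></edge>',
               '</graph>'), dangling)
  expect_error(read_linkset(dangling), "x:1")

  expect_error(write_linkset(structure(list(name = ""), class = "linkset"),
                             tempfile()), "invalid")
})

test_that("a large generated linkset matches an independent XML edge count", {
  fx <- make_fixture(7, n_network_nodes = 100, n_linksets = 1,
                     edges_per_linkset = 1000, match_fraction = 0.4)
  path <- fx$paths$linksets[1]
  ls <- read_linkset(path)
  expect_identical(nrow(ls$edges), 1000L)
  # oracle: raw text scan, no XML machinery
  raw <- paste(readLines(path), collapse = "\n")
  expect_identical(lengths(regmatches(raw, gregexpr("<edge ", raw,
                                                    fixed = TRUE))), 1000L)
})

test_that("TSV builder deduplicates nodes and edges and reports drops", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_id\ttarget_id", "gx:1\tpx:1", "gx:2\tpx:1"), p)
  res <- build_linkset_from_tsv(
    p, linkset_tsv_config(source_id = "source_id", target_id = "target_id",
                          source_type = "gene", target_type = "pathway",
                          name = "t", version = "1"))
  expect_identical(nrow(res$linkset$nodes), 3L)
  expect_identical(nrow(res$linkset$edges), 2L)
  expect_identical(res$report$rows_dropped, 0L)

  writeLines(c("source_id\ttarget_id", "gx:1\tpx:1", "gx:1\tpx:1"), p)
  res <- build_linkset_from_tsv(
    p, linkset_tsv_config(source_id = "source_id", target_id = "target_id",
                          name = "t"))
  expect_identical(res$report$rows_dropped, 1L)
  expect_identical(res$report$drop_reasons$reason, "duplicate edge")

  expect_error(build_linkset_from_tsv(
    p, linkset_tsv_config(source_id = "nope", target_id = "target_id",
                          name = "t")), "nope")
})

test_that("planted duplicates in a 500-row table are dropped exactly", {
  rows <- withr::with_seed(11, {
    base <- tibble::tibble(
      source_id = sprintf("gx:%03d", sample.int(300, 450, replace = TRUE)),
      target_id = sprintf("px:%03d", sample.int(80, 450, replace = TRUE)),
      interaction = sample(c("targets", "partOf"), 450, replace = TRUE))
    base <- base[!duplicated(paste(base$source_id, base$target_id,
                                   base$interaction)), ]
    while (nrow(base) < 450) {
      extra <- tibble::tibble(
        source_id = sprintf("gx:%03d", sample.int(300, 1)),
        target_id = sprintf("px:%03d", sample.int(80, 1)),
        interaction = sample(c("targets", "partOf"), 1))
      base <- rbind(base, extra)
      base <- base[!duplicated(paste(base$source_id, base$target_id,
                                     base$interaction)), ]
    }
    dup <- base[sample.int(450, 50, replace = TRUE), ]
    rows <- rbind(base, dup)
    rows[sample.int(nrow(rows)), ]
  })
  p <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(rows, p, progress = FALSE)
  res <- build_linkset_from_tsv(
    p, linkset_tsv_config(source_id = "source_id", target_id = "target_id",
                          interaction = "interaction", source_type = "gene",
                          target_type = "pathway", name = "big"))
  # oracle: independent distinct-triple count over the raw table
  expect_identical(nrow(res$linkset$edges),
                   nrow(unique(rows)))
  expect_identical(nrow(res$linkset$edges), 450L)
  expect_identical(res$report$rows_dropped, 50L)
  expect_identical(res$report$rows_total, 500L)
})

test_that("the builder is invariant to row order", {
  fx <- make_fixture(13, n_network_nodes = 40, n_linksets = 1,
                     edges_per_linkset = 60, match_fraction = 0.5)
  cfg <- linkset_tsv_config(source_id = "source_id", target_id = "target_id",
                            source_label = "source_label",
                            target_label = "target_label",
                            source_type = "source_type",
                            target_type = "target_type",
                            interaction = "interaction", name = "LS01",
                            version = "1.0", date = "2020-01-01")
  a <- build_linkset_from_tsv(fx$paths$tsv[1], cfg)$linkset
  tab <- readr::read_tsv(fx$paths$tsv[1], show_col_types = FALSE)
  shuffled <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab[rev(seq_len(nrow(tab))), ], shuffled, progress = FALSE)
  b <- build_linkset_from_tsv(shuffled, cfg)$linkset
  linkset_equal(a, b)
})

test_that("bare ids gain the configured system prefix; unprefixable rows drop", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g\tp", "MECP2\tWP1", "\tWP2"), p)
  res <- build_linkset_from_tsv(
    p, linkset_tsv_config(source_id = "g", target_id = "p",
                          source_system = "hgnc", target_system = "wikipathways",
                          name = "m"))
  expect_identical(res$linkset$edges$source, "hgnc:MECP2")
  expect_identical(res$report$rows_dropped, 1L)
  expect_identical(res$report$drop_reasons$reason, "missing id")
})

test_that("identifier mapping adds cross-references and honours policy", {
  ls <- tiny_linkset("m", tibble::tibble(source = "hgnc:MECP2",
                                         target = "px:1",
                                         interaction = "partOf"))
  tab <- tibble::tibble(from = "hgnc:MECP2", to = "ncbigene:4204")
  res <- map_linkset_identifiers(ls, tab, "ncbigene")
  i <- which(res$linkset$nodes$node_id == "hgnc:MECP2")
  expect_true("ncbigene:4204" %in% res$linkset$nodes$identifiers[[i]])
  expect_identical(res$report$nodes_mapped, 1L)

  # empty table + drop-unmapped empties the linkset
  res <- map_linkset_identifiers(ls, tibble::tibble(from = character(),
                                                    to = character()),
                                 "ncbigene", policy = "drop-unmapped")
  expect_identical(nrow(res$linkset$nodes), 0L)
  expect_identical(res$report$nodes_unmapped, 2L)

  # identity mapping with keep-unmapped is a no-op
  ids <- ls$nodes$node_id
  res <- map_linkset_identifiers(ls, tibble::tibble(from = ids, to = ids),
                                 id_system(ids[1]))
  linkset_equal(res$linkset, ls)
})

test_that("drop-unmapped retains exactly the covered node set", {
  fx <- make_fixture(3, n_network_nodes = 150, n_linksets = 1,
                     edges_per_linkset = 200, match_fraction = 1)
  ls <- fx$linksets[[1]]
  tab <- read_mapping_table(fx$paths$mapping)
  res <- map_linkset_identifiers(ls, tab, "hx", policy = "drop-unmapped")
  # oracle: independent set intersection between linkset nodes and coverage
  covered <- sort(intersect(ls$nodes$node_id, fx$mapping_covered))
  expect_identical(sort(res$linkset$nodes$node_id), covered)
  expect_true(all(res$linkset$edges$source %in% covered))
  expect_true(all(res$linkset$edges$target %in% covered))
  expect_identical(res$report$nodes_mapped, length(covered))
})
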