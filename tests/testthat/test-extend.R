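pk <- provenance_keys()

one_node_net <- function() {
  network(nodes = tibble::tibble(key = "g1", attr = "g1",
                                 `shared name` = "g1"))
}

two_edge_linkset <- function() {
  tiny_linkset("L", tibble::tibble(
    source = c("px:p1", "px:p2"),
    target = c("sym:g1", "sym:g2"),
    interaction = "partOf"),
    types = c(`px:p1` = "pathway", `px:p2` = "pathway",
              `sym:g1` = "gene", `sym:g2` = "gene"))
}

test_that("the match index separates canonical and bare values", {
  net <- network(nodes = tibble::tibble(
    key = c("a", "b", "c"),
    ids = c("MECP2", "ncbigene:4204", "MECP2")))
  idx <- build_match_index(net, "ids")
  # bare value indexes bare; both carriers are found
  expect_setequal(linksetr:::match_keys(idx, "sym:MECP2"), c("a", "c"))
  # CURIE-valued attribute matches canonically only, never via value part
  expect_identical(linksetr:::match_keys(idx, "ncbigene:4204"), "b")
  expect_length(linksetr:::match_keys(idx, "other:4204"), 0)
  expect_error(build_match_index(net, ""), "non-empty")
})

test_that("direction controls which side of a linkset edge must match", {
  net <- one_node_net()
  ls <- two_edge_linkset()
  src <- extend_network(net, ls, id_attribute = "attr",
                        direction = "SOURCES")
  g <- glance(src)
  expect_identical(c(g$nodes_added, g$edges_added), c(1L, 1L))
  expect_identical(src$network$edges$source, "px:p1")
  expect_identical(src$network$edges$target, "g1")

  tgt <- extend_network(net, ls, id_attribute = "attr",
                        direction = "TARGETS")
  g <- glance(tgt)
  expect_identical(c(g$nodes_added, g$edges_added), c(0L, 0L))
})

test_that("the same edge asserted by two linksets is stored once with overlap 2", {
  net <- network(nodes = tibble::tibble(key = "a", attr = "a"))
  l1 <- tiny_linkset("L1", tibble::tibble(source = "xx:x", target = "sym:a",
                                          interaction = "t"))
  l2 <- tiny_linkset("L2", tibble::tibble(source = "xx:x", target = "sym:a",
                                          interaction = "t"))
  ext <- extend_network(net, list(l1, l2), id_attribute = "attr",
                        direction = "SOURCES")
  expect_identical(nrow(ext$network$edges), 1L)
  expect_identical(ext$network$edges[[pk[["overlap"]]]], 1L + 1L)
  expect_setequal(ext$network$edges[[pk[["linkset"]]]][[1]],
                  c("L1 (1.0)", "L2 (1.0)"))
  # the shared added node is attributed to both linksets but counted once
  expect_identical(glance(ext)$nodes_added, 1L)
  added <- ext$network$nodes[2, ]
  expect_setequal(added[[pk[["linksets"]]]][[1]], c("L1 (1.0)", "L2 (1.0)"))
})

test_that("an endpoint matching an existing node reuses it; existing edges are untouched", {
  net <- network(
    nodes = tibble::tibble(key = c("a", "b"), attr = c("a", "b")),
    edges = tibble::tibble(source = "a", target = "b", interaction = "t"))
  ls <- tiny_linkset("L", tibble::tibble(
    source = c("sym:a", "sym:a"), target = c("sym:b", "ux:new"),
    interaction = "t"))
  ext <- extend_network(net, ls, id_attribute = "attr")
  # a->b already exists: skipped entirely; a->ux:new is a true addition
  expect_identical(nrow(ext$network$edges), 2L)
  expect_identical(glance(ext)$edges_added, 1L)
  expect_true(is.na(ext$network$edges[[pk[["overlap"]]]][1]))
  expect_identical(ext$network$edges$target[2], "ux:new")
  expect_identical(glance(ext)$nodes_added, 1L)
})

test_that("added-node keys avoid collisions with existing network keys", {
  net <- network(nodes = tibble::tibble(key = c("g1", "ux:x"),
                                        attr = c("g1", "other")))
  ls <- tiny_linkset("L", tibble::tibble(source = "ux:x", target = "sym:g1",
                                         interaction = "t"))
  ext <- extend_network(net, ls, id_attribute = "attr",
                        direction = "SOURCES")
  expect_identical(ext$network$nodes$key[3], "ctl:ux:x")
  expect_identical(ext$network$edges$source, "ctl:ux:x")
})

test_that("missing id attribute warns and yields an all-zero report", {
  net <- network(nodes = tibble::tibble(key = "a"))
  ls <- tiny_linkset("L", tibble::tibble(source = "x:1", target = "y:1",
                                         interaction = "t"))
  expect_warning(ext <- extend_network(net, ls, id_attribute = "absent"),
                 "no network node")
  expect_identical(glance(ext)$edges_added, 0L)
  expect_error(extend_network(net, list(), id_attribute = "a"),
               "at least one linkset")
})

test_that("extension equals ground truth and brute-force oracle across fixtures", {
  for (seed in c(42, 77, 101)) {
    fx <- make_fixture(seed, n_network_nodes = 60, n_linksets = 3,
                       edges_per_linkset = 80, match_fraction = 0.4)
    for (dir in c("SOURCES", "TARGETS", "BOTH")) {
      ext <- extend_network(fx$network, fx$linksets,
                            id_attribute = "shared name", direction = dir)
      got <- engine_added(ext$network)
      expect_same_additions(got, gt_additions(fx, dir))
      expect_same_additions(
        got, oracle_extend(fx$network, fx$linksets, "shared name", dir))
    }
  }
})

test_that("extension is idempotent and never mutates the original subgraph", {
  fx <- make_fixture(55, n_network_nodes = 50, n_linksets = 2,
                     edges_per_linkset = 60, match_fraction = 0.5)
  ext <- extend_network(fx$network, fx$linksets, id_attribute = "shared name")
  again <- extend_network(ext$network, fx$linksets,
                          id_attribute = "shared name")
  expect_identical(glance(again)$nodes_added, glance(ext)$nodes_added)
  expect_identical(nrow(again$network$nodes), nrow(ext$network$nodes))
  expect_identical(nrow(again$network$edges), nrow(ext$network$edges))

  stripped <- strip_extension(ext$network)
  expect_identical(as.data.frame(stripped$nodes),
                   as.data.frame(fx$network$nodes))
  expect_identical(as.data.frame(stripped$edges),
                   as.data.frame(fx$network$edges))
})

test_that("BOTH decomposes into the union of SOURCES and TARGETS", {
  for (seed in c(8, 19)) {
    fx <- make_fixture(seed, n_network_nodes = 40, n_linksets = 2,
                       edges_per_linkset = 50, match_fraction = 0.5)
    parts <- purrr::map(c("SOURCES", "TARGETS", "BOTH"), function(dir) {
      e <- extend_network(fx$network, fx$linksets,
                          id_attribute = "shared name", direction = dir)
      engine_added(e$network)
    })
    names(parts) <- c("SOURCES", "TARGETS", "BOTH")
    union_edges <- unique(rbind(parts$SOURCES$added_edges[1:3],
                                parts$TARGETS$added_edges[1:3]))
    union_edges <- union_edges[order(union_edges$source, union_edges$target,
                                     union_edges$interaction), ]
    expect_identical(as.data.frame(parts$BOTH$added_edges[1:3]),
                     as.data.frame(union_edges))
    expect_identical(parts$BOTH$added_node_keys,
                     sort(union(parts$SOURCES$added_node_keys,
                                parts$TARGETS$added_node_keys)))
  }
})

test_that("single-call extension matches sequential calls when tiers are independent", {
  fx <- make_fixture(31, n_network_nodes = 40, n_linksets = 2,
                     edges_per_linkset = 40, match_fraction = 0.5)
  once <- extend_network(fx$network, fx$linksets,
                         id_attribute = "shared name")
  step1 <- extend_network(fx$network, fx$linksets[[1]],
                          id_attribute = "shared name")
  step2 <- extend_network(step1$network, fx$linksets[[2]],
                          id_attribute = "shared name")
  a <- engine_added(once$network)
  b <- engine_added(step2$network)
  expect_identical(a$added_node_keys, b$added_node_keys)
  expect_identical(as.data.frame(a$added_edges[1:3]),
                   as.data.frame(b$added_edges[1:3]))
})

test_that("chained linksets require a two-step extension", {
  dir <- withr::local_tempdir()
  usecase_fixtures(dir)
  seeds <- read_network(file.path(dir, "scenario3", "authors.tsv"))
  pub <- read_linkset(file.path(dir, "scenario3", "publications.xgmml"))
  jou <- read_linkset(file.path(dir, "scenario3", "journals.xgmml"))

  step1 <- extend_network(seeds, pub, id_attribute = "shared name")
  types1 <- unique(stats::na.omit(step1$network$nodes[[pk[["type"]]]]))
  expect_identical(types1, "article")      # tier 2 only

  step2 <- extend_network(step1$network, jou, id_attribute = "shared name")
  types2 <- sort(unique(stats::na.omit(step2$network$nodes[[pk[["type"]]]])))
  expect_identical(types2, c("article", "journal"))
  # articles connect authors to journals
  art_keys <- step2$network$nodes$key[
    step2$network$nodes[[pk[["type"]]]] %in% "article"]
  expect_true(all(step2$network$edges$target[
    step2$network$edges$interaction == "authorOf"] %in% art_keys))
  expect_true(all(step2$network$edges$source[
    step2$network$edges$interaction == "publishedIn"] %in% art_keys))

  # a single call with both linksets must not reach tier 3
  once <- extend_network(seeds, list(pub, jou), id_attribute = "shared name")
  expect_false("journal" %in% once$network$nodes[[pk[["type"]]]])
})

test_that("summarize recomputes the extension report from attributes alone", {
  net <- network(nodes = tibble::tibble(key = "a"))
  rep0 <- summarize_extension(net)
  expect_identical(nrow(tidy(rep0)), 0L)
  expect_identical(glance(rep0)$edges_added, 0L)

  fx <- make_fixture(61, n_network_nodes = 40, n_linksets = 3,
                     edges_per_linkset = 50, match_fraction = 0.5)
  ext <- extend_network(fx$network, fx$linksets, id_attribute = "shared name")
  expect_identical(tidy(summarize_extension(ext$network)), tidy(ext))
})

test_that("filter_overlap removes weakly supported extensions and orphans only", {
  fx <- make_fixture(9, n_network_nodes = 50, n_linksets = 3,
                     overlap_histogram = c("1" = 40, "2" = 25, "3" = 10))
  ext <- extend_network(fx$network, fx$linksets, id_attribute = "shared name")

  res1 <- filter_overlap(ext, 1)
  expect_identical(res1$counts$edges_affected, 0L)

  res2 <- filter_overlap(ext, 2)
  expect_identical(res2$counts$edges_affected, 40L)
  left <- res2$network$edges[[pk[["overlap"]]]]
  expect_identical(sum(!is.na(left)), 35L)
  expect_true(all(left[!is.na(left)] >= 2))

  res3 <- filter_overlap(ext, 3)
  expect_identical(sum(!is.na(res3$network$edges[[pk[["overlap"]]]])), 10L)

  # hide mode keeps edges but flags them
  hid <- filter_overlap(ext, 2, mode = "hide")
  expect_identical(nrow(hid$network$edges), nrow(ext$network$edges))
  expect_identical(sum(purrr::map_lgl(hid$network$edges[[pk[["hidden"]]]],
                                      isTRUE)), 40L)

  # summarize reflects the filtered state
  after <- summarize_extension(res3$network)
  expect_identical(glance(after)$edges_added, 10L)
  expect_error(filter_overlap(ext, 0), ">= 1")
})
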