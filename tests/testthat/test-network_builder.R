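fake_table <- function(rows) {
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(focal = r[[1]], gene = r[[2]], stratum = "all",
               R = as.numeric(r[[3]]), support = as.integer(r[[4]]),
               stringsAsFactors = FALSE)))
  class(tab) <- c("coexpression_table", "data.frame")
  tab
}

test_that("top_k_partners ranks by signed R with lexicographic tie-break", {
  tab <- fake_table(list(
    list("f1", "g9", 0.9, 5), list("f1", "g7", 0.5, 5),
    list("f1", "g2", 0.5, 5), list("f1", "g1", 0.1, 5),
    list("f1", "f1", 1.0, 5)))                 # self-pair excluded
  top <- top_k_partners(tab, "f1", k = 3)
  expect_identical(top$gene, c("g9", "g2", "g7"))  # tie g2 < g7
  expect_identical(top$rank, 1:3)
  # under-full: all candidates returned
  expect_equal(nrow(top_k_partners(tab, "f1", k = 20)), 4L)
  # absolute-value ranking puts a strong negative first
  tab2 <- fake_table(list(list("f1", "gN", -0.95, 5),
                          list("f1", "gP", 0.5, 5)))
  expect_identical(top_k_partners(tab2, "f1", 1,
                                  rank_by_abs = TRUE)$gene, "gN")
  expect_identical(top_k_partners(tab2, "f1", 1)$gene, "gP")
  expect_warning(top_k_partners(tab, "zz", 3), "no candidates")
})

test_that("build_gene_network respects the edge bound and dedups focal pairs", {
  tab <- fake_table(list(
    list("f1", "f2", 0.9, 5), list("f1", "g3", 0.8, 5),
    list("f2", "f1", 0.9, 5), list("f2", "g4", 0.7, 5)))
  net <- build_gene_network(tab, c("f1", "f2"), k = 2)
  # f1-f2 mutual top-k collapses to one undirected edge
  expect_equal(nrow(net$edges), 3L)
  expect_equal(sum(net$edges$from == "f1" & net$edges$to == "f2"), 1L)
  expect_true(all(net$nodes$is_focal[net$nodes$id %in% c("f1", "f2")]))
  # single focal gene -> star graph
  star <- build_gene_network(tab, "f1", k = 2)
  expect_equal(nrow(star$edges), 2L)
  expect_true(all(star$edges$from == "f1" | star$edges$to == "f1"))
})

test_that("gene network edges stay within focal x k and carry table weights", {
  coll <- toy_collection(seed = 13, n_datasets = 4, n_genes = 15)
  focal <- c("g0001", "g0002", "g0003")
  tab <- average_coexpression(coll, focal, "all")
  k <- 4
  net <- build_gene_network(tab, focal, k = k)
  expect_lte(nrow(net$edges), length(focal) * k + choose(length(focal), 2))
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    hit <- tab[(tab$focal == e$from & tab$gene == e$to) |
                 (tab$focal == e$to & tab$gene == e$from), ]
    expect_true(any(abs(hit$R - e$weight) < 1e-14))
  }
  expect_false(any(net$edges$from == net$edges$to))  # no self-edges
})

fake_scores <- function(rows) {
  s <- do.call(rbind, lapply(rows, function(r)
    data.frame(focal = r[[1]], pathway_id = r[[2]], tissue = r[[3]],
               score = r[[4]], pathway_size = 3L, n_members_used = 3L,
               n_datasets_used = as.integer(r[[5]]), null_exceed = 0L,
               B = 100L, empirical_p = 1 / 101,
               significant = isTRUE(r[[6]]), stringsAsFactors = FALSE)))
  class(s) <- c("pathway_scores", "data.frame")
  s
}

test_that("build_pathway_network applies significance, top and support rules", {
  s <- fake_scores(list(
    list("f1", "P1", "root", 0.9, 6, TRUE),
    list("f1", "P2", "leaf", 0.8, 4, TRUE),   # support 4 -> dropped
    list("f1", "P3", "root", 0.95, 6, FALSE), # not significant
    list("f1", "P4", "leaf", 0.5, 6, TRUE),
    list("f2", "P1", "leaf", 0.7, 7, TRUE)))
  net <- build_pathway_network(s, top = 10, min_support = 5)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("f1 P1", "f1 P4", "f2 P1"))
  expect_true(all(net$edges$significant))
  expect_true(all(net$edges$support >= 5))
  expect_identical(net$edges$tissue[net$edges$to == "P4"], "leaf")
  # top limit applies before the support filter, per focal gene
  net1 <- build_pathway_network(s, top = 1, min_support = 1)
  expect_identical(net1$edges$to[net1$edges$from == "f1"], "P1")
  # under-full: fewer significant scores than top
  expect_equal(nrow(build_pathway_network(s, top = 10,
                                          min_support = 1)$edges), 4L)
  # support filter is idempotent: reapplying changes nothing
  again <- build_pathway_network(s, top = 10, min_support = 5)
  expect_identical(again, net)
})

test_that("exports round-trip through GraphML and emit valid SIF/TSV", {
  s <- fake_scores(list(list("f1", "P1", "root", 0.9, 6, TRUE)))
  pnet <- build_pathway_network(s, 10, 5)
  coll <- toy_collection(seed = 99, n_datasets = 3, n_genes = 10)
  tab <- average_coexpression(coll, c("g0001", "g0002"), "all")
  gnet <- build_gene_network(tab, c("g0001", "g0002"), k = 3)

  for (net in list(pnet, gnet)) {
    f <- withr::local_tempfile(fileext = ".graphml")
    export_network(net, f, "graphml")
    back <- import_network(f)
    expect_equal(back$nodes, net$nodes)
    expect_equal(back$edges, net$edges, tolerance = 1e-12)
  }

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(pnet, sif, "sif")
  lines <- readLines(sif)
  expect_match(lines[grepl("\t", lines)][1], "pathway-coexpr")
  # 2-node 1-edge network -> exactly one SIF line
  two <- coex_network(
    data.frame(id = c("a", "b"), node_type = "gene",
               is_focal = c(TRUE, FALSE)),
    data.frame(from = "a", to = "b", edge_type = "gene-gene",
               weight = 0.5, tissue = "all", support = 3L,
               significant = NA, empirical_p = NA_real_))
  export_network(two, sif, "sif")
  expect_length(readLines(sif), 1L)

  # empty network -> valid zero-edge exports
  empty <- build_pathway_network(fake_scores(list(
    list("f1", "P1", "root", 0.9, 1, TRUE))), 10, 5)
  expect_equal(nrow(empty$edges), 0L)
  export_network(empty, sif, "sif")
  expect_identical(readLines(sif), "f1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, tsv, "tsv")
  expect_equal(nrow(utils::read.delim(tsv)), 0L)

  # byte-identical determinism of exports on identical inputs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  export_network(gnet, f1, "graphml")
  export_network(build_gene_network(tab, c("g0001", "g0002"), k = 3),
                 f2, "graphml")
  expect_identical(readLines(f1), readLines(f2))
  expect_error(export_network(gnet, f1, "dot"), "arg")
})

test_that("an all-mixed collection yields an empty pathway network, not an error", {
  # no unanimous-tissue datasets -> zero score rows -> focal-only nodes
  coll <- toy_collection(seed = 55, n_datasets = 3, n_genes = 12,
                         tissues = "mixed")
  de <- de_scan(coll)
  db <- random_pathway_db(coll$gene_universe, n_pathways = 3, seed = 1,
                          size_range = c(3L, 5L))
  scores <- score_pathways(c("g0001", "g0002"), db, coll, de, B = 10,
                           seed = 2)
  expect_equal(nrow(scores), 0L)
  net <- build_pathway_network(scores, top = 10, min_support = 5)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(net$nodes), 0L)
})

test_that("coex_network validates its structure", {
  nodes <- data.frame(id = c("a", "b"), node_type = "gene",
                      is_focal = FALSE)
  edge <- data.frame(from = "a", to = "a", edge_type = "gene-gene",
                     weight = 1, tissue = "all", support = 1L,
                     significant = NA, empirical_p = NA_real_)
  expect_error(coex_network(nodes, edge), "self-edge")
  edge$to <- "c"
  expect_error(coex_network(nodes, edge), "endpoint")
})
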