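# Heterogeneous graph container, TSV round trips, hierarchy extraction.

nodes3 <- data.frame(node_id = c("a", "b", "c"),
                     node_type = c("H", "H", "V"),
                     label = c(NA, NA, "0"))
edges2 <- data.frame(source = c("a", "c"), target = c("b", "a"),
                     edge_type = c("HH", "VH"),
                     hierarchical = c(TRUE, FALSE))

test_that("graph construction validates ids, endpoints and duplicates", {
  g <- hetero_graph(nodes3, edges2)
  expect_s3_class(g, "hetero_graph")
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_error(hetero_graph(rbind(nodes3, nodes3[1, ]), edges2), "duplicate")
  bad <- edges2; bad$target[1] <- "x9"
  expect_error(hetero_graph(nodes3, bad), "x9")
  expect_warning(g2 <- hetero_graph(nodes3, rbind(edges2, edges2[1, ])),
                 "duplicate")
  expect_equal(nrow(g2$edges), 2L)
  # undirected duplicates are recognized in either orientation
  flip <- edges2[2, ]; flip[, c("source", "target")] <- flip[, c("target", "source")]
  expect_warning(g3 <- hetero_graph(nodes3, rbind(edges2, flip)), "duplicate")
  expect_equal(nrow(g3$edges), 2L)
})

test_that("graph TSV round trip is the identity after dedup", {
  g <- tiny_graph()
  np <- tempfile(fileext = ".tsv"); ep <- tempfile(fileext = ".tsv")
  write_graph(g, np, ep)
  g2 <- read_graph(np, ep)
  expect_equal(g2$nodes$node_id, g$nodes$node_id)
  expect_equal(g2$edges[, c("source", "target", "edge_type", "hierarchical")],
               g$edges[, c("source", "target", "edge_type", "hierarchical")])
  expect_error(read_graph(tempfile(), ep), "not found")
})

test_that("hierarchy extraction finds roots, depths, parents, poly count", {
  # two disjoint chains a -> b -> c and x -> y
  n <- data.frame(node_id = c("a", "b", "c", "x", "y"), node_type = "H",
                  label = NA)
  e <- data.frame(source = c("a", "b", "x"), target = c("b", "c", "y"),
                  edge_type = "HH", hierarchical = TRUE)
  h <- extract_hierarchy(hetero_graph(n, e))
  expect_setequal(h$roots, c("a", "x"))
  expect_identical(h$depth[["c"]], 2L)
  expect_identical(h$n_poly, 0L)
  # diamond: d has two parents
  n2 <- data.frame(node_id = letters[1:4], node_type = "H", label = NA)
  e2 <- data.frame(source = c("a", "a", "b", "c"),
                   target = c("b", "c", "d", "d"),
                   edge_type = "HH", hierarchical = TRUE)
  h2 <- extract_hierarchy(hetero_graph(n2, e2))
  expect_identical(h2$parents[["d"]], c("b", "c"))
  expect_identical(h2$n_poly, 1L)
  expect_identical(h2$depth[["d"]], 2L)
  # cycle is rejected with the offending cycle named
  e3 <- data.frame(source = c("a", "b"), target = c("b", "a"),
                   edge_type = "HH", hierarchical = TRUE)
  expect_error(hetero_graph(n2, e3), "cycle")
})

test_that("embedding TSV round trip is lossless and validates norms", {
  set.seed(3)
  emb <- matrix(runif(30, -0.5, 0.5), 10, 3)
  rownames(emb) <- sprintf("n%02d", 1:10)
  p <- tempfile(fileext = ".tsv")
  write_embeddings(emb, p)
  emb2 <- read_embeddings(p)
  expect_identical(emb2, `colnames<-`(emb, NULL))
  # an out-of-ball row is refused, naming the node
  bad <- emb; bad[4, ] <- c(1.2, 0, 0)
  p2 <- tempfile(fileext = ".tsv")
  write_embeddings(bad, p2)
  expect_error(read_embeddings(p2), "n04")
  # empty table still round-trips through the header
  p3 <- tempfile(fileext = ".tsv")
  write_embeddings(emb[0, , drop = FALSE], p3)
  expect_equal(nrow(read_embeddings(p3)), 0L)
})
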