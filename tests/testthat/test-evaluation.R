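# Structure report, reconstruction MAP, and the frozen-embedding softmax
# classifier.

test_that("structure report scores a hand-placed embedding exactly", {
  n <- data.frame(node_id = c("r", "a", "b", "v"),
                  node_type = c("H", "H", "H", "V"), label = NA)
  e <- data.frame(source = c("r", "a", "v"), target = c("a", "b", "a"),
                  edge_type = c("HH", "HH", "VH"),
                  hierarchical = c(TRUE, TRUE, FALSE))
  g <- hetero_graph(n, e)
  # all constraints satisfied: a ladder on one ray
  emb <- rbind(r = c(0.2, 0), a = c(0.45, 0), b = c(0.7, 0), v = c(0.6, 0.0))
  rep1 <- structure_report(emb, g, delta = 0.5, K = 0.1)
  expect_equal(rep1$root_containment_rate, 1)
  expect_equal(rep1$parent_child_ordering_rate, 1)
  expect_equal(rep1$cone_containment_rate, 1)
  expect_equal(rep1$nonhier_cone_rate, 1)
  expect_equal(rep1$n_eligible_cones, 3L)
  # all points coincident: strict ordering fails everywhere
  emb2 <- emb; emb2[] <- rep(c(0.24, 0), each = 4)
  rep2 <- structure_report(emb2, g, delta = 0.5, K = 0.1)
  expect_equal(rep2$parent_child_ordering_rate, 0)
  expect_equal(rep2$root_containment_rate, 1)  # 2 atanh(0.24) < 0.5
  # a gated (near-origin) parent drops out of the cone denominator
  emb3 <- emb; emb3["a", ] <- c(0.01, 0)
  rep3 <- structure_report(emb3, g, delta = 0.5, K = 0.1)
  expect_equal(rep3$n_eligible_cones, 1L)   # only r -> a stays eligible
})

test_that("reconstruction MAP matches a brute-force oracle on small graphs", {
  set.seed(13)
  for (i in 1:5) {
    g <- make_forest(forest_spec(n_trees = 2, branching = 2, depth = 1,
                                 n_nonhier = 4, attach_min = 1,
                                 attach_max = 2, vv_prob = 0.4, seed = i))
    emb <- project_to_ball(matrix(runif(nrow(g$nodes) * 3, -0.5, 0.5),
                                  nrow(g$nodes)))
    rownames(emb) <- g$nodes$node_id
    expect_equal(reconstruction_map(emb, g), map_brute(emb, g),
                 tolerance = 1e-12)
  }
})

test_that("MAP is 1 when neighbors occupy the top ranks, and rotation invariant", {
  # 2-node single-edge graph: the only candidate is the neighbor
  n <- data.frame(node_id = c("a", "b"), node_type = "V", label = NA)
  e <- data.frame(source = "a", target = "b", edge_type = "VV",
                  hierarchical = FALSE)
  g2 <- hetero_graph(n, e)
  emb2 <- rbind(a = c(0.1, 0), b = c(0.2, 0))
  expect_equal(reconstruction_map(emb2, g2), 1)
  # rotation invariance of the full report on a real fit
  g <- tiny_graph()
  fit <- coneforest(g, train_config(epochs = 15, final_sweeps = 5,
                                    cone_warmup_epochs = 5, seed = 2))
  R <- random_rotation(ncol(fit$embedding))
  emb_rot <- fit$embedding %*% R
  rownames(emb_rot) <- rownames(fit$embedding)
  r1 <- structure_report(fit$embedding, g, delta = 0.5, K = 0.1)
  r2 <- structure_report(emb_rot, g, delta = 0.5, K = 0.1)
  for (f in c("root_containment_rate", "parent_child_ordering_rate",
              "cone_containment_rate", "nonhier_cone_rate",
              "reconstruction_map")) {
    expect_equal(r2[[f]], r1[[f]], tolerance = 1e-9)
  }
})

test_that("classifier separates separable embeddings and handles ties", {
  set.seed(5)
  n <- 60
  emb <- rbind(matrix(rnorm(n / 2 * 4, mean = 0.15, sd = 0.02), n / 2),
               matrix(rnorm(n / 2 * 4, mean = -0.15, sd = 0.02), n / 2))
  emb <- project_to_ball(emb)
  rownames(emb) <- sprintf("x%02d", 1:n)
  labels <- setNames(rep(c(1L, 0L), each = n / 2), rownames(emb))
  expect_equal(classifier_eval(emb, labels, seed = 1), 1.0)
  # identical embeddings for every node: tied scores give AUC 1/2
  emb0 <- matrix(0.1, n, 4, dimnames = list(rownames(emb), NULL))
  expect_equal(classifier_eval(emb0, labels, seed = 1), 0.5)
  # relabeling classes leaves the (binary, symmetric) AUC unchanged
  flip <- setNames(1L - labels, names(labels))
  expect_equal(classifier_eval(emb, flip, seed = 1),
               classifier_eval(emb, labels, seed = 1))
  expect_error(classifier_eval(emb, labels[1:3] * 0, seed = 1), "single class")
})

test_that("labels independent of the embedding score near chance", {
  set.seed(7)
  n <- 200
  emb <- project_to_ball(matrix(rnorm(n * 5, sd = 0.1), n))
  rownames(emb) <- sprintf("y%03d", 1:n)
  labels <- setNames(sample(0:1, n, replace = TRUE), rownames(emb))
  auc <- classifier_eval(emb, labels, seed = 3)
  # permutation band: AUC of a useless classifier on a 60-case test split
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
})
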