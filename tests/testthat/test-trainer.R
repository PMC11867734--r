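# Configuration, losses, penalties, gradients, and the training loop.

test_that("variant switches zero the right penalty weights", {
  w <- function(cfg) c(cfg$lambda_root, cfg$lambda_child, cfg$lambda_cone,
                       cfg$lambda_nonhier)
  expect_equal(w(train_config(variant = "poincare")), c(0, 0, 0, 0))
  expect_equal(w(train_config(variant = "R")), c(1, 0, 0, 0))
  expect_equal(w(train_config(variant = "Ch")), c(0, 1, 0, 0))
  expect_equal(w(train_config(variant = "C")), c(1, 1, 1, 0))
  expect_equal(w(train_config(variant = "full")), c(1, 1, 1, 1))
  expect_error(train_config(variant = "bogus"))
  expect_error(train_config(delta = -1))
})

test_that("config files round-trip and unknown keys are rejected", {
  p <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", "dim = 5", "delta = 0.4", "variant = Ch",
               "seed = 42"), p)
  cfg <- read_train_config(p)
  expect_equal(cfg$dim, 5L)
  expect_equal(cfg$delta, 0.4)
  expect_equal(cfg$variant, "Ch")
  expect_equal(cfg$lambda_root, 0)
  p2 <- tempfile(fileext = ".cfg")
  writeLines("lamda_root = 2", p2)
  expect_error(read_train_config(p2), "lamda_root")
})

test_that("initialization is deterministic, bounded and seed-sensitive", {
  g <- tiny_graph()
  cfg <- train_config(dim = 10, init_scale = 1e-3, seed = 3)
  e1 <- init_embeddings(g, cfg)
  e2 <- init_embeddings(g, cfg)
  expect_identical(e1, e2)
  expect_true(all(sqrt(rowSums(e1^2)) <= 1e-3 * sqrt(10)))
  expect_false(identical(e1, init_embeddings(g, train_config(dim = 10, seed = 4))))
  e0 <- init_embeddings(g, train_config(init_scale = 0))
  expect_true(all(e0 == 0))
})

test_that("base loss reduces to closed forms in symmetric cases", {
  emb <- rbind(u = c(0.2, 0), v = c(-0.2, 0), n1 = c(0, 0.2), n2 = c(0, -0.2))
  # one negative at the same distance as the positive -> log 2
  expect_equal(base_loss(emb, c("u", "n1"), "n2"),
               log(2), tolerance = 1e-12)
  # five equidistant candidates -> log 6 (uniform softmax)
  emb2 <- rbind(u = c(0, 0),
                t(sapply(0:5, function(k) 0.3 * c(cos(k), sin(k)))))
  rownames(emb2) <- c("u", paste0("c", 0:5))
  expect_equal(base_loss(emb2, c("u", "c0"), paste0("c", 1:5)), log(6),
               tolerance = 1e-12)
  expect_error(base_loss(emb, c("u", "v"), c("v")), "negatives")
  expect_error(base_loss(emb, c("u", "zz"), "n1"), "zz")
})

test_that("hinge penalties obey their algebra", {
  emb <- rbind(r1 = c(0.1, 0), r2 = c(0.8, 0), p = c(0.3, 0), c1 = c(0.7, 0))
  # root within delta contributes 0; violating root contributes its excess
  expect_equal(root_penalty(emb, "r1", delta = 0.5), 0)
  excess <- origin_distance(c(0.8, 0)) - 0.5
  expect_equal(root_penalty(emb, c("r1", "r2"), delta = 0.5), excess)
  expect_equal(root_penalty(emb, c("r2", "r2"), delta = 0.5), 2 * excess)
  # ordering: satisfied chain is 0; coincident pair pays the margin
  n <- data.frame(node_id = c("p", "c1"), node_type = "H", label = NA)
  e <- data.frame(source = "p", target = "c1", edge_type = "HH",
                  hierarchical = TRUE)
  h <- extract_hierarchy(hetero_graph(n, e))
  expect_equal(child_penalty(emb, h, margin = 0), 0)
  emb_eq <- emb; emb_eq["c1", ] <- emb_eq["p", ]
  expect_equal(child_penalty(emb_eq, h, margin = 0.1), 0.1)
  # cone penalty: child on the outward ray contributes 0; gated apex 0
  expect_equal(cone_penalty_hier(emb, h, K = 0.1), 0)
  emb_g <- emb; emb_g["p", ] <- c(0.01, 0)
  expect_equal(cone_penalty_hier(emb_g, h, K = 0.1), 0)
  # apex at 0.5 with child at angle pi/2
  emb_v <- emb; emb_v["p", ] <- c(0.5, 0); emb_v["c1", ] <- c(0.5, 0.3)
  expect_equal(cone_penalty_hier(emb_v, h, K = 0.1), pi / 2 - asin(0.15),
               tolerance = 1e-12)
})

test_that("non-hierarchical cone penalty sums over V-H links only", {
  n <- data.frame(node_id = c("h1", "h2", "v1", "v2"),
                  node_type = c("H", "H", "V", "V"), label = NA)
  e <- data.frame(source = c("h1", "v1", "v1", "v1"),
                  target = c("h2", "h1", "h2", "v2"),
                  edge_type = c("HH", "VH", "VH", "VV"),
                  hierarchical = c(TRUE, FALSE, FALSE, FALSE))
  g <- hetero_graph(n, e)
  emb <- rbind(h1 = c(0.5, 0), h2 = c(0.7, 0), v1 = c(0.75, 0),
               v2 = c(0, 0.6))
  # v1 on both apexes' outward rays: zero; V-V link contributes nothing
  expect_equal(cone_penalty_nonhier(emb, g, K = 0.1), 0)
  # move v1 off-axis; expected value from planar trigonometry per link
  v <- c(0.5, 0.3)
  emb2 <- emb; emb2["v1", ] <- v
  ang2 <- acos((sum(v^2) - 0.49 - sum((v - c(0.7, 0))^2)) /
               (2 * 0.7 * sqrt(sum((v - c(0.7, 0))^2))))
  expected <- (pi / 2 - asin(0.15)) +
    max(0, ang2 - asin(0.1 * (1 - 0.49) / 0.7))
  expect_equal(cone_penalty_nonhier(emb2, g, K = 0.1), expected,
               tolerance = 1e-12)
})

test_that("total loss composes terms linearly and honors variants", {
  g <- tiny_graph()
  hier <- extract_hierarchy(g)
  cfg_full <- train_config(variant = "full", seed = 2)
  cfg_poin <- train_config(variant = "poincare", seed = 2)
  set.seed(8)
  emb <- project_to_ball(matrix(runif(nrow(g$nodes) * 10, -0.3, 0.3),
                                nrow(g$nodes)))
  rownames(emb) <- g$nodes$node_id
  negs <- edge_negatives(g, 5, seed = 3)
  lp <- total_loss(emb, g, hier, cfg_poin, negs)
  lf <- total_loss(emb, g, hier, cfg_full, negs)
  terms <- attr(lf, "terms")
  expect_equal(as.numeric(lp), unname(terms["base"]))
  expect_equal(as.numeric(lf), unname(sum(terms)))
  # doubling all weights doubles exactly the penalty part
  cfg2 <- train_config(variant = NULL, lambda_root = 2, lambda_child = 2,
                       lambda_cone = 2, lambda_nonhier = 2, seed = 2)
  l2 <- total_loss(emb, g, hier, cfg2, negs)
  expect_equal(as.numeric(l2 - lp), 2 * as.numeric(lf - lp), tolerance = 1e-9)
  # the poincare objective is invariant to delta, K, margin
  cfg_p2 <- train_config(variant = "poincare", delta = 2, K = 5, margin = 0.7,
                         seed = 2)
  expect_equal(as.numeric(total_loss(emb, g, hier, cfg_p2, negs)),
               as.numeric(lp))
})

test_that("negative sampling avoids neighbors and is deterministic", {
  g <- tiny_graph()
  u <- g$nodes$node_id[1]
  touches <- g$edges$source == u | g$edges$target == u
  nbrs <- unique(c(g$edges$source[touches], g$edges$target[touches]))
  s1 <- sample_negatives(g, u, 5, rng_state = 9)
  s2 <- sample_negatives(g, u, 5, rng_state = 9)
  expect_identical(s1, s2)
  expect_false(any(s1 %in% c(u, nbrs)))
  # complete graph forces the replacement branch
  n <- data.frame(node_id = c("a", "b", "c"), node_type = "V", label = NA)
  e <- data.frame(source = c("a", "a", "b"), target = c("b", "c", "c"),
                  edge_type = "VV", hierarchical = FALSE)
  gk <- hetero_graph(n, e)
  expect_error(sample_negatives(gk, "a", 3), "candidates")
  # star center: negatives only from the single non-neighbor, with
  # replacement once the pool is exhausted
  n2 <- data.frame(node_id = c("s", "l1", "l2", "l3", "far"),
                   node_type = "V", label = NA)
  e2 <- data.frame(source = "s", target = c("l1", "l2", "l3"),
                   edge_type = "VV", hierarchical = FALSE)
  g2 <- hetero_graph(n2, e2)
  expect_identical(sample_negatives(g2, "s", 1, rng_state = 1), "far")
  expect_message(reps <- sample_negatives(g2, "s", 3, rng_state = 1),
                 "replacement")
  expect_identical(reps, rep("far", 3))
})

test_that("analytic gradients match central differences", {
  g <- tiny_graph()
  hier <- extract_hierarchy(g)
  cfg <- train_config(dim = 3, variant = "full", seed = 1)
  set.seed(42)
  for (rep in 1:5) {
    X <- project_to_ball(matrix(runif(nrow(g$nodes) * 3, -0.25, 0.25),
                                nrow(g$nodes)))
    rownames(X) <- g$nodes$node_id
    negs <- edge_negatives(g, 5, seed = rep)
    tg <- total_loss_grad(X, g, hier, cfg, negs)
    # step small enough that the stencil cannot straddle a hinge or
    # aperture-gating boundary (the objective is piecewise smooth)
    h <- 1e-7
    num <- matrix(0, nrow(X), ncol(X))
    for (i in seq_len(nrow(X))) for (j in 1:3) {
      Xp <- X; Xp[i, j] <- Xp[i, j] + h
      Xm <- X; Xm[i, j] <- Xm[i, j] - h
      num[i, j] <- (total_loss_grad(Xp, g, hier, cfg, negs,
                                    want_grad = FALSE)$loss -
                    total_loss_grad(Xm, g, hier, cfg, negs,
                                    want_grad = FALSE)$loss) / (2 * h)
    }
    rel <- sqrt(sum((num - tg$grad)^2)) / max(1, sqrt(sum(num^2)))
    expect_lt(rel, 1e-5)
  }
})

test_that("training is deterministic, respects the ball, returns init at 0 epochs", {
  g <- tiny_graph()
  cfg0 <- train_config(epochs = 0, seed = 6)
  fit0 <- coneforest(g, cfg0)
  expect_identical(fit0$embedding, init_embeddings(g, cfg0))
  cfg <- train_config(epochs = 25, final_sweeps = 10, cone_warmup_epochs = 5,
                      seed = 6)
  f1 <- coneforest(g, cfg)
  f2 <- coneforest(g, cfg)
  expect_identical(f1$embedding, f2$embedding)
  expect_identical(f1$log, f2$log)
  expect_true(all(f1$log$max_norm <= 1 - cfg$eps_ball + 1e-12))
  expect_true(all(sqrt(rowSums(f1$embedding^2)) <= 1 - cfg$eps_ball + 1e-12))
  # a different seed changes the result
  expect_false(identical(
    f1$embedding, coneforest(g, train_config(epochs = 25, final_sweeps = 10,
                                             cone_warmup_epochs = 5,
                                             seed = 7))$embedding))
})

test_that("the poincare variant ignores delta, K and margin end to end", {
  g <- tiny_graph()
  f1 <- coneforest(g, train_config(epochs = 15, variant = "poincare",
                                   seed = 3, final_sweeps = 5))
  f2 <- coneforest(g, train_config(epochs = 15, variant = "poincare",
                                   delta = 2, K = 7, margin = 0.5, seed = 3,
                                   final_sweeps = 5))
  expect_identical(f1$embedding, f2$embedding)
})

test_that("regularized training beats the plain variant on its own constraints", {
  # stochastic parameter-effect property over three seeds (standard forest)
  roots <- sapply(1:3, function(s) std_report("full", s)$root_containment_rate)
  expect_true(all(roots == 1))
  ord_full <- mean(sapply(1:3, function(s) std_report("full", s)$parent_child_ordering_rate))
  ord_poin <- mean(sapply(1:3, function(s) std_report("poincare", s)$parent_child_ordering_rate))
  expect_gt(ord_full, ord_poin)
  cone_full <- mean(sapply(1:3, function(s) std_report("full", s)$cone_containment_rate))
  cone_ch <- mean(sapply(1:3, function(s) std_report("Ch", s)$cone_containment_rate))
  expect_gt(cone_full, cone_ch)
})

test_that("fitted object methods expose the embedding coherently", {
  fit <- std_fit("full", 7)
  expect_s3_class(fit, "coneforest")
  expect_identical(coef(fit), fit$embedding)
  expect_output(print(fit), "variant 'full'")
  nn <- predict(fit, nodes = "v0001", k = 3)
  expect_equal(nrow(nn), 3L)
  expect_true(all(diff(nn$distance) >= 0))
  expect_error(predict(fit, nodes = "nope"), "unknown")
})
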