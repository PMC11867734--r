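# Evaluation of a trained embedding table: constraint-satisfaction rates
# for each structural condition, distance-ranking reconstruction (mean
# average precision of true neighbors), and a frozen-embedding softmax
# classifier on planted labels.

#' Constraint-satisfaction report of an embedding
#'
#' Measures how well an embedding satisfies each structural condition of
#' the model, as frequencies:
#'
#' * `root_containment_rate`: fraction of roots with
#'   `origin_distance(root) < delta`.
#' * `parent_child_ordering_rate`: fraction of hierarchical edges with the
#'   parent strictly closer to the origin than the child (ties count as
#'   violations).
#' * `cone_containment_rate`: over hierarchical edges whose parent has a
#'   defined aperture (norm at least [cone_r_min()]), the fraction of
#'   children inside the parent's cone.
#' * `nonhier_cone_rate`: same over links from non-hierarchy nodes to
#'   cone-eligible hierarchy nodes.
#' * `reconstruction_map`: see [reconstruction_map()].
#' * `n_eligible_cones`: number of cone-eligible constrained pairs (both
#'   families).
#'
#' Rates with empty denominators are `NA`.
#'
#' @param emb embedding matrix with node-id row names (or a fitted
#'   `coneforest` object, whose embedding and graph are used).
#' @param g a [hetero_graph()] covered by `emb`.
#' @param hier the graph's [extract_hierarchy()] view (recomputed if
#'   missing).
#' @param delta root radius bound.
#' @param K cone aperture scale.
#' @return Object of class `structure_report` (named list of the fields
#'   above).
#' @export
structure_report <- function(emb, g, hier = NULL, delta = 0.5, K = 0.1) {
  if (inherits(emb, "coneforest")) {
    fit <- emb
    emb <- fit$embedding
    if (missing(g)) g <- fit$graph
    if (is.null(hier)) hier <- fit$hierarchy
    if (missing(delta)) delta <- fit$config$delta
    if (missing(K)) K <- fit$config$K
  }
  stopifnot(inherits(g, "hetero_graph"))
  if (is.null(hier)) hier <- extract_hierarchy(g)
  miss <- setdiff(g$nodes$node_id, rownames(emb))
  if (length(miss)) stop(sprintf("embedding does not cover node(s): %s",
                                 paste(utils::head(miss, 5), collapse = ", ")),
                         call. = FALSE)
  pr <- training_indices(g, hier, rownames(emb))

  root_rate <- if (length(pr$root_idx)) {
    mean(origin_distance(emb[pr$root_idx, , drop = FALSE]) < delta)
  } else NA_real_

  order_rate <- if (nrow(pr$hier_pc)) {
    mean(origin_distance(emb[pr$hier_pc[, 1], , drop = FALSE]) <
         origin_distance(emb[pr$hier_pc[, 2], , drop = FALSE]))
  } else NA_real_

  # a member exactly coincident with its apex has no defined apex angle;
  # such degenerate pairs count as violations rather than erroring
  safe_angles <- function(A, B) {
    out <- rep(pi, nrow(A))
    ok <- rowSums((A - B)^2) > 0 & rowSums(A^2) > 0
    if (any(ok)) out[ok] <- angle_at_apex(A[ok, , drop = FALSE],
                                          B[ok, , drop = FALSE])
    out
  }
  eligible <- 0L
  cone_rate <- NA_real_
  if (nrow(pr$hier_pc)) {
    psi <- cone_aperture(emb[pr$hier_pc[, 1], , drop = FALSE], K)
    ok <- !is.na(psi)
    eligible <- eligible + sum(ok)
    if (any(ok)) {
      ang <- safe_angles(emb[pr$hier_pc[ok, 1], , drop = FALSE],
                         emb[pr$hier_pc[ok, 2], , drop = FALSE])
      cone_rate <- mean(ang <= psi[ok])
    }
  }

  nonhier_rate <- NA_real_
  if (length(pr$vh_h)) {
    psi <- cone_aperture(emb[pr$vh_h, , drop = FALSE], K)
    ok <- !is.na(psi)
    eligible <- eligible + sum(ok)
    if (any(ok)) {
      ang <- safe_angles(emb[pr$vh_h[ok], , drop = FALSE],
                         emb[pr$vh_v[ok], , drop = FALSE])
      nonhier_rate <- mean(ang <= psi[ok])
    }
  }

  structure(list(root_containment_rate = root_rate,
                 parent_child_ordering_rate = order_rate,
                 cone_containment_rate = cone_rate,
                 nonhier_cone_rate = nonhier_rate,
                 reconstruction_map = reconstruction_map(emb, g),
                 n_eligible_cones = eligible),
            class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report>\n")
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("  root containment rate        %s\n", fmt(x$root_containment_rate)))
  cat(sprintf("  parent-child ordering rate   %s\n", fmt(x$parent_child_ordering_rate)))
  cat(sprintf("  cone containment rate        %s\n", fmt(x$cone_containment_rate)))
  cat(sprintf("  non-hierarchical cone rate   %s\n", fmt(x$nonhier_cone_rate)))
  cat(sprintf("  reconstruction MAP           %s\n", fmt(x$reconstruction_map)))
  cat(sprintf("  eligible cone pairs          %d\n", x$n_eligible_cones))
  invisible(x)
}

#' Distance-ranking reconstruction (mean average precision)
#'
#' For each node, all other nodes are ranked by hyperbolic distance
#' ascending (ties broken by node id), and the average precision of the
#' node's true neighbor set (all nodes linked to it by any edge type) is
#' computed; the mean over nodes with at least one neighbor is returned.
#' Equals 1 exactly when every node's neighbors occupy the top ranks.
#'
#' @param emb embedding matrix with node-id row names.
#' @param g a [hetero_graph()] with at least one edge.
#' @return Scalar in `[0, 1]`.
#' @export
reconstruction_map <- function(emb, g) {
  stopifnot(inherits(g, "hetero_graph"), nrow(g$edges) >= 1L)
  ids <- rownames(emb)
  idx <- stats::setNames(seq_along(ids), ids)
  n <- length(ids)
  nbr <- vector("list", n)
  a <- idx[g$edges$source]; b <- idx[g$edges$target]
  und <- split(c(b, a), c(a, b))
  nbr[as.integer(names(und))] <- lapply(und, unique)
  # full pairwise hyperbolic distance matrix
  sq <- rowSums(emb^2)
  gram <- emb %*% t(emb)
  d2 <- outer(sq, sq, "+") - 2 * gram
  d2[d2 < 0] <- 0
  a1 <- 1 - sq
  gam <- 1 + 2 * d2 / outer(a1, a1)
  diag(gam) <- 1
  D <- acosh(pmax(gam, 1))
  tie_rank <- rank(ids)                  # lexicographic tie-break key
  ap <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tn <- nbr[[i]]
    if (!length(tn)) next
    others <- setdiff(seq_len(n), i)
    o <- others[order(D[i, others], tie_rank[others])]
    hits <- o %in% tn
    ranks <- which(hits)
    ap[i] <- mean(seq_along(ranks) / ranks)
  }
  mean(ap, na.rm = TRUE)
}

#' Frozen-embedding softmax classifier evaluation
#'
#' Trains a single softmax (multinomial logistic) layer on the fixed
#' embedding coordinates of the labeled nodes, on a random train split, and
#' reports AUC on the held-out split: plain binary AUC for two classes,
#' one-vs-rest averaged AUC for more. The embedding is never fine-tuned
#' (the representation model is unsupervised). Deterministic given `seed`.
#'
#' @param emb embedding matrix with node-id row names (or a `coneforest`
#'   fit).
#' @param labels named vector (names = node ids) of class labels.
#' @param test_fraction held-out fraction, default `0.3` (a 70/30 split).
#' @param seed integer seed controlling the split.
#' @return AUC in `[0, 1]`.
#' @export
classifier_eval <- function(emb, labels, test_fraction = 0.3, seed = 1L) {
  if (inherits(emb, "coneforest")) emb <- emb$embedding
  stopifnot(!is.null(names(labels)), test_fraction > 0, test_fraction < 1)
  miss <- setdiff(names(labels), rownames(emb))
  if (length(miss)) stop(sprintf("labeled node(s) missing from embedding: %s",
                                 paste(utils::head(miss, 5), collapse = ", ")),
                         call. = FALSE)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("labels contain a single class", call. = FALSE)
  X <- emb[names(labels), , drop = FALSE]
  n <- length(y)
  test <- local_seed(seed, sample.int(n, max(1L, round(test_fraction * n))))
  train <- setdiff(seq_len(n), test)
  if (nlevels(droplevels(y[train])) < 2L || nlevels(droplevels(y[test])) < 2L) {
    stop("train/test split contains a single class; use a different seed",
         call. = FALSE)
  }
  df <- data.frame(y = y, X)
  fit <- nnet::multinom(y ~ ., data = df[train, , drop = FALSE],
                        decay = 1e-4, maxit = 500, trace = FALSE)
  prob <- stats::predict(fit, newdata = df[test, , drop = FALSE], type = "probs")
  ytest <- y[test]
  if (nlevels(y) == 2L) {
    p1 <- if (is.matrix(prob)) prob[, 2] else prob
    auc_binary(ytest == levels(y)[2], p1)
  } else {
    present <- levels(y)[levels(y) %in% unique(as.character(ytest))]
    mean(vapply(present, function(cl) {
      auc_binary(ytest == cl, prob[, cl])
    }, 1.0))
  }
}

# AUC of a binary response; ties handled by pROC's trapezoid convention
auc_binary <- function(truth, score) {
  if (length(unique(score)) == 1L) return(0.5)
  as.numeric(pROC::auc(pROC::roc(response = as.integer(truth),
                                 predictor = as.numeric(score),
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}
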