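# The training objective: negative-sampling Poincare distance loss over all
# edges, plus four structural hinge penalties (root radius, radial
# parent/child ordering, entailment cones over hierarchical edges, and
# entailment cones over links from non-hierarchical nodes to hierarchy
# nodes). All constraints are soft: satisfaction is measured afterwards,
# never assumed.

#' Initialize an embedding table
#'
#' One row per node (lexicographic node order), coordinates i.i.d. uniform
#' on `[-init_scale, init_scale]`. Deterministic given `cfg$seed`.
#'
#' @param g a [hetero_graph()].
#' @param cfg a [train_config()].
#' @return Numeric matrix `n x dim` with node ids as row names.
#' @export
init_embeddings <- function(g, cfg) {
  stopifnot(inherits(g, "hetero_graph"), inherits(cfg, "train_config"))
  ids <- g$nodes$node_id
  X <- local_seed(cfg$seed, {
    matrix(stats::runif(length(ids) * cfg$dim, -cfg$init_scale, cfg$init_scale),
           nrow = length(ids), ncol = cfg$dim, byrow = TRUE)
  })
  rownames(X) <- ids
  project_to_ball(X, cfg$eps_ball)
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# integer index structures shared by the loss terms and the trainer
training_indices <- function(g, hier, ids = g$nodes$node_id) {
  idx <- stats::setNames(seq_along(ids), ids)
  edges <- g$edges
  src <- idx[edges$source]
  dst <- idx[edges$target]
  hvec <- if (nrow(hier$edges)) cbind(idx[hier$edges$parent], idx[hier$edges$child])
          else matrix(integer(0), 0, 2)
  hset <- names(hier$depth)
  nh <- edges[!edges$hierarchical, , drop = FALSE]
  s_in <- nh$source %in% hset
  t_in <- nh$target %in% hset
  vh <- nh[xor(s_in, t_in), , drop = FALSE]
  vh_h <- ifelse(vh$source %in% hset, vh$source, vh$target)
  vh_v <- ifelse(vh$source %in% hset, vh$target, vh$source)
  # per-edge structural role: 1 = hierarchical (parent = source),
  # 2 = link between a non-hierarchy node and a hierarchy node, 0 = other
  es_in <- edges$source %in% hset
  et_in <- edges$target %in% hset
  edge_struct <- ifelse(edges$hierarchical, 1L,
                        ifelse(xor(es_in, et_in), 2L, 0L))
  edge_apex <- ifelse(edge_struct == 2L,
                      idx[ifelse(es_in, edges$source, edges$target)], NA_integer_)
  edge_member <- ifelse(edge_struct == 2L,
                        idx[ifelse(es_in, edges$target, edges$source)], NA_integer_)
  n <- length(ids)
  nbr <- vector("list", n)
  if (length(src)) {
    und <- data.frame(a = c(src, dst), b = c(dst, src))
    nbr_map <- split(und$b, und$a)
    nbr[as.integer(names(nbr_map))] <- lapply(nbr_map, unique)
  }
  candidates <- lapply(seq_len(n), function(i) setdiff(seq_len(n), c(i, nbr[[i]])))
  list(ids = ids, idx = idx, n = n,
       edge_src = unname(src), edge_dst = unname(dst),
       hier_pc = unname(hvec),
       root_idx = unname(idx[hier$roots]),
       vh_h = unname(idx[vh_h]), vh_v = unname(idx[vh_v]),
       apex_idx = sort(unique(c(unname(hvec[, 1]), unname(idx[vh_h])))),
       parent_idx = sort(unique(unname(hvec[, 1]))),
       vh_apex_idx = sort(unique(unname(idx[vh_h]))),
       hier_node_idx = sort(unname(idx[hset])),
       edge_struct = unname(edge_struct),
       edge_apex = unname(edge_apex), edge_member = unname(edge_member),
       member_apexes = member_apex_map(idx, hvec, vh_h, vh_v, length(ids)),
       candidates = candidates)
}

# For every node constrained by more than one cone (a poly-hierarchical
# child, or a non-hierarchy node linked to several hierarchy nodes), the
# integer indices of all its cone apexes; nodes with a single apex map to
# NULL. Used by the optimizer's nearest-cone projection rule.
member_apex_map <- function(idx, hvec, vh_h, vh_v, n) {
  mem <- c(if (nrow(hvec)) hvec[, 2] else integer(0), unname(idx[vh_v]))
  apx <- c(if (nrow(hvec)) hvec[, 1] else integer(0), unname(idx[vh_h]))
  out <- vector("list", n)
  if (length(mem)) {
    mm <- split(apx, mem)
    multi <- mm[vapply(mm, length, 1L) > 1L]
    out[as.integer(names(multi))] <- multi
  }
  out
}

#' Sample negative nodes for a positive edge
#'
#' Draws `n_negatives` nodes uniformly from the nodes that are neither `u`
#' itself nor linked to `u` (by any edge type). When fewer candidates than
#' `n_negatives` exist, sampling falls back to replacement with a one-time
#' message.
#'
#' @param g a [hetero_graph()].
#' @param u node id to sample negatives for.
#' @param n_negatives number of draws.
#' @param rng_state integer seed making the draw deterministic.
#' @return Character vector of node ids.
#' @export
sample_negatives <- function(g, u, n_negatives, rng_state = 1L) {
  stopifnot(inherits(g, "hetero_graph"), n_negatives >= 1L)
  ids <- g$nodes$node_id
  if (!u %in% ids) stop(sprintf("unknown node id '%s'", u), call. = FALSE)
  touches <- g$edges$source == u | g$edges$target == u
  nbrs <- unique(c(g$edges$source[touches], g$edges$target[touches]))
  cand <- setdiff(ids, c(u, nbrs))
  local_seed(rng_state, draw_negatives(cand, n_negatives))
}

draw_negatives <- function(cand, k) {
  if (length(cand) == 0L) stop("no negative-sample candidates available", call. = FALSE)
  if (length(cand) < k) {
    message(sprintf("fewer candidates (%d) than negatives (%d); sampling with replacement",
                    length(cand), k))
    cand[sample.int(length(cand), k, replace = TRUE)]
  } else {
    cand[sample.int(length(cand), k)]
  }
}

#' Pre-draw a negative-sample table for every edge
#'
#' One row per edge of `g` (in the graph's canonical edge order), each row
#' `n_negatives` node ids sampled as in [sample_negatives()] for that edge's
#' source node. Used to make [total_loss()] a deterministic function of the
#' embedding in gradient checks.
#'
#' @inheritParams sample_negatives
#' @param seed integer seed.
#' @return Character matrix, `nrow(g$edges)` by `n_negatives`.
#' @export
edge_negatives <- function(g, n_negatives, seed = 1L) {
  stopifnot(inherits(g, "hetero_graph"))
  hier <- extract_hierarchy(g)
  pr <- training_indices(g, hier)
  local_seed(seed, {
    m <- length(pr$edge_src)
    out <- matrix(NA_character_, m, n_negatives)
    for (e in seq_len(m)) {
      cand <- pr$candidates[[pr$edge_src[e]]]
      out[e, ] <- pr$ids[suppressMessages(draw_negatives(cand, n_negatives))]
    }
    out
  })
}

#' Negative-sampling distance loss of one edge
#'
#' The softmax objective of distance-based Poincare embedding:
#' \deqn{\ell(u,v) = -\log\frac{e^{-d(u,v)}}
#'   {\sum_{v' \in \{v\} \cup N} e^{-d(u,v')}}}
#' over the positive node `v` and negative samples `N`. Both hierarchical
#' and non-hierarchical edges are treated as undirected pairs here;
#' direction is enforced only by the regularizers.
#'
#' @param emb embedding matrix with node-id row names.
#' @param edge length-2 character vector `(u, v)`.
#' @param negatives character vector of negative node ids (must not contain
#'   `v`).
#' @return Nonnegative scalar.
#' @export
base_loss <- function(emb, edge, negatives) {
  u <- edge[[1]]; v <- edge[[2]]
  ids <- c(u, v, negatives)
  miss <- setdiff(ids, rownames(emb))
  if (length(miss)) stop(sprintf("node id(s) missing from embedding: %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  if (v %in% negatives) stop("positive node must not appear among negatives", call. = FALSE)
  cand <- c(v, negatives)
  dd <- poincare_distance(emb[rep(u, length(cand)), , drop = FALSE],
                          emb[cand, , drop = FALSE])
  unname(dd[1] + log(sum(exp(-(dd - min(dd))))) - min(dd))
}

#' Root-radius penalty
#'
#' `sum over roots of max(0, origin_distance(root) - delta)`: zero exactly
#' when every root lies within hyperbolic distance `delta` of the origin.
#'
#' @param emb embedding matrix with node-id row names.
#' @param roots character vector of root ids.
#' @param delta radius bound.
#' @return Nonnegative scalar.
#' @export
root_penalty <- function(emb, roots, delta) {
  if (!length(roots)) return(0)
  sum(pmax(0, origin_distance(emb[roots, , drop = FALSE]) - delta))
}

#' Radial parent/child ordering penalty
#'
#' For every hierarchical edge (p, c):
#' `max(0, origin_distance(p) - origin_distance(c) + margin)`, summed. Zero
#' exactly when each parent is at least `margin` closer to the origin (in
#' hyperbolic distance) than each of its children; a poly-hierarchical child
#' is constrained against every one of its parents.
#'
#' @param emb embedding matrix with node-id row names.
#' @param hier a [extract_hierarchy()] view.
#' @param margin nonnegative hinge slack.
#' @return Nonnegative scalar.
#' @export
child_penalty <- function(emb, hier, margin = 0) {
  stopifnot(margin >= 0)
  if (!nrow(hier$edges)) return(0)
  dp <- origin_distance(emb[hier$edges$parent, , drop = FALSE])
  dc <- origin_distance(emb[hier$edges$child, , drop = FALSE])
  sum(pmax(0, dp - dc + margin))
}

#' Entailment-cone penalty over hierarchical edges
#'
#' Sums [cone_energy()] of each child in its parent's cone, over every
#' hierarchical edge. Parents too close to the origin for a defined
#' aperture are gated (zero energy). A poly-hierarchical child accumulates
#' one term per parent, driving it toward the intersection of the cones.
#'
#' @inheritParams child_penalty
#' @param K positive aperture scale.
#' @return Nonnegative scalar.
#' @export
cone_penalty_hier <- function(emb, hier, K) {
  if (!nrow(hier$edges)) return(0)
  sum(cone_energy(emb[hier$edges$parent, , drop = FALSE],
                  emb[hier$edges$child, , drop = FALSE], K))
}

#' Entailment-cone penalty over non-hierarchical links to hierarchy nodes
#'
#' For every non-hierarchical edge joining a non-hierarchy node `v` to a
#' hierarchy node `h` (a node incident to at least one hierarchical edge),
#' adds [cone_energy()] of `v` in `h`'s cone, gated as usual. Links between
#' two non-hierarchy nodes (or two hierarchy nodes) contribute nothing: they
#' enter only the base distance loss.
#'
#' @param emb embedding matrix with node-id row names.
#' @param g a [hetero_graph()].
#' @param K positive aperture scale.
#' @return Nonnegative scalar.
#' @export
cone_penalty_nonhier <- function(emb, g, K) {
  hier <- extract_hierarchy(g)
  pr <- training_indices(g, hier)
  if (!length(pr$vh_h)) return(0)
  sum(cone_energy(emb[pr$vh_h, , drop = FALSE],
                  emb[pr$vh_v, , drop = FALSE], K))
}

#' Full training objective
#'
#' `sum of base_loss over all edges + lambda_root * root_penalty +
#' lambda_child * child_penalty + lambda_cone * cone_penalty_hier +
#' lambda_nonhier * cone_penalty_nonhier`, with the weights taken from
#' `cfg` (so the `variant` ablation switches act here).
#'
#' @param emb embedding matrix with node-id row names.
#' @param g a [hetero_graph()].
#' @param hier the graph's [extract_hierarchy()] view.
#' @param cfg a [train_config()].
#' @param negatives character matrix from [edge_negatives()] (one row per
#'   edge); if `NULL`, drawn deterministically from `cfg$seed`.
#' @return Scalar loss with attribute `"terms"` giving the named breakdown.
#' @export
total_loss <- function(emb, g, hier, cfg, negatives = NULL) {
  tl <- total_loss_grad(emb, g, hier, cfg, negatives, want_grad = FALSE)
  structure(tl$loss, terms = tl$terms)
}

#' Full objective with its analytic Euclidean gradient
#'
#' Same value as [total_loss()], plus the exact Euclidean gradient of the
#' objective with respect to every embedding coordinate (before Riemannian
#' rescaling). Used by the optimizer's full-batch penalty step and by
#' central-difference correctness checks.
#'
#' @inheritParams total_loss
#' @param want_grad compute the gradient (set `FALSE` to get the loss only).
#' @return List with `loss` (scalar), `terms` (named vector) and `grad`
#'   (matrix like `emb`, or `NULL`).
#' @export
total_loss_grad <- function(emb, g, hier, cfg, negatives = NULL,
                            want_grad = TRUE) {
  pr <- training_indices(g, hier, rownames(emb))
  if (is.null(negatives)) negatives <- edge_negatives(g, cfg$n_negatives, cfg$seed)
  neg_idx <- matrix(pr$idx[negatives], nrow = nrow(negatives))
  grad <- if (want_grad) matrix(0, nrow(emb), ncol(emb)) else NULL
  acc <- function(idx, G) {
    rs <- rowsum(G, idx)
    tgt <- as.integer(rownames(rs))
    grad[tgt, ] <<- grad[tgt, , drop = FALSE] + rs
  }

  # base loss over all edges
  base <- 0
  m <- length(pr$edge_src)
  if (m) {
    k1 <- ncol(neg_idx) + 1L
    urep <- rep(pr$edge_src, each = k1)
    cand <- as.vector(t(cbind(pr$edge_dst, neg_idx)))
    dg <- dist_grad(emb[urep, , drop = FALSE], emb[cand, , drop = FALSE])
    dd <- matrix(dg$d, nrow = m, ncol = k1, byrow = TRUE)
    mn <- apply(dd, 1, min)
    p <- exp(-(dd - mn))
    p <- p / rowSums(p)
    base <- sum(dd[, 1] + log(rowSums(exp(-(dd - mn)))) - mn)
    if (want_grad) {
      w <- -p
      w[, 1] <- w[, 1] + 1
      wv <- as.vector(t(w))
      acc(urep, dg$gu * wv)
      acc(cand, dg$gv * wv)
    }
  }

  # root penalty
  root <- 0
  if (cfg$lambda_root > 0 && length(pr$root_idx)) {
    od <- origin_dist_grad(emb[pr$root_idx, , drop = FALSE])
    viol <- od$d - cfg$delta
    act <- viol > 0
    root <- sum(pmax(0, viol))
    if (want_grad && any(act)) {
      acc(pr$root_idx[act], cfg$lambda_root * od$g[act, , drop = FALSE])
    }
  }

  # radial ordering penalty
  child <- 0
  if (cfg$lambda_child > 0 && nrow(pr$hier_pc)) {
    pi_ <- pr$hier_pc[, 1]; ci_ <- pr$hier_pc[, 2]
    odp <- origin_dist_grad(emb[pi_, , drop = FALSE])
    odc <- origin_dist_grad(emb[ci_, , drop = FALSE])
    viol <- odp$d - odc$d + cfg$margin
    act <- viol > 0
    child <- sum(pmax(0, viol))
    if (want_grad && any(act)) {
      acc(pi_[act], cfg$lambda_child * odp$g[act, , drop = FALSE])
      acc(ci_[act], -cfg$lambda_child * odc$g[act, , drop = FALSE])
    }
  }

  # entailment cones over hierarchical edges
  cone_h <- 0
  if (cfg$lambda_cone > 0 && nrow(pr$hier_pc)) {
    ce <- cone_energy_grad(emb[pr$hier_pc[, 1], , drop = FALSE],
                           emb[pr$hier_pc[, 2], , drop = FALSE], cfg$K)
    cone_h <- sum(ce$e)
    if (want_grad) {
      acc(pr$hier_pc[, 1], cfg$lambda_cone * ce$gx)
      acc(pr$hier_pc[, 2], cfg$lambda_cone * ce$gy)
    }
  }

  # entailment cones over non-hierarchical V-H links
  cone_v <- 0
  if (cfg$lambda_nonhier > 0 && length(pr$vh_h)) {
    ce <- cone_energy_grad(emb[pr$vh_h, , drop = FALSE],
                           emb[pr$vh_v, , drop = FALSE], cfg$K)
    cone_v <- sum(ce$e)
    if (want_grad) {
      acc(pr$vh_h, cfg$lambda_nonhier * ce$gx)
      acc(pr$vh_v, cfg$lambda_nonhier * ce$gy)
    }
  }

  terms <- c(base = base, root = root, child = child,
             cone_hier = cone_h, cone_nonhier = cone_v)
  bad <- names(terms)[!is.finite(terms)]
  if (length(bad)) {
    stop(sprintf("non-finite loss term: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  loss <- base + cfg$lambda_root * root + cfg$lambda_child * child +
    cfg$lambda_cone * cone_h + cfg$lambda_nonhier * cone_v
  list(loss = loss, terms = terms, grad = grad)
}
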