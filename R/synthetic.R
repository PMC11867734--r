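# Deterministic generator of mixed synthetic graphs: a forest of complete
# b-ary trees ("H" nodes, directed parent->child edges), optional
# poly-hierarchy (extra cross-tree parents at strictly smaller depth), and
# "V" nodes attached non-hierarchically inside one tree (their home tree is
# the planted classification label), plus sparse V-V links within a tree.

#' Specification of a synthetic mixed forest
#'
#' @param n_trees number of disjoint trees (roots).
#' @param branching children per internal hierarchy node.
#' @param depth tree depth (0 = roots only).
#' @param poly_prob probability that a non-root hierarchy node gains one
#'   extra parent, chosen uniformly from the nodes of another tree at a
#'   strictly smaller depth (keeps the level structure jointly satisfiable).
#' @param n_nonhier number of non-hierarchical ("V") nodes.
#' @param attach_min,attach_max each V node links to between `attach_min`
#'   and `attach_max` hierarchy nodes, sampled from the subtree of one
#'   random node of its home tree (locality makes the home-tree label
#'   recoverable from the embedding).
#' @param vv_prob link probability between two V nodes sharing a home tree.
#' @param seed integer seed; generation is fully deterministic.
#' @return Object of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 2L, branching = 2L, depth = 2L,
                        poly_prob = 0, n_nonhier = 0L,
                        attach_min = 1L, attach_max = 3L,
                        vv_prob = 0, seed = 1L) {
  spec <- list(n_trees = as.integer(n_trees), branching = as.integer(branching),
               depth = as.integer(depth), poly_prob = poly_prob,
               n_nonhier = as.integer(n_nonhier),
               attach_min = as.integer(attach_min),
               attach_max = as.integer(attach_max),
               vv_prob = vv_prob, seed = as.integer(seed))
  stopifnot(spec$n_trees >= 1L, spec$branching >= 1L, spec$depth >= 0L,
            spec$poly_prob >= 0, spec$poly_prob <= 1,
            spec$n_nonhier >= 0L,
            spec$attach_min >= 1L, spec$attach_max >= spec$attach_min,
            spec$vv_prob >= 0, spec$vv_prob <= 1)
  n_per_tree <- sum(spec$branching^(0:spec$depth))
  if (spec$n_trees * n_per_tree + spec$n_nonhier > 1e6) {
    stop("forest_spec would generate more than 1e6 nodes", call. = FALSE)
  }
  structure(spec, class = "forest_spec")
}

#' The standard synthetic forest used throughout the package
#'
#' Three complete 3-ary trees of depth 4 (121 hierarchy nodes each), 10%
#' poly-hierarchy, 100 non-hierarchical nodes with 1-3 links into one
#' tree's subtree, 2% within-tree V-V link density, seed 7.
#'
#' @return A [forest_spec()].
#' @export
standard_forest <- function() {
  forest_spec(n_trees = 3L, branching = 3L, depth = 4L, poly_prob = 0.1,
              n_nonhier = 100L, attach_min = 1L, attach_max = 3L,
              vv_prob = 0.02, seed = 7L)
}

#' Generate a synthetic mixed graph
#'
#' Builds the forest described by `spec`: `n_trees` complete
#' `branching`-ary trees of the given depth (node type `"H"`, hierarchical
#' edges parent -> child, edge type `"HH"`); with probability `poly_prob`
#' each non-root hierarchy node gains one extra parent from another tree at
#' strictly smaller depth; `n_nonhier` V nodes (type `"V"`) are each
#' assigned a uniform home tree, linked non-hierarchically (edge type
#' `"VH"`) to 1 or more hierarchy nodes sampled from the subtree of one
#' random home-tree node, and labeled by the 0-based home-tree index;
#' V pairs sharing a home tree are linked (edge type `"VV"`) with
#' probability `vv_prob`. Fully deterministic given `spec$seed`.
#'
#' The generator's own records (roots, parent sets, labels, home trees) are
#' attached and retrievable with [ground_truth()].
#'
#' @param spec a [forest_spec()].
#' @return A [hetero_graph()] with a `ground_truth` attribute.
#' @export
make_forest <- function(spec) {
  stopifnot(inherits(spec, "forest_spec"))
  local_seed(spec$seed, {
    per_level <- spec$branching^(0:spec$depth)
    nodes <- list(); edges <- list()
    tree_of <- character(0); depth_of <- integer(0)
    id_of <- function(t, i) sprintf("t%d_n%04d", t, i)
    true_parents <- list()
    for (t in seq_len(spec$n_trees)) {
      n_t <- sum(per_level)
      ids <- id_of(t, seq_len(n_t))
      lv <- rep(0:spec$depth, per_level)
      nodes[[t]] <- data.frame(node_id = ids, node_type = "H",
                               label = NA_character_, stringsAsFactors = FALSE)
      tree_of <- c(tree_of, stats::setNames(rep(sprintf("tree%d", t), n_t), ids))
      depth_of <- c(depth_of, stats::setNames(lv, ids))
      if (spec$depth >= 1L) {
        child_pos <- which(lv >= 1L)           # breadth-first numbering
        par_pos <- (child_pos - 2L) %/% spec$branching + 1L
        edges[[t]] <- data.frame(source = ids[par_pos], target = ids[child_pos],
                                 edge_type = "HH", hierarchical = TRUE,
                                 stringsAsFactors = FALSE)
        tp <- split(ids[par_pos], ids[child_pos])
        true_parents <- c(true_parents, tp)
      }
    }
    nodes <- do.call(rbind, nodes)
    edges <- if (length(edges)) do.call(rbind, edges) else
      data.frame(source = character(0), target = character(0),
                 edge_type = character(0), hierarchical = logical(0))

    # poly-hierarchy: extra cross-tree parents at strictly smaller depth
    if (spec$poly_prob > 0 && spec$n_trees >= 2L && spec$depth >= 1L) {
      hids <- nodes$node_id
      nonroot <- hids[depth_of[hids] >= 1L]
      gains <- nonroot[stats::runif(length(nonroot)) < spec$poly_prob]
      poly <- lapply(gains, function(ch) {
        pool <- hids[tree_of[hids] != tree_of[ch] & depth_of[hids] < depth_of[ch]]
        if (!length(pool)) return(NULL)
        p <- pool[sample.int(length(pool), 1L)]
        true_parents[[ch]] <<- sort(c(true_parents[[ch]], p))
        data.frame(source = p, target = ch, edge_type = "HH",
                   hierarchical = TRUE, stringsAsFactors = FALSE)
      })
      poly <- do.call(rbind, poly)
      if (!is.null(poly)) edges <- rbind(edges, poly)
    }

    # V nodes: home tree, subtree-local attachments, planted label
    v_label <- integer(0); v_home <- character(0)
    if (spec$n_nonhier > 0L) {
      # subtree membership within each pure tree (breadth-first indexing)
      subtree_ids <- function(t, i) {
        n_t <- sum(per_level)
        out <- i
        frontier <- i
        while (length(frontier)) {
          kids <- unlist(lapply(frontier, function(j) {
            ks <- ((j - 1L) * spec$branching + 2L):(j * spec$branching + 1L)
            ks[ks <= n_t]
          }))
          frontier <- kids
          out <- c(out, kids)
        }
        id_of(t, out)
      }
      vids <- sprintf("v%04d", seq_len(spec$n_nonhier))
      v_nodes <- data.frame(node_id = vids, node_type = "V",
                            label = NA_character_, stringsAsFactors = FALSE)
      v_home_t <- sample.int(spec$n_trees, spec$n_nonhier, replace = TRUE)
      v_label <- v_home_t - 1L
      v_home <- sprintf("tree%d", v_home_t)
      names(v_label) <- vids; names(v_home) <- vids
      v_nodes$label <- as.character(v_label)
      n_t <- sum(per_level)
      vh <- lapply(seq_len(spec$n_nonhier), function(i) {
        t <- v_home_t[i]
        anchor <- sample.int(n_t, 1L)
        pool <- subtree_ids(t, anchor)
        kk <- sample(seq(spec$attach_min, spec$attach_max), 1L)
        kk <- min(kk, length(pool))
        data.frame(source = vids[i],
                   target = pool[sample.int(length(pool), kk)],
                   edge_type = "VH", hierarchical = FALSE,
                   stringsAsFactors = FALSE)
      })
      vv <- NULL
      if (spec$vv_prob > 0 && spec$n_nonhier >= 2L) {
        pairs <- utils::combn(seq_len(spec$n_nonhier), 2L)
        same <- v_home_t[pairs[1, ]] == v_home_t[pairs[2, ]]
        keep <- same & (stats::runif(ncol(pairs)) < spec$vv_prob)
        if (any(keep)) {
          vv <- data.frame(source = vids[pairs[1, keep]],
                           target = vids[pairs[2, keep]],
                           edge_type = "VV", hierarchical = FALSE,
                           stringsAsFactors = FALSE)
        }
      }
      nodes <- rbind(nodes, v_nodes)
      edges <- rbind(edges, do.call(rbind, vh), vv)
    }

    g <- hetero_graph(nodes, edges)
    attr(g, "ground_truth") <- list(
      roots = sort(id_of(seq_len(spec$n_trees), 1L)),
      parents = if (length(true_parents)) true_parents[order(names(true_parents))] else list(),
      labels = v_label,
      home_tree = v_home,
      tree_of = tree_of,
      depth = depth_of,
      spec = spec)
    g
  })
}

#' Ground-truth records of a generated forest
#'
#' Returns the generator's own bookkeeping for a graph produced by
#' [make_forest()]: the planted roots, each child's parent set, the V-node
#' labels (0-based home-tree index) and home-tree map. [extract_hierarchy()]
#' must agree with these exactly; tests use them as the oracle.
#'
#' @param g a graph from [make_forest()].
#' @return List with `roots`, `parents`, `labels`, `home_tree`, `tree_of`,
#'   `depth`, `spec`.
#' @export
ground_truth <- function(g) {
  gt <- attr(g, "ground_truth")
  if (is.null(gt)) stop("graph carries no ground-truth records (not made by make_forest?)",
                        call. = FALSE)
  gt
}

#' Write the planted V-node labels of a generated forest
#'
#' @param g a graph from [make_forest()].
#' @param path output TSV path (columns `node_id`, `label`).
#' @return Invisibly, the label data.frame.
#' @export
write_labels <- function(g, path) {
  gt <- ground_truth(g)
  df <- data.frame(node_id = names(gt$labels), label = unname(gt$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(df)
}
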