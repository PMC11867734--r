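# Model fitting. The numerical core (stochastic pass, constraint
# projections, settling sweeps) is compiled C++ (src/train.cpp); this file
# prepares the index structures, runs the core, and assembles the fitted
# object. The R-level loss and gradient functions in loss.R remain the
# analytic reference that the optimizer is checked against.
#
# Optimizer design, in brief. Each epoch makes one stochastic pass over
# the edges, visiting every undirected edge from both endpoints: a visit
# takes a Riemannian-rescaled, length-clipped negative-sampling step on
# the base distance loss (half the negatives drawn uniformly, half from
# the node's current nearest non-neighbors), then projects the visited
# edge's own structural constraints. Constraint steps are projections, not
# gradient steps: the radial-ordering projection closes (at most) its own
# violation, split between parent and child; the entailment-cone
# projection rotates the member about the origin onto the cone at constant
# radius and rotates the apex toward the member at a capped rate (an apex
# position doubles as its cone's axis with leverage 1/||apex||, so an
# uncapped apex move whips between spread children). A member constrained
# by several cones is only projected onto the nearest one. Root-radius
# projections run full batch at each epoch's end, cone apexes are kept in
# the annulus where their apertures are usable, and all radii are bounded
# by an outer trust region so the softmax repulsion cannot push the
# population onto the ball boundary where the metric factor freezes it.
# After the last epoch a settling phase of deterministic projection sweeps
# (damped apex rotation, members landing inside the cone boundary) lets
# the coupled constraints crystallize with the stochastic pass frozen.

#' Fit a cone-regularized Poincare embedding
#'
#' Embeds every node of a heterogeneous graph in the open Poincare ball by
#' minimizing a negative-sampling distance loss over all edges plus four
#' structural hinge penalties: roots within hyperbolic distance `delta` of
#' the origin, parents radially inside their children, children inside
#' their parents' entailment cones, and non-hierarchical nodes inside the
#' cones of the hierarchy nodes they link to. The `variant` field of the
#' configuration switches the standard ablations (see [train_config()]).
#'
#' Optimization is projected Riemannian stochastic gradient descent on the
#' distance loss, interleaved with per-constraint projection steps for the
#' structural penalties and followed by a settling phase of deterministic
#' projection sweeps; the entailment-cone constraints activate after
#' `cone_warmup_epochs` once the radial skeleton has formed. Training is
#' fully deterministic given the configuration's seed. The phases and
#' their rationale are documented in the methods vignette.
#'
#' @param graph a [hetero_graph()].
#' @param config a [train_config()].
#' @param verbose print a short fitting banner.
#' @return An object of class `coneforest`: a list with `embedding`
#'   (matrix, node ids as row names), `config`, `graph`, `hierarchy`, and
#'   `log` (one row per epoch: total loss, the base term, each penalty
#'   term, the constraint satisfaction rates, and the maximum embedding
#'   norm).
#' @seealso [structure_report()], [reconstruction_map()],
#'   [classifier_eval()] for evaluating the fit.
#' @examples
#' g <- make_forest(forest_spec(n_trees = 2, branching = 2, depth = 2,
#'                              seed = 1))
#' fit <- coneforest(g, train_config(epochs = 20, final_sweeps = 10,
#'                                   cone_warmup_epochs = 5, seed = 1))
#' structure_report(fit)
#' @export
coneforest <- function(graph, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(graph, "hetero_graph"), inherits(config, "train_config"))
  validate_config(config)
  cfg <- config
  if (cfg$n_negatives > 63L) stop("n_negatives must be at most 63", call. = FALSE)
  hier <- extract_hierarchy(graph)
  pr <- training_indices(graph, hier)
  X <- init_embeddings(graph, cfg)
  if (verbose) {
    cat(sprintf("fitting variant '%s': %d nodes, %d edges, %d epochs (+%d settling sweeps)\n",
                cfg$variant, nrow(X), length(pr$edge_src), cfg$epochs,
                cfg$final_sweeps))
  }

  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  hvec <- pr$hier_pc
  res <- cpp_train(X, unclass(cfg),
                   as.integer(pr$edge_src), as.integer(pr$edge_dst),
                   as.integer(pr$edge_struct),
                   as.integer(pr$edge_apex), as.integer(pr$edge_member),
                   as.integer(pr$root_idx), as.integer(pr$apex_idx),
                   as.integer(pr$parent_idx), as.integer(pr$vh_apex_idx),
                   pr$candidates, pr$member_apexes,
                   as.integer(hvec[, 1]), as.integer(hvec[, 2]),
                   as.integer(pr$vh_h), as.integer(pr$vh_v))
  if (isTRUE(res$replacement)) {
    message("some node had fewer negative-sample candidates than n_negatives; sampled with replacement")
  }
  Xout <- res$X
  rownames(Xout) <- pr$ids
  log_df <- as.data.frame(res$log)
  names(log_df) <- c("epoch", "loss", "base", "root", "child", "cone_hier",
                     "cone_nonhier", "root_rate", "order_rate", "cone_rate",
                     "max_norm")
  structure(list(embedding = Xout, config = cfg, graph = graph,
                 hierarchy = hier, log = log_df),
            class = "coneforest")
}
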