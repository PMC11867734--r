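# S3 methods for the fitted model object.

#' @export
print.coneforest <- function(x, ...) {
  cat(sprintf("Cone-regularized Poincare embedding (variant '%s')\n",
              x$config$variant))
  print(x$graph)
  cat(sprintf("  dimension %d, %d epochs, seed %d\n",
              x$config$dim, x$config$epochs, x$config$seed))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final loss %.3f; satisfaction rates: root %.3f, ordering %.3f, cone %.3f\n",
                last$loss, last$root_rate, last$order_rate, last$cone_rate))
  }
  invisible(x)
}

#' Summarize a fitted embedding
#'
#' Prints the configuration, the final training-log line and the full
#' [structure_report()] of the fitted embedding.
#'
#' @param object a `coneforest` fit.
#' @param ... unused.
#' @return The `structure_report`, invisibly.
#' @export
summary.coneforest <- function(object, ...) {
  print(object)
  rep <- structure_report(object)
  print(rep)
  invisible(rep)
}

#' Embedding coordinates of a fit
#'
#' @param object a `coneforest` fit.
#' @param ... unused.
#' @return The embedding matrix (nodes by dimensions, node ids as row
#'   names).
#' @export
coef.coneforest <- function(object, ...) object$embedding

#' Nearest neighbors under the trained metric
#'
#' For each query node, returns the `k` nearest other nodes by hyperbolic
#' distance in the trained embedding — the retrieval operation behind the
#' reconstruction metric.
#'
#' @param object a `coneforest` fit.
#' @param nodes character vector of query node ids (default: all).
#' @param k neighbors per query.
#' @param ... unused.
#' @return data.frame with columns `node`, `neighbor`, `rank`, `distance`.
#' @export
predict.coneforest <- function(object, nodes = NULL, k = 5L, ...) {
  emb <- object$embedding
  if (is.null(nodes)) nodes <- rownames(emb)
  miss <- setdiff(nodes, rownames(emb))
  if (length(miss)) stop(sprintf("unknown node id(s): %s",
                                 paste(utils::head(miss, 5), collapse = ", ")),
                         call. = FALSE)
  all_ids <- rownames(emb)
  out <- lapply(nodes, function(u) {
    others <- setdiff(all_ids, u)
    d <- poincare_distance(emb[rep(u, length(others)), , drop = FALSE],
                           emb[others, , drop = FALSE])
    o <- order(d, rank(others))[seq_len(min(k, length(others)))]
    data.frame(node = u, neighbor = others[o], rank = seq_along(o),
               distance = d[o], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Plot a fitted embedding
#'
#' Draws the first two embedding coordinates inside the unit circle,
#' hierarchy nodes colored by root ancestry where available, hierarchical
#' edges as segments. For `dim > 2` this is a linear projection, so ball
#' membership is preserved but hyperbolic distances are only suggestive.
#'
#' @param x a `coneforest` fit.
#' @param show_edges draw hierarchical edges.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.coneforest <- function(x, show_edges = TRUE, ...) {
  emb <- x$embedding
  p2 <- emb[, 1:2, drop = FALSE]
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 xlab = "dim 1", ylab = "dim 2",
                 main = "Poincare-ball embedding (first two coordinates)", ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey70")
  if (show_edges && nrow(x$hierarchy$edges)) {
    e <- x$hierarchy$edges
    graphics::segments(p2[e$parent, 1], p2[e$parent, 2],
                       p2[e$child, 1], p2[e$child, 2], col = "grey80")
  }
  is_v <- x$graph$nodes$node_type[match(rownames(emb), x$graph$nodes$node_id)] == "V"
  col <- ifelse(is_v, "steelblue", "firebrick")
  pch <- ifelse(is_v, 17, 19)
  graphics::points(p2[, 1], p2[, 2], col = col, pch = pch, cex = 0.6)
  roots <- x$hierarchy$roots
  if (length(roots)) graphics::points(p2[roots, 1], p2[roots, 2], pch = 1,
                                      cex = 1.6, lwd = 2)
  invisible(x)
}
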