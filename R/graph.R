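# Heterogeneous graph container, TSV readers/writers, and hierarchy
# extraction. Hierarchical edges are directed parent -> child; everything
# else is undirected. The hierarchical subgraph must be a DAG (poly-
# hierarchy allowed, cycles not).

#' Construct a validated heterogeneous graph
#'
#' A graph with typed nodes and two edge families: directed hierarchical
#' edges (source = parent, target = child) and undirected non-hierarchical
#' edges. Node ids must be unique, every edge endpoint must exist, duplicate
#' edges are collapsed with a warning, and the hierarchical subgraph must be
#' acyclic.
#'
#' @param nodes data.frame with columns `node_id`, `node_type` and
#'   optionally `label` (character; may be `NA`).
#' @param edges data.frame with columns `source`, `target`, `edge_type`,
#'   `hierarchical` (logical, or "1"/"0").
#' @return An object of class `hetero_graph`: a list with validated `nodes`
#'   and `edges` data.frames, nodes sorted by id.
#' @export
hetero_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_n <- c("node_id", "node_type")
  if (!all(need_n %in% names(nodes))) {
    stop("`nodes` must have columns node_id, node_type", call. = FALSE)
  }
  if (!"label" %in% names(nodes)) nodes$label <- NA_character_
  nodes$node_id <- as.character(nodes$node_id)
  nodes$node_type <- as.character(nodes$node_type)
  nodes$label <- as.character(nodes$label)
  need_e <- c("source", "target", "edge_type", "hierarchical")
  if (!all(need_e %in% names(edges))) {
    stop("`edges` must have columns source, target, edge_type, hierarchical",
         call. = FALSE)
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$edge_type <- as.character(edges$edge_type)
  if (!is.logical(edges$hierarchical)) {
    edges$hierarchical <- as.character(edges$hierarchical) %in% c("1", "TRUE", "true")
  }
  dup <- duplicated(nodes$node_id)
  if (any(dup)) {
    stop(sprintf("duplicate node id(s): %s",
                 paste(unique(nodes$node_id[dup]), collapse = ", ")), call. = FALSE)
  }
  missing_ref <- setdiff(c(edges$source, edges$target), nodes$node_id)
  if (length(missing_ref)) {
    stop(sprintf("edge endpoint(s) not in node table: %s",
                 paste(missing_ref, collapse = ", ")), call. = FALSE)
  }
  # canonicalize undirected non-hierarchical edges before dedup
  canon <- edges
  flip <- !canon$hierarchical & canon$source > canon$target
  if (any(flip)) {
    tmp <- canon$source[flip]
    canon$source[flip] <- canon$target[flip]
    canon$target[flip] <- tmp
  }
  key <- paste(canon$source, canon$target, canon$edge_type, canon$hierarchical)
  dup_e <- duplicated(key)
  if (any(dup_e)) {
    warning(sprintf("dropped %d duplicate edge row(s)", sum(dup_e)), call. = FALSE)
    edges <- edges[!dup_e, , drop = FALSE]
  }
  if (any(edges$source == edges$target)) {
    stop("self-loop edges are not allowed", call. = FALSE)
  }
  # deterministic lexicographic ordering
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$edge_type), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges), class = "hetero_graph")
  hier <- edges[edges$hierarchical, , drop = FALSE]
  if (nrow(hier)) {
    ig <- igraph::graph_from_data_frame(hier[, c("source", "target")],
                                        directed = TRUE,
                                        vertices = nodes$node_id)
    if (!igraph::is_dag(ig)) {
      stop(sprintf("hierarchical subgraph contains a cycle: %s",
                   paste(find_cycle(hier), collapse = " -> ")), call. = FALSE)
    }
  }
  g
}

# DFS cycle finder on the hierarchical edge list; only reached when the DAG
# check has already failed, so a cycle is guaranteed to exist.
find_cycle <- function(hier) {
  adj <- split(hier$target, hier$source)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- get0(v, envir = state, ifnotfound = 0L)
    if (st == 1L) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (st == 2L) return()
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (w in adj[[v]]) if (is.null(found)) visit(w)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in unique(hier$source)) {
    if (is.null(found)) visit(v)
  }
  found
}

#' @export
print.hetero_graph <- function(x, ...) {
  nh <- sum(x$edges$hierarchical)
  cat(sprintf("<hetero_graph> %d nodes (%s), %d edges (%d hierarchical, %d non-hierarchical)\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(table(x$nodes$node_type)),
                            as.integer(table(x$nodes$node_type))), collapse = ", "),
              nrow(x$edges), nh, nrow(x$edges) - nh))
  invisible(x)
}

#' Read a heterogeneous graph from node and edge TSV files
#'
#' Both files are UTF-8, tab-separated, with one header row. `nodes.tsv`
#' has columns `node_id`, `node_type`, `label` (label may be empty);
#' `edges.tsv` has `source`, `target`, `edge_type`, `hierarchical`
#' ("1"/"0"). Duplicate edge rows are collapsed with a warning; an edge
#' naming an unknown node is an error.
#'
#' @param node_path,edge_path paths to the TSV files.
#' @return A validated [hetero_graph()].
#' @export
read_graph <- function(node_path, edge_path) {
  nodes <- read_tsv_checked(node_path, c("node_id", "node_type"))
  edges <- read_tsv_checked(edge_path, c("source", "target", "edge_type", "hierarchical"))
  hetero_graph(nodes, edges)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                      colClasses = "character", na.strings = NULL,
                      fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("parse error in %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s (header row is line 1)", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a heterogeneous graph to node and edge TSV files
#'
#' @param g a [hetero_graph()].
#' @param node_path,edge_path output paths.
#' @return Invisibly, `g`.
#' @export
write_graph <- function(g, node_path, edge_path) {
  stopifnot(inherits(g, "hetero_graph"))
  nodes <- g$nodes
  nodes$label[is.na(nodes$label)] <- ""
  edges <- g$edges
  edges$hierarchical <- ifelse(edges$hierarchical, "1", "0")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(g)
}

#' Extract the hierarchy view of a graph
#'
#' Restricts to hierarchical (parent -> child) edges and derives: the roots
#' (nodes of hierarchical in-degree zero among nodes that touch a
#' hierarchical edge), each node's parent and child sets, each node's depth
#' (minimum hop count from any root), and the number of poly-hierarchical
#' nodes (children with more than one parent).
#'
#' @param g a [hetero_graph()].
#' @return Object of class `hierarchy_view`: list with `roots` (character),
#'   `parents` and `children` (named lists of character vectors), `depth`
#'   (named integer), `edges` (parent/child data.frame) and `n_poly`.
#' @export
extract_hierarchy <- function(g) {
  stopifnot(inherits(g, "hetero_graph"))
  hier <- g$edges[g$edges$hierarchical, c("source", "target")]
  hnodes <- sort(unique(c(hier$source, hier$target)))
  if (nrow(hier) == 0L) {
    # every hierarchy-typed node (if any) is its own root; by convention an
    # edgeless graph has no hierarchy nodes unless typed "H"
    hnodes <- sort(g$nodes$node_id[g$nodes$node_type == "H"])
    depth <- stats::setNames(integer(length(hnodes)), hnodes)
    return(structure(list(roots = hnodes,
                          parents = stats::setNames(vector("list", length(hnodes)), hnodes),
                          children = stats::setNames(vector("list", length(hnodes)), hnodes),
                          depth = depth,
                          edges = data.frame(parent = character(0), child = character(0)),
                          n_poly = 0L),
                     class = "hierarchy_view"))
  }
  ig <- igraph::graph_from_data_frame(hier, directed = TRUE, vertices = hnodes)
  if (!igraph::is_dag(ig)) {
    stop(sprintf("hierarchical subgraph contains a cycle: %s",
                 paste(find_cycle(data.frame(source = hier$source,
                                             target = hier$target)),
                       collapse = " -> ")), call. = FALSE)
  }
  indeg <- igraph::degree(ig, mode = "in")
  roots <- sort(names(indeg)[indeg == 0])
  dmat <- igraph::distances(ig, v = roots, mode = "out")
  depth_num <- apply(dmat, 2, min)
  if (any(!is.finite(depth_num))) {
    stop(sprintf("hierarchy node(s) unreachable from any root: %s",
                 paste(names(depth_num)[!is.finite(depth_num)], collapse = ", ")),
         call. = FALSE)
  }
  depth <- stats::setNames(as.integer(depth_num), colnames(dmat))
  depth <- depth[order(names(depth))]
  parents <- lapply(split(hier$source, hier$target), function(p) sort(unique(p)))
  children <- lapply(split(hier$target, hier$source), function(ch) sort(unique(ch)))
  structure(list(roots = roots,
                 parents = parents,
                 children = children,
                 depth = depth,
                 edges = data.frame(parent = hier$source, child = hier$target,
                                    stringsAsFactors = FALSE),
                 n_poly = sum(vapply(parents, length, 1L) > 1L)),
            class = "hierarchy_view")
}

#' @export
print.hierarchy_view <- function(x, ...) {
  cat(sprintf("<hierarchy_view> %d roots, %d nodes, %d parent-child edges, max depth %d, %d poly-hierarchical node(s)\n",
              length(x$roots), length(x$depth), nrow(x$edges),
              if (length(x$depth)) max(x$depth) else 0L, x$n_poly))
  invisible(x)
}

#' Write / read an embedding table
#'
#' Tab-separated with a header row: `node_id` then one column per
#' coordinate (`x1 ... xd`), printed with 17 significant digits so a
#' write/read round trip reproduces the doubles exactly. Reading validates
#' that every row lies strictly inside the unit ball.
#'
#' @param emb numeric matrix with one embedding per row and node ids as row
#'   names.
#' @param path output path.
#' @return `write_embeddings` returns `emb` invisibly; `read_embeddings`
#'   returns the matrix with node-id row names.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(is.matrix(emb), nrow(emb) == 0L || !is.null(rownames(emb)))
  d <- ncol(emb)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("node_id", paste0("x", seq_len(d))), collapse = "\t"), con)
  if (nrow(emb)) {
    coords <- apply(emb, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(paste(rownames(emb), coords, sep = "\t"), con)
  }
  invisible(emb)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- read_tsv_checked(path, "node_id")
  ids <- df$node_id
  if (ncol(df) < 2L && nrow(df) > 0L) stop("embedding file has no coordinate columns", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- NULL
  nrm <- sqrt(rowSums(m * m))
  bad <- which(nrm >= 1)
  if (length(bad)) {
    stop(sprintf("embedding norm >= 1 for node(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  m
}
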