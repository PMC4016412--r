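#' Collapse tightly correlated genes into multi-gene nodes
#'
#' Within each module, genes are clustered by average linkage on the
#' dissimilarity `1 - |r|` and the tree is cut at `1 - cut` (default cut
#' `|r| = 0.75`). Clusters of two or more genes become multi-gene nodes;
#' the rest are single-gene nodes. The multi-node cut must exceed the edge
#' threshold 0.7 so that collapsing happens strictly inside the strongest
#' correlation tier. Unassigned genes (module `"M0"`) are excluded.
#'
#' @param r Correlation matrix over genes.
#' @param p A `dawn_modules` partition on the same genes.
#' @param cut Absolute-correlation cut for multi-gene clusters, must be
#'   `> 0.7` (default 0.75).
#' @return A `dawn_nodegraph` with `nodes` (list of gene character
#'   vectors), `node_of_gene`, empty `adjacency` (see [build_adjacency()]),
#'   and the partition's `representation_id`.
#' @export
collapse_multinodes <- function(r, p, cut = 0.75) {
  if (cut <= 0.7)
    stop("multi-gene cluster cut must be greater than 0.7")
  members <- module_members(p)
  nodes <- list()
  for (lab in names(members)) {
    genes <- sort(members[[lab]])
    if (length(genes) == 1L) {
      nodes[[length(nodes) + 1L]] <- genes
      next
    }
    d <- 1 - abs(r[genes, genes, drop = FALSE])
    d[is.na(d)] <- 1
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, h = 1 - cut)
    for (k in sort(unique(cl)))
      nodes[[length(nodes) + 1L]] <- genes[cl == k]
  }
  names(nodes) <- paste0("N", seq_along(nodes))
  node_of_gene <- stats::setNames(rep(names(nodes),
                                      lengths(nodes)), unlist(nodes))
  structure(list(nodes = nodes,
                 node_of_gene = node_of_gene,
                 adjacency = NULL,
                 representation_id = p$representation_id),
            class = "dawn_nodegraph")
}

#' Connect nodes whose average absolute correlation exceeds a threshold
#'
#' Adds the binary adjacency to a node graph: nodes `u`, `v` are connected
#' when the average of `|r_ij|` over gene pairs `i` in `u`, `j` in `v`
#' strictly exceeds `threshold` (default 0.7; for two single-gene nodes
#' this reduces to `|r_ij| > threshold`). Edges may cross module
#' boundaries: adjacency is a property of correlation, not of the module
#' partition.
#'
#' @param g A `dawn_nodegraph` from [collapse_multinodes()].
#' @param r Correlation matrix over genes.
#' @param threshold Edge threshold on average `|r|` (default 0.7).
#' @return The node graph with a logical `adjacency` matrix filled in.
#' @export
build_adjacency <- function(g, r, threshold = 0.7) {
  genes <- names(g$node_of_gene)
  ar <- abs(r[genes, genes, drop = FALSE])
  ar[is.na(ar)] <- 0
  m <- matrix(0, length(genes), length(g$nodes),
              dimnames = list(genes, names(g$nodes)))
  m[cbind(genes, g$node_of_gene[genes])] <- 1
  s <- t(m) %*% ar %*% m
  cnt <- outer(lengths(g$nodes), lengths(g$nodes))
  avg <- s / cnt
  adj <- avg > threshold
  diag(adj) <- FALSE
  g$adjacency <- adj
  g$edge_threshold <- threshold
  g
}

#' @export
print.dawn_nodegraph <- function(x, ...) {
  multi <- sum(lengths(x$nodes) > 1L)
  cat(sprintf("dawn_nodegraph '%s': %d nodes (%d multi-gene) over %d genes",
              x$representation_id, length(x$nodes), multi,
              length(x$node_of_gene)))
  if (!is.null(x$adjacency))
    cat(sprintf(", %d edges", sum(x$adjacency) / 2))
  cat("\n")
  invisible(x)
}
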