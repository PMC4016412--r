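#' Soft-thresholded co-expression adjacency
#'
#' Raises the absolute Pearson correlation to a soft power,
#' `a_ij = |r_ij|^beta`, with a zero diagonal by convention. Power 1 keeps
#' the full correlation structure; higher powers (the pipeline default uses
#' 6) suppress weak correlations and emphasise hubs.
#'
#' @param r Symmetric correlation matrix (unit diagonal).
#' @param power Integer soft power, >= 1.
#' @return Adjacency matrix with entries in `[0, 1]` and zero diagonal.
#' @export
soft_adjacency <- function(r, power = 1) {
  if (!is.numeric(power) || length(power) != 1L || power < 1)
    stop("power must be a single number >= 1")
  a <- abs(r)^power
  diag(a) <- 0
  a
}

#' Topological overlap dissimilarity
#'
#' Computes the topological overlap measure
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`, and returns the dissimilarity `1 - TOM`. Two genes
#' are similar when they share neighbourhoods, not merely when they are
#' directly connected. Degenerate pairs with a zero denominator get
#' dissimilarity 1; the diagonal is 0.
#'
#' @param a Symmetric adjacency in `[0, 1]` with zero diagonal, as from
#'   [soft_adjacency()].
#' @return Symmetric dissimilarity matrix in `[0, 1]`.
#' @export
topological_overlap <- function(a) {
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- ifelse(den <= 0, 0, num / den)
  d <- 1 - tom
  d[] <- pmin(1, pmax(0, d))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Recursive branch cut of an average-linkage dendrogram ("tree" variant):
# merges at or above the static cut height are split when both branches
# hold at least min_size leaves; a small branch peeling off at such a
# height is unassigned; everything below the cut height stays together.
cut_tree_recursive <- function(hc, n, h_cut, min_size) {
  merge <- hc$merge
  height <- hc$height
  sizes <- integer(nrow(merge))
  for (m in seq_len(nrow(merge))) {
    s <- 0L
    for (ch in merge[m, ]) s <- s + if (ch < 0) 1L else sizes[ch]
    sizes[m] <- s
  }
  node_size <- function(ch) if (ch < 0) 1L else sizes[ch]
  leaves_of <- function(node) {
    out <- integer(0)
    stack <- node
    while (length(stack) > 0L) {
      nd <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (nd < 0) out <- c(out, -nd)
      else stack <- c(stack, merge[nd, 1L], merge[nd, 2L])
    }
    out
  }
  cluster <- integer(n)      # 0 = unassigned
  next_id <- 0L
  stack <- nrow(merge)       # root
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (nd < 0) next                       # lone leaf peeled at the top
    c1 <- merge[nd, 1L]; c2 <- merge[nd, 2L]
    s1 <- node_size(c1); s2 <- node_size(c2)
    if (height[nd] >= h_cut && s1 >= min_size && s2 >= min_size) {
      stack <- c(stack, c1, c2)
    } else if (height[nd] >= h_cut && max(s1, s2) >= min_size) {
      big <- if (s1 >= s2) c1 else c2      # small branch stays unassigned
      stack <- c(stack, big)
    } else {
      lv <- leaves_of(nd)
      if (length(lv) >= min_size) {
        next_id <- next_id + 1L
        cluster[lv] <- next_id
      }
    }
  }
  cluster
}

#' Detect co-expression modules by dynamic branch cutting
#'
#' Builds an average-linkage dendrogram from a dissimilarity matrix
#' (typically topological-overlap dissimilarity) and cuts it with a
#' deterministic "tree" variant of dynamic branch cutting: merges at or
#' above a static height (`static_frac` times the tallest merge) are split
#' recursively whenever both branches hold at least `min_size` genes;
#' small branches peeling off at such heights are left unassigned.
#' Clusters smaller than `min_size` end up unassigned (module `"M0"`).
#' Genes are clustered in lexicographic symbol order so ties break
#' reproducibly.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal and gene
#'   names on both dimensions.
#' @param min_size Minimum module size (default 30 genes).
#' @param static_frac Static cut height as a fraction of the maximum merge
#'   height (default 0.99).
#' @param representation_id Label stored with the partition.
#' @param power Soft power recorded with the partition (metadata only).
#' @return A `dawn_modules` object: list with `assignment` (named character
#'   vector gene -> module label, `"M0"` = unassigned), `representation_id`,
#'   `power`, `min_module_size`, `merged`.
#' @export
cut_modules <- function(d, min_size = 30, static_frac = 0.99,
                        representation_id = "rep1", power = NA_real_) {
  genes <- rownames(d)
  if (is.null(genes)) stop("dissimilarity matrix needs gene names")
  n <- length(genes)
  assignment <- stats::setNames(rep("M0", n), genes)
  if (n < min_size) {
    warning("fewer genes than min_size; all genes unassigned")
    return(new_modules(assignment, representation_id, power, min_size, FALSE))
  }
  ord <- order(genes)
  dd <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(dd), method = "average")
  h_cut <- static_frac * max(hc$height)
  cl <- cut_tree_recursive(hc, n, h_cut, min_size)
  lab <- genes[ord]
  # relabel by decreasing module size, deterministic ties by first gene
  ids <- setdiff(unique(cl), 0L)
  if (length(ids) > 0L) {
    sz <- vapply(ids, function(i) sum(cl == i), integer(1))
    first <- vapply(ids, function(i) min(which(cl == i)), integer(1))
    ids <- ids[order(-sz, first)]
    for (k in seq_along(ids))
      assignment[lab[cl == ids[k]]] <- paste0("M", k)
  }
  new_modules(assignment, representation_id, power, min_size, FALSE)
}

new_modules <- function(assignment, representation_id, power,
                        min_module_size, merged) {
  structure(list(assignment = assignment,
                 representation_id = representation_id,
                 power = power,
                 min_module_size = min_module_size,
                 merged = merged),
            class = "dawn_modules")
}

#' @export
print.dawn_modules <- function(x, ...) {
  tab <- table(x$assignment)
  n_mod <- sum(names(tab) != "M0")
  cat(sprintf("dawn_modules '%s': %d genes, %d modules (%d unassigned)%s\n",
              x$representation_id, length(x$assignment), n_mod,
              sum(x$assignment == "M0"),
              if (x$merged) ", eigengene-merged" else ""))
  invisible(x)
}

#' Module labels as a factor-free list of gene vectors
#' @param p A `dawn_modules` partition.
#' @param drop_unassigned Drop the `"M0"` pool (default `TRUE`).
#' @return Named list of gene character vectors.
#' @export
module_members <- function(p, drop_unassigned = TRUE) {
  sp <- split(names(p$assignment), p$assignment)
  if (drop_unassigned) sp[["M0"]] <- NULL
  sp
}

module_eigengene <- function(x, genes) {
  e <- t(x[genes, , drop = FALSE])          # replicates x genes
  e <- scale(e)
  e[!is.finite(e)] <- 0
  pc <- svd(e, nu = 1, nv = 0)
  eig <- pc$u[, 1L] * pc$d[1L]
  avg <- rowMeans(e)
  if (stats::sd(eig) > 0 && stats::sd(avg) > 0 &&
      stats::cor(eig, avg) < 0) eig <- -eig
  eig
}

#' Merge similar modules by eigengene correlation
#'
#' The eigengene of a module is the first principal-component score vector
#' of its standardised expression (oriented to correlate positively with
#' mean module expression). Modules whose eigengene correlation
#' dissimilarity `1 - r` falls below `height` are merged iteratively,
#' closest pair first, until no pair qualifies. Modules with fewer than two
#' genes and the unassigned pool are left untouched.
#'
#' @param p A `dawn_modules` partition.
#' @param x Expression matrix the partition was built from.
#' @param height Merge height on the `1 - r` scale, in `[0, 1)`
#'   (default 0.15).
#' @return A `dawn_modules` partition with `merged = TRUE`.
#' @export
merge_by_eigengene <- function(p, x, height = 0.15) {
  if (height < 0 || height >= 1) stop("height must lie in [0, 1)")
  members <- module_members(p)
  assignment <- p$assignment
  if (height > 0 && length(members) >= 2L) {
    eligible <- names(members)[vapply(members, length, integer(1)) >= 2L]
    eigs <- lapply(members[eligible], function(g) module_eigengene(x, g))
    repeat {
      if (length(eigs) < 2L) break
      em <- do.call(cbind, eigs)
      re <- suppressWarnings(stats::cor(em))
      diss <- 1 - re
      diag(diss) <- Inf
      idx <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
      if (!is.finite(diss[idx[1L], idx[2L]]) ||
          diss[idx[1L], idx[2L]] >= height) break
      keep <- colnames(em)[min(idx)]
      gone <- colnames(em)[max(idx)]
      members[[keep]] <- c(members[[keep]], members[[gone]])
      members[[gone]] <- NULL
      eigs[[keep]] <- module_eigengene(x, members[[keep]])
      eigs[[gone]] <- NULL
    }
    assignment[] <- "M0"
    for (lab in names(members)) assignment[members[[lab]]] <- lab
  }
  out <- new_modules(assignment, p$representation_id, p$power,
                     p$min_module_size, TRUE)
  out
}

#' Build the modular representations of one or two expression periods
#'
#' For each expression period and each soft power, computes the Pearson
#' correlation, soft adjacency, topological-overlap dissimilarity and the
#' module partition. Power-1 partitions are returned unmerged; partitions
#' for powers above 1 (the pipeline uses 6) are eigengene-merged.
#' With two periods and powers `c(1, 6)` this yields the standard four
#' representations of the co-expression network.
#'
#' @param x_list Named list of expression matrices, one per period.
#' @param powers Integer vector of soft powers (default `c(1, 6)`).
#' @param min_module_size,merge_height Module parameters (defaults 30 and
#'   0.15).
#' @param static_frac Static cut height fraction passed to [cut_modules()].
#' @return List with `correlations` (one matrix per period) and
#'   `partitions` (one `dawn_modules` per period x power, named
#'   `"<period>_pow<power>"`).
#' @export
build_representations <- function(x_list, powers = c(1, 6),
                                  min_module_size = 30, merge_height = 0.15,
                                  static_frac = 0.99) {
  if (is.null(names(x_list)))
    names(x_list) <- paste0("period", seq_along(x_list))
  correlations <- lapply(x_list, pearson_correlation)
  partitions <- list()
  for (period in names(x_list)) {
    r <- correlations[[period]]
    for (beta in powers) {
      rep_id <- sprintf("%s_pow%d", period, as.integer(beta))
      a <- soft_adjacency(r, beta)
      d <- topological_overlap(a)
      p <- cut_modules(d, min_size = min_module_size,
                       static_frac = static_frac,
                       representation_id = rep_id, power = beta)
      if (beta > 1)
        p <- merge_by_eigengene(p, x_list[[period]], merge_height)
      partitions[[rep_id]] <- p
    }
  }
  list(correlations = correlations, partitions = partitions)
}
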