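#' Convert association P values to Z-scores
#'
#' `Z = qnorm(1 - P)`, the standard normal probability integral transform.
#' Under the null (no association) `Z` is standard normal; for risk genes
#' it is approximately normal with positive mean. P values are clamped to
#' `[1e-16, 1 - 1e-16]` before inversion (with a warning below the floor)
#' for numerical stability of the inverse CDF.
#'
#' @param p Numeric vector of P values in `(0, 1]`.
#' @return Z-scores, same length as `p`.
#' @export
p_to_z <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p > 1)))
    stop("P values must lie in (0, 1]")
  floor_p <- 1e-16
  if (any(!is.na(p) & p < floor_p))
    warning("P value(s) below 1e-16 clamped to the floor")
  p2 <- pmin(pmax(p, floor_p), 1 - floor_p)
  stats::qnorm(p2, lower.tail = FALSE)
}

#' Read a gene score table (TADA P values and dnLoF counts)
#'
#' Expects a tab-separated file with columns `gene`, `tada_p` and
#' optionally `dnlof`. Adds the Z-score column via [p_to_z()].
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `gene`, `p_value`, `z`, `dnlof`.
#' @export
load_gene_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "tada_p") %in% names(df)))
    stop("gene score table needs columns 'gene' and 'tada_p'")
  if (anyDuplicated(df$gene))
    stop("duplicate gene in score table: ",
         df$gene[duplicated(df$gene)][1L])
  gene_score_table(df$gene, df$tada_p,
                   if ("dnlof" %in% names(df)) df$dnlof else 0L)
}

#' Construct a gene score table from vectors
#' @param gene Gene symbols.
#' @param p_value TADA P values in `(0, 1]`.
#' @param dnlof De novo loss-of-function mutation counts (default 0).
#' @return `data.frame` with columns `gene`, `p_value`, `z`, `dnlof`.
#' @export
gene_score_table <- function(gene, p_value, dnlof = 0L) {
  data.frame(gene = as.character(gene),
             p_value = p_value,
             z = p_to_z(p_value),
             dnlof = as.integer(rep_len(dnlof, length(gene))),
             stringsAsFactors = FALSE)
}

#' Assign node-level scores from gene-level P values
#'
#' A node's score is the minimum P value over its member genes; the node
#' Z-score is `qnorm(1 - p_min)`. Member genes absent from the score table
#' are ignored in the minimum; a node with no scored gene at all keeps a
#' neutral `z = 0` (the null mean) and `p_min = NA`, so it stays a network
#' vertex without fabricating signal.
#'
#' @param g A `dawn_nodegraph`.
#' @param scores Gene score table from [gene_score_table()].
#' @return `data.frame` with columns `node`, `n_genes`, `p_min`, `z`,
#'   `scored`.
#' @export
score_nodes <- function(g, scores) {
  pv <- stats::setNames(scores$p_value, scores$gene)
  p_min <- vapply(g$nodes, function(genes) {
    ps <- pv[intersect(genes, names(pv))]
    ps <- ps[!is.na(ps)]
    if (length(ps) == 0L) NA_real_ else min(ps)
  }, numeric(1))
  n_unscored <- sum(is.na(p_min))
  if (n_unscored > 0L)
    message(n_unscored, " node(s) without any scored gene kept at z = 0")
  z <- ifelse(is.na(p_min), 0, p_to_z(ifelse(is.na(p_min), 0.5, p_min)))
  data.frame(node = names(g$nodes),
             n_genes = lengths(g$nodes),
             p_min = p_min,
             z = z,
             scored = !is.na(p_min),
             stringsAsFactors = FALSE,
             row.names = NULL)
}
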