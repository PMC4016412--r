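#' Validation scores by signal-removal cross-validation
#'
#' Probes the robustness of the initial `q <= q_threshold` gene set. Per
#' iteration a random fraction of those genes has its genetic signal
#' replaced by a null draw (`p ~ Uniform(0, 1)`, the network left intact)
#' and the scoring stages are re-run on the prepared network. A gene's
#' validation score is the fraction of iterations, among those in which
#' its own signal was retained, in which it stayed in the updated
#' `q <= q_threshold` list. Scores below 0.9 are conventionally flagged
#' non-robust.
#'
#' @param prepared A `dawn_prepared` network.
#' @param scores Gene score table.
#' @param config A `dawn_config`.
#' @param n_iter Number of iterations (default 100; fewer than 10 warns).
#' @param frac_removed Fraction of the initial set whose signal is
#'   removed per iteration (default 0.10).
#' @param seed Integer seed.
#' @return `data.frame` with columns `gene`, `score`, `n_retained` (the
#'   per-gene denominator).
#' @export
validation_scores <- function(prepared, scores, config = prepared$config,
                              n_iter = 100L, frac_removed = 0.10,
                              seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be at least 1")
  if (n_iter < 10L) warning("n_iter < 10: validation scores are unstable")
  base <- dawn_score(prepared, scores, config)
  initial <- base$combined$gene[base$combined$q_min <= config$q_threshold]
  if (length(initial) == 0L)
    return(data.frame(gene = character(0), score = numeric(0),
                      n_retained = integer(0)))
  retained <- stats::setNames(integer(length(initial)), initial)
  present <- retained
  n_remove <- max(1L, round(frac_removed * length(initial)))
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    removed <- sample(initial, n_remove)
    sc <- scores
    idx <- match(removed, sc$gene)
    sc$p_value[idx] <- stats::runif(n_remove)
    sc$z <- p_to_z(sc$p_value)
    res <- dawn_score(prepared, sc, config)
    updated <- res$combined$gene[res$combined$q_min <= config$q_threshold]
    kept <- setdiff(initial, removed)
    retained[kept] <- retained[kept] + 1L
    present[intersect(kept, updated)] <-
      present[intersect(kept, updated)] + 1L
  }
  data.frame(gene = initial,
             score = ifelse(retained > 0, present / retained, NA_real_),
             n_retained = unname(retained),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dilution permutation experiments on the node graph
#'
#' Probes how screening performance depends on the association signal and
#' on its clustering, by permuting node-level P values on one prepared
#' representation. Experiment `"I"` (diluting signals) swaps the P values
#' of a proportion `l` of nodes with `P <= p_split` against randomly
#' chosen nodes with `P > p_split`, separating small P values from their
#' genes. Experiment `"II"` (diluting clustering) swaps entire nodes --
#' P value and gene content -- relocating signal-bearing genes randomly
#' in the network and destroying the co-location of signal. After each
#' permutation the HMRF is refitted and two outcomes are recorded: the
#' number of screened-in genes carrying at least one dnLoF mutation, and
#' the fitted interaction parameter `c`.
#'
#' @param prepared A `dawn_prepared` network.
#' @param scores Gene score table (source of P values and dnLoF counts).
#' @param mode `"I"` or `"II"`.
#' @param l Dilution proportions (default `c(0.2, 0.4, 0.6, 0.8, 1)`).
#' @param n_rep Replicates per level (default 20).
#' @param config A `dawn_config`.
#' @param rep_index Which representation to use (default 1).
#' @param p_split Node P value split point (default 0.1).
#' @param seed Integer seed.
#' @return `data.frame` with columns `mode`, `l`, `rep`,
#'   `n_dnlof_detected`, `c_hat`.
#' @export
dilution_experiment <- function(prepared, scores, mode = c("I", "II"),
                                l = c(0.2, 0.4, 0.6, 0.8, 1),
                                n_rep = 20L, config = prepared$config,
                                rep_index = 1L, p_split = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  rep_obj <- prepared$representations[[rep_index]]
  graph <- rep_obj$graph
  ns0 <- score_nodes(graph, scores)
  hot <- which(!is.na(ns0$p_min) & ns0$p_min <= p_split)
  cold <- which(!is.na(ns0$p_min) & ns0$p_min > p_split)
  dn <- stats::setNames(scores$dnlof, scores$gene)
  run_one <- function(ns, genemap) {
    fit <- fit_hmrf(graph, ns, seed = config$seed, init_p = config$init_p)
    called <- names(fit$posteriors)[fit$posteriors >=
                                      config$posterior_threshold]
    genes <- unlist(genemap[called], use.names = FALSE)
    hit <- dn[intersect(genes, names(dn))]
    list(n = sum(hit >= 1L, na.rm = TRUE), c_hat = fit$c)
  }
  out <- list()
  set.seed(seed)
  for (lv in l) {
    k <- round(lv * length(hot))
    if (k > length(cold))
      stop(sprintf("need %d nodes with P > %g but only %d available",
                   k, p_split, length(cold)))
    for (rp in seq_len(n_rep)) {
      ns <- ns0
      genemap <- graph$nodes
      if (k > 0L) {
        sel_hot <- sample(hot, k)
        sel_cold <- sample(cold, k)
        ns$p_min[c(sel_hot, sel_cold)] <- ns0$p_min[c(sel_cold, sel_hot)]
        ns$z[c(sel_hot, sel_cold)] <- ns0$z[c(sel_cold, sel_hot)]
        if (mode == "II")
          genemap[c(sel_hot, sel_cold)] <-
            graph$nodes[c(sel_cold, sel_hot)]
      }
      r1 <- run_one(ns, genemap)
      out[[length(out) + 1L]] <- data.frame(mode = mode, l = lv, rep = rp,
                                            n_dnlof_detected = r1$n,
                                            c_hat = r1$c_hat)
    }
  }
  do.call(rbind, out)
}
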