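#' Pipeline configuration
#'
#' Collects every tunable of the screen-and-clean pipeline with the
#' published defaults: edge threshold `|r| > 0.7`, multi-gene cluster cut
#' `|r| = 0.75`, posterior screening threshold 0.5, FDR threshold 0.05,
#' network-score thresholds `r_min = 0.7` / `z_min = 1.2`, soft powers
#' `{1, 6}`, minimum module size 30 and eigengene merge height 0.15.
#'
#' @param edge_threshold,multinode_cut,posterior_threshold,q_threshold
#'   Core thresholds (see above).
#' @param r_min,z_min Network-score thresholds.
#' @param powers Soft powers for the representations.
#' @param min_module_size,merge_height,static_frac Module detection
#'   parameters.
#' @param min_stratum Exclusive node-size bound for FDR strata.
#' @param init_p HMRF label initialisation threshold.
#' @param robust_min Minimum validation score for a robust call.
#' @param seed Integer seed used by every stochastic stage.
#' @return A validated `dawn_config` list.
#' @export
dawn_config <- function(edge_threshold = 0.7, multinode_cut = 0.75,
                        posterior_threshold = 0.5, q_threshold = 0.05,
                        r_min = 0.7, z_min = 1.2, powers = c(1, 6),
                        min_module_size = 30, merge_height = 0.15,
                        static_frac = 0.99, min_stratum = 10L,
                        init_p = 0.05, robust_min = 0.9, seed = 1L) {
  cfg <- list(edge_threshold = edge_threshold, multinode_cut = multinode_cut,
              posterior_threshold = posterior_threshold,
              q_threshold = q_threshold, r_min = r_min, z_min = z_min,
              powers = powers, min_module_size = min_module_size,
              merge_height = merge_height, static_frac = static_frac,
              min_stratum = min_stratum, init_p = init_p,
              robust_min = robust_min, seed = as.integer(seed))
  if (cfg$multinode_cut <= cfg$edge_threshold)
    stop("multinode_cut must exceed edge_threshold")
  if (cfg$posterior_threshold < 0 || cfg$posterior_threshold > 1)
    stop("posterior_threshold must lie in [0, 1]")
  if (cfg$q_threshold < 0 || cfg$q_threshold > 1)
    stop("q_threshold must lie in [0, 1]")
  if (cfg$merge_height < 0 || cfg$merge_height >= 1)
    stop("merge_height must lie in [0, 1)")
  structure(cfg, class = "dawn_config")
}

#' Prepare the network representations of the expression data
#'
#' Runs everything that depends on expression only: correlations, module
#' partitions per period x power, multi-gene node collapsing and the
#' thresholded node adjacency. The result can be re-scored cheaply with
#' different gene score tables, which the robustness and dilution
#' experiments exploit.
#'
#' @param x_list Named list of expression matrices (one per period).
#' @param config A `dawn_config`.
#' @return A `dawn_prepared` list with `correlations` and
#'   `representations` (each with `id`, `period`, `partition`, `graph`).
#' @export
dawn_prepare <- function(x_list, config = dawn_config()) {
  if (!is.list(x_list)) x_list <- list(period1 = x_list)
  reps <- build_representations(x_list, powers = config$powers,
                                min_module_size = config$min_module_size,
                                merge_height = config$merge_height,
                                static_frac = config$static_frac)
  representations <- list()
  for (period in names(x_list)) {
    r <- reps$correlations[[period]]
    for (beta in config$powers) {
      id <- sprintf("%s_pow%d", period, as.integer(beta))
      p <- reps$partitions[[id]]
      g <- collapse_multinodes(r, p, cut = config$multinode_cut)
      g <- build_adjacency(g, r, threshold = config$edge_threshold)
      representations[[id]] <- list(id = id, period = period,
                                    partition = p, graph = g)
    }
  }
  structure(list(correlations = reps$correlations,
                 representations = representations,
                 config = config),
            class = "dawn_prepared")
}

#' Score a prepared network with a gene score table
#'
#' Runs the genetics-dependent stages on an already prepared network: node
#' scores, HMRF screening and nASD calls per representation, stratified
#' mixture FDR, the minimum-FDR consensus across representations, and
#' network scores (computed on the elementwise maximum `|r|` across
#' periods).
#'
#' @param prepared A `dawn_prepared` object.
#' @param scores Gene score table.
#' @param config A `dawn_config` (defaults to the one used to prepare).
#' @return A `dawn_result` list; see [run_dawn()].
#' @export
dawn_score <- function(prepared, scores, config = prepared$config) {
  fits <- list(); screens <- list(); qtables <- list()
  for (rep in prepared$representations) {
    ns <- score_nodes(rep$graph, scores)
    fit <- fit_hmrf(rep$graph, ns, seed = config$seed,
                    init_p = config$init_p)
    screen <- call_nasd(fit, rep$graph, config$posterior_threshold)
    fits[[rep$id]] <- fit
    screens[[rep$id]] <- screen
    qtables[[rep$id]] <- stratified_q(screen, rep$graph, scores,
                                      min_stratum = config$min_stratum,
                                      seed = config$seed)
  }
  combined <- combine_representations(qtables,
                                      q_threshold = config$q_threshold)
  rmax <- abs(prepared$correlations[[1L]])
  for (r in prepared$correlations[-1L]) rmax <- pmax(rmax, abs(r))
  net <- network_score(rmax, scores, r_min = config$r_min,
                       z_min = config$z_min)
  nasd_genes <- sort(unique(unlist(lapply(screens, `[[`, "nasd_genes"))))
  gene_table <- data.frame(gene = scores$gene,
                           p_value = scores$p_value,
                           z = scores$z,
                           dnlof = scores$dnlof,
                           nASD = scores$gene %in% nasd_genes,
                           network_score = unname(net[match(scores$gene,
                                                            names(net))]),
                           stringsAsFactors = FALSE)
  gene_table <- merge(gene_table,
                      combined[, c("gene", "q_min", "rASD")],
                      by = "gene", all.x = TRUE, sort = TRUE)
  gene_table$rASD[is.na(gene_table$rASD)] <- FALSE
  structure(list(config = config,
                 fits = fits, screens = screens, qtables = qtables,
                 combined = combined,
                 network_scores = net,
                 gene_table = gene_table,
                 nasd_genes = nasd_genes,
                 rasd_genes = combined$gene[combined$rASD]),
            class = "dawn_result")
}

#' Run the full screen-and-clean pipeline
#'
#' Convenience wrapper: [dawn_prepare()] on the expression periods, then
#' [dawn_score()] with the gene score table, then (optionally) the
#' validation-score robustness filter, which re-runs the scoring stages
#' with 10% of the initial signals removed per iteration and drops genes
#' whose validation score falls below `config$robust_min`.
#'
#' @param x_list Named list of expression matrices, or a single matrix.
#' @param scores Gene score table (see [gene_score_table()]).
#' @param config A `dawn_config`.
#' @param validate If `TRUE`, apply the robustness filter.
#' @param n_iter Validation iterations when `validate = TRUE`
#'   (default 100).
#' @return A `dawn_result` with elements `gene_table` (per-gene summary),
#'   `nasd_genes`, `rasd_genes`, per-representation `fits`, `screens` and
#'   `qtables`, the consensus `combined` table, and `network_scores`.
#' @export
run_dawn <- function(x_list, scores, config = dawn_config(),
                     validate = FALSE, n_iter = 100L) {
  prepared <- dawn_prepare(x_list, config)
  res <- dawn_score(prepared, scores, config)
  if (validate) {
    vs <- validation_scores(prepared, scores, config, n_iter = n_iter,
                            seed = config$seed)
    res$validation <- vs
    res$combined <- combine_representations(res$qtables, validation = vs,
                                            q_threshold = config$q_threshold,
                                            robust_min = config$robust_min)
    res$rasd_genes <- res$combined$gene[res$combined$rASD]
    res$gene_table$rASD <- res$gene_table$gene %in% res$rasd_genes
  }
  res$prepared <- prepared
  res
}

#' @export
print.dawn_result <- function(x, ...) {
  cat(sprintf("dawn_result: %d representations, %d nASD genes, %d rASD genes\n",
              length(x$fits), length(x$nasd_genes), length(x$rasd_genes)))
  for (id in names(x$fits))
    cat(sprintf("  %s: c = %.3f, mu = %.3f, %d nASD nodes\n", id,
                x$fits[[id]]$c, x$fits[[id]]$mu,
                length(x$screens[[id]]$nasd_nodes)))
  invisible(x)
}
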