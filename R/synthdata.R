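#' Default block layout for synthetic expression
#'
#' Ten correlation blocks of 50 genes: three tight blocks (rho = 0.81,
#' which collapse into multi-gene nodes at the 0.75 cut), four
#' intermediate blocks (rho = 0.72, connected mostly as single-gene
#' nodes at the 0.7 edge threshold) and three loose blocks (rho = 0.5,
#' modules with few edges). The remaining genes are independent noise.
#'
#' @return `data.frame` with columns `size` and `rho`.
#' @export
default_blocks <- function() {
  data.frame(size = rep(50L, 10L),
             rho = c(rep(0.81, 3), rep(0.72, 4), rep(0.5, 3)))
}

#' Generate block-correlated synthetic expression
#'
#' Each block is drawn from a one-factor model
#' `x = sqrt(rho) * f_block + sqrt(1 - rho) * eps`, so the expected
#' within-block correlation equals `rho` and the block eigengene is the
#' shared factor. Genes outside any block are independent N(0, 1) noise.
#'
#' @param n_genes Total number of genes (default 1000).
#' @param blocks `data.frame` with columns `size`, `rho` (default
#'   [default_blocks()]); sizes must sum to at most `n_genes`, `rho` in
#'   `[0, 1)`.
#' @param n_replicates Number of replicate samples (default 120, between
#'   the 107 and 140 replicates of the two mid-fetal brain windows the
#'   generator emulates).
#' @param seed Integer seed.
#' @return List with `expression` (genes x replicates matrix) and `truth`
#'   (a `dawn_synth` list recording `block_of_gene`, `blocks`, and the
#'   generator parameters).
#' @export
generate_expression <- function(n_genes = 1000L, blocks = default_blocks(),
                                n_replicates = 120L, seed = 1L) {
  if (any(blocks$rho < 0 | blocks$rho >= 1))
    stop("block rho must lie in [0, 1)")
  if (sum(blocks$size) > n_genes)
    stop("block sizes exceed n_genes")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  x <- matrix(stats::rnorm(n_genes * n_replicates), n_genes, n_replicates,
              dimnames = list(genes, sprintf("s%03d", seq_len(n_replicates))))
  block_of_gene <- integer(n_genes)
  at <- 1L
  for (bi in seq_len(nrow(blocks))) {
    sz <- blocks$size[bi]; rho <- blocks$rho[bi]
    idx <- at:(at + sz - 1L)
    f <- stats::rnorm(n_replicates)
    x[idx, ] <- sqrt(rho) * matrix(f, sz, n_replicates, byrow = TRUE) +
      sqrt(1 - rho) * x[idx, ]
    block_of_gene[idx] <- bi
    at <- at + sz
  }
  truth <- structure(list(block_of_gene = stats::setNames(block_of_gene,
                                                          genes),
                          blocks = blocks, n_genes = n_genes,
                          n_replicates = n_replicates, seed = seed),
                     class = "dawn_synth")
  list(expression = x, truth = truth)
}

#' Plant gene-level association signal over a synthetic truth
#'
#' Risk genes receive `z ~ N(mu_true, 1)` and null genes `z ~ N(0, 1)`;
#' `p = 1 - pnorm(z)`. With `clustering = "within-block"` the risk genes
#' part-fill (`fill_frac` of each) randomly chosen tight correlation
#' blocks -- blocks with `rho >= 0.7`, the ones that materialise as
#' connected hot spots in the thresholded network; planting in looser
#' blocks would be indistinguishable from scattering. `"scattered"`
#' places risk genes uniformly, the contrast the dilution experiments
#' probe. De novo LoF carrier status is
#' drawn so that about half of the carriers are true risk genes,
#' emulating the empirical rate at which dnLoF-hit genes are true risk
#' genes.
#'
#' @param truth A `dawn_synth` truth from [generate_expression()].
#' @param frac_risk Fraction of genes that are risk genes (default 0.05).
#' @param mu_true Alternative Z mean, > 0 unless simulating a pure null
#'   (default 3).
#' @param clustering `"within-block"` or `"scattered"`.
#' @param seed Integer seed.
#' @param carrier_rate Fraction of risk genes drawn as dnLoF carriers
#'   (default 0.2; an equal number of null carriers is drawn).
#' @param fill_frac Fraction of each chosen block occupied by risk genes
#'   under within-block placement (default 0.5, so strata mix risk and
#'   null genes).
#' @return List with `scores` (gene score table), `risk_genes`, and
#'   `is_risk` (named logical vector).
#' @export
plant_genetic_signal <- function(truth, frac_risk = 0.05, mu_true = 3,
                                 clustering = c("within-block", "scattered"),
                                 seed = 1L, carrier_rate = 0.2,
                                 fill_frac = 0.5) {
  clustering <- match.arg(clustering)
  stopifnot(inherits(truth, "dawn_synth"))
  if (frac_risk <= 0 || frac_risk >= 1) stop("frac_risk must be in (0, 1)")
  if (mu_true < 0) stop("mu_true must be non-negative")
  set.seed(seed)
  genes <- names(truth$block_of_gene)
  n <- length(genes)
  n_risk <- max(1L, round(frac_risk * n))
  if (clustering == "within-block") {
    tight <- which(truth$blocks$rho >= 0.7)
    if (length(tight) == 0L) tight <- seq_len(nrow(truth$blocks))
    risk <- character(0)
    for (bi in sample(tight)) {
      bg <- genes[truth$block_of_gene == bi]
      cap <- ceiling(fill_frac * length(bg))
      take <- min(cap, n_risk - length(risk))
      risk <- c(risk, bg[seq_len(take)])
      if (length(risk) >= n_risk) break
    }
    if (length(risk) < n_risk)     # more risk genes than block capacity
      risk <- c(risk, sample(setdiff(genes, risk), n_risk - length(risk)))
  } else {
    risk <- sample(genes, n_risk)
  }
  is_risk <- stats::setNames(genes %in% risk, genes)
  z <- stats::rnorm(n) + ifelse(is_risk, mu_true, 0)
  p <- stats::pnorm(z, lower.tail = FALSE)
  dnlof <- integer(n)
  n_carriers <- round(carrier_rate * n_risk)
  if (n_carriers > 0L) {
    risk_carriers <- sample(which(is_risk), n_carriers)
    null_carriers <- sample(which(!is_risk), n_carriers)
    dnlof[risk_carriers] <- 1L + stats::rbinom(n_carriers, 1L, 0.2)
    dnlof[null_carriers] <- 1L
  }
  scores <- gene_score_table(genes, p, dnlof)
  list(scores = scores, risk_genes = sort(risk), is_risk = is_risk)
}

#' One-call desk-scale synthetic scenario
#'
#' Generates one or two expression periods sharing the same block
#' structure (independent replicate draws per period, as two overlapping
#' developmental windows would give) plus a planted gene score table.
#'
#' @param seed Integer seed.
#' @param periods Named integer vector of replicate counts per period
#'   (default `c(p35 = 107, p46 = 140)`, the two windows' replicate
#'   counts).
#' @param n_genes,blocks,frac_risk,mu_true,clustering,carrier_rate Passed
#'   through to the generators.
#' @return List with `expression` (named list of matrices), `truth`,
#'   `scores`, `risk_genes`, `is_risk`.
#' @export
synth_scenario <- function(seed = 1L, periods = c(p35 = 107L, p46 = 140L),
                           n_genes = 1000L, blocks = default_blocks(),
                           frac_risk = 0.05, mu_true = 3,
                           clustering = "within-block", carrier_rate = 0.2) {
  x_list <- list()
  truth <- NULL
  for (i in seq_along(periods)) {
    gen <- generate_expression(n_genes, blocks, periods[[i]],
                               seed = seed + 1000L * i)
    x_list[[names(periods)[i]]] <- gen$expression
    truth <- gen$truth
  }
  sig <- plant_genetic_signal(truth, frac_risk, mu_true, clustering,
                              seed = seed)
  list(expression = x_list, truth = truth, scores = sig$scores,
       risk_genes = sig$risk_genes, is_risk = sig$is_risk)
}
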