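#' Fit a two-component Gaussian mixture to Z-scores
#'
#' `f(z) = pi0 * dnorm(z) + pi1 * dnorm(z, mu1, sigma1)` with the null
#' component fixed at N(0, 1), fitted by expectation-maximisation with
#' seeded multi-start. `pi0` estimates the fraction of null genes; the
#' alternative mean is constrained non-negative (risk shifts Z upward).
#'
#' @param z Numeric vector of Z-scores, length >= 5.
#' @param n_starts Number of EM restarts (default 10; the first start is
#'   deterministic, the rest randomised under `seed`).
#' @param seed Integer seed for the random restarts.
#' @param tol Convergence tolerance on the log-likelihood gain
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations per start (default 1000).
#' @param mu_min Lower bound on the alternative mean (default 1): an
#'   alternative component sitting within one null SD of zero is not
#'   identifiable from noise and would let a narrow component swallow
#'   tight null clusters. The screening model relaxes this to its own
#'   documented floor.
#' @param sigma_min Lower bound on the alternative SD (default 0.5),
#'   preventing collapse onto a few identical scores.
#' @return A `dawn_mixture` list: `pi0`, `mu1`, `sigma1`, `loglik`, `n`.
#' @export
fit_mixture <- function(z, n_starts = 10L, seed = 1L, tol = 1e-8,
                        max_iter = 1000L, mu_min = 1, sigma_min = 0.5) {
  z <- z[is.finite(z)]
  if (length(z) < 5L)
    stop("fit_mixture needs at least 5 scores; fall back to the pooled fit")
  if (stats::sd(z) == 0) {
    warning("degenerate input: all Z-scores identical; returning pi0 = 1")
    return(new_mixture(1, 0.1, 1, sum(stats::dnorm(z, log = TRUE)),
                       length(z)))
  }
  set.seed(seed)
  hi <- stats::quantile(z, 0.9, names = FALSE)
  starts <- list(list(pi0 = 0.9, mu1 = max(mu_min, 1, hi), sigma1 = 1))
  for (k in seq_len(max(0L, n_starts - 1L)))
    starts[[k + 1L]] <- list(pi0 = stats::runif(1, 0.3, 0.95),
                             mu1 = max(mu_min, stats::quantile(
                               z, stats::runif(1, 0.6, 0.99), names = FALSE)),
                             sigma1 = stats::runif(1, max(0.5, sigma_min), 2))
  best <- NULL
  for (st in starts) {
    fit <- em_mixture(z, st$pi0, st$mu1, st$sigma1, tol, max_iter,
                      mu_min, sigma_min)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

em_mixture <- function(z, pi0, mu1, sigma1, tol, max_iter,
                       mu_min = 1, sigma_min = 0.5) {
  n <- length(z)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d0 <- pi0 * stats::dnorm(z)
    d1 <- (1 - pi0) * stats::dnorm(z, mu1, sigma1)
    f <- d0 + d1
    ll <- sum(log(f))
    if (is.finite(ll) && ll - ll_old < tol && it > 1L) break
    ll_old <- ll
    w1 <- d1 / f
    sw <- sum(w1)
    if (sw < 1e-10) { pi0 <- 1; break }
    pi0 <- min(1, max(0, 1 - sw / n))
    mu1 <- max(mu_min, sum(w1 * z) / sw)
    sigma1 <- max(sigma_min, sqrt(sum(w1 * (z - mu1)^2) / sw))
  }
  d0 <- pi0 * stats::dnorm(z)
  d1 <- (1 - pi0) * stats::dnorm(z, mu1, sigma1)
  new_mixture(pi0, mu1, sigma1, sum(log(d0 + d1)), n)
}

new_mixture <- function(pi0, mu1, sigma1, loglik, n) {
  structure(list(pi0 = pi0, mu1 = mu1, sigma1 = sigma1,
                 loglik = loglik, n = n),
            class = "dawn_mixture")
}

#' @export
print.dawn_mixture <- function(x, ...) {
  cat(sprintf("dawn_mixture: pi0 = %.3f, mu1 = %.3f, sigma1 = %.3f (n = %d)\n",
              x$pi0, x$mu1, x$sigma1, x$n))
  invisible(x)
}

# local false discovery rate under a fitted two-group mixture
lfdr_mixture <- function(fit, z) {
  d0 <- fit$pi0 * stats::dnorm(z)
  d1 <- (1 - fit$pi0) * stats::dnorm(z, fit$mu1, fit$sigma1)
  pmin(1, d0 / (d0 + d1))
}

# tail-averaged local FDR: q_i = mean lfdr over stratum genes with
# z >= z_i, then made monotone non-increasing in z by raising the q of
# lower-z genes (conservative isotonic step; ties share one value)
tail_averaged_q <- function(z, lfdr) {
  ord <- order(z, decreasing = TRUE)
  cm <- cumsum(lfdr[ord]) / seq_along(ord)
  last_of_tie <- stats::ave(seq_along(ord), z[ord], FUN = max)
  q <- cummax(cm[last_of_tie])
  out <- numeric(length(z))
  out[ord] <- q
  out
}

#' Stratified mixture-model FDR over the screened genes
#'
#' Cleaning stage for one representation. Every screened-in (nASD)
#' multi-gene node with more than `min_stratum` genes defines its own
#' stratum: the mixture is fitted to that node's member Z-scores, so
#' signal-dense nodes gain power through a locally estimated risk
#' fraction. All remaining nASD genes (including small multi-gene nodes)
#' form one pooled stratum whose mixture is fitted to the entire set of
#' scored statistics -- not only to the screened-in genes, whose
#' selection on large `z` would bias the null fraction towards zero.
#' Within each stratum the q-value of a gene is the tail-averaged local
#' FDR, `q = mean(lfdr)` over stratum genes with `z` at least as large.
#' Genes without a score and genes not screened in are absent from the
#' table.
#'
#' @param screen A `dawn_screen` from [call_nasd()].
#' @param g The node graph.
#' @param scores Gene score table.
#' @param min_stratum Minimum node size (exclusive) for a node to form its
#'   own stratum (default 10).
#' @param seed Seed forwarded to [fit_mixture()].
#' @return `data.frame` with columns `gene`, `node`, `stratum`, `z`,
#'   `lfdr`, `q` and attribute `"representation_id"`.
#' @export
stratified_q <- function(screen, g, scores, min_stratum = 10L, seed = 1L) {
  zs <- stats::setNames(scores$z, scores$gene)
  rows <- list()
  pooled_genes <- character(0)
  large <- screen$nasd_nodes[lengths(g$nodes[screen$nasd_nodes]) >
                               min_stratum]
  for (nd in screen$nasd_nodes) {
    genes <- intersect(g$nodes[[nd]], names(zs))
    if (length(genes) == 0L) next
    if (nd %in% large && length(genes) >= 5L) {
      fit <- fit_mixture(zs[genes], seed = seed)
      lf <- lfdr_mixture(fit, zs[genes])
      rows[[nd]] <- data.frame(gene = genes, node = nd, stratum = nd,
                               z = unname(zs[genes]), lfdr = lf,
                               q = tail_averaged_q(zs[genes], lf),
                               stringsAsFactors = FALSE)
    } else {
      pooled_genes <- c(pooled_genes,
                        stats::setNames(genes, rep(nd, length(genes))))
    }
  }
  if (length(pooled_genes) > 0L) {
    zp <- zs[pooled_genes]
    fit <- fit_mixture(zs[!is.na(zs)], seed = seed)
    lf <- lfdr_mixture(fit, zp)
    rows[["pooled"]] <- data.frame(gene = unname(pooled_genes),
                                   node = names(pooled_genes),
                                   stratum = "pooled",
                                   z = unname(zp), lfdr = lf,
                                   q = tail_averaged_q(zp, lf),
                                   stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0L)
    data.frame(gene = character(0), node = character(0),
               stratum = character(0), z = numeric(0), lfdr = numeric(0),
               q = numeric(0), stringsAsFactors = FALSE)
  else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "representation_id") <- g$representation_id
  out
}

#' Combine q-value tables across representations (minimum FDR)
#'
#' The consensus q-value of a gene is the minimum q over the
#' representations in which it appears; rASD genes are those with
#' `q_min <= q_threshold` that additionally pass the robustness filter
#' (validation score >= `robust_min`) when validation scores are supplied.
#' Genes with no validation score are not filtered.
#'
#' @param tables List of q-value tables from [stratified_q()].
#' @param validation Optional `data.frame` with columns `gene`, `score`
#'   from [validation_scores()].
#' @param q_threshold FDR threshold (default 0.05).
#' @param robust_min Minimum validation score (default 0.9).
#' @return `data.frame` with one row per gene: per-representation `q_*`
#'   columns, `q_min`, `robust`, `rASD`.
#' @export
combine_representations <- function(tables, validation = NULL,
                                    q_threshold = 0.05, robust_min = 0.9) {
  if (length(tables) == 0L) stop("need at least one representation table")
  ids <- vapply(seq_along(tables), function(i) {
    id <- attr(tables[[i]], "representation_id")
    if (is.null(id)) id <- names(tables)[i]
    if (is.null(id) || is.na(id) || id == "") paste0("rep", i) else id
  }, character(1))
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  qm <- matrix(NA_real_, length(genes), length(tables),
               dimnames = list(genes, paste0("q_", ids)))
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    agg <- tapply(tb$q, tb$gene, min)       # gene may sit in two strata
    qm[names(agg), i] <- agg
  }
  q_min <- apply(qm, 1L, min, na.rm = TRUE)
  robust <- rep(TRUE, length(genes))
  if (!is.null(validation)) {
    sc <- validation$score[match(genes, validation$gene)]
    robust <- is.na(sc) | sc >= robust_min
  }
  data.frame(gene = genes, qm, q_min = q_min, robust = robust,
             rASD = q_min <= q_threshold & robust,
             stringsAsFactors = FALSE, row.names = NULL,
             check.names = FALSE)
}
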