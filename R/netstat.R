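#' Network score: genetic signal in a gene's co-expression neighbourhood
#'
#' `S_i = sum_{j != i} |r_ij| * z_j`, where both factors carry hard
#' thresholds: a term contributes 0 unless `|r_ij| >= r_min` (default
#' 0.7) and `z_j >= z_min` (default 1.2). A high score means the gene sits
#' among strongly co-expressed neighbours that themselves carry
#' association signal.
#'
#' @param r Correlation matrix over genes.
#' @param scores Gene score table; genes absent from it contribute
#'   nothing (their `z` is below any positive threshold).
#' @param r_min,z_min Hard thresholds (defaults 0.7 and 1.2).
#' @return Named numeric vector `S` over the genes of `r`.
#' @export
network_score <- function(r, scores, r_min = 0.7, z_min = 1.2) {
  genes <- rownames(r)
  z <- scores$z[match(genes, scores$gene)]
  z[is.na(z) | z < z_min] <- 0
  a <- abs(r)
  a[is.na(a) | a < r_min] <- 0
  diag(a) <- 0
  stats::setNames(drop(a %*% z), genes)
}

#' Permutation test of within-list connectivity
#'
#' Tests whether a target gene list is more densely interconnected in the
#' co-expression network than random lists of equal size drawn from a
#' pool, matched on a per-gene mutability covariate (based on, e.g., gene
#' size and GC content) by decile binning. The statistic is the mean
#' per-gene count of within-list partners with `|r| > r_threshold`; the
#' permutation P value is `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param target Character vector of genes (must be contained in `pool`).
#' @param pool Character vector of candidate genes.
#' @param mutability Numeric mutability covariate, parallel to `pool`.
#' @param r Correlation matrix covering the pool.
#' @param n_perm Number of permutations (must be >= 1).
#' @param seed Integer seed.
#' @param r_threshold Edge threshold (default 0.7).
#' @param n_bins Number of mutability bins (default 10, i.e. deciles).
#' @return List with `observed`, `p_value`, `null_stats`.
#' @export
connectivity_test <- function(target, pool, mutability, r, n_perm = 1000L,
                              seed = 1L, r_threshold = 0.7, n_bins = 10L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (!all(target %in% pool)) stop("target list must be contained in pool")
  if (length(mutability) != length(pool))
    stop("mutability must be parallel to pool")
  conn_stat <- function(genes) {
    a <- abs(r[genes, genes]) > r_threshold
    diag(a) <- FALSE
    mean(rowSums(a))
  }
  brk <- unique(stats::quantile(mutability, probs = seq(0, 1,
                                                        length.out = n_bins + 1)))
  bins <- cut(mutability, breaks = brk, include.lowest = TRUE,
              labels = FALSE)
  names(bins) <- pool
  need <- table(bins[target])
  have <- table(bins)
  if (any(need > have[names(need)]))
    stop("pool too small for mutability-matched sampling in some bin")
  set.seed(seed)
  observed <- conn_stat(target)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    draw <- unlist(lapply(names(need), function(bn) {
      sample(pool[bins == as.integer(bn)], need[[bn]])
    }), use.names = FALSE)
    conn_stat(draw)
  }, numeric(1))
  list(observed = observed,
       p_value = (1 + sum(null_stats >= observed)) / (n_perm + 1),
       null_stats = null_stats)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' pool of `N` containing `K` marked items. Evaluated as an exact sum of
#' binomial-coefficient terms on the log scale.
#'
#' @param N Pool size.
#' @param K Number of marked items in the pool.
#' @param n Number drawn.
#' @param k Observed number of marked items among the drawn.
#' @return Upper-tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(n, K))
    stop("inconsistent hypergeometric counts")
  if (k <= max(0, n - (N - K))) return(1)
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

#' One-sided Fisher exact test with conditional-MLE odds ratio
#'
#' For a 2x2 table `[[a, b], [c, d]]`, the one-sided
#' (alternative "greater") exact P value is the hypergeometric upper tail
#' on the fixed margins. The odds ratio is the conditional maximum
#' likelihood estimate under the noncentral hypergeometric likelihood
#' (not the sample cross-product ratio), found by one-dimensional
#' maximisation over the log odds ratio; it is infinite (or zero) when
#' the observed cell sits at the boundary of its support.
#'
#' @param tab 2x2 integer matrix, or a length-4 vector `(a, b, c, d)` in
#'   row-major order.
#' @return List with `p_value` and `odds_ratio`.
#' @export
fisher_exact_test <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (any(tab < 0)) stop("negative cell count")
  if (sum(tab) == 0) stop("all-zero table")
  a <- tab[1, 1]
  N <- sum(tab); K <- sum(tab[1, ]); n <- sum(tab[, 1])
  p <- hypergeom_tail(N, K, n, a)
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  support <- lo:hi
  lw <- lchoose(K, support) + lchoose(N - K, n - support)
  or <- if (a >= hi) Inf else if (a <= lo) 0 else {
    negll <- function(theta) {                  # theta = log odds ratio
      lt <- lw + support * theta
      mx <- max(lt)
      -(a * theta - (mx + log(sum(exp(lt - mx)))))
    }
    opt <- stats::optimize(negll, interval = c(-36, 36), tol = 1e-10)
    exp(opt$minimum)
  }
  list(p_value = p, odds_ratio = or)
}

#' Describe an observed de novo mutation process
#'
#' @param trios_obs Number of sequenced trios.
#' @param events_obs Number of de novo LoF events observed.
#' @param unique_obs Number of unique genes hit.
#' @param multi_obs Number of genes hit more than once.
#' @return A validated `dawn_denovo` list; `single_obs` is derived.
#' @export
denovo_model <- function(trios_obs = 1043L, events_obs = 143L,
                         unique_obs = 130L, multi_obs = 9L) {
  if (events_obs < unique_obs)
    stop("events must be at least the number of unique genes")
  if (multi_obs > unique_obs) stop("multi-hit genes cannot exceed unique")
  structure(list(trios_obs = trios_obs, events_obs = events_obs,
                 unique_obs = unique_obs, multi_obs = multi_obs,
                 single_obs = unique_obs - multi_obs),
            class = "dawn_denovo")
}

# negative-binomial occupancy probabilities for a gamma-heterogeneous
# Poisson process: per-gene counts ~ NB(size alpha, mean nu)
occupancy_probs <- function(nu, alpha) {
  p0 <- (alpha / (alpha + nu))^alpha
  p1 <- alpha * (nu / (alpha + nu)) * p0
  c(p0 = p0, p1 = p1, p2plus = 1 - p0 - p1)
}

#' Extrapolate de novo LoF event occupancy to a larger trio sample
#'
#' Expected event counts scale linearly in the number of trios. Unique
#' and multi-hit gene counts are extrapolated two ways: (a) linear
#' scaling of each observed count, and (b) a gamma-heterogeneous Poisson
#' occupancy model (per-gene counts negative binomial) whose effective
#' gene pool and rate heterogeneity are calibrated by least squares so the
#' model reproduces the observed unique/multi split at the observed event
#' total, then evaluated at the scaled total. When
#' `trios_target == trios_obs` the observed counts are returned unchanged.
#'
#' @param m A `dawn_denovo` model from [denovo_model()].
#' @param trios_target Target number of trios (> 0).
#' @return List with `trios_target`, `events` (linear expectation),
#'   `linear` and `occupancy` count breakdowns, and `calibration`
#'   (`G`, `alpha`).
#' @export
extrapolate_denovo <- function(m, trios_target) {
  stopifnot(inherits(m, "dawn_denovo"))
  if (trios_target <= 0) stop("trios_target must be positive")
  scale <- trios_target / m$trios_obs
  events <- m$events_obs * scale
  linear <- list(events = events, unique = m$unique_obs * scale,
                 multi = m$multi_obs * scale,
                 single = m$single_obs * scale)
  obj <- function(par) {
    G <- exp(par[1L]); alpha <- min(1e6, exp(par[2L]))
    pr <- occupancy_probs(m$events_obs / G, alpha)
    (G * (1 - pr["p0"]) / m$unique_obs - 1)^2 +
      (G * pr["p2plus"] / max(1, m$multi_obs) - 1)^2
  }
  opt <- stats::optim(c(log(800), log(10)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  G <- exp(opt$par[1L]); alpha <- min(1e6, exp(opt$par[2L]))
  if (abs(scale - 1) < .Machine$double.eps^0.5) {
    occ <- list(events = m$events_obs, unique = m$unique_obs,
                multi = m$multi_obs, single = m$single_obs)
  } else {
    pr <- occupancy_probs(m$events_obs * scale / G, alpha)
    uq <- G * (1 - pr[["p0"]]); mu2 <- G * pr[["p2plus"]]
    occ <- list(events = events, unique = uq, multi = mu2,
                single = uq - mu2)
  }
  list(trios_target = trios_target, events = events,
       linear = linear, occupancy = occ,
       calibration = list(G = G, alpha = alpha))
}

#' A priori probability that a true risk gene is hit
#'
#' @param true_gene_hits Expected number of true risk genes with at least
#'   one de novo LoF hit.
#' @param n_true_genes Assumed number of true risk genes.
#' @return `true_gene_hits / n_true_genes`.
#' @export
prior_hit_probability <- function(true_gene_hits, n_true_genes) {
  if (n_true_genes <= 0) stop("n_true_genes must be positive")
  true_gene_hits / n_true_genes
}
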