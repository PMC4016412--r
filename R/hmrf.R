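#' Hidden Markov random field screening of the node graph
#'
#' Fits the screening-stage model: hidden binary risk labels `I` on the
#' node graph with an Ising prior
#' `P(I) ~ exp(b * sum_i I_i + c * sum_(i,j) in E I_i I_j)` and Gaussian
#' emissions `Z_i | I_i = 0 ~ N(0, 1)`, `Z_i | I_i = 1 ~ N(mu, sigma^2)`
#' (`mu > 0`). `b` is the external field (how common risk labels are per
#' se) and `c` the interaction (how strongly risk labels cluster on the
#' graph; positive `c` means clustered signal).
#'
#' Estimation alternates (1) iterative-conditional-modes (ICM) sweeps that
#' set each label to its conditional posterior mode given its neighbours,
#' and (2) `(b, c)` updates maximising the logistic pseudo-likelihood of
#' the labels given neighbour sums (a logistic regression of `I_i` on
#' `m_i = sum_(j in N(i)) I_j`). The emission parameters `(mu, sigma)`
#' are, by default (`emission = "mixture"`), estimated once from the
#' marginal two-group mixture of the node Z-scores via [fit_mixture()]:
#' the marginal law of each `z` is exactly that mixture regardless of the
#' label dependence, so this composite-likelihood estimate is free of the
#' upward truncation bias that plagues hard-label updates (which average
#' `z` over currently labelled nodes only; that classic scheme remains
#' available as `emission = "icm"` and is the automatic fallback with
#' fewer than 5 scored nodes). Both floors `mu >= 0.1` and
#' `sigma >= 0.5` apply, preventing emission collapse onto degenerate
#' one-point clusters. Labels are initialised at `I_i = 1` iff the node
#' P value is at most `init_p`. The loop stops when the label vector is
#' unchanged across an outer iteration. Within every ICM sweep the joint
#' (unnormalised) log posterior is non-decreasing; per-sweep values are
#' kept in `sweep_logpost`.
#'
#' Pseudo-likelihood evaluated at the converged ICM labels over-states the
#' clustering when classification is sharp (the labels are the model's own
#' smoothed modes; with clean hot spots the logistic fit separates and `c`
#' diverges). The reported `(b, c)` are therefore refined by default via a
#' short Monte-Carlo EM: Gibbs sampling of the labels given `z` at the
#' current parameters, prior pseudo-likelihood maximised on the sampled
#' (stochastic, hence non-separated) configurations, estimates averaged
#' over the late outer iterations. The refinement is seeded and
#' deterministic given `seed`; posteriors are computed at the refined
#' parameters. Set `refine = FALSE` (or `fix_c`) to keep the raw ICM
#' pseudo-likelihood estimates.
#'
#' @param g A `dawn_nodegraph` with adjacency.
#' @param s Node score table from [score_nodes()].
#' @param seed Integer seed (used only when `gibbs_samples > 0`).
#' @param max_iter Maximum outer iterations (default 100).
#' @param init_p Initialisation threshold on the node P value
#'   (default 0.05).
#' @param fix_c Optional fixed value for the interaction parameter; `0`
#'   reduces the model to the independent two-group mixture classifier.
#' @param emission `"mixture"` (default) or `"icm"`; see Details.
#' @param refine Refine `(b, c)` by Monte-Carlo EM (default `TRUE`;
#'   ignored when `fix_c` is given).
#' @param refine_outer,refine_sweeps Monte-Carlo EM budget: outer
#'   iterations (default 8; the last half are averaged) and Gibbs sweeps
#'   per outer iteration (default 30; the last third are used for the
#'   pseudo-likelihood fit).
#' @param gibbs_samples If positive, additionally compute Gibbs-averaged
#'   posteriors over this many sweeps at the fitted parameters (stored as
#'   `posteriors_gibbs`); the default 0 uses the ICM plug-in posterior.
#' @return A `dawn_hmrf` object: list with `b`, `c`, `mu`, `sigma`,
#'   `labels`, `posteriors`, `iterations`, `converged`, `sweep_logpost`.
#' @export
fit_hmrf <- function(g, s, seed = 1L, max_iter = 100L, init_p = 0.05,
                     fix_c = NULL, gibbs_samples = 0L,
                     emission = c("mixture", "icm"), refine = TRUE,
                     refine_outer = 8L, refine_sweeps = 30L) {
  stopifnot(inherits(g, "dawn_nodegraph"), !is.null(g$adjacency))
  emission <- match.arg(emission)
  nodes <- names(g$nodes)
  s <- s[match(nodes, s$node), , drop = FALSE]
  z <- s$z
  n <- length(z)
  nb <- apply(g$adjacency, 1L, which, simplify = FALSE)
  I <- !is.na(s$p_min) & s$p_min <= init_p
  if (!any(I)) {
    warning("no node has P <= ", init_p, "; HMRF degenerates to all-null")
    fit <- new_hmrf(b = -10, c = 0, mu = 0.1, sigma = 1,
                    labels = I, iterations = 0L, converged = TRUE,
                    sweep_logpost = list(), nodes = nodes)
    fit$posteriors <- posterior_probabilities(fit, g, s)
    return(fit)
  }
  z_scored <- z[s$scored]
  fixed_emission <- emission == "mixture" && length(z_scored) >= 5L &&
    stats::sd(z_scored) > 0
  mpar <- if (fixed_emission) {
    mx <- fit_mixture(z_scored, seed = seed, mu_min = 0.1)
    list(mu = max(0.1, mx$mu1), sigma = max(0.5, mx$sigma1))
  } else update_emission(z, I)
  ipar <- update_ising(I, neighbor_sums(nb, I), fix_c)
  sweep_logpost <- list()
  iterations <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    I_old <- I
    llr <- stats::dnorm(z, mpar$mu, mpar$sigma, log = TRUE) -
      stats::dnorm(z, log = TRUE)
    res <- icm_sweeps(I, nb, ipar$b, ipar$c, llr, z, mpar)
    I <- res$I
    sweep_logpost[[iter]] <- res$lp
    if (!fixed_emission) mpar <- update_emission(z, I)
    ipar <- update_ising(I, neighbor_sums(nb, I), fix_c)
    if (identical(I, I_old)) { converged <- TRUE; break }
  }
  if (refine && is.null(fix_c)) {
    llr <- stats::dnorm(z, mpar$mu, mpar$sigma, log = TRUE) -
      stats::dnorm(z, log = TRUE)
    ipar <- mcem_ising(I, nb, ipar$b, ipar$c, llr, seed,
                       outer = refine_outer, sweeps = refine_sweeps)
  }
  fit <- new_hmrf(b = ipar$b, c = ipar$c, mu = mpar$mu, sigma = mpar$sigma,
                  labels = I, iterations = iterations, converged = converged,
                  sweep_logpost = sweep_logpost, nodes = nodes)
  fit$posteriors <- posterior_probabilities(fit, g, s)
  if (gibbs_samples > 0L)
    fit$posteriors_gibbs <- gibbs_posterior(fit, nb, z, gibbs_samples, seed)
  fit
}

new_hmrf <- function(b, c, mu, sigma, labels, iterations, converged,
                     sweep_logpost, nodes) {
  structure(list(b = b, c = c, mu = mu, sigma = sigma,
                 labels = stats::setNames(as.integer(labels), nodes),
                 posteriors = NULL,
                 iterations = iterations, converged = converged,
                 sweep_logpost = sweep_logpost),
            class = "dawn_hmrf")
}

#' @export
print.dawn_hmrf <- function(x, ...) {
  cat(sprintf(paste0("dawn_hmrf: b = %.3f, c = %.3f, mu = %.3f, ",
                     "sigma = %.3f; %d/%d labelled; %d iterations%s\n"),
              x$b, x$c, x$mu, x$sigma, sum(x$labels), length(x$labels),
              x$iterations,
              if (x$converged) " (converged)" else " (not converged)"))
  invisible(x)
}

neighbor_sums <- function(nb, I) {
  vapply(nb, function(j) sum(I[j]), numeric(1))
}

# joint unnormalised log posterior of the Ising + emission model
joint_logpost <- function(I, m, b, c, llr_alt_null, z, mpar) {
  b * sum(I) + c * sum(I * m) / 2 +
    sum(stats::dnorm(z, log = TRUE)) + sum(llr_alt_null[I])
}

icm_sweeps <- function(I, nb, b, c, llr, z, mpar, max_sweeps = 50L) {
  n <- length(I)
  m <- neighbor_sums(nb, I)
  lp <- joint_logpost(I, m, b, c, llr, z, mpar)
  for (sw in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      new <- (b + c * m[i] + llr[i]) > 0
      if (new != I[i]) {
        delta <- if (new) 1 else -1
        I[i] <- new
        m[nb[[i]]] <- m[nb[[i]]] + delta
        changed <- TRUE
      }
    }
    lp <- c(lp, joint_logpost(I, m, b, c, llr, z, mpar))
    if (!changed) break
  }
  list(I = I, lp = lp)
}

update_emission <- function(z, I, mu_floor = 0.1, sigma_floor = 0.5) {
  if (sum(I) == 0L) return(list(mu = mu_floor, sigma = 1))
  mu <- max(mu_floor, mean(z[I]))
  sigma <- if (sum(I) >= 2L) stats::sd(z[I]) else 1
  if (!is.finite(sigma)) sigma <- 1
  list(mu = mu, sigma = max(sigma_floor, sigma))
}

# ridge-penalised logistic fit of labels on neighbour sums. The mild
# penalty on the interaction (lambda = 1, negligible against thousands of
# observations when c is identified) keeps c near 0 instead of diverging
# when the labels are rare or separated, e.g. on heavily diluted signal.
ridge_logistic <- function(y, x, lambda = 1, start = c(0, 0), cap = 15) {
  nll <- function(th) {
    eta <- th[1L] + th[2L] * x
    lse <- ifelse(eta > 30, eta, log1p(exp(eta)))
    -sum(y * eta - lse) + 0.5 * lambda * th[2L]^2
  }
  fit <- tryCatch(stats::optim(start, nll, method = "BFGS"),
                  error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$par)) return(start)
  pmin(cap, pmax(-cap, fit$par))
}

update_ising <- function(I, m, fix_c = NULL, cap = 15) {
  clamp <- function(v) pmin(cap, pmax(-cap, v))
  p_bar <- (sum(I) + 0.5) / (length(I) + 1)
  if (!is.null(fix_c)) {
    # b maximises the pseudo-likelihood with c held fixed: profile by
    # one-dimensional logistic fit with offset fix_c * m
    fit <- tryCatch(
      stats::glm(I ~ 1, offset = fix_c * m,
                 family = stats::binomial()),
      error = function(e) NULL)
    b <- if (is.null(fit)) stats::qlogis(p_bar) else unname(stats::coef(fit))
    return(list(b = clamp(b), c = fix_c))
  }
  if (stats::var(as.numeric(I)) == 0 || stats::var(m) == 0)
    return(list(b = clamp(stats::qlogis(p_bar)), c = 0))
  co <- ridge_logistic(as.numeric(I), m,
                       start = c(stats::qlogis(p_bar), 0), cap = cap)
  list(b = co[1L], c = co[2L])
}

# Monte-Carlo EM refinement of the Ising parameters: Gibbs-sample the
# labels given z at the current (b, c), maximise the prior
# pseudo-likelihood on the sampled configurations, iterate; the last
# half of the outer iterations is averaged. Isolated nodes have an
# independent conditional and are sampled vectorised.
mcem_ising <- function(I, nb, b, c, llr, seed, outer = 8L, sweeps = 30L,
                       cap = 15) {
  set.seed(seed + 7L)
  n <- length(I)
  deg <- lengths(nb)
  conn <- which(deg > 0L)
  iso <- which(deg == 0L)
  m <- neighbor_sums(nb, I)
  keep_from <- ceiling(2 * sweeps / 3)
  bs <- cs <- numeric(0)
  for (it in seq_len(outer)) {
    Is <- list(); Ms <- list()
    for (sw in seq_len(sweeps)) {
      u <- stats::runif(n)
      I[iso] <- u[iso] < stats::plogis(b + llr[iso])
      for (i in conn) {
        new <- u[i] < stats::plogis(b + c * m[i] + llr[i])
        if (new != I[i]) {
          I[i] <- new
          m[nb[[i]]] <- m[nb[[i]]] + if (new) 1 else -1
        }
      }
      if (sw > keep_from) {
        Is[[length(Is) + 1L]] <- I
        Ms[[length(Ms) + 1L]] <- m
      }
    }
    II <- unlist(Is); MM <- unlist(Ms)
    if (stats::var(MM) == 0) {
      co <- c(ridge_logistic(II, MM, start = c(b, 0), cap = cap)[1L], 0)
    } else {
      co <- ridge_logistic(II, MM, start = c(b, c), cap = cap)
    }
    b <- co[1L]
    c <- co[2L]
    if (it > outer / 2) { bs <- c(bs, b); cs <- c(cs, c) }
  }
  list(b = mean(bs), c = mean(cs))
}

#' Per-node posterior risk probabilities at the fitted labels
#'
#' Computes the ICM plug-in posterior
#' `P(I_i = 1 | z_i, labels of neighbours) = plogis(b + c * m_i +
#' log(dnorm(z_i, mu, sigma)) - log(dnorm(z_i)))` where `m_i` is the
#' number of labelled neighbours at convergence.
#'
#' @param f A `dawn_hmrf` fit.
#' @param g The node graph the fit was computed on.
#' @param s Node score table.
#' @return Named numeric vector of posteriors in `[0, 1]`.
#' @export
posterior_probabilities <- function(f, g, s) {
  s <- s[match(names(g$nodes), s$node), , drop = FALSE]
  z <- s$z
  nb <- apply(g$adjacency, 1L, which, simplify = FALSE)
  m <- neighbor_sums(nb, f$labels == 1L)
  llr <- stats::dnorm(z, f$mu, f$sigma, log = TRUE) -
    stats::dnorm(z, log = TRUE)
  stats::setNames(stats::plogis(f$b + f$c * m + llr), names(g$nodes))
}

gibbs_posterior <- function(f, nb, z, n_sweeps, seed, burn_frac = 0.5) {
  set.seed(seed)
  n <- length(z)
  llr <- stats::dnorm(z, f$mu, f$sigma, log = TRUE) -
    stats::dnorm(z, log = TRUE)
  I <- f$labels == 1L
  m <- neighbor_sums(nb, I)
  burn <- ceiling(burn_frac * n_sweeps)
  acc <- numeric(n)
  kept <- 0L
  for (sw in seq_len(n_sweeps + burn)) {
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      p1 <- stats::plogis(f$b + f$c * m[i] + llr[i])
      new <- u[i] < p1
      if (new != I[i]) {
        I[i] <- new
        m[nb[[i]]] <- m[nb[[i]]] + if (new) 1 else -1
      }
    }
    if (sw > burn) { acc <- acc + I; kept <- kept + 1L }
  }
  acc / kept
}

#' Simulate labels and Z-scores from the hidden Markov random field
#'
#' Draws hidden labels from the Ising prior by Gibbs sampling on the given
#' graph and then emissions `z | I`. Used for parameter-recovery checks
#' and power studies.
#'
#' @param adjacency Symmetric logical/0-1 adjacency matrix.
#' @param b,c Ising external field and interaction parameters.
#' @param mu,sigma Alternative emission mean and SD.
#' @param n_sweeps Gibbs sweeps (default 100).
#' @param seed Integer seed.
#' @return List with `labels` (0/1 integer vector) and `z`.
#' @export
simulate_hmrf <- function(adjacency, b, c, mu, sigma,
                          n_sweeps = 100L, seed = 1L) {
  set.seed(seed)
  n <- nrow(adjacency)
  nb <- apply(adjacency != 0, 1L, which, simplify = FALSE)
  I <- stats::runif(n) < stats::plogis(b)
  m <- neighbor_sums(nb, I)
  for (sw in seq_len(n_sweeps)) {
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      new <- u[i] < stats::plogis(b + c * m[i])
      if (new != I[i]) {
        I[i] <- new
        m[nb[[i]]] <- m[nb[[i]]] + if (new) 1 else -1
      }
    }
  }
  z <- ifelse(I, stats::rnorm(n, mu, sigma), stats::rnorm(n))
  list(labels = as.integer(I), z = z)
}

#' Call network-associated (nASD) genes from the screening fit
#'
#' Nodes whose posterior risk probability reaches `threshold` (default
#' 0.5, ties included) are screened in; their member genes form the nASD
#' gene set.
#'
#' @param f A `dawn_hmrf` fit with posteriors.
#' @param g The node graph.
#' @param threshold Posterior threshold (default 0.5; `>=` convention).
#' @return A `dawn_screen` list with `nasd_nodes`, `nasd_genes`,
#'   `posteriors`.
#' @export
call_nasd <- function(f, g, threshold = 0.5) {
  post <- f$posteriors
  called <- names(post)[post >= threshold]
  genes <- sort(unique(unlist(g$nodes[called], use.names = FALSE)))
  structure(list(nasd_nodes = called,
                 nasd_genes = genes,
                 posteriors = post,
                 threshold = threshold),
            class = "dawn_screen")
}

#' @export
print.dawn_screen <- function(x, ...) {
  cat(sprintf("dawn_screen: %d nodes at posterior >= %g -> %d nASD genes\n",
              length(x$nasd_nodes), x$threshold, length(x$nasd_genes)))
  invisible(x)
}
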