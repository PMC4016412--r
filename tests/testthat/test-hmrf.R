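# closed-form two-group posterior used as the c = 0 oracle
two_group_posterior <- function(z, b, mu, sigma) {
  pi1 <- plogis(b)
  f1 <- dnorm(z, mu, sigma); f0 <- dnorm(z)
  pi1 * f1 / ((1 - pi1) * f0 + pi1 * f1)
}

test_that("with c fixed at 0 the fit equals the independent Bayes rule", {
  set.seed(21)
  n <- 200
  g <- make_graph(ring_adj(n, 4))
  z <- c(rnorm(30, 2.5), rnorm(n - 30))
  ns <- make_node_scores(g, pnorm(z, lower.tail = FALSE))
  f <- fit_hmrf(g, ns, fix_c = 0)
  expect_identical(f$c, 0)
  expect_equal(unname(f$posteriors),
               two_group_posterior(ns$z, f$b, f$mu, f$sigma),
               tolerance = 1e-10)
})

test_that("single-node posteriors follow the closed form", {
  g <- make_graph(matrix(FALSE, 1, 1))
  mu <- 1.7
  fit <- dawn:::new_hmrf(b = 0, c = 2, mu = mu, sigma = 1,
                         labels = 0L, iterations = 1L, converged = TRUE,
                         sweep_logpost = list(), nodes = names(g$nodes))
  s <- make_node_scores(g, pnorm(mu, lower.tail = FALSE))  # z = mu
  post <- posterior_probabilities(fit, g, s)
  expect_equal(unname(post), 1 / (1 + dnorm(mu) / dnorm(0)),
               tolerance = 1e-9)
})

test_that("no signal means no calls", {
  g <- make_graph(ring_adj(50, 2))
  ns <- make_node_scores(g, rep(0.5, 50))      # all z = 0
  expect_warning(f <- fit_hmrf(g, ns), "all-null")
  expect_true(all(f$posteriors < 0.5))
  expect_length(call_nasd(f, g)$nasd_genes, 0L)
})

test_that("posterior is monotone in the labelled-neighbour count", {
  b <- -2; cc <- 1; mu <- 2
  post_at <- function(m) plogis(b + cc * m + dnorm(1, mu, 1, log = TRUE) -
                                  dnorm(1, log = TRUE))
  expect_true(all(diff(post_at(0:10)) > 0))
})

test_that("ICM sweeps never decrease the joint log posterior", {
  set.seed(33)
  n <- 300
  adj <- ring_adj(n, 4)
  sim <- simulate_hmrf(adj, b = -2, c = 1, mu = 2, sigma = 1,
                       n_sweeps = 50, seed = 33)
  g <- make_graph(adj)
  ns <- make_node_scores(g, pnorm(sim$z, lower.tail = FALSE))
  f <- fit_hmrf(g, ns, seed = 33)
  expect_gt(length(f$sweep_logpost), 0L)
  for (lp in f$sweep_logpost)
    expect_true(all(diff(lp) >= -1e-9))
})

test_that("calling is monotone in a node's own z at fixed parameters", {
  set.seed(44)
  n <- 120
  adj <- ring_adj(n, 4)
  g <- make_graph(adj)
  z <- c(rnorm(20, 2.5), rnorm(n - 20))
  ns <- make_node_scores(g, pnorm(z, lower.tail = FALSE))
  f <- fit_hmrf(g, ns, seed = 44)
  expect_gte(f$sigma, 1 - 0.3)     # emission wide enough for monotone llr
  called <- names(f$posteriors)[f$posteriors >= 0.5]
  expect_gt(length(called), 0)
  nb <- apply(g$adjacency, 1, which, simplify = FALSE)
  # raise one called node's z; labels re-inferred at the fitted
  # parameters; the node must remain called
  for (nd in head(called, 3)) {
    i <- match(nd, ns$node)
    z2 <- ns$z
    z2[i] <- z2[i] + 2
    llr <- dnorm(z2, f$mu, max(1, f$sigma), log = TRUE) -
      dnorm(z2, log = TRUE)
    relab <- dawn:::icm_sweeps(f$labels == 1L, nb, f$b, f$c, llr, z2,
                               list(mu = f$mu, sigma = max(1, f$sigma)))
    m <- sapply(nb, function(j) sum(relab$I[j]))
    post2 <- plogis(f$b + f$c * m + llr)
    expect_gte(post2[i], 0.5)
  }
})

test_that("nASD calls expand multi-gene nodes and respect the threshold", {
  g <- make_graph(matrix(FALSE, 3, 3),
                  node_genes = list("A", c("B", "C"), "D"))
  fit <- dawn:::new_hmrf(b = 0, c = 0, mu = 1, sigma = 1, labels = c(0L, 1L, 1L),
                         iterations = 1L, converged = TRUE,
                         sweep_logpost = list(), nodes = names(g$nodes))
  fit$posteriors <- setNames(c(0.49, 0.50, 0.90), names(g$nodes))
  res <- call_nasd(fit, g)
  expect_setequal(res$nasd_nodes, c("N002", "N003"))
  expect_setequal(res$nasd_genes, c("B", "C", "D"))   # ties at 0.5 called
})

test_that("clustered signal yields larger c than permuted signal", {
  set.seed(55)
  n <- 300
  adj <- ring_adj(n, 4)
  g <- make_graph(adj)
  diffs <- sapply(1:8, function(s) {
    sim <- simulate_hmrf(adj, b = -2.5, c = 1, mu = 2.5, sigma = 1,
                         n_sweeps = 50, seed = s)
    ns <- make_node_scores(g, pnorm(sim$z, lower.tail = FALSE))
    f1 <- fit_hmrf(g, ns, seed = s)
    set.seed(s + 100)
    ns_perm <- ns[sample(n), ]
    ns_perm$node <- ns$node
    f2 <- fit_hmrf(g, ns_perm, seed = s)
    f1$c - f2$c
  })
  expect_lt(wilcox.test(diffs, alternative = "greater")$p.value, 0.05)
})
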