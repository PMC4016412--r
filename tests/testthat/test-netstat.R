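test_that("network_score applies both hard thresholds", {
  genes <- c("i", "a", "b", "c")
  r <- diag(4); dimnames(r) <- list(genes, genes)
  r["i", "a"] <- r["a", "i"] <- 0.9
  r["i", "b"] <- r["b", "i"] <- 0.5    # fails r_min
  r["i", "c"] <- r["c", "i"] <- 0.8    # neighbour z fails z_min
  sc <- gene_score_table(c("a", "b", "c"),
                         pnorm(c(2, 5, 1), lower.tail = FALSE))
  s <- network_score(r, sc)
  expect_equal(unname(s["i"]), 0.9 * 2, tolerance = 1e-9)

  # nobody passes both thresholds -> all zero
  sc0 <- gene_score_table(c("a", "b", "c"), rep(0.5, 3))   # z = 0 < 1.2
  expect_equal(unname(network_score(r, sc0)), rep(0, 4))
})

test_that("network_score is additive over neighbours and order-invariant", {
  set.seed(10)
  genes <- paste0("g", 1:8)
  r <- matrix(runif(64, -1, 1), 8); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(genes, genes)
  z <- rnorm(8, 1.5)
  sc <- gene_score_table(genes, pnorm(z, lower.tail = FALSE))
  s <- network_score(r, sc)
  # brute force per gene
  for (i in seq_along(genes)) {
    expected <- sum(sapply(seq_along(genes)[-i], function(j) {
      rr <- abs(r[i, j]); zz <- sc$z[j]
      if (rr >= 0.7 && zz >= 1.2) rr * zz else 0
    }))
    expect_equal(unname(s[i]), expected, tolerance = 1e-9)
  }
  perm <- sample(8)
  s2 <- network_score(r[perm, perm], sc)
  expect_equal(s2[genes], s[genes], tolerance = 1e-12)
})

test_that("hypergeom_tail equals brute-force enumeration of binomial terms", {
  brute <- function(N, K, n, k) {
    j <- k:min(n, K)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  set.seed(14)
  for (trial in 1:25) {
    N <- sample(5:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_tail(N, K, n, k), brute(N, K, n, k),
                 tolerance = 1e-12)
  }
  expect_equal(hypergeom_tail(44, 10, 8, 6), 121935 / 177232627,
               tolerance = 1e-12)
  expect_equal(hypergeom_tail(30, 5, 10, 0), 1)
  expect_error(hypergeom_tail(10, 12, 5, 2), "inconsistent")
})

test_that("fisher_exact_test matches enumeration and the reference oracle", {
  # [[1,1],[1,1]]: all tables with these margins -> P = 5/6
  expect_equal(fisher_exact_test(c(1, 1, 1, 1))$p_value, 5 / 6,
               tolerance = 1e-12)

  # zero-cell table reduces to the plain hypergeometric tail
  t0 <- matrix(c(3, 0, 2, 7), 2, byrow = TRUE)
  expect_equal(fisher_exact_test(t0)$p_value,
               hypergeom_tail(12, 3, 5, 3), tolerance = 1e-12)

  # independent oracle: stats::fisher.test (conditional MLE odds ratio)
  set.seed(15)
  for (trial in 1:12) {
    tab <- matrix(rpois(4, 5) + c(1, 0, 0, 1), 2)
    ours <- fisher_exact_test(tab)
    ref <- fisher.test(tab, alternative = "greater")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    if (is.finite(ours$odds_ratio))
      expect_equal(ours$odds_ratio, unname(ref$estimate), tolerance = 1e-4)
  }
  expect_error(fisher_exact_test(c(0, 0, 0, 0)), "all-zero")
})

test_that("connectivity_test flags planted clusters and stays calibrated", {
  gen <- generate_expression(300, data.frame(size = 30, rho = 0.85),
                             n_replicates = 100, seed = 20)
  r <- pearson_correlation(gen$expression)
  pool <- rownames(gen$expression)
  set.seed(20)
  mutability <- runif(300)
  target <- pool[1:30]                       # the planted tight block
  res <- connectivity_test(target, pool, mutability, r,
                           n_perm = 500, seed = 1)
  expect_lte(res$p_value, 0.01)

  # null targets give approximately uniform P values. Uses a multi-block
  # world so random lists carry a near-continuous statistic (in a
  # single-block pool most draws tie at zero connectivity and the P mass
  # piles near 1); the remaining permutation-grid discreteness is
  # smoothed with sub-grid jitter before the KS comparison.
  gen2 <- generate_expression(400, data.frame(size = rep(40, 6),
                                              rho = rep(0.8, 6)),
                              n_replicates = 100, seed = 20)
  r2 <- pearson_correlation(gen2$expression)
  pool2 <- rownames(gen2$expression)
  set.seed(20)
  mutability2 <- runif(400)
  pvals <- sapply(1:50, function(s) {
    set.seed(1000 + s)
    tgt <- sample(pool2, 40)
    connectivity_test(tgt, pool2, mutability2, r2, n_perm = 99,
                      seed = s)$p_value
  })
  set.seed(2)
  smoothed <- pvals - runif(length(pvals), 0, 1 / 100)
  expect_gt(suppressWarnings(ks.test(smoothed, "punif"))$p.value, 0.01)

  expect_error(connectivity_test(target, pool, mutability, r, n_perm = 0),
               "n_perm")
})

test_that("de novo extrapolation scales events linearly and keeps identities", {
  m <- denovo_model()      # 1043 trios, 143 events, 130 unique, 9 multi
  expect_equal(m$single_obs, 121)
  out <- extrapolate_denovo(m, 2500)
  expect_equal(out$events, 143 * 2500 / 1043, tolerance = 1e-12)  # 342.8
  expect_equal(out$linear$unique, 130 * 2500 / 1043, tolerance = 1e-12)

  # identity at the observed sample size
  id <- extrapolate_denovo(m, 1043)
  expect_equal(id$occupancy$events, 143)
  expect_equal(id$occupancy$unique, 130)
  expect_equal(id$occupancy$multi, 9)

  # structural invariants and monotonicity in the target size
  targets <- c(1200, 1800, 2500, 4000)
  uq <- mu2 <- ev <- numeric(0)
  for (tt in targets) {
    o <- extrapolate_denovo(m, tt)
    expect_lte(o$occupancy$unique, o$events)
    expect_equal(o$occupancy$multi + o$occupancy$single,
                 o$occupancy$unique, tolerance = 1e-9)
    ev <- c(ev, o$events); uq <- c(uq, o$occupancy$unique)
    mu2 <- c(mu2, o$occupancy$multi)
  }
  expect_true(all(diff(ev) > 0) && all(diff(uq) > 0) && all(diff(mu2) > 0))
  expect_error(extrapolate_denovo(m, -5), "positive")

  expect_equal(prior_hit_probability(162, 1000), 0.162)
  expect_error(denovo_model(events_obs = 100, unique_obs = 130), "at least")
})
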