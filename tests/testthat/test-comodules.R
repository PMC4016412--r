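test_that("soft_adjacency applies the power with a zero diagonal", {
  r <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0.3, -0.5, 0.3, 1), 3, 3)
  a1 <- soft_adjacency(r, 1)
  expect_equal(a1[1, 2], 0.5)
  expect_equal(unname(diag(a1)), rep(0, 3))
  expect_equal(a1[upper.tri(a1)], abs(r)[upper.tri(r)])  # identity power
  a6 <- soft_adjacency(r, 6)
  expect_equal(a6[1, 3], 0.5^6)   # (-0.5)^6 = 0.015625
  expect_error(soft_adjacency(r, 0), "power")
})

test_that("topological overlap matches hand-evaluated cases", {
  ones <- matrix(1, 3, 3); diag(ones) <- 0
  d <- topological_overlap(ones)       # fully connected triangle
  expect_equal(d[upper.tri(d)], rep(0, 3))

  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
  d2 <- topological_overlap(a)         # pair connected only to each other
  expect_equal(d2[1, 2], 0)            # TOM = (0 + 1)/(1 + 1 - 1) = 1
  expect_equal(d2[1, 3], 1)            # isolated pair -> dissimilarity 1

  empty <- matrix(0, 4, 4)
  d3 <- topological_overlap(empty)
  expect_equal(d3[upper.tri(d3)], rep(1, 6))

  set.seed(3)
  r <- matrix(runif(49, -1, 1), 7, 7); r <- (r + t(r)) / 2; diag(r) <- 1
  dr <- topological_overlap(soft_adjacency(r, 2))
  expect_true(all(dr >= 0 & dr <= 1))
  expect_true(isSymmetric(dr))
})

test_that("cut_modules recovers planted blocks and applies the size rule", {
  genes <- sprintf("g%02d", 1:80)
  d <- matrix(0.9, 80, 80, dimnames = list(genes, genes))
  d[1:40, 1:40] <- 0.1
  d[41:80, 41:80] <- 0.1
  diag(d) <- 0
  p <- cut_modules(d, min_size = 30)
  expect_identical(sort(unique(p$assignment)), c("M1", "M2"))
  expect_length(unique(p$assignment[genes[1:40]]), 1L)
  expect_length(unique(p$assignment[genes[41:80]]), 1L)
  expect_false(p$assignment[genes[1]] == p$assignment[genes[41]])

  small <- d[1:10, 1:10]
  expect_warning(ps <- cut_modules(small, min_size = 30), "unassigned")
  expect_true(all(ps$assignment == "M0"))

  # degenerate equal dissimilarity: result is deterministic
  dd <- matrix(0.5, 40, 40, dimnames = list(genes[1:40], genes[1:40]))
  diag(dd) <- 0
  p1 <- cut_modules(dd, min_size = 10)
  p2 <- cut_modules(dd, min_size = 10)
  expect_identical(p1$assignment, p2$assignment)
})

test_that("planted factor blocks are recovered with Rand index > 0.95", {
  gen <- generate_expression(n_genes = 200,
                             blocks = data.frame(size = c(60, 60, 60),
                                                 rho = c(0.8, 0.8, 0.8)),
                             n_replicates = 120, seed = 5)
  r <- pearson_correlation(gen$expression)
  d <- topological_overlap(soft_adjacency(r, 6))
  p <- cut_modules(d, min_size = 30)
  keep <- gen$truth$block_of_gene > 0
  expect_gt(rand_index(p$assignment[names(which(keep))],
                       gen$truth$block_of_gene[keep]), 0.95)
})

test_that("eigengene merging joins shared-factor modules and is monotone", {
  set.seed(9)
  n_rep <- 100
  f1 <- rnorm(n_rep); f2 <- rnorm(n_rep)
  mk <- function(f, n, noise) t(sapply(seq_len(n), function(i)
    f + rnorm(n_rep, sd = noise)))
  # modules A and B share factor f1; module C is independent
  x <- rbind(mk(f1, 30, 0.1), mk(f1, 30, 0.1), mk(f2, 30, 0.1))
  rownames(x) <- sprintf("g%02d", 1:90)
  assignment <- setNames(rep(c("M1", "M2", "M3"), each = 30), rownames(x))
  p <- dawn:::new_modules(assignment, "toy", 1, 30, FALSE)

  merged <- merge_by_eigengene(p, x, height = 0.15)
  labs <- merged$assignment
  expect_identical(unname(labs["g01"]), unname(labs["g31"]))  # A+B merged
  expect_false(labs["g01"] == labs["g61"])                     # C apart

  unchanged <- merge_by_eigengene(p, x, height = 0)
  expect_identical(unchanged$assignment, p$assignment)

  n_mod <- function(h) {
    m <- merge_by_eigengene(p, x, height = h)
    length(setdiff(unique(m$assignment), "M0"))
  }
  counts <- vapply(c(0, 0.1, 0.5, 0.9), n_mod, numeric(1))
  expect_true(all(diff(counts) <= 0))   # monotone in merge height
})

test_that("build_representations yields period x power partitions", {
  gen1 <- generate_expression(300, data.frame(size = c(60, 60),
                                              rho = c(0.8, 0.75)),
                              n_replicates = 80, seed = 2)
  gen2 <- generate_expression(300, data.frame(size = c(60, 60),
                                              rho = c(0.8, 0.75)),
                              n_replicates = 90, seed = 3)
  one <- build_representations(list(pA = gen1$expression))
  expect_length(one$partitions, 2L)
  expect_true(one$partitions$pA_pow6$merged)
  expect_false(one$partitions$pA_pow1$merged)

  both <- build_representations(list(pA = gen1$expression,
                                     pB = gen2$expression))
  expect_length(both$partitions, 4L)
  expect_setequal(names(both$partitions),
                  c("pA_pow1", "pA_pow6", "pB_pow1", "pB_pow6"))

  # merging cannot increase the module count
  p6 <- both$partitions$pA_pow6
  unmerged <- cut_modules(
    topological_overlap(soft_adjacency(both$correlations$pA, 6)),
    min_size = 30, representation_id = "pA_pow6", power = 6)
  n_mods <- function(p) length(setdiff(unique(p$assignment), "M0"))
  expect_lte(n_mods(p6), n_mods(unmerged))
})
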