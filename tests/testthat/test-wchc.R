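test_that("allele expansion follows the two-indicator coding", {
  Y <- rand_phenotypes(3, 2)
  d <- allele_expand(c(2L, 1L, 0L), Y)
  expect_equal(d$x, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(mean(d$x), 0.5)
  expect_equal(d$pairing, rep(1:3, each = 2))
  expect_equal(d$y[1, ], d$y[2, ])
  expect_equal(sum(d$x), sum(c(2L, 1L, 0L)))
  # all heterozygotes: allele frequency exactly one half
  d2 <- allele_expand(rep(1L, 10), rand_phenotypes(10, 1))
  expect_equal(mean(d2$x), 0.5)
  expect_error(allele_expand(c(0L, 3L), rand_phenotypes(2, 1)), "0, 1, 2")
})

test_that("combination weights are the per-phenotype slopes", {
  # phenotype identical to the allele indicator: slope one
  g <- c(1L, 1L, 0L, 2L)
  d <- allele_expand(g, rand_phenotypes(4, 1))
  d$y[, 1] <- d$x
  expect_equal(unname(combination_weights(d, 1L)), 1)
  # brute-force double-loop oracle on random instances
  set.seed(10)
  for (i in 1:20) {
    n <- 5; mk <- 3
    g <- rand_genotypes(n, 0.4)
    Y <- rand_phenotypes(n, mk)
    d <- allele_expand(g, Y)
    w_oracle <- vapply(1:mk, function(j) {
      num <- den <- 0
      xb <- mean(d$x); yb <- mean(d$y[, j])
      for (l in seq_along(d$x)) {
        num <- num + (d$x[l] - xb) * (d$y[l, j] - yb)
        den <- den + (d$y[l, j] - yb)^2
      }
      num / den
    }, numeric(1))
    expect_equal(unname(combination_weights(d, 1:mk)), w_oracle,
                 tolerance = 1e-12)
  }
  d$y[, 2] <- 5   # constant phenotype
  expect_error(combination_weights(d, 1:3), "zero-variance")
})

test_that("the cluster statistic has its closed form and is nonnegative", {
  # single phenotype equal to the indicator, x = (1,0,1,0): T = sum (x-1/2)^2
  Y <- matrix(0, 2, 1, dimnames = list(NULL, "Y1"))
  d <- allele_expand(c(1L, 1L), Y)
  d$y[, 1] <- d$x
  expect_equal(cluster_statistic(d, 1L)$T, 1.0)
  # zero cross-covariance gives T = 0
  dz <- allele_expand(c(1L, 1L), matrix(c(1, -1), 2, 1))
  dz$y[, 1] <- c(1, -1, -1, 1)   # balanced within both allele groups
  expect_equal(cluster_statistic(dz, 1L)$T, 0)
})

test_that("permutation preserves the genotype multiset and is seed-stable", {
  g <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L)
  set.seed(11); p1 <- permute_genotypes(g)
  set.seed(11); p2 <- permute_genotypes(g)
  expect_identical(p1, p2)
  expect_identical(sort(p1), sort(g))
  # uniformity over the two orderings of c(2, 0)
  set.seed(12)
  firsts <- replicate(10000, permute_genotypes(c(2L, 0L))[1])
  expect_lt(abs(mean(firsts == 2L) - 0.5), 0.02)
})

test_that("per-cluster permutation p-values use strict counting over B", {
  # observed 2.5 against permuted (1, 2, 3, 4): two exceed, p = 2/4
  p <- wchc:::.perm_pvalues(matrix(c(2.5, 1, 2, 3, 4), 1))
  expect_equal(p[1, 1], 0.5)
  # unique maximum gets p = 0
  p2 <- wchc:::.perm_pvalues(matrix(c(9, 1, 2, 3, 4), 1))
  expect_equal(p2[1, 1], 0)
  # all p-values bounded by [0, 1]
  expect_true(all(p >= 0 & p <= 1))
})

test_that("batched permutation pass matches the explicit loop form", {
  set.seed(13)
  g <- rand_genotypes(40)
  Y <- rand_phenotypes(40, 5)
  part <- make_partition(list(c(1L, 3L), c(2L, 4L, 5L)))
  fast <- wchc_test(g, Y, partition = part, B = 60, seed = 99)
  slow <- wchc:::.wchc_test_loop(g, Y, part, B = 60, seed = 99)
  expect_equal(fast$cluster_statistics, slow$Tmat[, 1], tolerance = 1e-12)
  expect_equal(fast$t_wchc, slow$t_wchc)
  expect_equal(fast$pvalue, slow$pvalue)
})

test_that("WCHC with one cluster is exactly WCmulP", {
  set.seed(14)
  g <- rand_genotypes(50)
  Y <- rand_phenotypes(50, 4)
  a <- wchc_test(g, Y, partition = trivial_partition(4), B = 100, seed = 5)
  b <- wcmulp_test(g, Y, B = 100, seed = 5)
  expect_identical(a$pvalue, b$pvalue)
  expect_identical(a$cluster_statistics, b$cluster_statistics)
  expect_identical(a$t_wchc, b$t_wchc)
})

test_that("the statistic is invariant to allele flip and phenotype scaling", {
  set.seed(15)
  g <- rand_genotypes(60)
  Y <- rand_phenotypes(60, 4)
  part <- make_partition(list(1:2, 3:4))
  base <- wchc_test(g, Y, partition = part, B = 1, seed = 1)
  flip <- wchc_test(2L - g, Y, partition = part, B = 1, seed = 1)
  expect_equal(base$cluster_statistics, flip$cluster_statistics,
               tolerance = 1e-10)
  scaled <- wchc_test(g, sweep(Y, 2, c(2, -3, 0.5, 10), "*") + 7,
                      partition = part, B = 1, seed = 1)
  expect_equal(base$cluster_statistics, scaled$cluster_statistics,
               tolerance = 1e-10)
})

test_that("heterozygote indicator order does not change the statistic", {
  set.seed(16)
  g <- rand_genotypes(20, 0.5)
  Y <- rand_phenotypes(20, 3)
  d <- allele_expand(g, Y)
  T0 <- cluster_statistic(d, 1:3)$T
  # swap the (1,0) rows of every heterozygote
  for (i in which(g == 1L)) d$x[c(2 * i - 1, 2 * i)] <- c(0L, 1L)
  expect_equal(cluster_statistic(d, 1:3)$T, T0, tolerance = 1e-12)
})

test_that("fixed seeds give bit-identical test results", {
  set.seed(17)
  g <- rand_genotypes(50)
  Y <- rand_phenotypes(50, 3)
  r1 <- wchc_test(g, Y, B = 200, seed = 123)
  r2 <- wchc_test(g, Y, B = 200, seed = 123)
  expect_identical(r1$pvalue, r2$pvalue)
  expect_identical(r1$cluster_pvalues, r2$cluster_pvalues)
})

test_that("degenerate inputs are rejected with clear errors", {
  Y <- rand_phenotypes(10, 2)
  expect_error(wchc_test(rep(1L, 10), Y, B = 10), "monomorphic")
  Yc <- Y; Yc[, 2] <- 3
  expect_error(wchc_test(rand_genotypes(10), Yc, B = 10,
                         partition = trivial_partition(2)),
               "zero-variance")
  expect_error(wchc_test(rand_genotypes(10), Y, B = 10,
                         partition = make_partition(list(1L))),
               "cover")
})

test_that("null p-values are calibrated up to permutation granularity", {
  set.seed(18)
  n_rep <- 300
  rej05 <- rej01 <- logical(n_rep)
  part <- trivial_partition(4)
  for (i in seq_len(n_rep)) {
    g <- rand_genotypes(60)
    Y <- rand_phenotypes(60, 4)
    p <- wchc_test(g, Y, partition = part, B = 99)$pvalue
    rej05[i] <- p < 0.05
    rej01[i] <- p < 0.01
  }
  ci05 <- qnorm(0.995) * sqrt(0.05 * 0.95 / n_rep)
  ci01 <- qnorm(0.995) * sqrt(0.01 * 0.99 / n_rep)
  expect_lt(abs(mean(rej05) - 0.05), ci05)
  expect_lt(abs(mean(rej01) - 0.01), ci01 + 1 / 99)
})

test_that("the add-one estimator never returns zero", {
  set.seed(19)
  g <- rand_genotypes(40)
  Y <- rand_phenotypes(40, 2)
  Y[, 1] <- Y[, 1] + 2 * g     # strong signal: raw permutation p is 0
  raw <- wcmulp_test(g, Y, B = 50, seed = 1)
  mid <- wcmulp_test(g, Y, B = 50, seed = 1, correction = "add-one")
  expect_equal(raw$pvalue, 0)
  expect_equal(mid$pvalue, 1 / 51)
})
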