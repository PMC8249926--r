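# Own proportional-odds negative log-likelihood, used as an independent
# oracle for the reverse-regression comparator.
polr_nll <- function(par, geno, X) {
  n_cut <- length(unique(geno)) - 1L
  cuts <- cumsum(c(par[1], exp(par[2:n_cut])))  # ordered cut-points
  beta <- par[-(1:n_cut)]
  eta <- drop(X %*% beta)
  lev <- sort(unique(geno))
  ll <- 0
  for (i in seq_along(geno)) {
    k <- match(geno[i], lev)
    upper <- if (k <= n_cut) plogis(cuts[k] - eta[i]) else 1
    lower <- if (k > 1) plogis(cuts[k - 1] - eta[i]) else 0
    ll <- ll + log(max(upper - lower, 1e-300))
  }
  -ll
}

test_that("univariate statistics behave at the edges", {
  set.seed(20)
  g <- rand_genotypes(100)
  Y <- rand_phenotypes(100, 3)
  Y[, 2] <- Y[, 1]                       # duplicated phenotype
  us <- univariate_stats(g, Y)
  expect_equal(us$Corr[1, 2], 1)
  expect_equal(unname(us$t[1]), unname(us$t[2]))
  # perfect fit is capped, not infinite
  us2 <- univariate_stats(g, cbind(y = as.numeric(g)))
  expect_true(is.finite(us2$t[1]))
  expect_gt(abs(us2$t[1]), 100)
  expect_error(univariate_stats(rep(0L, 10), rand_phenotypes(10, 2)),
               "monomorphic")
})

test_that("univariate statistics are near standard normal under the null", {
  set.seed(21)
  t_vals <- replicate(500, {
    g <- rand_genotypes(100)
    univariate_stats(g, rand_phenotypes(100, 1))$t[1]
  })
  expect_lt(abs(mean(t_vals)), 0.15)
  expect_lt(abs(sd(t_vals) - 1), 0.15)
})

test_that("O'Brien reduces correctly under identity covariance", {
  M <- 4
  us <- list(t = rep(1.3, M), Sigma = diag(M))
  expect_equal(obrien_test(us)$statistic, sqrt(M) * 1.3)
  # equal and opposite statistics cancel exactly
  us2 <- list(t = c(2, -2, 1, -1), Sigma = diag(4))
  expect_equal(obrien_test(us2)$s, 0)
  expect_equal(obrien_test(us2)$pvalue, 1)
})

test_that("O'Brien matches an explicit matrix-inverse oracle", {
  set.seed(22)
  for (i in 1:10) {
    S <- cov2cor(crossprod(matrix(rnorm(9 * 3), ncol = 3)) + diag(3))
    t <- rnorm(3)
    Si <- solve(S)
    z_oracle <- sum(Si %*% t) / sqrt(sum(Si))
    expect_equal(obrien_test(list(t = t, Sigma = S))$statistic, z_oracle,
                 tolerance = 1e-10)
  }
  # flipping every statistic flips s but leaves the two-sided p unchanged
  S <- cov2cor(crossprod(matrix(rnorm(12), 4)) + diag(3))
  t <- rnorm(3)
  a1 <- obrien_test(list(t = t, Sigma = S))
  a2 <- obrien_test(list(t = -t, Sigma = S))
  expect_equal(a1$s, -a2$s, tolerance = 1e-12)
  expect_equal(a1$pvalue, a2$pvalue, tolerance = 1e-12)
  expect_error(obrien_test(list(t = c(1, 1), Sigma = matrix(1, 2, 2))),
               "singular")
})

test_that("SHet reduces to the squared O'Brien form at threshold zero", {
  set.seed(23)
  M <- 5
  t <- rnorm(M) + 0.5
  us <- list(t = t, Corr = diag(M), W = rep(1, M))
  s <- wchc:::shet_stat_kernel(matrix(t, 1), diag(M), rep(1, M), 0)
  expect_equal(s[1], sum(t)^2 / M, tolerance = 1e-12)
  # adaptive maximisation can only improve on the single-threshold value
  s_max <- wchc:::shet_stat_kernel(matrix(t, 1), diag(M), rep(1, M),
                                   numeric(0))
  expect_gte(s_max[1], s[1] - 1e-12)
})

test_that("the C++ SHet kernel agrees with the pure-R reference", {
  set.seed(24)
  for (i in 1:30) {
    M <- sample(2:12, 1)
    R <- cov2cor(crossprod(matrix(rnorm(4 * M * M), ncol = M)) + diag(M))
    t <- rnorm(M) * sample(c(1, 3), 1)
    w <- runif(M, 0.5, 2)
    a <- wchc:::shet_stat_kernel(matrix(t, 1), R, w, numeric(0))[1]
    b <- wchc:::.shet_stat_r(t, R, w)
    expect_equal(a, b, tolerance = 1e-10)
    # fixed grids agree too
    taus <- c(0, quantile(abs(t), 0.5))
    a2 <- wchc:::shet_stat_kernel(matrix(t, 1), R, w, taus)[1]
    b2 <- wchc:::.shet_stat_r(t, R, w, taus)
    expect_equal(a2, b2, tolerance = 1e-10)
  }
})

test_that("SHet p-values are seed-reproducible and calibrated-ish", {
  set.seed(25)
  g <- rand_genotypes(150)
  us <- univariate_stats(g, rand_phenotypes(150, 4))
  p1 <- shet_test(us, n_mc = 500, seed = 31)$pvalue
  p2 <- shet_test(us, n_mc = 500, seed = 31)$pvalue
  expect_identical(p1, p2)
  # null p-values roughly uniform: check the mean over replicates
  set.seed(26)
  ps <- replicate(150, {
    g <- rand_genotypes(80)
    shet_test(univariate_stats(g, rand_phenotypes(80, 3)),
              n_mc = 300)$pvalue
  })
  expect_lt(abs(mean(ps) - 0.5), 0.08)
})

test_that("TATES is Simes under independence and tracks duplicates", {
  # hand-computed Simes example
  expect_equal(tates_test(c(0.02, 0.80), diag(2)), 0.04)
  # random identity-correlation cases equal the Simes statistic exactly
  set.seed(27)
  for (i in 1:10) {
    M <- sample(2:8, 1)
    p <- runif(M)
    simes <- min(M * sort(p) / seq_len(M))
    expect_equal(tates_test(p, diag(M)), min(1, simes), tolerance = 1e-12)
  }
  # single phenotype passes through
  expect_equal(tates_test(0.37, matrix(1, 1, 1)), 0.37)
  # perfectly correlated duplicates: effective number near 1
  p <- c(0.03, 0.03)
  expect_equal(tates_test(p, matrix(1, 2, 2)), 0.03, tolerance = 0.02)
})

test_that("MANOVA matches the univariate F-test at M = 1", {
  set.seed(28)
  g <- rand_genotypes(80)
  y <- 0.2 * g + rnorm(80)
  res <- manova_test(g, cbind(y = y))
  r <- cor(g, y)
  f_oracle <- r^2 * (80 - 2) / (1 - r^2)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$pvalue, pf(f_oracle, 1, 78, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("MANOVA is calibrated under the null and rejects singular input", {
  set.seed(29)
  ps <- replicate(300, {
    g <- rand_genotypes(60)
    manova_test(g, rand_phenotypes(60, 3))$pvalue
  })
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  Y <- rand_phenotypes(50, 2)
  Y <- cbind(Y, Y[, 1])
  expect_error(manova_test(rand_genotypes(50), Y), "MANOVA failed")
})

test_that("reverse ordinal regression matches a direct likelihood oracle", {
  set.seed(30)
  g <- rand_genotypes(120, 0.4)
  y <- 0.3 * g + rnorm(120)
  res <- multiphen_test(g, cbind(y = y))
  # oracle: own optimisation of the proportional-odds likelihood
  X <- cbind(y)
  fit1 <- optim(c(-1, 0.5, 0), polr_nll, geno = g, X = X, method = "BFGS",
                control = list(reltol = 1e-14, maxit = 2000))
  counts <- table(g)
  ll0 <- sum(counts * log(counts / length(g)))
  lrt_oracle <- 2 * (-fit1$value - ll0)
  expect_equal(res$statistic, lrt_oracle, tolerance = 1e-6)
  expect_equal(res$df, 1L)
})

test_that("two genotype levels reduce to binary logistic regression", {
  set.seed(31)
  repeat {   # sample until no heterozygotes-free two-level case
    g <- rbinom(80, 2, 0.15)
    g[g == 2L] <- 1L
    if (length(unique(g)) == 2L) break
  }
  Y <- rand_phenotypes(80, 2)
  res <- multiphen_test(g, Y)
  fit <- glm(g ~ Y, family = binomial())
  expect_equal(res$statistic, fit$null.deviance - fit$deviance,
               tolerance = 1e-8)
})

test_that("the ordinal LRT has its chi-square null mean", {
  set.seed(32)
  M <- 3
  lrt <- replicate(200, {
    g <- rand_genotypes(150)
    multiphen_test(g, rand_phenotypes(150, M))$statistic
  })
  # mean of chi2_M is M; allow 3 standard errors of the replicate mean
  expect_lt(abs(mean(lrt) - M), 3 * sqrt(2 * M / 200))
})

test_that("compare_methods returns one p-value per requested method", {
  set.seed(33)
  g <- rand_genotypes(60)
  Y <- rand_phenotypes(60, 4)
  p <- compare_methods(g, Y, methods = c("wchc", "ob", "tates", "manova"),
                       B = 50, seed = 2)
  expect_named(p, c("wchc", "ob", "tates", "manova"))
  expect_true(all(p >= 0 & p <= 1))
})
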