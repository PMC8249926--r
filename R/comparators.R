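#' Per-phenotype univariate association statistics
#'
#' For each phenotype, the standardized statistic of the simple linear
#' regression on genotype dosage: `t_j = sqrt(N-2) r_j / sqrt(1 - r_j^2)`
#' where `r_j` is the sample correlation (asymptotically standard normal
#' under the null; a perfect fit is capped rather than returning infinity).
#' Under the null the statistics are correlated like the phenotypes, so the
#' phenotype correlation matrix serves as their null correlation/covariance
#' on the z-scale.
#'
#' @param g Polymorphic genotype dosage vector.
#' @param phenotypes Numeric matrix, individuals x phenotypes.
#' @return List of class `wchc_unistats` with `t` (length-M statistic
#'   vector), `Sigma` (covariance of `t`, equals `Corr` on the z-scale),
#'   `Corr`, `W` (diagonal weight vector, all ones), and two-sided normal
#'   `p` values.
#' @export
univariate_stats <- function(g, phenotypes) {
  Y <- .check_phenotypes(phenotypes, g)
  g <- .check_genotype(g)
  N <- length(g)
  r <- drop(cor(g, Y))
  t <- sqrt(N - 2) * r / sqrt(pmax(1 - r^2, 1e-12))
  Corr <- cor(Y)
  structure(list(t = setNames(t, colnames(Y)), Sigma = Corr, Corr = Corr,
                 W = rep(1, ncol(Y)),
                 p = 2 * pnorm(-abs(t)), N = N),
            class = "wchc_unistats")
}

#' O'Brien linear-combination test
#'
#' Combines the univariate statistics as `s = 1' Sigma^-1 t` with variance
#' `1' Sigma^-1 1`; the two-sided p-value comes from the standardized normal
#' statistic.  Most powerful among linear combinations when genetic effects
#' are homogeneous across phenotypes.
#'
#' @param stats A `wchc_unistats` object from [univariate_stats()].
#' @return List with `statistic` (the standardized z), `s`, and `pvalue`.
#' @export
obrien_test <- function(stats) {
  a <- tryCatch(solve(stats$Sigma, rep(1, length(stats$t))),
                error = function(e)
                  stop("singular covariance of univariate statistics ",
                       "(duplicated phenotypes?)", call. = FALSE))
  s <- sum(a * stats$t)
  z <- s / sqrt(sum(a))
  list(statistic = z, s = s, pvalue = 2 * pnorm(-abs(z)))
}

# Pure-R reference for the S_Het maximisation; one row of statistics.
# taus = NULL uses the adaptive grid {0} U {|t_j|}.
.shet_stat_r <- function(t, Corr, w, taus = NULL) {
  a <- abs(t)
  if (is.null(taus)) taus <- sort(unique(c(0, a)))
  best <- -Inf
  u_all <- 1 / w
  for (tau in taus) {
    sel <- which(a > tau)
    if (!length(sel)) next
    Cs <- Corr[sel, sel, drop = FALSE]
    X <- solve(Cs, cbind(t[sel], u_all[sel]))
    num <- sum(u_all[sel] * X[, 1])
    den <- sum(u_all[sel] * X[, 2])
    best <- max(best, num^2 / den)
  }
  if (!is.finite(best))
    stop("empty selection at every SHet threshold", call. = FALSE)
  best
}

#' SHet: heterogeneity-robust weighted combination test
#'
#' The homogeneous statistic `S_Hom = (1'(Corr W)^-1 t)^2 /
#' (1'(W Corr W)^-1 1)` is evaluated on every subset of phenotypes whose
#' absolute statistics exceed a threshold, over a grid of thresholds
#' (by default 0 plus the observed absolute statistics), and `S_Het` is the
#' maximum.  Its null distribution has no closed form; the p-value is
#' estimated by drawing `n_mc` multivariate-normal null statistic vectors
#' with correlation `Corr` and recomputing `S_Het` on each.
#'
#' @param stats A `wchc_unistats` object.
#' @param thresholds Optional fixed threshold grid; `NULL` uses the adaptive
#'   per-vector grid.
#' @param n_mc Monte-Carlo sample size for the p-value (default 10000).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List with `statistic` (S_Het), `pvalue`, and `n_mc`.
#' @export
shet_test <- function(stats, thresholds = NULL, n_mc = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taus <- if (is.null(thresholds)) numeric(0) else as.numeric(thresholds)
  Corr <- stats$Corr
  M <- length(stats$t)
  obs <- shet_stat_kernel(matrix(stats$t, 1L), Corr, stats$W, taus)
  L <- chol(Corr)
  Z <- matrix(rnorm(n_mc * M), n_mc, M) %*% L
  null_stats <- shet_stat_kernel(Z, Corr, stats$W, taus)
  list(statistic = obs[1L], pvalue = sum(null_stats > obs[1L]) / n_mc,
       n_mc = as.integer(n_mc))
}

# Sixth-degree polynomial mapping the correlation of two test statistics to
# the correlation of their two-sided p-values (Li et al. 2011, extended
# Simes / effective-number literature); the dependence is even in r, so the
# polynomial is applied to |r|.  Verified against direct Monte-Carlo
# integration of bivariate-normal two-sided p-values (agrees to ~1e-3
# across r in [0, 1]).
.tates_pval_corr <- function(r) {
  a <- abs(r)
  0.2982 * a^6 - 0.0127 * a^5 + 0.0588 * a^4 + 0.0099 * a^3 +
    0.6281 * a^2 - 0.0009 * a
}

# Effective number of independent tests from eigenvalues: m - sum over
# eigenvalues above 1 of (lambda - 1).
.effective_number <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    warning("p-value correlation matrix not positive semi-definite; ",
            "negative eigenvalues clipped at 0")
  ev <- pmax(ev, 0)
  length(ev) - sum(pmax(ev - 1, 0))
}

#' TATES: extended Simes combination of per-phenotype p-values
#'
#' Sorts the p-values ascending and returns
#' `min_j Me * p_(j) / Me(j)`, where the effective numbers of independent
#' tests `Me` (all phenotypes) and `Me(j)` (top-j subset) come from the
#' eigenvalues of the p-value correlation matrix, itself derived from the
#' phenotype correlation matrix through a published sixth-degree polynomial.
#' With an identity correlation matrix this is exactly the Simes procedure.
#'
#' @param p Per-phenotype two-sided p-values in `(0, 1]`.
#' @param pheno_corr M x M phenotype correlation matrix.
#' @return Combined p-value (capped at 1).
#' @export
tates_test <- function(p, pheno_corr) {
  M <- length(p)
  if (M == 1L) return(p[1L])
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  ord <- order(p)
  Rp <- .tates_pval_corr(pheno_corr[ord, ord, drop = FALSE])
  diag(Rp) <- 1
  me_j <- vapply(seq_len(M), function(j)
    .effective_number(Rp[seq_len(j), seq_len(j), drop = FALSE]), numeric(1))
  me <- me_j[M]
  min(1, min(me * p[ord] / me_j))
}

#' MANOVA test of a variant against all phenotypes
#'
#' Multivariate regression of the phenotype matrix on genotype dosage;
#' Wilks' lambda with the Rao F approximation tests the hypothesis that all
#' M regression coefficients are zero.  With a single phenotype this is the
#' ordinary regression F-test.
#'
#' @inheritParams univariate_stats
#' @return List with `statistic` (approximate F), `wilks` (NA when M = 1),
#'   and `pvalue`.
#' @export
manova_test <- function(g, phenotypes) {
  Y <- .check_phenotypes(phenotypes, g)
  g <- .check_genotype(g)
  if (nrow(Y) <= ncol(Y) + 2L)
    stop("need N > M + 2 for MANOVA", call. = FALSE)
  if (ncol(Y) == 1L) {
    an <- anova(lm(Y[, 1L] ~ g))
    return(list(statistic = an[["F value"]][1L], wilks = NA_real_,
                pvalue = an[["Pr(>F)"]][1L]))
  }
  sm <- tryCatch(summary(stats::manova(Y ~ g), test = "Wilks")$stats,
                 error = function(e)
                   stop("MANOVA failed (singular residual covariance?): ",
                        conditionMessage(e), call. = FALSE))
  list(statistic = sm["g", "approx F"], wilks = sm["g", "Wilks"],
       pvalue = sm["g", "Pr(>F)"])
}

#' Reverse ordinal regression test (MultiPhen-style)
#'
#' Proportional-odds logistic regression of the genotype (an ordered
#' response with levels 0 < 1 < 2; levels absent in-sample collapse the
#' cut-points) on all phenotypes, compared to the intercept-only model by a
#' likelihood-ratio test on M degrees of freedom.  When only two genotype
#' levels are present the model reduces to binary logistic regression.
#'
#' @inheritParams univariate_stats
#' @return List with `statistic` (the LRT), `df`, and `pvalue` (NA with a
#'   warning if the fit does not converge).
#' @export
multiphen_test <- function(g, phenotypes) {
  Y <- .check_phenotypes(phenotypes, g)
  g <- .check_genotype(g)
  M <- ncol(Y)
  if (length(g) <= M + 2L)
    stop("need N > M + 2 for the ordinal regression", call. = FALSE)
  counts <- table(g)
  ll0 <- sum(counts * log(counts / length(g)))   # saturated cut-points only
  lrt <- tryCatch({
    if (length(counts) == 2L) {
      fit <- glm(I(g == max(g)) ~ Y, family = binomial())
      fit$null.deviance - fit$deviance
    } else {
      dat <- data.frame(gf = factor(g, ordered = TRUE))
      fit <- MASS::polr(gf ~ Y, data = dat, method = "logistic")
      if (fit$convergence != 0) stop("polr did not converge")
      2 * (as.numeric(logLik(fit)) - ll0)
    }
  }, error = function(e) {
    warning("ordinal regression failed: ", conditionMessage(e))
    NA_real_
  })
  list(statistic = lrt, df = M,
       pvalue = if (is.na(lrt)) NA_real_ else pchisq(lrt, df = M,
                                                     lower.tail = FALSE))
}

#' Run several association tests on one variant
#'
#' Convenience wrapper computing any subset of the seven implemented tests
#' on the same data, sharing the univariate statistics where applicable.
#'
#' @inheritParams wchc_test
#' @param methods Character vector among `"wchc"`, `"wcmulp"`, `"ob"`,
#'   `"shet"`, `"tates"`, `"manova"`, `"multiphen"`.
#' @param n_mc Monte-Carlo sample size for the SHet p-value.
#' @return Named numeric vector of p-values (NA for failed fits).
#' @export
compare_methods <- function(g, phenotypes,
                            methods = c("wchc", "wcmulp", "ob", "shet",
                                        "tates", "manova", "multiphen"),
                            B = 1000L, n_mc = B, partition = NULL,
                            seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  Y <- .check_phenotypes(phenotypes, g)
  if (!is.null(seed)) set.seed(seed)
  us <- if (any(methods %in% c("ob", "shet", "tates")))
    univariate_stats(g, Y)
  p <- setNames(rep(NA_real_, length(methods)), methods)
  for (m in methods) {
    p[m] <- switch(m,
      wchc = wchc_test(g, Y, partition = partition, B = B)$pvalue,
      wcmulp = wcmulp_test(g, Y, B = B)$pvalue,
      ob = obrien_test(us)$pvalue,
      shet = shet_test(us, n_mc = n_mc)$pvalue,
      tates = tates_test(us$p, us$Corr),
      manova = manova_test(g, Y)$pvalue,
      multiphen = multiphen_test(g, Y)$pvalue)
  }
  p
}
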