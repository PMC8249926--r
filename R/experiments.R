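#' Run one simulation scenario and collect per-replicate p-values
#'
#' The workhorse behind the type-I-error and power drivers: per replicate,
#' fresh genotypes and phenotypes are simulated from the factor model and
#' every requested method is applied.  Runs on a single master seed with one
#' sequential RNG stream, so results are fully determined by
#' `(arguments, seed)`.
#'
#' @param model_id Architecture 1-6 (see [model_config()]).
#' @param M Phenotype count.
#' @param beta Genetic effect size (0 for null runs).
#' @param methods Methods to apply (see [compare_methods()]).
#' @param n_replicates Number of simulated data sets.
#' @param B Permutations per replicate for the permutation tests.
#' @param n_mc Monte-Carlo sample size for the SHet p-value.
#' @param c2,rho_c2,maf,N Factor-model parameters (paper defaults).
#' @param seed Optional master seed.
#' @return List with `pvalues` (n_replicates x methods matrix, NA where a
#'   fit failed) and `config`.
#' @export
run_study <- function(model_id, M, beta,
                      methods = c("wchc", "wcmulp", "ob", "shet", "tates",
                                  "manova", "multiphen"),
                      n_replicates = 500L, B = 500L, n_mc = B,
                      c2 = 0.5, rho_c2 = 0.1, maf = 0.3, N = 1000L,
                      seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  spec <- model_config(model_id, M, beta, c2 = c2, rho_c2 = rho_c2,
                       maf = maf, N = N)
  P <- matrix(NA_real_, n_replicates, length(methods),
              dimnames = list(NULL, methods))
  for (rep_i in seq_len(n_replicates)) {
    repeat {
      g <- simulate_genotypes(N, maf)
      if (length(unique(g)) > 1L) break
    }
    Y <- simulate_phenotypes(spec, g)
    us <- if (any(methods %in% c("ob", "shet", "tates")))
      univariate_stats(g, Y)
    if (all(c("wchc", "wcmulp") %in% methods)) {
      # one permutation batch serves both the clustered and the trivial
      # partition; the statistics are the same linear-algebra pass
      parts <- list(cluster_phenotypes(Y),
                    structure(list(clusters = list(seq_len(M)), K = 1L,
                                   b_hat = 0L), class = "wchc_partition"))
      cores <- .wchc_core(g, Y, parts, B)
      P[rep_i, "wchc"] <- cores[[1L]]$exceed / B
      P[rep_i, "wcmulp"] <- cores[[2L]]$exceed / B
    }
    for (m in setdiff(methods, if (all(c("wchc", "wcmulp") %in% methods))
      c("wchc", "wcmulp") else character(0))) {
      P[rep_i, m] <- switch(m,
        wchc = wchc_test(g, Y, B = B)$pvalue,
        wcmulp = wcmulp_test(g, Y, B = B)$pvalue,
        ob = obrien_test(us)$pvalue,
        shet = shet_test(us, n_mc = n_mc)$pvalue,
        tates = tates_test(us$p, us$Corr),
        manova = manova_test(g, Y)$pvalue,
        multiphen = suppressWarnings(multiphen_test(g, Y)$pvalue))
    }
  }
  list(pvalues = P,
       config = list(model_id = model_id, M = M, beta = beta, c2 = c2,
                     rho_c2 = rho_c2, maf = maf, N = N, B = B, n_mc = n_mc,
                     n_replicates = n_replicates, seed = seed))
}

#' Rejection rates with exact binomial confidence intervals
#'
#' The rejection rule is `p < alpha` uniformly (permutation p-values can be
#' exactly 0, and on the permutation grid `p <= alpha` and `p < alpha`
#' differ only at grid points).  Failed fits (NA p-values) are excluded from
#' the denominator and counted separately.
#'
#' @param study Output of [run_study()], or a p-value matrix.
#' @param alpha Nominal significance level(s).
#' @return Data frame with method, alpha, rate, exact binomial 95% CI,
#'   n (replicates used), and n_failed.
#' @export
rejection_rates <- function(study, alpha = c(0.01, 0.05)) {
  P <- if (is.list(study)) study$pvalues else study
  out <- do.call(rbind, lapply(colnames(P), function(m) {
    p <- P[, m]
    ok <- !is.na(p)
    do.call(rbind, lapply(alpha, function(a) {
      x <- sum(p[ok] < a)
      ci <- binom.test(x, sum(ok))$conf.int
      data.frame(method = m, alpha = a, rate = x / sum(ok),
                 ci_lower = ci[1], ci_upper = ci[2],
                 n = sum(ok), n_failed = sum(!ok))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Estimate type-I error rates under the null factor model
#'
#' Runs [run_study()] with `beta = 0` for each architecture and tabulates
#' rejection rates at the requested levels.
#'
#' @param models Architecture ids to cover (default the three factor counts
#'   R = 1, 2, 4 via models 1, 2, 4).
#' @inheritParams run_study
#' @param alpha Nominal levels.
#' @return Tidy data frame: model, R, method, alpha, rate, CI, n.
#' @export
estimate_type1_error <- function(models = c(1L, 2L, 4L), M = 16L,
                                 methods = c("wchc", "wcmulp", "ob", "shet",
                                             "tates", "manova", "multiphen"),
                                 n_replicates = 500L, B = 500L, n_mc = B,
                                 alpha = c(0.01, 0.05),
                                 c2 = 0.5, rho_c2 = 0.1, maf = 0.3,
                                 N = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(models, function(mod) {
    st <- run_study(mod, M, beta = 0, methods = methods,
                    n_replicates = n_replicates, B = B, n_mc = n_mc,
                    c2 = c2, rho_c2 = rho_c2, maf = maf, N = N)
    rr <- rejection_rates(st, alpha)
    cbind(data.frame(model = mod, R = c(1L, 2L, 2L, 4L, 4L, 4L)[mod]), rr)
  }))
  rownames(out) <- NULL
  out
}

#' Estimate power under the alternative factor model
#'
#' Sweeps a grid of effect sizes (and optionally within-factor
#' correlations) for one architecture; `beta = 0` rows degenerate to
#' type-I-error estimates.
#'
#' @inheritParams run_study
#' @param beta Vector of effect sizes.
#' @param c2 Vector of within-factor correlations.
#' @param alpha Significance level(s) for the rejection rule.
#' @return Tidy data frame: model, beta, c2, method, alpha, power, CI, n.
#' @export
estimate_power <- function(model_id, M, beta,
                           methods = c("wchc", "wcmulp", "ob", "shet",
                                       "tates", "manova", "multiphen"),
                           n_replicates = 500L, B = 500L, n_mc = B,
                           alpha = 0.05, c2 = 0.5, rho_c2 = 0.1, maf = 0.3,
                           N = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(beta = beta, c2 = c2)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    st <- run_study(model_id, M, beta = grid$beta[i], methods = methods,
                    n_replicates = n_replicates, B = B, n_mc = n_mc,
                    c2 = grid$c2[i], rho_c2 = rho_c2, maf = maf, N = N)
    rr <- rejection_rates(st, alpha)
    names(rr)[names(rr) == "rate"] <- "power"
    cbind(data.frame(model = model_id, beta = grid$beta[i],
                     c2 = grid$c2[i]), rr)
  }))
  rownames(out) <- NULL
  out
}

#' Normal-approximation confidence interval for a nominal rejection rate
#'
#' `alpha +/- z * sqrt(alpha (1 - alpha) / n)` — the interval the study
#' tables quote around nominal levels (e.g. (0.0056, 0.0144) at 0.01 and
#' (0.0404, 0.0596) at 0.05 for 2,000 replicates).
#'
#' @param alpha Nominal level.
#' @param n_replicates Number of replicates.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
nominal_type1_ci <- function(alpha, n_replicates, level = 0.95) {
  z <- qnorm((1 + level) / 2)
  half <- z * sqrt(alpha * (1 - alpha) / n_replicates)
  c(lower = alpha - half, upper = alpha + half)
}

#' Scenario presets for the reference simulation study
#'
#' Encodes the study grids: `table1`/`table2` are the null (type-I error)
#' runs at M = 16 / 32 over factor counts R = 1, 2, 4; `fig1`/`fig2` sweep
#' power against effect size for all six architectures; `fig3`/`fig4` sweep
#' power against the within-factor correlation at the per-model effect
#' sizes of the corresponding figure captions.
#'
#' @param name Preset name.
#' @param scale Multiplier applied to replicates, permutations, and the
#'   SHet Monte-Carlo size for desk-scale runs (1 = full scale).
#' @param beta_grid Effect-size grid for `fig1`/`fig2` (no canonical values
#'   exist; the default spans the reported power range).
#' @return A config list understood by [run_experiment()].
#' @export
experiment_preset <- function(name = c("table1", "table2", "fig1", "fig2",
                                       "fig3", "fig4"),
                              scale = 1, beta_grid = NULL) {
  name <- match.arg(name)
  sc <- function(n) max(10L, as.integer(round(n * scale)))
  base <- list(name = name, maf = 0.3, N = 1000L, rho_c2 = 0.1,
               scale = scale)
  if (name %in% c("table1", "table2")) {
    c(base, list(kind = "type1", models = c(1L, 2L, 4L),
                 M = if (name == "table1") 16L else 32L,
                 c2 = 0.5, alpha = c(0.01, 0.05),
                 n_replicates = sc(2000), B = sc(2000), n_mc = sc(2000)))
  } else if (name %in% c("fig1", "fig2")) {
    if (is.null(beta_grid)) beta_grid <- seq(0.02, 0.12, by = 0.02)
    c(base, list(kind = "power", models = 1:6,
                 M = if (name == "fig1") 16L else 32L,
                 beta = beta_grid, c2 = 0.5, alpha = 0.05,
                 n_replicates = sc(1000), B = sc(1000), n_mc = sc(1000)))
  } else {
    beta_by_model <- if (name == "fig3")
      c(0.09, 0.09, 0.08, 0.10, 0.10, 0.07)
    else
      c(0.10, 0.09, 0.08, 0.10, 0.10, 0.10)
    c(base, list(kind = "power_c2", models = 1:6,
                 M = if (name == "fig3") 16L else 32L,
                 beta_by_model = beta_by_model,
                 c2 = c(0.3, 0.5, 0.7, 0.9), alpha = 0.05,
                 n_replicates = sc(1000), B = sc(1000), n_mc = sc(1000)))
  }
}

#' Execute an experiment preset
#'
#' @param config A config list from [experiment_preset()].
#' @param methods Methods to run.
#' @param seed Master seed.
#' @return Tidy data frame of rates/powers across the preset's grid.
#' @export
run_experiment <- function(config,
                           methods = c("wchc", "wcmulp", "ob", "shet",
                                       "tates", "manova", "multiphen"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$kind == "type1") {
    estimate_type1_error(models = config$models, M = config$M,
                         methods = methods,
                         n_replicates = config$n_replicates, B = config$B,
                         n_mc = config$n_mc, alpha = config$alpha,
                         c2 = config$c2, rho_c2 = config$rho_c2,
                         maf = config$maf, N = config$N)
  } else if (config$kind == "power") {
    do.call(rbind, lapply(config$models, function(mod)
      estimate_power(mod, config$M, beta = config$beta, methods = methods,
                     n_replicates = config$n_replicates, B = config$B,
                     n_mc = config$n_mc, alpha = config$alpha,
                     c2 = config$c2, rho_c2 = config$rho_c2,
                     maf = config$maf, N = config$N)))
  } else {
    do.call(rbind, lapply(seq_along(config$models), function(i)
      estimate_power(config$models[i], config$M,
                     beta = config$beta_by_model[i], methods = methods,
                     n_replicates = config$n_replicates, B = config$B,
                     n_mc = config$n_mc, alpha = config$alpha,
                     c2 = config$c2, rho_c2 = config$rho_c2,
                     maf = config$maf, N = config$N)))
  }
}
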