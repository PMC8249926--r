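#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Minor-allele dosages are iid Binomial(2, MAF).
#'
#' @param N Sample size.
#' @param maf Minor-allele frequency in `(0, 0.5]`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of dosages in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(N, maf, seed = NULL) {
  if (maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rbinom(N, 2L, maf)
}

#' Factor-model configuration for the six genetic architectures
#'
#' Builds the effect-size vector lambda and the block-diagonal loading
#' matrix gamma for one of six architectures:
#' \describe{
#'   \item{1}{one factor; the variant affects all phenotypes equally
#'     (`R = 1`, `lambda = beta * 1_M`).}
#'   \item{2}{two factors; equal effects on the second factor's phenotypes
#'     only.}
#'   \item{3}{two factors; increasing effects
#'     `beta * (j/(M+1) + 1)`, `j = 1..M/2`, on the second factor.}
#'   \item{4}{four factors; equal effects on the last factor only.}
#'   \item{5}{four factors; increasing effects on the last factor.}
#'   \item{6}{four factors; effects of opposite sign on the last two
#'     factors (`-beta * (j/(M+1) + 1)` then `+beta`).}
#' }
#' Phenotypes sharing a factor have correlation `c2`; phenotypes on
#' different factors have correlation `rho_c2` (the factor correlation is
#' `rho = rho_c2 / c2`).
#'
#' @param model_id Integer 1-6.
#' @param M Phenotype count (divisible by 2 for models 2-3, by 4 for 4-6).
#' @param beta Genetic effect size (0 gives the null configuration).
#' @param c2 Within-factor phenotype correlation (loading constant squared).
#' @param rho_c2 Between-factor phenotype correlation.
#' @param maf Minor-allele frequency.
#' @param N Sample size carried in the spec.
#' @return A `wchc_sim_spec` list with `model_id`, `M`, `R`, `beta`,
#'   `lambda`, `gamma`, `c`, `c2`, `rho`, `rho_c2`, `maf`, `N`.
#' @export
model_config <- function(model_id, M, beta, c2 = 0.5, rho_c2 = 0.1,
                         maf = 0.3, N = 1000L) {
  stopifnot(model_id %in% 1:6, c2 >= 0, c2 <= 1, rho_c2 >= 0)
  R <- c(1L, 2L, 2L, 4L, 4L, 4L)[model_id]
  if (M %% R != 0L)
    stop("M = ", M, " is not divisible by the model's factor count R = ", R,
         call. = FALSE)
  blk <- M %/% R
  ramp <- function(n) beta / (M + 1) * seq_len(n) + beta
  lambda <- switch(model_id,
    rep(beta, M),
    c(rep(0, M / 2), rep(beta, M / 2)),
    c(rep(0, M / 2), ramp(M / 2)),
    c(rep(0, 3 * M / 4), rep(beta, M / 4)),
    c(rep(0, 3 * M / 4), ramp(M / 4)),
    c(rep(0, M / 2), -ramp(M / 4), rep(beta, M / 4)))
  gamma <- matrix(0, M, R)
  for (r in seq_len(R)) gamma[(r - 1L) * blk + seq_len(blk), r] <- 1
  rho <- if (c2 > 0) rho_c2 / c2 else 0
  if (rho > 1)
    stop("rho_c2 / c2 = ", rho, " exceeds 1: invalid factor correlation",
         call. = FALSE)
  structure(list(model_id = as.integer(model_id), M = as.integer(M), R = R,
                 beta = beta, lambda = lambda, gamma = gamma,
                 c = sqrt(c2), c2 = c2, rho = rho, rho_c2 = rho_c2,
                 maf = maf, N = as.integer(N)),
            class = "wchc_sim_spec")
}

#' Simulate phenotypes from the factor model
#'
#' Per individual with genotype `x`:
#' `y = lambda x + c gamma f + sqrt(1 - c^2) eps`, with factor vector
#' `f ~ MVN(0, (1 - rho) I_R + rho 1 1')` and iid standard-normal errors.
#' Under `beta = 0` every phenotype has unit variance and the phenotype
#' correlations are `c2` within and `rho_c2` between factors.  Factors are
#' drawn before errors, so the two noise components can be held fixed
#' independently by seeding.
#'
#' @param spec A `wchc_sim_spec` from [model_config()].
#' @param g Genotype dosage vector of length `spec$N` (or any length;
#'   phenotype rows follow `g`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return N x M numeric matrix with columns `Y1..YM`.
#' @export
simulate_phenotypes <- function(spec, g, seed = NULL) {
  stopifnot(inherits(spec, "wchc_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  N <- length(g)
  R <- spec$R
  Sf <- (1 - spec$rho) * diag(R) + spec$rho
  Fm <- matrix(rnorm(N * R), N, R) %*% chol(Sf)
  E <- matrix(rnorm(N * spec$M), N, spec$M)
  Y <- outer(g, spec$lambda) + spec$c * (Fm %*% t(spec$gamma)) +
    sqrt(1 - spec$c2) * E
  colnames(Y) <- paste0("Y", seq_len(spec$M))
  Y
}

#' Heritability implied by a simulation configuration
#'
#' Per phenotype, `h2_j = var(x) lambda_j^2 / (var(x) lambda_j^2 + 1)` with
#' `var(x) = 2 maf (1 - maf)`; the total is the sum over phenotypes, with
#' the first-order approximation `var(x) sum(lambda^2)` also reported.
#'
#' @param spec A `wchc_sim_spec`.
#' @return List with `var_x`, `per_phenotype`, `total`, `total_approx`.
#' @export
heritability <- function(spec) {
  stopifnot(inherits(spec, "wchc_sim_spec"))
  var_x <- 2 * spec$maf * (1 - spec$maf)
  h2 <- var_x * spec$lambda^2 / (var_x * spec$lambda^2 + 1)
  list(var_x = var_x, per_phenotype = h2, total = sum(h2),
       total_approx = var_x * sum(spec$lambda^2))
}
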