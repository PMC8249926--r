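#' Expand genotypes to allele-level indicators
#'
#' Each individual contributes two rows: genotype 2 (two minor alleles)
#' becomes indicators (1, 1), genotype 0 becomes (0, 0), and a heterozygote
#' becomes (1, 0).  Phenotype rows are duplicated accordingly, so the
#' association is scored on 2N allele records.  Every downstream statistic
#' depends on the indicators only through the per-individual sums, so the
#' (1, 0) vs (0, 1) order within a heterozygote is immaterial.
#'
#' @param g Genotype dosage vector (values in `{0, 1, 2}`).
#' @param phenotypes Numeric matrix, individuals x phenotypes.
#' @return List with `x` (binary vector, length 2N), `y` (2N x M matrix with
#'   duplicated rows), and `pairing` (2N-vector mapping rows to individuals).
#' @export
allele_expand <- function(g, phenotypes) {
  Y <- .check_phenotypes(phenotypes, g)
  g <- .check_genotype(g, require_polymorphic = FALSE)
  N <- length(g)
  x <- as.integer(rbind(g >= 1L, g == 2L))      # rows 2i-1, 2i per individual
  idx <- rep(seq_len(N), each = 2L)
  list(x = x, y = Y[idx, , drop = FALSE], pairing = idx)
}

#' Optimal combination weights for a phenotype cluster
#'
#' Per phenotype j in the cluster, the weight is the slope of the allele
#' indicator on that phenotype over the 2N expanded rows:
#' `w_j = sum((x - xbar) (y_j - ybar_j)) / sum((y_j - ybar_j)^2)`.
#' The weighted sum of cluster phenotypes is the single combined phenotype
#' that the score statistic is computed on.
#'
#' @param design An expanded design from [allele_expand()].
#' @param cluster Integer vector of phenotype column indices.
#' @return Numeric weight vector (one per cluster phenotype).
#' @export
combination_weights <- function(design, cluster) {
  x <- design$x
  Yk <- design$y[, cluster, drop = FALSE]
  xc <- x - mean(x)
  yc <- scale(Yk, center = TRUE, scale = FALSE)
  v <- colSums(yc^2)
  if (any(v == 0))
    stop("zero-variance phenotype in cluster: ",
         paste(colnames(Yk)[v == 0], collapse = ", "), call. = FALSE)
  drop(crossprod(yc, xc)) / v
}

#' Weighted-combination score statistic for one cluster
#'
#' Computes `T = sum((x - xbar) (y - ybar))` where `y` is the weighted
#' combination of the cluster phenotypes with the weights of
#' [combination_weights()].  Algebraically `T = sum_j c_j^2 / v_j` with
#' `c_j` the centered cross-sum of x with phenotype j and `v_j` that
#' phenotype's centered sum of squares, so `T >= 0` always.
#'
#' @inheritParams combination_weights
#' @return List with `weights` and the statistic `T`.
#' @export
cluster_statistic <- function(design, cluster) {
  w <- combination_weights(design, cluster)
  x <- design$x
  xc <- x - mean(x)
  ycomb <- drop(design$y[, cluster, drop = FALSE] %*% w)
  list(weights = w, T = sum(xc * (ycomb - mean(ycomb))))
}

#' Uniformly permute a genotype vector
#'
#' Shuffles dosages at the individual level using the current RNG stream;
#' allele expansion is re-derived from the permuted counts.
#'
#' @param g Genotype dosage vector.
#' @return Permuted genotype vector.
#' @export
permute_genotypes <- function(g) {
  g[sample.int(length(g))]
}

# p_k^(b) = #{d in 0..B : T[d] > T[b]} / B, columnwise for a K x (B+1)
# statistic matrix whose first column is the observed data.
.perm_pvalues <- function(Tmat) {
  B <- ncol(Tmat) - 1L
  t(apply(Tmat, 1L, function(tk)
    (length(tk) - rank(tk, ties.method = "max")) / B))
}

#' WCHC: min-p permutation test over phenotype clusters
#'
#' For each cluster of the partition the weighted-combination statistic is
#' computed on the observed data and on `B` random genotype permutations
#' (weights are recomputed in every permutation since they depend on the
#' allele indicators).  Per-cluster permutation p-values use strict
#' greater-than counting over all `B + 1` statistics with denominator `B`;
#' the global statistic is the minimum cluster p-value, and its p-value is
#' the fraction of permutations with a strictly smaller minimum.  The
#' partition is computed once from the observed phenotypes and held fixed
#' across permutations.
#'
#' @param g Genotype dosage vector (polymorphic).
#' @param phenotypes Numeric matrix, individuals x phenotypes (covariate
#'   residuals if adjustment applies; see [adjust_covariates()]).
#' @param partition Optional `wchc_partition`; computed by
#'   [cluster_phenotypes()] when `NULL`.
#' @param B Number of permutations (default 1000).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param correction `"none"` keeps the plain `r / B` estimator (p-values of
#'   exactly 0 are possible); `"add-one"` uses `(r + 1) / (B + 1)`.
#' @return A `wchc_result`: variant id, `K`, per-cluster statistics and
#'   p-values, `t_wchc` (the min cluster p-value), the global `pvalue`, `B`,
#'   and the seed used.
#' @export
#' @examples
#' set.seed(1)
#' g <- simulate_genotypes(200, maf = 0.3)
#' spec <- model_config(2, M = 8, beta = 0.25)
#' Y <- simulate_phenotypes(spec, g)
#' wchc_test(g, Y, B = 200, seed = 42)
wchc_test <- function(g, phenotypes, partition = NULL, B = 1000L,
                      seed = NULL, correction = c("none", "add-one")) {
  correction <- match.arg(correction)
  Y <- .check_phenotypes(phenotypes, g)
  g <- .check_genotype(g)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (is.null(partition)) {
    partition <- if (ncol(Y) == 1L)
      structure(list(clusters = list(1L), K = 1L, b_hat = 0L),
                class = "wchc_partition")
    else cluster_phenotypes(Y)
  }
  if (!setequal(unlist(partition$clusters), seq_len(ncol(Y))))
    stop("partition does not cover the phenotype columns", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  core <- .wchc_core(g, Y, list(partition), B)[[1L]]
  r <- core$exceed
  pvalue <- if (correction == "add-one") (r + 1) / (B + 1) else r / B
  structure(list(
    variant_id = attr(g, "variant_id") %||% "variant",
    K = partition$K, partition = partition,
    cluster_statistics = core$cluster_statistics,
    cluster_pvalues = core$cluster_pvalues,
    t_wchc = core$t_wchc, pvalue = pvalue,
    B = as.integer(B), seed = seed, correction = correction),
    class = "wchc_result")
}

# Shared permutation engine: one batch of permuted genotypes scored against
# one or more partitions of the same phenotype matrix.  Returns, per
# partition, the observed cluster statistics/p-values, the min-p statistic,
# and the count of permutations beating it.
.wchc_core <- function(g, Y, partitions, B) {
  N <- length(g)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  v <- 2 * colSums(Yc^2)              # centered SS over the 2N expanded rows
  if (any(v == 0))
    stop("zero-variance phenotype: ",
         paste(colnames(Y)[v == 0], collapse = ", "), call. = FALSE)
  G <- perm_matrix(as.integer(g), as.integer(B))
  # Yc has zero column sums, so crossprod(Yc, G) already equals the centered
  # cross-sums c_j^(b); over the expanded rows c is unchanged and v doubles.
  C2 <- crossprod(Yc, G)^2            # M x (B+1)
  lapply(partitions, function(partition) {
    K <- partition$K
    Tmat <- matrix(0, K, B + 1L)
    for (k in seq_len(K))
      Tmat[k, ] <- colSums(C2[partition$clusters[[k]], , drop = FALSE] /
                             v[partition$clusters[[k]]])
    pmat <- .perm_pvalues(Tmat)
    t_all <- apply(pmat, 2L, min)
    list(cluster_statistics = Tmat[, 1L], cluster_pvalues = pmat[, 1L],
         t_wchc = t_all[1L], exceed = sum(t_all[-1L] < t_all[1L]))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wchc_result <- function(x, ...) {
  cat("WCHC permutation test -", x$variant_id, "\n")
  cat("  clusters: K =", x$K, "\n")
  cat("  cluster p-values:", paste(format(x$cluster_pvalues, digits = 4),
                                   collapse = ", "), "\n")
  cat("  T_WCHC (min p):", format(x$t_wchc, digits = 4), "\n")
  cat(sprintf("  p-value: %s  (B = %d permutations)\n",
              format(x$pvalue, digits = 4), x$B))
  invisible(x)
}

#' WCmulP: weighted combination of all phenotypes, no clustering
#'
#' Identical to [wchc_test()] with the trivial single-cluster partition
#' containing every phenotype.
#'
#' @inheritParams wchc_test
#' @return A `wchc_result` with `K = 1`.
#' @export
wcmulp_test <- function(g, phenotypes, B = 1000L, seed = NULL,
                        correction = c("none", "add-one")) {
  Y <- .check_phenotypes(phenotypes, g)
  part <- structure(list(clusters = list(seq_len(ncol(Y))), K = 1L,
                         b_hat = 0L), class = "wchc_partition")
  wchc_test(g, Y, partition = part, B = B, seed = seed,
            correction = match.arg(correction))
}

# Reference (loop) form of the permutation pass: draws the same permutation
# batch, then recomputes every statistic through
# allele_expand()/cluster_statistic().  Used in tests to pin the batched
# linear-algebra path.
.wchc_test_loop <- function(g, phenotypes, partition, B, seed = NULL) {
  Y <- .check_phenotypes(phenotypes, g)
  g <- .check_genotype(g)
  if (!is.null(seed)) set.seed(seed)
  G <- perm_matrix(as.integer(g), as.integer(B))
  K <- partition$K
  Tmat <- matrix(0, K, B + 1L)
  for (b in 0:B) {
    design <- allele_expand(G[, b + 1L], Y)
    for (k in seq_len(K))
      Tmat[k, b + 1L] <- cluster_statistic(design,
                                           partition$clusters[[k]])$T
  }
  pmat <- .perm_pvalues(Tmat)
  t_all <- apply(pmat, 2L, min)
  list(Tmat = Tmat, pmat = pmat, t_wchc = t_all[1L],
       pvalue = sum(t_all[-1L] < t_all[1L]) / B)
}
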