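#' Similarity between two single phenotypes
#'
#' Absolute Pearson correlation.  The clustering similarity is sign-blind by
#' design: the per-phenotype combination weights downstream carry the sign of
#' the association, so strongly negatively correlated phenotypes belong in
#' the same cluster.
#'
#' @param y_a,y_b Numeric vectors of equal length with positive variance.
#' @return Similarity in `[0, 1]`.
#' @export
pairwise_similarity <- function(y_a, y_b) {
  if (sd(y_a) == 0 || sd(y_b) == 0)
    stop("zero-variance phenotype column", call. = FALSE)
  abs(cor(y_a, y_b))
}

#' Similarity between two clusters of phenotypes
#'
#' Size-dependent correlation similarity: absolute Pearson correlation for
#' singleton vs singleton, the multiple correlation coefficient (square root
#' of the OLS R-squared of the singleton on the block) for singleton vs
#' block, and the first canonical correlation for block vs block.  All three
#' are the largest singular value of the whitened cross-covariance, so one
#' eigen computation covers every case.
#'
#' @param block_a,block_b Numeric matrices (or vectors) holding the columns
#'   of each cluster; same number of rows.
#' @return Similarity in `[0, 1]`.
#' @export
cluster_similarity <- function(block_a, block_b) {
  A <- as.matrix(block_a); B <- as.matrix(block_b)
  if (nrow(A) != nrow(B)) stop("blocks must have equal rows", call. = FALSE)
  S <- cov(cbind(A, B))
  .block_similarity(S, seq_len(ncol(A)), ncol(A) + seq_len(ncol(B)))
}

# First canonical correlation from covariance sub-blocks:
# sqrt of the largest eigenvalue of Saa^-1 Sab Sbb^-1 Sba.  Reduces to the
# multiple correlation when |a| = 1 and to |Pearson| when both are singletons.
.block_similarity <- function(S, a, b) {
  if (length(a) == 1L && length(b) == 1L)
    return(min(1, abs(S[a, b]) / sqrt(S[a, a] * S[b, b])))
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  Sab <- S[a, b, drop = FALSE]
  if (length(a) == 1L) {             # multiple correlation, no eigen needed
    r2 <- drop(Sab %*% solve(S[b, b], t(Sab))) / S[a, a]
    return(sqrt(min(1, max(0, r2))))
  }
  M1 <- tryCatch(solve(S[a, a], Sab), error = function(e)
    stop("singular within-block covariance (collinear phenotypes)",
         call. = FALSE))
  M2 <- tryCatch(solve(S[b, b], t(Sab)), error = function(e)
    stop("singular within-block covariance (collinear phenotypes)",
         call. = FALSE))
  ev <- eigen(M1 %*% M2, only.values = TRUE)$values
  sqrt(min(1, max(0, max(Re(ev)))))
}

#' Bottom-up hierarchical clustering of phenotypes
#'
#' Starts from singleton clusters and repeatedly merges the pair with the
#' largest similarity ([cluster_similarity()]), recording the similarity of
#' each merged pair as the height of that iteration.  Similarities are
#' recomputed from the covariance matrix at every step (there is no
#' Lance-Williams update for multiple/canonical correlation).  Ties break to
#' the lexicographically smallest pair of smallest member indices, so results
#' are deterministic.
#'
#' @param phenotypes Numeric matrix, individuals x phenotypes (M >= 2
#'   columns, all with positive variance).
#' @return A `wchc_dendrogram`: list with `merges` (list of `members_a`,
#'   `members_b`, `height` per iteration) and `M`.
#' @export
agglomerate <- function(phenotypes) {
  Y <- .check_phenotypes(phenotypes)
  M <- ncol(Y)
  if (M < 2L) stop("need at least 2 phenotypes to cluster", call. = FALSE)
  if (any(apply(Y, 2L, sd) == 0))
    stop("zero-variance phenotype column", call. = FALSE)
  S <- cov(Y)
  clusters <- as.list(seq_len(M))     # kept ordered by smallest member
  n <- M
  sims <- matrix(NA_real_, M, M)
  for (i in seq_len(M - 1L)) for (j in seq((i + 1L), M))
    sims[i, j] <- .block_similarity(S, clusters[[i]], clusters[[j]])
  merges <- vector("list", M - 1L)
  for (step in seq_len(M - 1L)) {
    best <- -Inf; bi <- bj <- 0L
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      if (sims[i, j] > best) { best <- sims[i, j]; bi <- i; bj <- j }
    }
    merges[[step]] <- list(members_a = sort(clusters[[bi]]),
                           members_b = sort(clusters[[bj]]),
                           height = best)
    clusters[[bi]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bj]] <- NULL
    sims <- sims[-bj, -bj, drop = FALSE]
    n <- n - 1L
    if (n > 1L) {
      for (j in seq_len(n)) {
        if (j == bi) next
        i <- min(bi, j); jj <- max(bi, j)
        sims[i, jj] <- .block_similarity(S, clusters[[i]], clusters[[jj]])
      }
    }
  }
  structure(list(merges = merges, M = M), class = "wchc_dendrogram")
}

#' @export
print.wchc_dendrogram <- function(x, ...) {
  cat("Hierarchical phenotype clustering (", x$M, " phenotypes)\n", sep = "")
  for (b in seq_along(x$merges)) {
    m <- x$merges[[b]]
    cat(sprintf("  %2d: {%s} + {%s}  h = %.4f\n", b,
                paste(m$members_a, collapse = ","),
                paste(m$members_b, collapse = ","), m$height))
  }
  invisible(x)
}

#' Choose the number of clusters by the largest drop in merge height
#'
#' Picks the iteration b-hat minimising `h[b+1] - h[b]` (the biggest fall in
#' similarity between consecutive merges) over `b = 1..M-2`; the partition is
#' the set of clusters present after iteration b-hat, so `K = M - b_hat`.
#' Ties break to the smallest b (more clusters).  For `M = 2` the rule is
#' vacuous and the single all-phenotype cluster is returned.  Heights need
#' not be monotone and the rule does not assume they are.
#'
#' @param trace A `wchc_dendrogram` from [agglomerate()].
#' @return A `wchc_partition`: list with `clusters` (list of integer index
#'   vectors, ordered by smallest member), `K`, and `b_hat`.
#' @export
select_partition <- function(trace) {
  stopifnot(inherits(trace, "wchc_dendrogram"))
  M <- trace$M
  heights <- vapply(trace$merges, `[[`, numeric(1), "height")
  b_hat <- if (M == 2L) 1L else which.min(diff(heights))
  clusters <- as.list(seq_len(M))
  for (b in seq_len(b_hat)) {
    m <- trace$merges[[b]]
    ia <- which(vapply(clusters, function(cl) m$members_a[1] %in% cl,
                       logical(1)))
    ib <- which(vapply(clusters, function(cl) m$members_b[1] %in% cl,
                       logical(1)))
    clusters[[ia]] <- sort(c(clusters[[ia]], clusters[[ib]]))
    clusters[[ib]] <- NULL
  }
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  structure(list(clusters = clusters, K = length(clusters),
                 b_hat = as.integer(b_hat)),
            class = "wchc_partition")
}

#' @export
print.wchc_partition <- function(x, ...) {
  cat("Phenotype partition: K =", x$K, "(b_hat =", x$b_hat, ")\n")
  for (k in seq_len(x$K))
    cat(sprintf("  C%d: {%s}\n", k, paste(x$clusters[[k]], collapse = ",")))
  invisible(x)
}

#' Cluster phenotypes and select the partition in one call
#'
#' @inheritParams agglomerate
#' @return A `wchc_partition` (see [select_partition()]).
#' @export
cluster_phenotypes <- function(phenotypes) {
  select_partition(agglomerate(phenotypes))
}

#' Export a merge trace and partition as tab-separated tables
#'
#' @param trace A `wchc_dendrogram`.
#' @param path Output TSV path for the merge trace.
#' @param partition Optional `wchc_partition`; when given, written to
#'   `<path>.partition.tsv`.
#' @return Invisibly, the trace data frame.
#' @export
write_cluster_trace <- function(trace, path, partition = NULL) {
  df <- do.call(rbind, lapply(seq_along(trace$merges), function(b) {
    m <- trace$merges[[b]]
    data.frame(iteration = b,
               members_a = paste(m$members_a, collapse = ","),
               members_b = paste(m$members_b, collapse = ","),
               height = m$height)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(partition)) {
    pf <- data.frame(cluster = seq_len(partition$K),
                     members = vapply(partition$clusters, paste,
                                      character(1), collapse = ","))
    write.table(pf, paste0(path, ".partition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
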