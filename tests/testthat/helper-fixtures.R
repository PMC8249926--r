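# Shared fixture builders; everything is generated in code, nothing stored.

rand_phenotypes <- function(n, m) {
  Y <- matrix(rnorm(n * m), n, m)
  colnames(Y) <- paste0("Y", seq_len(m))
  Y
}

# polymorphic genotype vector of length n
rand_genotypes <- function(n, maf = 0.3) {
  repeat {
    g <- rbinom(n, 2, maf)
    if (length(unique(g)) > 1L) return(g)
  }
}

trivial_partition <- function(m) {
  structure(list(clusters = list(seq_len(m)), K = 1L, b_hat = 0L),
            class = "wchc_partition")
}

make_partition <- function(clusters) {
  structure(list(clusters = clusters, K = length(clusters),
                 b_hat = NA_integer_), class = "wchc_partition")
}

# dendrogram trace built by hand (merges must be replay-consistent)
make_trace <- function(merges, M) {
  structure(list(merges = merges, M = M), class = "wchc_dendrogram")
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal single-sample-block VCF with given GT strings (one row per variant)
write_vcf <- function(gt_rows, ids, path = tempfile(fileext = ".vcf"),
                      alts = NULL) {
  n_var <- length(gt_rows)
  if (is.null(alts)) alts <- rep("A", n_var)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(n_var), function(i)
    paste(c("1", as.character(100 + i), paste0("rs", i), "G", alts[i], ".",
            "PASS", ".", "GT", gt_rows[[i]]), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  path
}

# independent oracle for the cluster statistic: explicit double loop over
# the 2N expanded rows, per the sum-of-squares identity T = sum_j c_j^2/v_j
oracle_cluster_statistic <- function(g, Y, cluster) {
  x <- unlist(lapply(g, function(gi) switch(gi + 1L, c(0L, 0L), c(1L, 0L),
                                            c(1L, 1L))))
  Yx <- Y[rep(seq_along(g), each = 2L), , drop = FALSE]
  total <- 0
  for (j in cluster) {
    cj <- 0; vj <- 0
    ybar <- mean(Yx[, j]); xbar <- mean(x)
    for (l in seq_along(x)) {
      cj <- cj + (x[l] - xbar) * (Yx[l, j] - ybar)
      vj <- vj + (Yx[l, j] - ybar)^2
    }
    total <- total + cj^2 / vj
  }
  total
}
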