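#' Read a phenotype (or covariate) table
#'
#' Reads a delimited text file with one row per individual and named columns,
#' returning a numeric matrix with individual ids as row names.  Rows with a
#' missing or non-numeric value in any requested column are dropped
#' (complete-case ingestion) and the number of exclusions is reported via
#' [message()] and stored in the `"n_excluded"` attribute.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param id_column Name or index of the individual-id column (default: first
#'   column).
#' @param phenotype_columns Character vector of column names to keep; `NULL`
#'   keeps every column except the id column.
#' @param sep Field separator (tab by default; use `","` for CSV).
#' @return Numeric matrix (individuals x phenotypes) with `rownames` set to
#'   individual ids, and attribute `n_excluded` counting dropped rows.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(id = c("a", "b", "c"), bmi = c(27.1, 31.4, 24.9),
#'                        whr = c(0.91, 1.02, 0.88)),
#'             tf, sep = "\t", quote = FALSE, row.names = FALSE)
#' read_phenotype_table(tf)
read_phenotype_table <- function(path, id_column = 1L,
                                 phenotype_columns = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""),
                    comment.char = "#")
  if (is.numeric(id_column)) id_column <- names(raw)[id_column]
  if (!id_column %in% names(raw))
    stop("id column '", id_column, "' not found in ", path, call. = FALSE)
  if (is.null(phenotype_columns))
    phenotype_columns <- setdiff(names(raw), id_column)
  missing_cols <- setdiff(phenotype_columns, names(raw))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ids <- raw[[id_column]]
  vals <- suppressWarnings(
    vapply(raw[phenotype_columns], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, phenotype_columns))
  keep <- rowSums(is.na(vals)) == 0L
  n_excluded <- sum(!keep)
  if (n_excluded > 0L)
    message(n_excluded, " row(s) with missing/non-numeric values excluded")
  if (sum(keep) < 2L)
    stop("fewer than 2 complete rows in ", path, call. = FALSE)
  out <- vals[keep, , drop = FALSE]
  rownames(out) <- ids[keep]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Read genotype dosages from a TSV matrix or a VCF
#'
#' TSV input holds individuals as rows (first column = individual id) and
#' variants as columns with dosages in `{0, 1, 2}`; VCF input must contain
#' biallelic records with a GT field.  Dosages always count the in-sample
#' minor allele: if the counted (ALT) allele has in-sample frequency above
#' 0.5 the coding is flipped to the other allele and the flip is reported.
#' Individuals with a missing genotype are dropped for that variant only.
#'
#' @param path Path to the genotype file.
#' @param variant_ids Optional character vector restricting which variants to
#'   return (error if any is absent).
#' @param format `"auto"` (by file extension), `"tsv"`, or `"vcf"`.
#' @return Named list of genotype vectors.  Each element is an integer vector
#'   of dosages with individual ids as names and attributes `variant_id` and
#'   `flipped` (logical: was the allele orientation flipped at read time).
#' @export
read_genotypes <- function(path, variant_ids = NULL,
                           format = c("auto", "tsv", "vcf")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  vars <- if (format == "vcf") .read_genotypes_vcf(path)
          else .read_genotypes_tsv(path)
  if (!is.null(variant_ids)) {
    missing_ids <- setdiff(variant_ids, names(vars))
    if (length(missing_ids))
      stop("unknown variant id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    vars <- vars[variant_ids]
  }
  vars
}

.orient_minor <- function(dos, variant_id) {
  # enforce the minor-allele counting convention (ties left unflipped)
  flipped <- FALSE
  if (mean(dos, na.rm = TRUE) / 2 > 0.5) {
    dos <- 2L - dos
    flipped <- TRUE
    message("variant ", variant_id,
            ": counted allele was major in-sample; dosages flipped")
  }
  dos <- dos[!is.na(dos)]
  attr(dos, "variant_id") <- variant_id
  attr(dos, "flipped") <- flipped
  dos
}

.read_genotypes_tsv <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = c("NA", "", "."), comment.char = "#")
  ids <- as.character(tab[[1L]])
  out <- lapply(names(tab)[-1L], function(v) {
    dos <- tab[[v]]
    ok <- is.na(dos) | dos %in% c(0, 1, 2)
    if (!all(ok))
      stop("variant ", v, ": dosage outside {0,1,2,missing}", call. = FALSE)
    dos <- as.integer(dos)
    names(dos) <- ids
    .orient_minor(dos, v)
  })
  names(out) <- names(tab)[-1L]
  out
}

.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))                     # single-record VCF
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | fix[, "ALT"] %in% c("", ".")
  if (any(multi))
    stop("non-biallelic VCF record(s): ",
         paste(fix[multi, "ID"], collapse = ", "), call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  ids <- colnames(gt)
  vids <- fix[, "ID"]
  vids[is.na(vids) | vids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(vids) | vids == "."]
  out <- lapply(seq_len(nrow(gt)), function(i) {
    alleles <- strsplit(gsub("\\|", "/", gt[i, ]), "/", fixed = FALSE)
    dos <- vapply(alleles, function(a) {
      if (any(a %in% c(".", NA))) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
    names(dos) <- ids
    .orient_minor(dos, vids[i])
  })
  names(out) <- vids
  out
}

#' Align a genotype vector to phenotype rows by individual id
#'
#' Joins on ids (not row position) and applies pairwise complete-case
#' deletion: only individuals present in both objects, with a non-missing
#' genotype, are kept.
#'
#' @param g Genotype vector with individual ids as names (see
#'   [read_genotypes()]).
#' @param phenotypes Numeric phenotype matrix with ids as row names.
#' @return List with elements `g` and `phenotypes`, row-aligned.
#' @export
align_individuals <- function(g, phenotypes) {
  if (is.null(names(g)) || is.null(rownames(phenotypes)))
    stop("both genotype names and phenotype rownames are required for ",
         "id-based alignment", call. = FALSE)
  common <- intersect(rownames(phenotypes), names(g))
  if (length(common) < 2L)
    stop("fewer than 2 individuals shared between genotypes and phenotypes",
         call. = FALSE)
  vid <- attr(g, "variant_id")
  fl <- attr(g, "flipped")
  out_g <- g[common]
  attr(out_g, "variant_id") <- vid
  attr(out_g, "flipped") <- fl
  list(g = out_g, phenotypes = phenotypes[common, , drop = FALSE])
}

#' Replace phenotypes by covariate-adjusted residuals
#'
#' Regresses each phenotype column on an intercept plus the covariates by
#' ordinary least squares and returns the residual matrix (column means zero).
#' With no covariates this is plain column centering.
#'
#' @param phenotypes Numeric matrix, individuals x phenotypes.
#' @param covariates Optional numeric matrix (continuous or dummy-coded),
#'   same individuals in the same order.
#' @return Residual matrix of the same shape and dimnames as `phenotypes`.
#' @export
adjust_covariates <- function(phenotypes, covariates = NULL) {
  Y <- .check_phenotypes(phenotypes)
  n <- nrow(Y)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    res <- scale(Y, center = TRUE, scale = FALSE)
    attr(res, "scaled:center") <- NULL
    return(res)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (nrow(X) != n)
    stop("covariate rows (", nrow(X), ") do not match phenotype rows (",
         n, ")", call. = FALSE)
  if (anyNA(X)) stop("missing values in covariates", call. = FALSE)
  if (n <= ncol(X))
    stop("need more individuals (", n, ") than regression columns (",
         ncol(X), ")", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("covariate design is rank deficient", call. = FALSE)
  res <- Y - X %*% qr.coef(qx, Y)
  dimnames(res) <- dimnames(Y)
  res
}

#' Write association results to a TSV file
#'
#' One row per variant with columns `variant_id`, `K`, `p_1..p_K` (padded
#' with NA to the widest K), `T_WCHC`, `pvalue`, `B`, `seed`.
#'
#' @param results A `wchc_result` or list of them.
#' @param path Output path.
#' @return Invisibly, the data frame written.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "wchc_result")) results <- list(results)
  kmax <- max(vapply(results, function(r) r$K, integer(1)))
  rows <- lapply(results, function(r) {
    p <- c(r$cluster_pvalues, rep(NA_real_, kmax - r$K))
    names(p) <- paste0("p_", seq_len(kmax))
    data.frame(variant_id = r$variant_id, K = r$K, t(p),
               T_WCHC = r$t_wchc, pvalue = r$pvalue, B = r$B,
               seed = if (is.null(r$seed)) NA_integer_ else r$seed,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
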