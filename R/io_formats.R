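#' Construct a validated genotype matrix
#'
#' Additive-coded genotypes (0 = major homozygote, 1 = heterozygote,
#' 2 = minor homozygote) for `n` samples by `p` SNPs.  Missing genotypes are
#' `NA`.  This is the substrate of the combinatorial interaction search.
#'
#' @param values integer matrix, entries in `{0, 1, 2, NA}`.
#' @param samples character vector of unique sample identifiers (rows).
#' @param snps character vector of unique SNP identifiers (columns).
#' @return An integer matrix of class `"genotype_matrix"` with sample row
#'   names and SNP column names.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'                      samples = c("s1", "s2"), snps = c("rs1", "rs2"))
#' @export
genotype_matrix <- function(values, samples = rownames(values),
                            snps = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(samples) || is.null(snps))
    stop("sample and SNP identifiers are required")
  samples <- as.character(samples)
  snps <- as.character(snps)
  if (length(samples) != nrow(values))
    stop("length of 'samples' (", length(samples),
         ") does not match rows (", nrow(values), ")")
  if (length(snps) != ncol(values))
    stop("length of 'snps' (", length(snps),
         ") does not match columns (", ncol(values), ")")
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(snps))
    stop("duplicate SNP identifiers: ",
         paste(unique(snps[duplicated(snps)]), collapse = ", "))
  bad <- which(!is.na(values) & !(values %in% 0:2))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop("invalid genotype code ", values[bad[1L]], " at sample '",
         samples[i], "', SNP '", snps[j], "' (expected 0, 1, 2 or missing)")
  }
  dimnames(values) <- list(samples, snps)
  class(values) <- c("genotype_matrix", "matrix")
  values
}

#' Construct a phenotype table
#'
#' Holds the trait `y` (continuous, or binary coded 0/1), optional covariates
#' (the environmental terms of the null model), and the trait family.
#'
#' @param y numeric trait vector; for `family = "binomial"` only 0/1 with at
#'   least one of each class.
#' @param covariates data frame of per-sample covariates, or `NULL`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param samples sample identifiers aligned with `y`.
#' @return A list of class `"phenotype_table"` with elements `y`,
#'   `covariates`, `family`, `samples`.
#' @export
phenotype_table <- function(y, covariates = NULL,
                            family = c("gaussian", "binomial"),
                            samples = names(y)) {
  family <- match.arg(family)
  y <- as.numeric(y)
  if (is.null(samples)) samples <- as.character(seq_along(y))
  samples <- as.character(samples)
  if (length(samples) != length(y))
    stop("'samples' and 'y' lengths differ")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (anyNA(y)) stop("missing trait values are not supported")
  if (family == "binomial") {
    if (!all(y %in% c(0, 1)))
      stop("binary trait contains values outside {0, 1}: ",
           paste(utils::head(setdiff(unique(y), c(0, 1)), 3), collapse = ", "))
    if (length(unique(y)) < 2L)
      stop("binary trait needs at least one case and one control")
  }
  if (is.null(covariates)) covariates <- data.frame(row.names = samples)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) == 0L && ncol(covariates) == 0L)
    covariates <- data.frame(row.names = samples)
  if (nrow(covariates) != length(y))
    stop("covariate rows (", nrow(covariates),
         ") do not align with samples (", length(y), ")")
  rownames(covariates) <- samples
  structure(list(y = y, covariates = covariates, family = family,
                 samples = samples),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype_table: ", length(x$y), " samples, family ", x$family,
      ", ", ncol(x$covariates), " covariate(s)",
      if (ncol(x$covariates)) paste0(" [", paste(names(x$covariates),
                                                 collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

# Tokens accepted as missing genotype on input.
MISSING_TOKENS <- c("NA", "", "-9")

detect_sep <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t"
  else if (grepl(",", header_line, fixed = TRUE)) ","
  else " "
}

#' Read a genotype matrix from disk
#'
#' Two dialects are supported.  `"delimited"`: a tab- or comma-delimited
#' table whose header row carries SNP identifiers and whose first column
#' carries sample identifiers.  `"plink_raw"`: the PLINK `--recode A` text
#' format (whitespace-delimited, header `FID IID PAT MAT SEX PHENOTYPE`
#' followed by one column per SNP with an allele-count suffix such as
#' `rs123_A`, which is stripped so identifiers match across files; `IID` is
#' taken as the sample identifier).
#'
#' Missing genotypes may be written `NA`, an empty field, or `-9`.
#' Any other non-0/1/2 token is a parse error naming the offending cell.
#'
#' @param path file path.
#' @param dialect `"delimited"` or `"plink_raw"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("delimited", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "delimited") {
    sep <- detect_sep(readLines(path, n = 1L))
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character", check.names = FALSE,
                             na.strings = NULL, quote = "")
    if (ncol(raw) < 2L) stop("expected a sample-id column plus SNP columns")
    samples <- raw[[1L]]
    snps <- colnames(raw)[-1L]
    mat <- as.matrix(raw[, -1L, drop = FALSE])
  } else {
    raw <- utils::read.table(path, header = TRUE, colClasses = "character",
                             check.names = FALSE, na.strings = NULL,
                             quote = "")
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% colnames(raw)))
      stop("not a PLINK .raw file: missing metadata columns ",
           paste(setdiff(meta, colnames(raw)), collapse = ", "))
    samples <- raw[["IID"]]
    keep <- setdiff(colnames(raw), meta)
    if (!length(keep)) stop("PLINK .raw file has no genotype columns")
    snps <- sub("_[^_]*$", "", keep)
    mat <- as.matrix(raw[, keep, drop = FALSE])
  }
  parsed <- parse_geno_codes(mat, samples, snps)
  genotype_matrix(parsed, samples = samples, snps = snps)
}

parse_geno_codes <- function(charmat, samples, snps) {
  charmat <- trimws(charmat)
  out <- matrix(NA_integer_, nrow(charmat), ncol(charmat))
  miss <- charmat %in% MISSING_TOKENS
  ok <- charmat %in% c("0", "1", "2")
  bad <- which(!miss & !ok)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(charmat)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(charmat)) + 1L
    stop("cannot parse genotype code '", charmat[bad[1L]],
         "' at sample '", samples[i], "', SNP '", snps[j], "'")
  }
  out[ok] <- as.integer(charmat[ok])
  out
}

#' Write a genotype matrix
#'
#' Tab-delimited, one header row of SNP identifiers, first column `sample`.
#' Missing genotypes are written as `NA`.  `read_genotypes()` on the output
#' reproduces the input exactly.
#'
#' @param genos a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genos, path) {
  stopifnot(inherits(genos, "genotype_matrix"))
  df <- data.frame(sample = rownames(genos),
                   unclass(genos), check.names = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' The file must contain a sample-identifier column, the trait column, and
#' any requested covariate columns.  When `samples` is given, rows are
#' reordered to that sample order and every sample must be present.
#'
#' @param path delimited file (tab or comma; detected from the header).
#' @param trait_family `"gaussian"` or `"binomial"`.
#' @param covariate_names character vector of covariate column names.
#' @param trait_col name of the trait column (default `"y"`).
#' @param id_col name of the sample-identifier column; default: the first
#'   column.
#' @param samples optional sample order to align to (e.g.
#'   `rownames(genotypes)`).
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, trait_family = c("gaussian", "binomial"),
                            covariate_names = character(),
                            trait_col = "y", id_col = NULL,
                            samples = NULL) {
  trait_family <- match.arg(trait_family)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(readLines(path, n = 1L))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (is.null(id_col)) id_col <- colnames(df)[1L]
  for (col in c(id_col, trait_col)) {
    if (!col %in% colnames(df))
      stop("column '", col, "' not found; available: ",
           paste(colnames(df), collapse = ", "))
  }
  missing_cov <- setdiff(covariate_names, colnames(df))
  if (length(missing_cov))
    stop("unknown covariate column(s) ",
         paste0("'", missing_cov, "'", collapse = ", "),
         "; available: ", paste(setdiff(colnames(df),
                                        c(id_col, trait_col)),
                                collapse = ", "))
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in ", path)
  if (!is.null(samples)) {
    absent <- setdiff(as.character(samples), ids)
    if (length(absent))
      stop("sample(s) missing from phenotype file: ",
           paste(utils::head(absent, 5), collapse = ", "))
    df <- df[match(as.character(samples), ids), , drop = FALSE]
    ids <- as.character(samples)
  }
  covs <- if (length(covariate_names))
    df[, covariate_names, drop = FALSE] else NULL
  phenotype_table(as.numeric(df[[trait_col]]), covariates = covs,
                  family = trait_family, samples = ids)
}

#' Write ranked model results
#'
#' Tab-delimited columns `order`, `snp_combination`, `cvc`, `ba_train`,
#' `ba_test` (the layout of a cross-validated interaction summary: SNP
#' combination, cross-validation consistency, training/testing balanced
#' accuracy).  Rows are ordered by descending `ba_test`, then descending
#' `cvc`, then lexicographic `snp_combination`.
#'
#' @param results data frame with the columns above (e.g. the output of
#'   [cross_validated_search()]); must be non-empty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_results <- function(results, path) {
  results <- as.data.frame(results)
  need <- c("order", "snp_combination", "cvc", "ba_train", "ba_test")
  if (!all(need %in% colnames(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  if (nrow(results) == 0L) stop("empty result list; refusing to write")
  results <- results[order(-results$ba_test, -results$cvc,
                           results$snp_combination), need, drop = FALSE]
  out <- data.frame(order = as.integer(results$order),
                    snp_combination = as.character(results$snp_combination),
                    cvc = as.integer(results$cvc),
                    ba_train = format_roundtrip(results$ba_train),
                    ba_test = format_roundtrip(results$ba_test),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Shortest decimal representation that parses back to the same double.
format_roundtrip <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- is.finite(x) & (suppressWarnings(as.numeric(s)) != x)
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s
}

#' Read a model-result table written by [write_model_results()]
#'
#' @param path file path.
#' @return data frame with columns `order`, `snp_combination`, `cvc`,
#'   `ba_train`, `ba_test`.
#' @export
read_model_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  df$order <- as.integer(df$order)
  df$cvc <- as.integer(df$cvc)
  df$ba_train <- as.numeric(df$ba_train)
  df$ba_test <- as.numeric(df$ba_test)
  df
}

#' Write a per-cell report
#'
#' Tab-delimited rendering of [cell_report()]: one row per genotype cell
#' with its sample count, positive/negative score mass, mean score, and
#' high-risk membership degree.
#'
#' @param report data frame from [cell_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
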