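#' Build the genotype cell table for a SNP combination
#'
#' Partitions samples into the `3^k` genotype cells of a k-SNP combination
#' and accumulates, per cell: the sample count, the sum of nonnegative
#' scores (`pos_sum`), the magnitude of the sum of negative scores
#' (`neg_mag`), and the mean score.  Samples missing any genotype in the
#' combination are excluded from this table only.
#'
#' Cell `j` is the mixed-radix base-3 encoding of the genotype tuple in
#' combination order (first SNP most significant), so the enumeration order
#' matches the `AABB ... aabb` convention of the cell report.
#'
#' @param genos a [genotype_matrix()].
#' @param combination character vector of SNP identifiers (or integer column
#'   indices), length 1 to 5.
#' @param scores numeric score vector aligned with the rows of `genos`.
#' @return An object of class `"cell_table"`: list with `combination`, `k`,
#'   `cells` (data frame `cell`, `count`, `pos_sum`, `neg_mag`,
#'   `mean_score`), `n_complete`, `n_excluded`.
#' @export
build_cell_table <- function(genos, combination, scores) {
  stopifnot(inherits(genos, "genotype_matrix"))
  if (is.numeric(combination)) {
    if (any(combination < 1 | combination > ncol(genos)))
      stop("SNP index out of range")
    combination <- colnames(genos)[combination]
  }
  combination <- as.character(combination)
  k <- length(combination)
  if (k < 1L || k > 5L)
    stop("interaction order k must be between 1 and 5 (got ", k, ")")
  unknown <- setdiff(combination, colnames(genos))
  if (length(unknown))
    stop("unknown SNP id(s): ", paste(unknown, collapse = ", "))
  if (length(scores) != nrow(genos))
    stop("scores length (", length(scores),
         ") does not match samples (", nrow(genos), ")")
  g <- unclass(genos)[, combination, drop = FALSE]
  s <- as.numeric(scores)
  idx <- cell_index(g)
  complete <- !is.na(idx)
  agg <- aggregate_cells(idx[complete], s[complete], 3L^k)
  structure(list(combination = combination, k = k,
                 cells = agg,
                 n_complete = sum(complete),
                 n_excluded = sum(!complete)),
            class = "cell_table")
}

# Mixed-radix base-3 cell index (1-based); NA where any genotype is missing.
cell_index <- function(g) {
  idx <- rep(0L, nrow(g))
  for (m in seq_len(ncol(g))) idx <- idx * 3L + g[, m]
  idx + 1L
}

# Per-cell count / positive mass / negative magnitude / mean over n_cells.
aggregate_cells <- function(idx, s, n_cells) {
  sp <- ifelse(s >= 0, s, 0)
  sn <- ifelse(s < 0, -s, 0)
  count <- pos_sum <- neg_mag <- ssum <- numeric(n_cells)
  if (length(idx)) {
    rs <- rowsum(cbind(1, sp, sn, s), idx, reorder = TRUE)
    present <- as.integer(rownames(rs))
    count[present] <- rs[, 1L]
    pos_sum[present] <- rs[, 2L]
    neg_mag[present] <- rs[, 3L]
    ssum[present] <- rs[, 4L]
  }
  mean_score <- ifelse(count > 0, ssum / count, NA_real_)
  data.frame(cell = seq_len(n_cells), count = as.integer(count),
             pos_sum = pos_sum, neg_mag = neg_mag, mean_score = mean_score)
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table: ", paste(x$combination, collapse = " x "),
      " (k = ", x$k, "), ", x$n_complete, " samples",
      if (x$n_excluded) paste0(" (", x$n_excluded, " excluded for missing",
                               " genotypes)"), "\n", sep = "")
  print(x$cells[x$cells$count > 0, ], row.names = FALSE)
  invisible(x)
}

#' Fuzzy confusion masses of a cell table
#'
#' Membership-weighted score-mass sums over nonempty cells:
#' `TP = sum_j pos_sum_j * mu_H(mean_j)`, `FN = sum_j pos_sum_j * mu_L`,
#' `FP = sum_j neg_mag_j * mu_H`, `TN = sum_j neg_mag_j * mu_L`.  The
#' negative-score sum enters as its magnitude so all four masses are
#' nonnegative.  Empty cells have no mean score and contribute nothing.
#'
#' @param table a [build_cell_table()] result.
#' @param f a [membership_function()].
#' @return An object of class `"fuzzy_confusion"`: list `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
fuzzy_confusion <- function(table, f) {
  stopifnot(inherits(table, "cell_table"),
            inherits(f, "membership_function"))
  ne <- table$cells$count > 0L
  if (!any(ne)) stop("all cells are empty")
  pos <- table$cells$pos_sum[ne]
  neg <- table$cells$neg_mag[ne]
  muh <- mu_high(f, table$cells$mean_score[ne])
  mul <- 1 - muh
  structure(list(tp = sum(pos * muh), fn = sum(pos * mul),
                 fp = sum(neg * muh), tn = sum(neg * mul)),
            class = "fuzzy_confusion")
}

#' @export
print.fuzzy_confusion <- function(x, ...) {
  cat(sprintf("fuzzy_confusion: tp=%.6g fn=%.6g fp=%.6g tn=%.6g\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Balanced accuracy from a fuzzy confusion
#'
#' The arithmetic mean of fuzzy sensitivity `tp/(tp+fn)` and fuzzy
#' specificity `tn/(tn+fp)`.  With indicator membership this is the
#' classical (G)MDR balanced accuracy.
#'
#' @param conf a [fuzzy_confusion()] result.
#' @return Value in `[0, 1]`.
#' @export
balanced_accuracy <- function(conf) {
  stopifnot(inherits(conf, "fuzzy_confusion"))
  pos_mass <- conf$tp + conf$fn
  neg_mass <- conf$fp + conf$tn
  if (pos_mass <= 0)
    stop("degenerate table: no positive-score mass (tp + fn = 0)")
  if (neg_mass <= 0)
    stop("degenerate table: no negative-score mass (fp + tn = 0)")
  (conf$tp / pos_mass + conf$tn / neg_mass) / 2
}

#' Crisp high/low-risk cell labels
#'
#' The classical (G)MDR rule: a nonempty cell is `"H"` iff its mean score is
#' nonnegative (meets or exceeds the threshold `T`), `"L"` otherwise; empty
#' cells are `"empty"` and are excluded from confusion sums.
#'
#' @param table a [build_cell_table()] result.
#' @param threshold crisp threshold `T` (default 0).
#' @return Character vector of length `3^k` with values `"H"`, `"L"`,
#'   `"empty"`.
#' @export
classify_cells <- function(table, threshold = 0) {
  stopifnot(inherits(table, "cell_table"))
  out <- rep("empty", nrow(table$cells))
  ne <- table$cells$count > 0L
  out[ne] <- ifelse(table$cells$mean_score[ne] >= threshold, "H", "L")
  out
}

#' Per-cell report of a SNP combination
#'
#' One row per genotype cell with the major/minor-allele letter label
#' (locus 1 uses `A/a`, locus 2 `B/b`, ...: code 0 is the major homozygote
#' `AA`, 1 the heterozygote `Aa`, 2 the minor homozygote `aa`), the sample
#' count, positive score mass, negative score magnitude, mean score, and
#' high-risk membership degree.  This is the numeric content of the cell
#' diagram used to interpret a selected interaction.
#'
#' @param table a [build_cell_table()] result.
#' @param f a [membership_function()].
#' @return Data frame with columns `genotype`, `count`, `pos_sum`,
#'   `neg_mag`, `mean_score`, `mu_h`.
#' @export
cell_report <- function(table, f) {
  stopifnot(inherits(table, "cell_table"),
            inherits(f, "membership_function"))
  k <- table$k
  labels <- genotype_labels(k)
  ne <- table$cells$count > 0L
  muh <- rep(NA_real_, nrow(table$cells))
  if (any(ne)) muh[ne] <- mu_high(f, table$cells$mean_score[ne])
  data.frame(genotype = labels,
             count = table$cells$count,
             pos_sum = table$cells$pos_sum,
             neg_mag = table$cells$neg_mag,
             mean_score = table$cells$mean_score,
             mu_h = muh,
             stringsAsFactors = FALSE)
}

# "AABB", "AABb", ..., first locus most significant; locus m uses the m-th
# letter of the alphabet.
genotype_labels <- function(k) {
  per_locus <- lapply(seq_len(k), function(m) {
    up <- LETTERS[m]; lo <- letters[m]
    c(paste0(up, up), paste0(up, lo), paste0(lo, lo))
  })
  grid <- expand.grid(rev(per_locus), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}
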