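#' Search configuration
#'
#' Bundles the settings of an exhaustive k-locus interaction search.
#' Method dispatch: `mdr` and `fmdr` are the covariate-free special cases
#' (intercept-only null model); `gmdr` and `fgmdr` adjust for covariates.
#' `mdr`/`gmdr` use crisp indicator membership, `fmdr`/`fgmdr` the fuzzy
#' sigmoid.
#'
#' @param k interaction order, 1 to 5.
#' @param method one of `"fgmdr"`, `"gmdr"`, `"fmdr"`, `"mdr"`.
#' @param n_folds number of cross-validation folds (default 10).
#' @param t_l,t_h fixed sigmoid thresholds; if `NULL` (default) a symmetric
#'   band is fixed a priori for the whole analysis at `spread` standard
#'   errors of a typical cell mean (score standard deviation over
#'   `sqrt(n / 3^k)`, from training scores within each fold), so that cells
#'   whose mean is within sampling noise of zero are the graded ones.
#' @param spread band scale factor in cell-mean standard errors (default 1;
#'   0 degenerates to the indicator, i.e. the crisp method).
#' @param threshold crisp threshold `T` for indicator membership (default 0).
#' @param seed integer seed driving fold assignment.
#' @param stratify stratify folds by case/control status (default: yes for a
#'   binomial trait).
#' @param refit_scores refit the null model within each training fold rather
#'   than once on the full data (default `FALSE`; the null model has no
#'   genotype terms, so full-data scores leak no tested signal).
#' @param variant studentization variant, see [studentized_scores()].
#' @param max_combinations guard on `choose(p, k)`; exceeding it is an error
#'   advising pre-filtering of candidate SNPs.
#' @return An object of class `"search_config"`.
#' @export
search_config <- function(k, method = c("fgmdr", "gmdr", "fmdr", "mdr"),
                          n_folds = 10L, t_l = NULL, t_h = NULL,
                          spread = 1, threshold = 0, seed = 1L,
                          stratify = NULL, refit_scores = FALSE,
                          variant = "internal",
                          max_combinations = 100000L) {
  method <- match.arg(method)
  stopifnot(k >= 1L, k <= 5L, n_folds >= 2L)
  if (!is.null(t_l) || !is.null(t_h)) {
    if (is.null(t_l) || is.null(t_h))
      stop("supply both t_l and t_h, or neither")
    if (t_l > t_h) stop("t_l must not exceed t_h")
  }
  structure(list(k = as.integer(k), method = method,
                 n_folds = as.integer(n_folds),
                 fuzzy = method %in% c("fmdr", "fgmdr"),
                 use_covariates = method %in% c("gmdr", "fgmdr"),
                 t_l = t_l, t_h = t_h, spread = spread,
                 threshold = threshold, seed = as.integer(seed),
                 stratify = stratify, refit_scores = refit_scores,
                 variant = variant,
                 max_combinations = as.integer(max_combinations)),
            class = "search_config")
}

#' Cross-validation fold assignment
#'
#' Deterministic given `seed`; fold sizes differ by at most one.  With
#' `labels` and `stratify = TRUE`, assignment is stratified so each fold
#' preserves the case/control proportion to within one sample per class.
#'
#' @param n number of samples.
#' @param n_folds number of folds (at most `n`).
#' @param labels optional binary 0/1 vector for stratification.
#' @param stratify whether to stratify (default: `TRUE` when labels given).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
make_folds <- function(n, n_folds, labels = NULL,
                       stratify = !is.null(labels), seed = 1L) {
  stopifnot(n >= n_folds, n_folds >= 2L)
  fold <- integer(n)
  with_seed(seed, {
    if (stratify && !is.null(labels)) {
      stopifnot(length(labels) == n, all(labels %in% c(0, 1)))
      for (cls in c(0, 1)) {
        idx <- sample(which(labels == cls))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  if (stratify && !is.null(labels)) {
    tab <- table(factor(fold, levels = seq_len(n_folds)),
                 factor(labels, levels = c(0, 1)))
    if (any(tab == 0))
      stop("stratified folds have a fold with zero cases or zero controls; ",
           "reduce n_folds")
  }
  fold
}

#' Balanced accuracy of one SNP combination
#'
#' Composes [build_cell_table()], [fuzzy_confusion()] and
#' [balanced_accuracy()].  For the crisp methods use an indicator
#' [membership_function()], under which the result equals the classical
#' (G)MDR balanced accuracy exactly.
#'
#' @param genos a [genotype_matrix()].
#' @param scores score vector from [studentized_scores()].
#' @param combination SNP identifiers (or column indices).
#' @param f a [membership_function()].
#' @return Balanced accuracy in `[0, 1]`.
#' @export
evaluate_combination <- function(genos, scores, combination, f) {
  balanced_accuracy(fuzzy_confusion(build_cell_table(genos, combination,
                                                     scores), f))
}

# ---- internal fast evaluation -------------------------------------------

#' Default sigmoid band for a whole analysis
#'
#' The symmetric membership band used by the fuzzy methods when no fixed
#' `t_l`/`t_h` is supplied: `spread` standard errors of a typical cell
#' mean, i.e. `t_h = spread * sd(scores) / sqrt(n / 3^k)` and
#' `t_l = -t_h` (population standard deviation).  Fixed once per analysis
#' — before any combination is examined — so that cells whose mean score
#' lies within sampling noise of zero (the "tied" cells) get graded
#' memberships while cells beyond the band are effectively crisp, keeping
#' the fuzzy balanced accuracy comparable across combinations.
#'
#' @param scores score vector of the analysis (training scores, inside
#'   cross-validation).
#' @param k interaction order (the band scales with the `3^k` cell count).
#' @param spread band width in cell-mean standard errors (default 1).
#' @return Named numeric vector `c(t_l = ..., t_h = ...)`.
#' @export
score_band <- function(scores, k, spread = 1) {
  n <- length(scores)
  se <- pop_sd(scores) / sqrt(max(n / 3^k, 1))
  t_h <- spread * se
  c(t_l = -t_h, t_h = t_h)
}

# Membership degrees for a vector of cell means.  t_l == t_h degenerates
# to the indicator at that value.
mu_from_band <- function(m, membership) {
  if (membership$kind == "indicator")
    return(as.numeric(m >= membership$threshold))
  t_l <- membership$t_l; t_h <- membership$t_h
  if (t_l == t_h) return(as.numeric(m >= t_l))
  muh <- numeric(length(m))
  muh[m >= t_h] <- 1
  mid <- m > t_l & m < t_h
  if (any(mid)) {
    r <- (m[mid] - t_h) / (m[mid] - t_l)
    muh[mid] <- 1 / (1 + r * r)
  }
  muh
}

# BA from per-cell aggregates.  membership: list(kind, threshold, t_l,
# t_h) with concrete thresholds.  Returns NA when either score-mass side
# is zero (degenerate split).
ba_from_aggregates <- function(count, pos, neg, mean_score, membership) {
  ne <- count > 0
  if (!any(ne)) return(NA_real_)
  muh <- mu_from_band(mean_score[ne], membership)
  p <- pos[ne]; q <- neg[ne]
  tp <- sum(p * muh); fn <- sum(p * (1 - muh))
  fp <- sum(q * muh); tn <- sum(q * (1 - muh))
  if (tp + fn <= 0 || fp + tn <= 0) return(NA_real_)
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

membership_spec <- function(config) {
  list(kind = if (config$fuzzy) "sigmoid" else "indicator",
       threshold = config$threshold, t_l = config$t_l, t_h = config$t_h,
       spread = config$spread)
}

# Aggregates (count, pos, neg, sum) for one cell index vector restricted to
# `rows`; returns a list of length-n_cells vectors.
cells_for_rows <- function(idx, sp, sn, s, rows, n_cells) {
  idx <- idx[rows]
  keep <- !is.na(idx)
  idx <- idx[keep]
  count <- pos <- neg <- ssum <- numeric(n_cells)
  if (length(idx)) {
    rs <- rowsum(cbind(1, sp[rows][keep], sn[rows][keep], s[rows][keep]),
                 idx, reorder = TRUE)
    present <- as.integer(rownames(rs))
    count[present] <- rs[, 1L]
    pos[present] <- rs[, 2L]
    neg[present] <- rs[, 3L]
    ssum[present] <- rs[, 4L]
  }
  list(count = count, pos = pos, neg = neg,
       mean = ifelse(count > 0, ssum / count, NA_real_))
}

# Membership degrees learned from training aggregates (NULL if train empty).
train_membership <- function(tr, membership) {
  ne <- tr$count > 0
  if (!any(ne)) return(NULL)
  full <- rep(NA_real_, length(tr$count))
  full[ne] <- mu_from_band(tr$mean[ne], membership)
  full
}

# Test-fold BA using training-learned cell memberships; cells unseen in
# training contribute nothing.  NA when a score-mass side is empty.
ba_test_fold <- function(te, muh_train) {
  use <- te$count > 0 & !is.na(muh_train)
  if (!any(use)) return(NA_real_)
  muh <- muh_train[use]
  p <- te$pos[use]; q <- te$neg[use]
  tp <- sum(p * muh); fn <- sum(p * (1 - muh))
  fp <- sum(q * muh); tn <- sum(q * (1 - muh))
  if (tp + fn <= 0 || fp + tn <= 0) return(NA_real_)
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

# ---- cross-validated exhaustive search ----------------------------------

#' Exhaustive k-locus search with cross-validation
#'
#' Evaluates every `choose(p, k)` SNP combination.  Within each fold, all
#' combinations are ranked by training balanced accuracy; the fold winner is
#' recorded (cross-validation consistency, CVC, counts the folds each
#' combination wins).  Testing balanced accuracy drops the held-out samples
#' into the training-defined cells with training-learned memberships; test
#' cells empty in training contribute nothing.  The best model maximizes
#' CVC, tie-broken by testing balanced accuracy, then lexicographic SNP
#' combination.
#'
#' @param genos a [genotype_matrix()].
#' @param scores full-data score vector (ignored when
#'   `config$refit_scores = TRUE` and `phenos` is supplied).
#' @param config a [search_config()].
#' @param labels optional 0/1 vector for stratified folds.
#' @param phenos optional [phenotype_table()], needed only for per-fold
#'   score refitting.
#' @return Data frame of class `"fgmdr_search"` with columns `order`,
#'   `snp_combination`, `cvc`, `ba_train`, `ba_test`, ranked by the
#'   selection rule; the winning row first.  Attributes: `method`, `k`,
#'   `n_folds`, `seed`, `best`.
#' @export
cross_validated_search <- function(genos, scores, config, labels = NULL,
                                   phenos = NULL) {
  stopifnot(inherits(genos, "genotype_matrix"),
            inherits(config, "search_config"))
  p <- ncol(genos)
  n <- nrow(genos)
  k <- config$k
  if (p < k) stop("need at least k SNPs (p = ", p, ", k = ", k, ")")
  n_comb <- choose(p, k)
  if (n_comb > config$max_combinations)
    stop("choose(", p, ", ", k, ") = ", n_comb,
         " exceeds max_combinations = ", config$max_combinations,
         "; pre-filter candidate SNPs (e.g. by single-SNP association) ",
         "or raise the budget")
  stopifnot(length(scores) == n || config$refit_scores)

  combos <- utils::combn(p, k)
  n_cells <- 3L^k
  gmat <- unclass(genos)
  membership <- membership_spec(config)
  folds <- make_folds(n, config$n_folds, labels = labels,
                      stratify = isTRUE(config$stratify) ||
                        (is.null(config$stratify) && !is.null(labels)),
                      seed = config$seed)

  # cell index per combination computed once (fold-independent)
  idx_list <- lapply(seq_len(n_comb), function(ci)
    cell_index(gmat[, combos[, ci], drop = FALSE]))

  ba_train <- matrix(NA_real_, n_comb, config$n_folds)
  ba_test <- matrix(NA_real_, n_comb, config$n_folds)
  winners <- integer(config$n_folds)
  comb_ids <- vapply(seq_len(n_comb), function(ci)
    paste(sort(colnames(genos)[combos[, ci]]), collapse = ","),
    character(1))

  for (fold in seq_len(config$n_folds)) {
    train <- which(folds != fold)
    test <- which(folds == fold)
    if (config$refit_scores) {
      if (is.null(phenos))
        stop("refit_scores = TRUE requires 'phenos'")
      s_all <- fold_scores(phenos, train, config$variant)
    } else {
      s_all <- as.numeric(scores)
    }
    sp <- ifelse(s_all >= 0, s_all, 0)
    sn <- ifelse(s_all < 0, -s_all, 0)
    membership_fold <- membership
    if (config$fuzzy && is.null(membership$t_l)) {
      band <- score_band(s_all[train], k, config$spread)
      membership_fold$t_l <- band[["t_l"]]
      membership_fold$t_h <- band[["t_h"]]
    }
    for (ci in seq_len(n_comb)) {
      idx <- idx_list[[ci]]
      tr <- cells_for_rows(idx, sp, sn, s_all, train, n_cells)
      ba_train[ci, fold] <- ba_from_aggregates(tr$count, tr$pos, tr$neg,
                                               tr$mean, membership_fold)
      muh <- train_membership(tr, membership_fold)
      if (!is.null(muh)) {
        te <- cells_for_rows(idx, sp, sn, s_all, test, n_cells)
        ba_test[ci, fold] <- ba_test_fold(te, muh)
      }
    }
    bas <- ba_train[, fold]
    if (all(is.na(bas)))
      stop("no combination could be evaluated in fold ", fold)
    best <- which(bas == max(bas, na.rm = TRUE))
    winners[fold] <- best[order(comb_ids[best])][1L]
  }

  cvc <- tabulate(winners, nbins = n_comb)
  res <- data.frame(order = k,
                    snp_combination = comb_ids,
                    cvc = cvc,
                    ba_train = rowMeans(ba_train, na.rm = TRUE),
                    ba_test = rowMeans(ba_test, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$cvc, -res$ba_test, res$snp_combination), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "method") <- config$method
  attr(res, "k") <- k
  attr(res, "n_folds") <- config$n_folds
  attr(res, "seed") <- config$seed
  attr(res, "best") <- res$snp_combination[1L]
  class(res) <- c("fgmdr_search", "data.frame")
  res
}

# Scores for all samples from a null model fitted on the training rows.
# Held-out samples are scored as (y - mu_hat_train) / sqrt(dispersion_train)
# (no leverage term exists for out-of-fit observations).
fold_scores <- function(phenos, train, variant) {
  sub <- phenotype_table(phenos$y[train],
                         if (ncol(phenos$covariates))
                           phenos$covariates[train, , drop = FALSE]
                         else NULL,
                         family = phenos$family,
                         samples = phenos$samples[train])
  fit <- fit_null_model(sub)
  newdata <- cbind(data.frame(.y = phenos$y), phenos$covariates)
  mu <- stats::predict(fit$model, newdata = newdata, type = "response")
  if (phenos$family == "binomial") {
    (phenos$y - mu) / sqrt(mu * (1 - mu))
  } else {
    (phenos$y - mu) / sqrt(fit$dispersion)
  }
}

#' @export
print.fgmdr_search <- function(x, n = 5L, ...) {
  cat("Exhaustive ", attr(x, "k"), "-locus ", toupper(attr(x, "method")),
      " search (", attr(x, "n_folds"), "-fold CV), ",
      nrow(x), " combinations\n", sep = "")
  cat("best model: ", attr(x, "best"), "\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run one MDR-family method end to end
#'
#' Fits the appropriate null model (intercept-only for `mdr`/`fmdr`,
#' covariate-adjusted for `gmdr`/`fgmdr`), computes studentized score
#' residuals, and performs the cross-validated exhaustive search with the
#' method's membership kind (indicator for `mdr`/`gmdr`, sigmoid for
#' `fmdr`/`fgmdr`).  Covariates supplied to `mdr`/`fmdr` are ignored by
#' construction, with a warning.
#'
#' @param genos a [genotype_matrix()].
#' @param phenos a [phenotype_table()] aligned with `genos`.
#' @param config a [search_config()].
#' @return A `"fgmdr_search"` data frame, see [cross_validated_search()].
#' @export
run_method <- function(genos, phenos, config) {
  stopifnot(inherits(genos, "genotype_matrix"),
            inherits(phenos, "phenotype_table"),
            inherits(config, "search_config"))
  if (!identical(rownames(genos), phenos$samples))
    stop("genotype and phenotype sample identifiers differ or are ordered ",
         "differently")
  if (!config$use_covariates && ncol(phenos$covariates) > 0L) {
    warning(toupper(config$method),
            " ignores covariates by construction; ",
            ncol(phenos$covariates), " covariate(s) dropped")
    phenos <- phenotype_table(phenos$y, NULL, family = phenos$family,
                              samples = phenos$samples)
  }
  fit <- fit_null_model(phenos)
  scores <- studentized_scores(fit, variant = config$variant)
  labels <- if (phenos$family == "binomial") phenos$y else NULL
  cross_validated_search(genos, scores, config, labels = labels,
                         phenos = phenos)
}
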