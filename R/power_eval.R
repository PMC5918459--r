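# Scores for a simulated dataset under one method's null model:
# mdr/fmdr ignore the covariate, gmdr/fgmdr adjust for it.
method_scores <- function(dataset, method, variant = "internal") {
  ph <- dataset$phenotype
  if (method %in% c("mdr", "fmdr"))
    ph <- phenotype_table(ph$y, NULL, family = ph$family,
                          samples = ph$samples)
  studentized_scores(fit_null_model(ph), variant = variant)
}

# Balanced accuracy of every SNP pair on the full data (no CV).  Returns a
# numeric vector aligned with utils::combn(p, 2) columns.
rank_pairs <- function(gmat, scores, membership) {
  p <- ncol(gmat)
  s <- as.numeric(scores)
  sp <- ifelse(s >= 0, s, 0)
  sn <- ifelse(s < 0, -s, 0)
  if (membership$kind == "sigmoid" && is.null(membership$t_l)) {
    band <- score_band(s, 2L, membership$spread)
    membership$t_l <- band[["t_l"]]
    membership$t_h <- band[["t_h"]]
  }
  combos <- utils::combn(p, 2L)
  n_pairs <- ncol(combos)
  ba <- rep(NA_real_, n_pairs)
  rows <- seq_along(s)
  for (ci in seq_len(n_pairs)) {
    idx <- cell_index(gmat[, combos[, ci], drop = FALSE])
    agg <- cells_for_rows(idx, sp, sn, s, rows, 9L)
    ba[ci] <- ba_from_aggregates(agg$count, agg$pos, agg$neg, agg$mean,
                                 membership)
  }
  ba
}

#' Did a replicate recover its causal pair?
#'
#' Evaluates the method's two-locus balanced accuracy over all
#' `choose(p, 2)` SNP pairs on the full replicate and returns 1 iff the
#' recorded causal pair attains the strictly highest value (ties count as
#' misses).  With `with_cv = TRUE` the pair is instead required to be the
#' selected best model of a 10-fold cross-validated search.
#'
#' @param dataset a `"sim_dataset"` (or any list with `genotypes`,
#'   `phenotype`, `causal_idx`).
#' @param method `"mdr"`, `"fmdr"`, `"gmdr"` or `"fgmdr"`.
#' @param spread,threshold,t_l,t_h membership settings as in
#'   [search_config()].
#' @param with_cv use cross-validated model selection instead of full-data
#'   ranking (slower).
#' @param variant studentization variant.
#' @param cv_seed fold seed when `with_cv = TRUE`.
#' @return 0 or 1.
#' @export
replicate_hit <- function(dataset, method = c("fgmdr", "gmdr", "fmdr",
                                              "mdr"),
                          spread = 1, threshold = 0, t_l = NULL,
                          t_h = NULL, with_cv = FALSE,
                          variant = "internal", cv_seed = 1L) {
  method <- match.arg(method)
  if (is.null(dataset$causal_idx)) stop("dataset has no recorded causal pair")
  scores <- method_scores(dataset, method, variant)
  if (with_cv) {
    config <- search_config(2L, method = method, t_l = t_l, t_h = t_h,
                            spread = spread, threshold = threshold,
                            seed = cv_seed)
    res <- run_method(dataset$genotypes, dataset$phenotype, config)
    causal_id <- paste(sort(dataset$causal), collapse = ",")
    return(as.integer(attr(res, "best") == causal_id))
  }
  fuzzy <- method %in% c("fmdr", "fgmdr")
  membership <- list(kind = if (fuzzy) "sigmoid" else "indicator",
                     threshold = threshold, t_l = t_l, t_h = t_h,
                     spread = spread)
  gmat <- unclass(dataset$genotypes)
  ba <- rank_pairs(gmat, scores, membership)
  combos <- utils::combn(ncol(gmat), 2L)
  target <- which(combos[1L, ] == dataset$causal_idx[1L] &
                  combos[2L, ] == dataset$causal_idx[2L])
  if (is.na(ba[target])) return(0L)
  others <- ba[-target]
  as.integer(all(is.na(others) | ba[target] > others))
}

simulate_scenario <- function(scenario, model, n, p, seed,
                              n_cases = NULL, n_controls = NULL) {
  switch(as.character(scenario),
    "1" = simulate_scenario1(model, n = n, p = p, seed = seed),
    "2" = simulate_scenario2(model, n = n, p = p, seed = seed),
    "3" = simulate_scenario3(model,
                             n_cases = n_cases %||% (n %/% 2L),
                             n_controls = n_controls %||% (n %/% 2L),
                             p = p, seed = seed),
    stop("scenario must be 1, 2 or 3"))
}

#' Estimate detection power of one method under one scenario and model
#'
#' Power is the proportion of replicates in which the true causal SNP pair
#' is selected as the model with the strictly highest balanced accuracy
#' (crisp BA for `mdr`/`gmdr`, fuzzy BA for `fmdr`/`fgmdr`).  Replicate `r`
#' uses seed `base_seed + r`, so methods called with the same `base_seed`
#' see identical datasets and their per-replicate hit flags are paired.
#'
#' @param method `"mdr"`, `"fmdr"`, `"gmdr"` or `"fgmdr"`.
#' @param scenario 1, 2 or 3.
#' @param model a [make_penetrance_model()] result.
#' @param n_replicates number of replicates (100 at study scale).
#' @param base_seed integer; replicate seeds are `base_seed + 1 ..
#'   base_seed + n_replicates`.
#' @param n,p samples and SNPs per replicate (defaults 2000 and 100).
#' @param ... passed to [replicate_hit()].
#' @return Object of class `"power_result"`: list with `method`, `scenario`,
#'   `pattern`, `maf`, `heritability`, `n_replicates`, `power`, `hits`.
#' @export
estimate_power <- function(method, scenario, model, n_replicates = 100L,
                           base_seed = 0L, n = 2000L, p = 100L, ...) {
  stopifnot(n_replicates >= 1L)
  hits <- vapply(seq_len(n_replicates), function(r) {
    ds <- simulate_scenario(scenario, model, n, p, seed = base_seed + r)
    replicate_hit(ds, method, ...)
  }, integer(1))
  structure(list(method = method, scenario = scenario,
                 pattern = model$pattern, maf = model$maf,
                 heritability = model$heritability,
                 n_replicates = n_replicates,
                 power = mean(hits), hits = hits),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power_result: %s scenario %s, pattern %s, maf %.2g, h2 %.3g: power %.3f (%d replicates)\n",
              toupper(x$method), x$scenario, x$pattern, x$maf,
              x$heritability, x$power, x$n_replicates))
  invisible(x)
}

#' Power over a grid of penetrance models, all methods on shared replicates
#'
#' For each (scenario, pattern, maf, h2) cell, generates `n_replicates`
#' datasets once and scores every method on the same datasets, so powers
#' are paired across methods (as required for a signed-rank comparison).
#'
#' @param methods character vector of methods.
#' @param scenarios integer vector from `{1, 2, 3}`.
#' @param patterns character vector of [interaction_patterns()].
#' @param mafs,h2s numeric grids for minor allele frequency / heritability.
#' @param n_replicates replicates per model.
#' @param base_seed integer; model cells get disjoint seed blocks derived
#'   from it.
#' @param n,p samples and SNPs per replicate.
#' @param ... passed to [replicate_hit()].
#' @return Long-format data frame (class `"power_grid"`): one row per
#'   method x scenario x model with columns `method`, `scenario`, `pattern`,
#'   `maf`, `h2`, `n_replicates`, `power`; per-replicate hit flags in
#'   `attr(, "hits")` (named list of 0/1 vectors).
#' @export
power_grid <- function(methods = c("mdr", "fmdr", "gmdr", "fgmdr"),
                       scenarios = 1:3, patterns = "xor",
                       mafs = c(0.2, 0.4), h2s = c(0.1, 0.2, 0.4),
                       n_replicates = 25L, base_seed = 0L,
                       n = 2000L, p = 20L, ...) {
  cells <- expand.grid(scenario = scenarios, pattern = patterns,
                       maf = mafs, h2 = h2s, stringsAsFactors = FALSE)
  rows <- list()
  hits_store <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    model <- make_penetrance_model(cell$pattern, maf = cell$maf,
                                   heritability = cell$h2)
    seed0 <- base_seed + (ci - 1L) * (n_replicates + 11L)
    hit_mat <- matrix(0L, n_replicates, length(methods),
                      dimnames = list(NULL, methods))
    for (r in seq_len(n_replicates)) {
      ds <- simulate_scenario(cell$scenario, model, n, p,
                              seed = seed0 + r)
      for (m in methods)
        hit_mat[r, m] <- replicate_hit(ds, m, ...)
    }
    for (m in methods) {
      key <- paste(m, cell$scenario, cell$pattern, cell$maf, cell$h2,
                   sep = "|")
      hits_store[[key]] <- hit_mat[, m]
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, scenario = cell$scenario,
                   pattern = cell$pattern, maf = cell$maf, h2 = cell$h2,
                   n_replicates = n_replicates,
                   power = mean(hit_mat[, m]),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hits") <- hits_store
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Paired signed-rank comparison of two methods' powers
#'
#' Wilcoxon signed-rank test on per-model power differences between two
#' method result sets computed on the same models with shared replicate
#' seeds.  Zero differences are dropped (the conventional treatment).
#'
#' @param results_a,results_b data frames with a `power` column and matching
#'   model descriptors (`scenario`, `pattern`, `maf`, `h2`), e.g. method
#'   slices of a [power_grid()] result, or lists of `"power_result"`
#'   objects over the same models.
#' @param alternative passed to [stats::wilcox.test()] (`results_a` minus
#'   `results_b`).
#' @return List with `statistic`, `p_value`, `n_models`, `n_nonzero`,
#'   `mean_diff`.
#' @export
compare_methods <- function(results_a, results_b,
                            alternative = "two.sided") {
  as_power_df <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(r)
      data.frame(scenario = r$scenario, pattern = r$pattern, maf = r$maf,
                 h2 = r$heritability, power = r$power,
                 stringsAsFactors = FALSE)))
  }
  a <- as_power_df(results_a)
  b <- as_power_df(results_b)
  if (nrow(a) != nrow(b)) stop("result sets cover different model counts")
  keys <- intersect(c("scenario", "pattern", "maf", "h2"),
                    intersect(colnames(a), colnames(b)))
  if (length(keys)) {
    ka <- do.call(paste, c(a[keys], sep = "|"))
    kb <- do.call(paste, c(b[keys], sep = "|"))
    if (!identical(sort(ka), sort(kb)))
      stop("result sets cover different models")
    b <- b[match(ka, kb), , drop = FALSE]
  }
  d <- a$power - b$power
  if (sum(d != 0) < 2L)
    stop("fewer than 2 nonzero power differences; the signed-rank test ",
         "is undefined")
  wt <- suppressWarnings(stats::wilcox.test(a$power, b$power, paired = TRUE,
                                            alternative = alternative))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_models = length(d), n_nonzero = sum(d != 0),
       mean_diff = mean(d))
}
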