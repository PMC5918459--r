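#' Deterministic toy datasets for testing and demonstration
#'
#' Three kinds.  `"separable"`: 60 samples, 4 SNPs; a two-locus XOR pattern
#' on the first two SNPs determines a binary trait exactly, so a two-locus
#' search must recover the pair with perfect balanced accuracy.  `"null"`:
#' the trait is independent of all genotypes.  `"covariate_confounded"`: a
#' continuous trait driven mostly by a covariate plus a weak two-locus
#' genotype effect — the situation where skipping covariate adjustment can
#' hide a trait-associated interaction.
#'
#' @param kind `"separable"`, `"null"` or `"covariate_confounded"`.
#' @param seed integer seed; regeneration is bit-identical given it.
#' @return List with `genotypes` ([genotype_matrix()]), `phenotype`
#'   ([phenotype_table()]), `planted` (SNP ids of the planted pair),
#'   `causal_idx` (their column indices).
#' @export
toy_dataset <- function(kind = c("separable", "null",
                                 "covariate_confounded"), seed = 1L) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "separable") {
      n <- 60L
      g <- sapply(1:4, function(i) hwe_genotypes(0.5, n))
      y <- as.numeric((g[, 1L] + g[, 2L]) %% 2 == 1)
      # regenerate the causal columns until both classes appear (all but
      # certain at n = 60, maf 0.5)
      tries <- 0L
      while (length(unique(y)) < 2L && tries < 100L) {
        g[, 1L] <- hwe_genotypes(0.5, n)
        g[, 2L] <- hwe_genotypes(0.5, n)
        y <- as.numeric((g[, 1L] + g[, 2L]) %% 2 == 1)
        tries <- tries + 1L
      }
      fam <- "binomial"
      covs <- NULL
    } else if (kind == "null") {
      n <- 80L
      g <- sapply(1:4, function(i) hwe_genotypes(0.3, n))
      y <- stats::rbinom(n, 1L, 0.5)
      while (length(unique(y)) < 2L) y <- stats::rbinom(n, 1L, 0.5)
      fam <- "binomial"
      covs <- NULL
    } else {
      n <- 200L
      g <- sapply(1:4, function(i) hwe_genotypes(0.4, n))
      z <- stats::rnorm(n)
      effect <- as.numeric((g[, 1L] + g[, 2L]) %% 2 == 1) - 0.5
      y <- 1.0 * z + 0.35 * effect + stats::rnorm(n, 0, 0.8)
      fam <- "gaussian"
      covs <- data.frame(z = z)
    }
    samples <- sprintf("S%03d", seq_len(n))
    snps <- sprintf("SNP%d", 1:4)
    genos <- genotype_matrix(g, samples = samples, snps = snps)
    phenos <- phenotype_table(y, covs, family = fam, samples = samples)
    list(genotypes = genos, phenotype = phenos,
         planted = snps[1:2], causal_idx = 1:2)
  })
}

#' Brute-force fuzzy balanced accuracy (testing oracle)
#'
#' Recomputes the fuzzy balanced accuracy of one SNP combination by direct
#' per-sample loops, sharing no code with the production path: samples are
#' binned by literal genotype-tuple comparison, cell means and the
#' membership sigmoid are evaluated inline, and the four confusion masses
#' are accumulated term by term.  Intentionally slow and simple; intended
#' for validating [evaluate_combination()] and the search internals on
#' small instances.
#'
#' @param genos a [genotype_matrix()] (n at most ~1000 for tolerable speed).
#' @param combination SNP identifiers or column indices (k at most 3).
#' @param scores numeric score vector.
#' @param f a [membership_function()].
#' @return Balanced accuracy in `[0, 1]`.
#' @export
brute_force_ba <- function(genos, combination, scores, f) {
  if (is.numeric(combination)) combination <- colnames(genos)[combination]
  k <- length(combination)
  stopifnot(k >= 1L, k <= 3L, nrow(genos) <= 1000L)
  g <- unclass(genos)[, combination, drop = FALSE]
  n <- nrow(g)

  # enumerate all genotype tuples
  tuples <- as.matrix(expand.grid(rep(list(0:2), k)))[, k:1, drop = FALSE]
  if (k == 1L) tuples <- matrix(tuples[order(tuples[, 1L]), ], ncol = 1L)

  tp <- fn <- fp <- tn <- 0
  for (t in seq_len(nrow(tuples))) {
    cell_scores <- c()
    for (i in seq_len(n)) {
      gi <- g[i, ]
      if (any(is.na(gi))) next
      match_all <- TRUE
      for (m in seq_len(k)) if (gi[m] != tuples[t, m]) match_all <- FALSE
      if (match_all) cell_scores <- c(cell_scores, scores[i])
    }
    if (length(cell_scores) == 0L) next
    cell_mean <- sum(cell_scores) / length(cell_scores)
    # membership evaluated inline
    if (f$kind == "indicator") {
      muh <- if (cell_mean >= f$threshold) 1 else 0
    } else if (f$t_l == f$t_h) {
      muh <- if (cell_mean >= f$t_l) 1 else 0
    } else if (cell_mean <= f$t_l) {
      muh <- 0
    } else if (cell_mean >= f$t_h) {
      muh <- 1
    } else {
      ratio <- (cell_mean - f$t_h) / (cell_mean - f$t_l)
      muh <- 1 / (1 + ratio^2)
    }
    pos <- 0; neg <- 0
    for (s in cell_scores) {
      if (s >= 0) pos <- pos + s else neg <- neg + (-s)
    }
    tp <- tp + pos * muh
    fn <- fn + pos * (1 - muh)
    fp <- fp + neg * muh
    tn <- tn + neg * (1 - muh)
  }
  if (tp + fn <= 0 || fp + tn <= 0)
    stop("degenerate instance: one-sided score mass")
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}
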