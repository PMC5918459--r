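test_that("fold assignment is balanced, stratified and deterministic", {
  f <- make_folds(20, 10, seed = 3)
  expect_identical(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 2))
  f2 <- make_folds(20, 10, seed = 3)
  expect_identical(f, f2)
  expect_false(identical(f, make_folds(20, 10, seed = 4)))

  y <- rep(c(0, 1), each = 1000)
  fs <- make_folds(2000, 10, labels = y, seed = 5)
  tab <- table(fs, y)
  expect_true(all(tab == 100))

  # unstratified sizes differ by at most one
  f3 <- make_folds(23, 10, seed = 6)
  expect_lte(diff(range(table(factor(f3, levels = 1:10)))), 1)

  # a class too small to reach every fold is an error
  y2 <- c(rep(0, 30), rep(1, 3))
  expect_error(make_folds(33, 10, labels = y2, seed = 7),
               "zero cases or zero controls")
})

test_that("the exhaustive search enumerates choose(p, k) combinations and CVC sums to the fold count", {
  set.seed(31)
  genos <- random_geno(60, 5)
  s <- rnorm(60)
  cfg <- search_config(2, "fgmdr", n_folds = 10, seed = 2)
  res <- cross_validated_search(genos, s, cfg)
  expect_identical(nrow(res), 10L)           # C(5,2)
  expect_identical(sum(res$cvc), 10L)
  expect_true(all(res$ba_train >= 0 & res$ba_train <= 1, na.rm = TRUE))
  expect_true(all(res$ba_test >= 0 & res$ba_test <= 1, na.rm = TRUE))
  # selected model has maximal CVC
  expect_identical(res$cvc[1], max(res$cvc))
})

test_that("a planted separable signal attains full cross-validation consistency", {
  td <- toy_dataset("separable", seed = 9)
  cfg <- search_config(2, "fgmdr", t_l = 0, t_h = 0, seed = 11)
  res <- run_method(td$genotypes, td$phenotype, cfg)
  expect_identical(attr(res, "best"), "SNP1,SNP2")
  expect_identical(res$cvc[1], 10L)
})

test_that("FGMDR with a zero-width band reproduces GMDR exactly", {
  set.seed(32)
  td <- toy_dataset("covariate_confounded", seed = 4)
  cfg_g <- search_config(2, "gmdr", seed = 8)
  cfg_f <- search_config(2, "fgmdr", t_l = 0, t_h = 0, seed = 8)
  res_g <- run_method(td$genotypes, td$phenotype, cfg_g)
  res_f <- run_method(td$genotypes, td$phenotype, cfg_f)
  expect_identical(res_f$snp_combination, res_g$snp_combination)
  expect_identical(res_f$ba_train, res_g$ba_train)
  expect_identical(res_f$ba_test, res_g$ba_test)
  expect_identical(res_f$cvc, res_g$cvc)
})

test_that("MDR equals GMDR on a binary trait without covariates", {
  td <- toy_dataset("separable", seed = 13)
  r1 <- run_method(td$genotypes, td$phenotype,
                   search_config(2, "mdr", seed = 2))
  r2 <- run_method(td$genotypes, td$phenotype,
                   search_config(2, "gmdr", seed = 2))
  expect_identical(r1$ba_train, r2$ba_train)
  expect_identical(r1$cvc, r2$cvc)
})

test_that("results do not depend on SNP column order", {
  set.seed(33)
  genos <- random_geno(80, 5)
  s <- rnorm(80)
  cfg <- search_config(2, "fgmdr", seed = 21)
  res <- cross_validated_search(genos, s, cfg)
  perm <- c(4, 1, 5, 3, 2)
  genos_p <- genotype_matrix(unclass(genos)[, perm],
                             samples = rownames(genos),
                             snps = colnames(genos)[perm])
  res_p <- cross_validated_search(genos_p, s, cfg)
  ord <- order(res$snp_combination)
  ord_p <- order(res_p$snp_combination)
  expect_identical(res$snp_combination[ord], res_p$snp_combination[ord_p])
  expect_equal(res$ba_train[ord], res_p$ba_train[ord_p], tolerance = 1e-12)
  expect_identical(res$cvc[ord], res_p$cvc[ord_p])
})

test_that("covariates passed to covariate-blind methods are dropped with a warning", {
  td <- toy_dataset("covariate_confounded", seed = 5)
  expect_warning(
    run_method(td$genotypes, td$phenotype,
               search_config(2, "fmdr", seed = 2)),
    "ignores covariates")
})

test_that("the combinatorial budget guards runaway searches", {
  genos <- random_geno(20, 6)
  s <- rnorm(20)
  cfg <- search_config(3, "gmdr", seed = 1, max_combinations = 10)
  expect_error(cross_validated_search(genos, s, cfg), "pre-filter")
})

test_that("pure-noise data yields testing accuracy centred near one half", {
  set.seed(34)
  best_ba <- vapply(1:15, function(i) {
    td <- toy_dataset("null", seed = 100 + i)
    res <- run_method(td$genotypes, td$phenotype,
                      search_config(2, "gmdr", seed = i))
    res$ba_test[1]
  }, numeric(1))
  expect_lt(abs(mean(best_ba) - 0.5), 0.08)
})

test_that("per-fold score refitting runs and stays close to the fixed-score path", {
  td <- toy_dataset("covariate_confounded", seed = 6)
  cfg <- search_config(2, "fgmdr", seed = 3, refit_scores = TRUE)
  res <- run_method(td$genotypes, td$phenotype, cfg)
  expect_true(all(is.finite(res$ba_train)))
  cfg0 <- search_config(2, "fgmdr", seed = 3)
  res0 <- run_method(td$genotypes, td$phenotype, cfg0)
  ord <- order(res$snp_combination); ord0 <- order(res0$snp_combination)
  expect_lt(max(abs(res$ba_train[ord] - res0$ba_train[ord0])), 0.05)
})
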