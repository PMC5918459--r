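test_that("Hardy-Weinberg draws match the closed-form proportions", {
  g <- hwe_genotypes(0.5, 1e5, seed = 41)
  prop <- tabulate(g + 1L, 3L) / 1e5
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 1e5)
  expect_true(all(abs(prop - c(0.25, 0.5, 0.25)) < 3 * se))

  g2 <- hwe_genotypes(0.2, 1e5, seed = 42)
  prop2 <- tabulate(g2 + 1L, 3L) / 1e5
  exp2 <- c(0.64, 0.32, 0.04)
  se2 <- sqrt(exp2 * (1 - exp2) / 1e5)
  expect_true(all(abs(prop2 - exp2) < 3 * se2))

  # goodness of fit does not reject at alpha = 0.001
  chi <- chisq.test(tabulate(g2 + 1L, 3L), p = exp2)
  expect_gt(chi$p.value, 0.001)

  expect_identical(hwe_genotypes(0.3, 50, seed = 7),
                   hwe_genotypes(0.3, 50, seed = 7))
  expect_error(hwe_genotypes(0.6, 10), "maf")
  expect_error(hwe_genotypes(0, 10), "maf")
})

test_that("generated penetrance models are marginal-effect-free at the target heritability", {
  # h2 = 0.001 is attainable for every pattern/maf pair; the stronger
  # 0.1 target is additionally exercised where the pattern supports it
  for (pat in interaction_patterns()) {
    for (maf in c(0.2, 0.4)) {
      m <- make_penetrance_model(pat, maf = maf, heritability = 0.001)
      expect_lt(fgmdr:::marginal_effect_size(m), 1e-8)
      expect_equal(penetrance_heritability(m), 0.001, tolerance = 1e-3)
      expect_true(all(m$table >= 0 & m$table <= 1))
    }
  }
  for (pat in c("xor", "domdom")) {
    for (maf in c(0.2, 0.4)) {
      m <- make_penetrance_model(pat, maf = maf, heritability = 0.1)
      expect_lt(fgmdr:::marginal_effect_size(m), 1e-8)
      expect_equal(penetrance_heritability(m), 0.1, tolerance = 1e-3)
    }
  }
  # XOR at maf 0.5 scaled to h2 = 0.1: direct variance computation over the
  # nine weighted cells recovers the target
  m <- make_penetrance_model("xor", maf = 0.5, heritability = 0.1)
  w <- c(0.25, 0.5, 0.25)
  W <- outer(w, w)
  fbar <- sum(W * m$table)
  h2 <- sum(W * (m$table - fbar)^2) / (fbar * (1 - fbar))
  expect_equal(h2, 0.1, tolerance = 1e-3)
})

test_that("a constant table has zero heritability and no marginal effect", {
  m <- make_penetrance_model("xor", maf = 0.3, heritability = 0)
  expect_true(all(m$table == 0.5))
  expect_equal(penetrance_heritability(m), 0)
  expect_lt(fgmdr:::marginal_effect_size(m), 1e-12)
})

test_that("unattainable heritability targets report the attainable maximum", {
  err <- tryCatch(make_penetrance_model("recrec", maf = 0.2,
                                        heritability = 0.9),
                  error = function(e) conditionMessage(e))
  expect_match(err, "maximum attainable h2")
})

test_that("penetrance model files round-trip", {
  m <- make_penetrance_model("domdom", maf = 0.4, heritability = 0.2)
  path <- withr_local_file("model.txt")
  write_penetrance_model(m, path)
  m2 <- read_penetrance_model(path)
  expect_equal(m2$table, m$table, tolerance = 1e-15)
  expect_identical(m2$maf, m$maf)
  expect_identical(m2$heritability, m$heritability)
})

test_that("scenario 1 obeys its variance decomposition", {
  m <- make_penetrance_model("xor", maf = 0.4, heritability = 0.2)
  ds <- simulate_scenario1(m, n = 1e5, p = 2, seed = 43)
  w <- fgmdr:::hwe_weights(0.4)
  W <- outer(w, w)
  fbar <- sum(W * m$table)
  varg <- sum(W * (m$table - fbar)^2)
  expect_equal(var(ds$phenotype$y), varg + 0.01 + 0.49 + 1,
               tolerance = 0.03)
  # coefficients at zero leave only the unit error variance
  ds0 <- simulate_scenario1(m, n = 1e5, p = 2, seed = 44,
                            beta = 0, gamma = 0)
  expect_equal(var(ds0$phenotype$y), 1, tolerance = 0.03)
})

test_that("scenario datasets are bit-reproducible under a fixed seed", {
  m <- make_penetrance_model("xor", maf = 0.2, heritability = 0.1)
  for (sim in list(function(seed) simulate_scenario1(m, 200, 6, seed),
                   function(seed) simulate_scenario2(m, 200, 6, seed),
                   function(seed) simulate_scenario3(m, 100, 100, 6,
                                                     seed))) {
    a <- sim(99); b <- sim(99)
    expect_identical(unclass(a$genotypes), unclass(b$genotypes))
    expect_identical(a$phenotype$y, b$phenotype$y)
    expect_identical(a$phenotype$covariates$Z, b$phenotype$covariates$Z)
    expect_identical(a$causal_idx, b$causal_idx)
  }
})

test_that("scenario 2 median split yields an exact case/control balance", {
  m <- make_penetrance_model("threshold", maf = 0.4, heritability = 0.1)
  ds <- simulate_scenario2(m, n = 2000, p = 5, seed = 45)
  expect_identical(sum(ds$phenotype$y == 1), 1000L)
  expect_identical(sum(ds$phenotype$y == 0), 1000L)
  expect_identical(ds$phenotype$family, "binomial")
})

test_that("scenario 3 fills exact case/control quotas and fails on impossible ones", {
  m <- make_penetrance_model("xor", maf = 0.4, heritability = 0.1)
  ds <- simulate_scenario3(m, n_cases = 150, n_controls = 250, p = 5,
                           seed = 46)
  expect_identical(sum(ds$phenotype$y == 1), 150L)
  expect_identical(sum(ds$phenotype$y == 0), 250L)
  # an extreme intercept starves one arm within a small draw budget
  expect_error(simulate_scenario3(m, n_cases = 50, n_controls = 50, p = 5,
                                  seed = 47, alpha = -40, sd_e = 0.1,
                                  max_draw_factor = 5L),
               "quota")
})

test_that("causal genotypes follow the model maf and non-causal SNPs stay in HWE", {
  m <- make_penetrance_model("xor", maf = 0.2, heritability = 0.1)
  ds <- simulate_scenario1(m, n = 2e4, p = 4, seed = 48)
  g <- unclass(ds$genotypes)
  for (j in ds$causal_idx) {
    maf_hat <- mean(g[, j]) / 2
    expect_lt(abs(maf_hat - 0.2), 0.01)
  }
  # every non-causal SNP passes an HWE goodness-of-fit check at its own maf
  for (j in setdiff(1:4, ds$causal_idx)) {
    maf_hat <- mean(g[, j]) / 2
    expected <- fgmdr:::hwe_weights(maf_hat)
    chi <- suppressWarnings(chisq.test(tabulate(g[, j] + 1L, 3L),
                                       p = expected))
    expect_gt(chi$p.value, 0.001)
  }
})
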