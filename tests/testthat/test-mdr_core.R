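hand_table <- function() {
  # one-locus example: genotypes (0,0,1,2), scores (1,-1,2,-3)
  g <- genotype_matrix(matrix(c(0L, 0L, 1L, 2L), 4, 1),
                       samples = paste0("s", 1:4), snps = "A")
  build_cell_table(g, "A", c(1, -1, 2, -3))
}

test_that("cell aggregation matches the hand-worked one-locus example", {
  ct <- hand_table()
  expect_identical(ct$cells$count, c(2L, 1L, 1L))
  expect_equal(ct$cells$pos_sum, c(1, 2, 0))
  expect_equal(ct$cells$neg_mag, c(1, 0, 3))
  expect_equal(ct$cells$mean_score, c(0, 2, -3))
  expect_identical(ct$n_complete, 4L)
})

test_that("counts are conserved and missing genotypes excluded per table", {
  set.seed(21)
  for (i in 1:10) {
    genos <- random_geno(40, 4, miss_rate = 0.1)
    s <- rnorm(40)
    comb <- sample(colnames(genos), 2)
    ct <- build_cell_table(genos, comb, s)
    n_complete <- sum(stats::complete.cases(unclass(genos)[, comb]))
    expect_identical(sum(ct$cells$count), n_complete)
    # pos - neg == count * mean on every nonempty cell
    ne <- ct$cells$count > 0
    expect_equal(ct$cells$pos_sum[ne] - ct$cells$neg_mag[ne],
                 ct$cells$count[ne] * ct$cells$mean_score[ne],
                 tolerance = 1e-12)
    expect_true(all(ct$cells$pos_sum >= 0 & ct$cells$neg_mag >= 0))
  }
  # one sample missing SNP B drops that sample from this table only
  g <- matrix(c(0L, 1L, 2L, 0L, NA, 1L), 3, 2,
              dimnames = list(paste0("s", 1:3), c("A", "B")))
  genos <- genotype_matrix(g)
  ct <- build_cell_table(genos, c("A", "B"), c(1, 2, 3))
  expect_identical(sum(ct$cells$count), 2L)
  ct1 <- build_cell_table(genos, "A", c(1, 2, 3))
  expect_identical(sum(ct1$cells$count), 3L)
})

test_that("order bounds and unknown SNPs are rejected", {
  genos <- random_geno(10, 6)
  s <- rnorm(10)
  expect_error(build_cell_table(genos, colnames(genos), s), "between 1 and 5")
  expect_error(build_cell_table(genos, "nope", s), "unknown SNP")
})

test_that("fuzzy confusion reproduces the two-cell hand arithmetic", {
  # cells with (pos, neg) = (3,1) and (1,2) and memberships (0.8, 0.2):
  # tp = 2.6, fn = 1.4, fp = 1.2, tn = 1.8; BA = (0.65 + 0.60)/2 = 0.625
  ct <- structure(list(
    combination = "A", k = 1L,
    cells = data.frame(cell = 1:3, count = c(1L, 1L, 0L),
                       pos_sum = c(3, 1, 0), neg_mag = c(1, 2, 0),
                       mean_score = c(1/3, -1/3, NA)),
    n_complete = 2L, n_excluded = 0L), class = "cell_table")
  f <- membership_function("sigmoid", t_l = -1, t_h = 1)  # mu(1/3)=0.8
  conf <- fuzzy_confusion(ct, f)
  expect_equal(conf$tp, 2.6, tolerance = 1e-12)
  expect_equal(conf$fn, 1.4, tolerance = 1e-12)
  expect_equal(conf$fp, 1.2, tolerance = 1e-12)
  expect_equal(conf$tn, 1.8, tolerance = 1e-12)
  expect_equal(balanced_accuracy(conf), 0.625, tolerance = 1e-12)
})

test_that("confusion masses conserve the score mass split by sign", {
  set.seed(22)
  for (i in 1:20) {
    genos <- random_geno(30, 3)
    s <- rnorm(30)
    ct <- build_cell_table(genos, colnames(genos)[1:2], s)
    f <- membership_function("sigmoid", t_l = -abs(rnorm(1)),
                             t_h = abs(rnorm(1)))
    conf <- fuzzy_confusion(ct, f)
    expect_equal(conf$tp + conf$fn, sum(ct$cells$pos_sum),
                 tolerance = 1e-12)
    expect_equal(conf$fp + conf$tn, sum(ct$cells$neg_mag),
                 tolerance = 1e-12)
  }
})

test_that("balanced accuracy spans its degenerate extremes", {
  half <- structure(list(tp = 2, fn = 2, fp = 1.5, tn = 1.5),
                    class = "fuzzy_confusion")
  expect_equal(balanced_accuracy(half), 0.5)
  perfect <- structure(list(tp = 3, fn = 0, fp = 0, tn = 2),
                       class = "fuzzy_confusion")
  expect_equal(balanced_accuracy(perfect), 1)
  onesided <- structure(list(tp = 0, fn = 0, fp = 1, tn = 1),
                        class = "fuzzy_confusion")
  expect_error(balanced_accuracy(onesided), "no positive-score mass")
})

test_that("uniform 0.5 membership equalizes tp/fn and fp/tn", {
  ct <- hand_table()
  # means are (0, 2, -3); a wide symmetric band puts 0 at exactly 0.5
  f <- membership_function("sigmoid", t_l = -1e8, t_h = 1e8)
  conf <- fuzzy_confusion(ct, f)
  expect_equal(conf$tp, conf$fn, tolerance = 1e-6)
  expect_equal(conf$fp, conf$tn, tolerance = 1e-6)
})

test_that("crisp classification follows the nonnegative-mean rule", {
  ct <- hand_table()
  expect_identical(classify_cells(ct, threshold = 0), c("H", "H", "L"))
  ct$cells$mean_score[1] <- -0.001
  expect_identical(classify_cells(ct, threshold = 0), c("L", "H", "L"))
  ct$cells$count[1] <- 0L
  expect_identical(classify_cells(ct, threshold = 0), c("empty", "H", "L"))
})

test_that("indicator membership yields the crisp high/low split exactly", {
  set.seed(23)
  for (i in 1:20) {
    genos <- random_geno(35, 4, miss_rate = 0.05)
    s <- rnorm(35)
    comb <- sample(colnames(genos), 2)
    ct <- build_cell_table(genos, comb, s)
    f <- membership_function("indicator", threshold = 0)
    conf <- fuzzy_confusion(ct, f)
    h <- classify_cells(ct) == "H"
    l <- classify_cells(ct) == "L"
    expect_identical(conf$tp, sum(ct$cells$pos_sum[h]))
    expect_identical(conf$fn, sum(ct$cells$pos_sum[l]))
    expect_identical(conf$fp, sum(ct$cells$neg_mag[h]))
    expect_identical(conf$tn, sum(ct$cells$neg_mag[l]))
  }
})

test_that("BA is invariant to SNP order within a combination and to score scaling", {
  set.seed(24)
  genos <- random_geno(50, 5)
  s <- rnorm(50)
  f <- membership_function("sigmoid", t_l = -0.6, t_h = 0.8)
  ba1 <- evaluate_combination(genos, s, c("SNP2", "SNP4"), f)
  ba2 <- evaluate_combination(genos, s, c("SNP4", "SNP2"), f)
  expect_equal(ba1, ba2, tolerance = 1e-12)
  # positive rescaling of scores and thresholds together changes nothing
  c0 <- 3.7
  f2 <- membership_function("sigmoid", t_l = -0.6 * c0, t_h = 0.8 * c0)
  ba3 <- evaluate_combination(genos, s * c0, c("SNP2", "SNP4"), f2)
  expect_equal(ba1, ba3, tolerance = 1e-12)
})

test_that("fuzzy BA approaches the crisp BA as the band shrinks", {
  set.seed(25)
  genos <- random_geno(60, 3)
  s <- rnorm(60)
  target <- crisp_ba(genos, c("SNP1", "SNP2"), s, threshold = 0)
  widths <- c(0.5, 0.1, 0.01, 0.001, 1e-6)
  bas <- vapply(widths, function(w)
    evaluate_combination(genos, s, c("SNP1", "SNP2"),
                         membership_function("sigmoid", t_l = -w / 2,
                                             t_h = w / 2)),
    numeric(1))
  errs <- abs(bas - target)
  expect_lt(errs[4], 1e-2)
  expect_lt(errs[5], 1e-6)
  expect_lte(errs[5], errs[1])
})

test_that("cell reports enumerate genotype labels in AABB..aabb order", {
  set.seed(26)
  genos <- random_geno(80, 2)
  s <- rnorm(80)
  ct <- build_cell_table(genos, c("SNP1", "SNP2"), s)
  rep_f <- cell_report(ct, membership_function("sigmoid", t_l = -1,
                                               t_h = 1))
  expect_identical(nrow(rep_f), 9L)
  expect_identical(rep_f$genotype,
                   c("AABB", "AABb", "AAbb", "AaBB", "AaBb", "Aabb",
                     "aaBB", "aaBb", "aabb"))
  ne <- !is.na(rep_f$mu_h)
  expect_true(all(rep_f$mu_h[ne] >= 0 & rep_f$mu_h[ne] <= 1))
  rep_i <- cell_report(ct, membership_function("indicator"))
  expect_true(all(rep_i$mu_h[!is.na(rep_i$mu_h)] %in% c(0, 1)))
})
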