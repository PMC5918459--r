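# Randomized small instances shared across tests.

random_geno <- function(n, p, miss_rate = 0) {
  g <- matrix(sample(0:2, n * p, replace = TRUE,
                     prob = c(0.45, 0.4, 0.15)), n, p)
  if (miss_rate > 0) {
    drop <- which(runif(n * p) < miss_rate)
    g[drop] <- NA_integer_
  }
  genotype_matrix(g, samples = sprintf("s%03d", seq_len(n)),
                  snps = sprintf("SNP%d", seq_len(p)))
}

# genotypes + scores + a random membership function (sigmoid or indicator)
random_instance <- function(seed, n_range = c(20L, 50L),
                            p_range = c(3L, 5L), k_max = 3L,
                            miss_rate = 0.02) {
  set.seed(seed)
  n <- sample(n_range[1]:n_range[2], 1L)
  p <- sample(p_range[1]:p_range[2], 1L)
  genos <- random_geno(n, p, miss_rate)
  scores <- rnorm(n)
  k <- sample(seq_len(min(k_max, p)), 1L)
  combination <- sort(sample(colnames(genos), k))
  if (runif(1) < 0.5) {
    tl <- rnorm(1, sd = 0.5)
    f <- membership_function("sigmoid", t_l = tl,
                             t_h = tl + rexp(1, rate = 2))
  } else {
    f <- membership_function("indicator", threshold = rnorm(1, sd = 0.2))
  }
  list(genos = genos, scores = scores, combination = combination, f = f,
       n = n, p = p, k = k)
}

withr_local_file <- function(name) {
  file.path(tempdir(), paste0(sample.int(1e9, 1), "_", name))
}

# Crisp (G)MDR balanced accuracy computed through the classify_cells route:
# hard-partition cells into H/L and sum the residual masses.
crisp_ba <- function(genos, combination, scores, threshold = 0) {
  ct <- build_cell_table(genos, combination, scores)
  lab <- classify_cells(ct, threshold = threshold)
  h <- lab == "H"; l <- lab == "L"
  tp <- sum(ct$cells$pos_sum[h]); fn <- sum(ct$cells$pos_sum[l])
  fp <- sum(ct$cells$neg_mag[h]); tn <- sum(ct$cells$neg_mag[l])
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}
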