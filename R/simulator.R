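#' Hardy-Weinberg genotype draws
#'
#' i.i.d. additive-coded genotypes with `P(0) = (1-maf)^2`,
#' `P(1) = 2 maf (1-maf)`, `P(2) = maf^2`.
#'
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @param n number of draws.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of genotypes in `{0, 1, 2}`.
#' @export
hwe_genotypes <- function(maf, n, seed = NULL) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("maf must be in (0, 0.5], got ", maf)
  with_seed(seed,
    sample(0:2, n, replace = TRUE, prob = hwe_weights(maf)))
}

hwe_weights <- function(maf) {
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

# Built-in two-locus epistasis patterns (before projection onto the
# marginal-effect-free space).  Rows index locus 1 genotypes 0..2, columns
# locus 2.
base_patterns <- function() {
  g <- 0:2
  list(
    xor        = outer(g, g, function(a, b) as.numeric((a + b) %% 2 == 1)),
    domdom     = outer(g, g, function(a, b) as.numeric(a >= 1 & b >= 1)),
    recrec     = outer(g, g, function(a, b) as.numeric(a == 2 & b == 2)),
    addmult    = outer(g, g, function(a, b) a * b),
    threshold  = outer(g, g, function(a, b) as.numeric(a + b >= 3))
  )
}

#' Names of the built-in interaction patterns
#' @return Character vector of pattern identifiers.
#' @export
interaction_patterns <- function() names(base_patterns())

#' Construct a marginal-effect-free two-locus penetrance model
#'
#' Starts from a named epistasis pattern, removes all marginal effects by
#' weighted double-centering under the Hardy-Weinberg genotype weights of
#' `maf`, and scales the centred pattern around a constant baseline so the
#' model's heritability hits the target.  Heritability is the penetrance
#' heritability `h2 = Var_g / (fbar (1 - fbar))`, where `Var_g` is the
#' HWE-weighted variance of the 9 cell penetrances and `fbar` their weighted
#' mean (which equals the baseline).
#'
#' @param pattern one of [interaction_patterns()], or a user 3x3 matrix
#'   (which is likewise double-centred before scaling).
#' @param maf minor allele frequency of both causal SNPs (0.2 and 0.4 in the
#'   simulation grid).
#' @param heritability target `h2` in `[0, 1)`.
#' @param baseline constant penetrance baseline `fbar` (default 0.5, which
#'   maximizes the attainable `h2` range).
#' @return Object of class `"penetrance_model"`: list with `table` (3x3,
#'   entries in `[0, 1]`, HWE-weighted row and column means all equal to
#'   `baseline`), `maf`, `heritability`, `pattern`, `baseline`.
#' @export
make_penetrance_model <- function(pattern = "xor", maf, heritability,
                                  baseline = 0.5) {
  stopifnot(maf > 0, maf <= 0.5, heritability >= 0, heritability < 1,
            baseline > 0, baseline < 1)
  if (is.character(pattern)) {
    pat_name <- match.arg(pattern, interaction_patterns())
    P <- base_patterns()[[pat_name]]
  } else {
    P <- as.matrix(pattern)
    if (!all(dim(P) == c(3L, 3L))) stop("pattern matrix must be 3x3")
    pat_name <- "custom"
  }
  w <- hwe_weights(maf)
  C <- double_center(P, w)
  ss <- sum(outer(w, w) * C^2)
  if (ss < 1e-10)
    stop("pattern '", pat_name, "' has no interaction component after ",
         "removing marginal effects; pick another pattern")
  delta <- sqrt(heritability * baseline * (1 - baseline) / ss)
  f <- baseline + delta * C
  if (any(f < 0 | f > 1)) {
    dmax <- min(ifelse(C > 0, (1 - baseline) / C, Inf),
                ifelse(C < 0, -baseline / C, Inf))
    h2max <- dmax^2 * ss / (baseline * (1 - baseline))
    stop("target heritability ", heritability, " is unattainable for ",
         "pattern '", pat_name, "' at maf ", maf, " with baseline ",
         baseline, "; maximum attainable h2 is ", signif(h2max, 4))
  }
  dimnames(f) <- list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb"))
  structure(list(table = f, maf = maf, heritability = heritability,
                 pattern = pat_name, baseline = baseline),
            class = "penetrance_model")
}

# Weighted double-centering: removes HWE-weighted row and column means so
# the result has zero marginal effect at both loci.
double_center <- function(P, w) {
  rowm <- as.numeric(P %*% w)
  colm <- as.numeric(w %*% P)
  grand <- sum(outer(w, w) * P)
  sweep(sweep(P, 1, rowm), 2, colm) + grand
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("penetrance_model: pattern ", x$pattern, ", maf ", x$maf,
      ", h2 ", x$heritability, "\n", sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' Penetrance heritability of a model
#'
#' Recomputes `h2 = Var_g / (fbar (1 - fbar))` from the 3x3 table and the
#' HWE weights implied by the model's minor allele frequency.
#'
#' @param model a [make_penetrance_model()] result (or any list with a 3x3
#'   `table` and `maf`).
#' @return Numeric `h2`.
#' @export
penetrance_heritability <- function(model) {
  w <- hwe_weights(model$maf)
  W <- outer(w, w)
  fbar <- sum(W * model$table)
  varg <- sum(W * (model$table - fbar)^2)
  varg / (fbar * (1 - fbar))
}

# Max abs deviation of HWE-weighted row/column penetrance means from their
# overall mean (0 for a marginal-effect-free model).
marginal_effect_size <- function(model) {
  w <- hwe_weights(model$maf)
  rowm <- as.numeric(model$table %*% w)
  colm <- as.numeric(w %*% model$table)
  fbar <- sum(outer(w, w) * model$table)
  max(abs(c(rowm - fbar, colm - fbar)))
}

#' Write / read a penetrance-model file
#'
#' Plain-text format: comment lines `# maf=`, `# heritability=`,
#' `# pattern=` followed by the 3x3 tab-delimited table.
#'
#' @param model a `"penetrance_model"`.
#' @param path file path.
#' @return `path` invisibly (writer); a `"penetrance_model"` (reader).
#' @export
write_penetrance_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# maf=", model$maf),
               paste0("# heritability=", model$heritability),
               paste0("# pattern=", model$pattern)), con)
  utils::write.table(format(model$table, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_penetrance_model
#' @export
read_penetrance_model <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta_lines, value = TRUE)
    if (!length(hit)) stop("missing metadata line '# ", key, "=' in ", path)
    sub(paste0("^#\\s*", key, "="), "", hit[1L])
  }
  maf <- as.numeric(get_meta("maf"))
  h2 <- as.numeric(get_meta("heritability"))
  pattern <- tryCatch(get_meta("pattern"), error = function(e) "custom")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  tab <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  if (!all(dim(tab) == c(3L, 3L))) stop("penetrance table must be 3x3")
  if (any(tab < 0 | tab > 1)) stop("penetrance values must lie in [0, 1]")
  dimnames(tab) <- list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb"))
  structure(list(table = tab, maf = maf, heritability = h2,
                 pattern = pattern, baseline = NA_real_),
            class = "penetrance_model")
}

# Shared machinery: genotypes for p SNPs with a causal pair at `causal`
# positions drawn at the model maf, remaining SNPs at mafs uniform in
# [0.05, 0.5]; genetic effect X ~ N(f(g1, g2), sd_x); covariate
# Z ~ N(0, sd_z).  Assumes the RNG is already seeded by the caller.
draw_population <- function(model, n, p, sd_x, sd_z) {
  stopifnot(p >= 2L)
  causal <- sort(sample.int(p, 2L))
  g <- matrix(NA_integer_, n, p)
  g[, causal[1L]] <- hwe_genotypes(model$maf, n)
  g[, causal[2L]] <- hwe_genotypes(model$maf, n)
  noncausal <- setdiff(seq_len(p), causal)
  mafs <- stats::runif(length(noncausal), 0.05, 0.5)
  for (i in seq_along(noncausal))
    g[, noncausal[i]] <- hwe_genotypes(mafs[i], n)
  pen <- model$table[cbind(g[, causal[1L]] + 1L, g[, causal[2L]] + 1L)]
  X <- stats::rnorm(n, mean = pen, sd = sd_x)
  Z <- stats::rnorm(n, mean = 0, sd = sd_z)
  list(g = g, X = X, Z = Z, causal = causal)
}

finish_dataset <- function(g, y, Z, family, causal, scenario, seed, model) {
  n <- nrow(g); p <- ncol(g)
  snps <- sprintf("SNP%03d", seq_len(p))
  samples <- sprintf("S%04d", seq_len(n))
  genos <- genotype_matrix(g, samples = samples, snps = snps)
  phenos <- phenotype_table(y, data.frame(Z = Z), family = family,
                            samples = samples)
  structure(list(genotypes = genos, phenotype = phenos,
                 causal = snps[causal], causal_idx = causal,
                 scenario = scenario, seed = seed, model = model),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset: scenario ", x$scenario, ", n = ",
      nrow(x$genotypes), ", p = ", ncol(x$genotypes),
      ", causal pair ", paste(x$causal, collapse = ","),
      " (pattern ", x$model$pattern, ", maf ", x$model$maf,
      ", h2 ", x$model$heritability, ")\n", sep = "")
  invisible(x)
}

#' Scenario 1: continuous trait
#'
#' `Y_i = alpha + beta * X_i + gamma * Z_i + eps_i` with identity link:
#' the genetic effect `X_i` is normal with mean equal to the penetrance
#' value of individual `i`'s causal-pair genotype and standard deviation
#' `sd_x = 0.1`; the covariate `Z_i ~ N(0, 0.7^2)`; `eps_i ~ N(0, 1)`;
#' `alpha = 0`, `beta = gamma = 1`.  Defaults `n = 2000`, `p = 100`.
#'
#' @param model a [make_penetrance_model()] result.
#' @param n,p sample and SNP counts.
#' @param seed integer seed; the dataset is bit-reproducible given it.
#' @param alpha,beta,gamma,sd_x,sd_z,sd_e model coefficients and noise
#'   standard deviations (defaults as above).
#' @return Object of class `"sim_dataset"`: list with `genotypes`,
#'   `phenotype` (gaussian, covariate `Z`), `causal`, `causal_idx`,
#'   `scenario`, `seed`, `model`.
#' @export
simulate_scenario1 <- function(model, n = 2000L, p = 100L, seed = 1L,
                               alpha = 0, beta = 1, gamma = 1,
                               sd_x = 0.1, sd_z = 0.7, sd_e = 1) {
  stopifnot(inherits(model, "penetrance_model"), n > 0L, p >= 2L)
  with_seed(seed, {
    pop <- draw_population(model, n, p, sd_x, sd_z)
    y <- alpha + beta * pop$X + gamma * pop$Z + stats::rnorm(n, 0, sd_e)
    finish_dataset(pop$g, y, pop$Z, "gaussian", pop$causal, 1L, seed, model)
  })
}

#' Scenario 2: binary trait from a thresholded continuous value
#'
#' The continuous value is generated as in scenario 1 but with error
#' standard deviation `sd_e = 0.5`; the trait is 1 for values above the
#' per-replicate median and 0 otherwise, giving an exact 50/50 case/control
#' split for even `n` (1000 cases and 1000 controls at the default
#' `n = 2000`).
#'
#' @inheritParams simulate_scenario1
#' @return A `"sim_dataset"` with a binomial phenotype.
#' @export
simulate_scenario2 <- function(model, n = 2000L, p = 100L, seed = 1L,
                               alpha = 0, beta = 1, gamma = 1,
                               sd_x = 0.1, sd_z = 0.7, sd_e = 0.5) {
  stopifnot(inherits(model, "penetrance_model"), n > 0L, p >= 2L)
  with_seed(seed, {
    pop <- draw_population(model, n, p, sd_x, sd_z)
    latent <- alpha + beta * pop$X + gamma * pop$Z + stats::rnorm(n, 0, sd_e)
    y <- as.integer(latent > stats::median(latent))
    finish_dataset(pop$g, y, pop$Z, "binomial", pop$causal, 2L, seed, model)
  })
}

#' Scenario 3: binary trait from a logit model, case-control sampled
#'
#' `logit P(Y_i = 1) = alpha + beta * X_i + gamma * Z_i + eps_i` with
#' `beta = 0.5` and error standard deviation `sd_e = 2` (an over-dispersion
#' term inside the linear predictor).  Individuals are drawn from the
#' population model, labelled Bernoulli, and accumulated by rejection until
#' exactly `n_cases` cases and `n_controls` controls are collected.
#'
#' @param model a [make_penetrance_model()] result.
#' @param n_cases,n_controls case/control quotas (defaults 1000/1000).
#' @param p number of SNPs.
#' @param seed integer seed.
#' @param alpha,beta,gamma,sd_x,sd_z,sd_e model parameters (defaults as
#'   above).
#' @param max_draw_factor budget: at most `max_draw_factor * (n_cases +
#'   n_controls)` individuals are drawn before giving up.
#' @return A `"sim_dataset"` with a binomial phenotype.
#' @export
simulate_scenario3 <- function(model, n_cases = 1000L, n_controls = 1000L,
                               p = 100L, seed = 1L,
                               alpha = 0, beta = 0.5, gamma = 1,
                               sd_x = 0.1, sd_z = 0.7, sd_e = 2,
                               max_draw_factor = 500L) {
  stopifnot(inherits(model, "penetrance_model"),
            n_cases > 0L, n_controls > 0L, p >= 2L)
  need <- n_cases + n_controls
  with_seed(seed, {
    causal <- sort(sample.int(p, 2L))
    acc_g1 <- acc_g2 <- integer(0)
    acc_z <- numeric(0)
    acc_y <- integer(0)
    drawn <- 0L
    while ((sum(acc_y == 1L) < n_cases || sum(acc_y == 0L) < n_controls)) {
      if (drawn >= max_draw_factor * need)
        stop("case/control quota not met within ", drawn,
             " draws; the case probability is too extreme under these ",
             "coefficients")
      m <- max(need, 2L * need - length(acc_y))
      g1 <- hwe_genotypes(model$maf, m)
      g2 <- hwe_genotypes(model$maf, m)
      pen <- model$table[cbind(g1 + 1L, g2 + 1L)]
      X <- stats::rnorm(m, pen, sd_x)
      Z <- stats::rnorm(m, 0, sd_z)
      eta <- alpha + beta * X + gamma * Z + stats::rnorm(m, 0, sd_e)
      y <- stats::rbinom(m, 1L, stats::plogis(eta))
      acc_g1 <- c(acc_g1, g1); acc_g2 <- c(acc_g2, g2)
      acc_z <- c(acc_z, Z); acc_y <- c(acc_y, y)
      drawn <- drawn + m
    }
    take_cases <- which(acc_y == 1L)[seq_len(n_cases)]
    take_controls <- which(acc_y == 0L)[seq_len(n_controls)]
    take <- sort(c(take_cases, take_controls))
    n <- length(take)
    g <- matrix(NA_integer_, n, p)
    g[, causal[1L]] <- acc_g1[take]
    g[, causal[2L]] <- acc_g2[take]
    noncausal <- setdiff(seq_len(p), causal)
    mafs <- stats::runif(length(noncausal), 0.05, 0.5)
    for (i in seq_along(noncausal))
      g[, noncausal[i]] <- hwe_genotypes(mafs[i], n)
    finish_dataset(g, acc_y[take], acc_z[take], "binomial", causal, 3L,
                   seed, model)
  })
}
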