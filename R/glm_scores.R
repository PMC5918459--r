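#' Fit the covariate-only null model
#'
#' Fits the generalized linear model `l(mu_i) = alpha + z_i' gamma` with no
#' genotype terms: identity-link least squares for a gaussian trait, logit
#' maximum likelihood for a binomial trait.  Per-sample score residuals from
#' this fit are what the interaction search aggregates, so the genotype
#' effect under test never enters the fit.
#'
#' @param phenos a [phenotype_table()]; its covariates (possibly none) form
#'   the design matrix together with an intercept.
#' @return An object of class `"null_model_fit"`: list with `model` (the
#'   `lm`/`glm` fit), `family`, `fitted`, `dispersion`, `n`.
#' @examples
#' ph <- phenotype_table(rnorm(20), family = "gaussian")
#' fit <- fit_null_model(ph)
#' all.equal(unname(fit$fitted), rep(mean(ph$y), 20))
#' @export
fit_null_model <- function(phenos) {
  stopifnot(inherits(phenos, "phenotype_table"))
  df <- cbind(data.frame(.y = phenos$y), phenos$covariates)
  form <- if (ncol(phenos$covariates)) stats::as.formula(".y ~ .")
          else stats::as.formula(".y ~ 1")
  mm <- stats::model.matrix(form, data = df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("covariate design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (phenos$family == "gaussian") {
    fit <- stats::lm(form, data = df)
    sigma2 <- sum(stats::residuals(fit)^2) / fit$df.residual
    if (!is.finite(sigma2) || sigma2 < 1e-12 * max(stats::var(phenos$y), 1e-300))
      warning("degenerate residual variance: covariates fit the trait ",
              "(almost) perfectly; scores are undefined")
  } else {
    fit <- stats::glm(form, data = df, family = stats::binomial())
    if (!fit$converged)
      stop("logistic null model did not converge after ", fit$iter,
           " IRLS iterations")
    sigma2 <- 1
  }
  structure(list(model = fit, family = phenos$family,
                 fitted = stats::fitted(fit), dispersion = sigma2,
                 n = length(phenos$y), samples = phenos$samples),
            class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat("null_model_fit: family ", x$family, ", n = ", x$n,
      ", ", length(stats::coef(x$model)), " coefficient(s)\n", sep = "")
  invisible(x)
}

#' Per-sample studentized score residuals
#'
#' Computes the score `S_i = (y_i - mu_hat_i) / sqrt(Var_hat(y_i - mu_hat_i))`
#' from the null fit.  The default `"internal"` variant is leverage-adjusted:
#' for a gaussian trait the internally studentized residual
#' `r_i / (sigma_hat * sqrt(1 - h_i))`, for a binomial trait the Pearson
#' residual divided by `sqrt(1 - h_i)`.  `"pearson"` omits the leverage
#' adjustment; `"none"` returns raw residuals unscaled.
#'
#' @param fit a [fit_null_model()] result.
#' @param variant studentization variant: `"internal"`, `"pearson"` or
#'   `"none"`.
#' @return Named numeric vector of finite scores, one per sample, with
#'   attributes `family` and `variant`.
#' @export
studentized_scores <- function(fit,
                               variant = c("internal", "pearson", "none")) {
  stopifnot(inherits(fit, "null_model_fit"))
  variant <- match.arg(variant)
  m <- fit$model
  if (fit$family == "binomial") {
    mu <- fit$fitted
    eps <- 1e-10
    if (any(mu < eps | mu > 1 - eps))
      stop("fitted probabilities of 0 or 1 (separation); ",
           "scores are undefined")
    s <- switch(variant,
      internal = stats::rstandard(m, type = "pearson"),
      pearson  = stats::residuals(m, type = "pearson"),
      none     = stats::residuals(m, type = "response"))
  } else {
    if (fit$dispersion <= 0 || !is.finite(fit$dispersion) ||
        fit$dispersion < 1e-12 * max(stats::var(m$model$.y), 1e-300))
      stop("zero residual variance in the null fit; scores are undefined")
    s <- switch(variant,
      internal = stats::rstandard(m),
      pearson  = stats::residuals(m) / sqrt(fit$dispersion),
      none     = stats::residuals(m))
  }
  s <- as.numeric(s)
  if (any(!is.finite(s)))
    stop("non-finite score for sample(s): ",
         paste(utils::head(fit$samples[!is.finite(s)], 5), collapse = ", "))
  names(s) <- fit$samples
  attr(s, "family") <- fit$family
  attr(s, "variant") <- variant
  s
}
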