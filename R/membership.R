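#' Define a high-risk membership function
#'
#' The fuzzy high-risk membership of a cell with mean score `s` is the
#' piecewise sigmoid
#' \deqn{\mu_H(s) = 0 \; (s < t_l); \quad
#'       1/\{1 + ((s - t_h)/(s - t_l))^2\} \; (t_l \le s < t_h); \quad
#'       1 \; (s \ge t_h)}
#' with `t_l <= t_h`, and `mu_L = 1 - mu_H`.  The `"indicator"` kind is the
#' crisp degenerate form `mu_H(s) = 1[s >= T]`, which recovers the classical
#' high/low-risk split of (G)MDR.  A sigmoid with `t_l == t_h` degenerates to
#' the indicator at `T = t_l`.
#'
#' @param kind `"sigmoid"` or `"indicator"`.
#' @param t_l,t_h lower/upper thresholds (score units) for the sigmoid kind.
#' @param threshold crisp threshold `T` for the indicator kind (default 0,
#'   i.e. a cell is high-risk iff its mean score is nonnegative).
#' @return An object of class `"membership_function"`.
#' @examples
#' f <- membership_function("sigmoid", t_l = -1, t_h = 1)
#' mu_high(f, 0)       # 0.5 at the midpoint
#' mu_high(f, c(-2, 1))  # 0 below t_l, 1 at and above t_h
#' @export
membership_function <- function(kind = c("sigmoid", "indicator"),
                                t_l = NULL, t_h = NULL, threshold = 0) {
  kind <- match.arg(kind)
  if (kind == "sigmoid") {
    if (is.null(t_l) || is.null(t_h))
      stop("sigmoid membership requires t_l and t_h")
    stopifnot(is.finite(t_l), is.finite(t_h))
    if (t_l > t_h) stop("t_l must not exceed t_h (got ", t_l, " > ", t_h, ")")
  } else {
    stopifnot(is.finite(threshold))
  }
  structure(list(kind = kind, t_l = t_l, t_h = t_h, threshold = threshold),
            class = "membership_function")
}

#' @export
print.membership_function <- function(x, ...) {
  if (x$kind == "sigmoid")
    cat("membership_function: sigmoid, t_l = ", x$t_l,
        ", t_h = ", x$t_h, "\n", sep = "")
  else
    cat("membership_function: indicator, T = ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' High-risk membership degree
#'
#' @param f a [membership_function()].
#' @param s numeric vector of (mean cell) scores; must be finite.
#' @return Degrees in `[0, 1]`, monotone non-decreasing in `s`.  At `s = t_l`
#'   the value is 0 (the continuous limit of the interior branch); at
#'   `s = t_h` it is 1.
#' @export
mu_high <- function(f, s) {
  stopifnot(inherits(f, "membership_function"))
  if (any(!is.finite(s))) stop("non-finite score passed to mu_high")
  if (f$kind == "indicator") return(as.numeric(s >= f$threshold))
  if (f$t_l == f$t_h) return(as.numeric(s >= f$t_l))
  out <- numeric(length(s))
  out[s >= f$t_h] <- 1
  mid <- s > f$t_l & s < f$t_h
  if (any(mid)) {
    r <- (s[mid] - f$t_h) / (s[mid] - f$t_l)
    out[mid] <- 1 / (1 + r * r)
  }
  out
}

#' Low-risk membership degree, exactly `1 - mu_high`
#'
#' @inheritParams mu_high
#' @return Degrees in `[0, 1]` with `mu_high + mu_low == 1` exactly.
#' @export
mu_low <- function(f, s) 1 - mu_high(f, s)

#' Default sigmoid thresholds from cell mean scores
#'
#' The thresholds must be fixed a priori; absent a user choice, a symmetric
#' band around zero is used: `t_h = spread * sd(cell_means)` and
#' `t_l = -t_h`, with the population (divide-by-n) standard deviation over
#' nonempty-cell mean scores.  Score residuals are centred near zero, so a
#' symmetric band is the least arbitrary default.
#'
#' @param cell_means numeric vector of nonempty-cell mean scores (at least
#'   two distinct finite values).
#' @param spread positive scale factor (default 1).  `spread = 0` gives the
#'   degenerate pair `(0, 0)`, i.e. indicator behaviour at `T = 0`.
#' @return Named numeric vector `c(t_l = ..., t_h = ...)`.
#' @export
default_thresholds <- function(cell_means, spread = 1) {
  cell_means <- cell_means[is.finite(cell_means)]
  if (length(cell_means) < 2L)
    stop("need at least two finite cell means")
  stopifnot(is.finite(spread), spread >= 0)
  if (length(unique(cell_means)) < 2L)
    stop("all cell means are identical; sigmoid thresholds are undefined ",
         "- use indicator membership instead")
  t_h <- spread * pop_sd(cell_means)
  c(t_l = -t_h, t_h = t_h)
}
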