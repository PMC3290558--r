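#' Curve estimation: linear, exponential, logarithmic
#'
#' Classic "curve estimation" fits of a response against a single
#' predictor: `y = a*x + b` (linear), `y = a*exp(b*x)` (exponential,
#' fitted by ordinary least squares on `log y`), or `y = a*ln(x) + b`
#' (logarithmic, least squares on `ln x`). The coefficient of
#' determination, F statistic with (1, n-2) degrees of freedom and
#' two-sided p-value are reported on the fitted (transformed) scale,
#' with `F = R^2 * (n - 2) / (1 - R^2)`. On exactly collinear data the
#' F statistic is capped at a large finite sentinel.
#'
#' @param x predictor values (at least 3; positive for the logarithmic
#'   family).
#' @param y responses (positive for the exponential family).
#' @param family `"linear"`, `"exponential"` or `"logarithmic"`.
#' @return An object of class `curve_fit`: list with `family`, `a`,
#'   `b`, `r_squared`, `f_stat`, `df` (= `c(1, n - 2)`), `p_value`,
#'   `n`, and the underlying `lm` fit.
#' @seealso [best_curve()]
#' @export
#' @examples
#' curve_estimation(1:5, 2 * (1:5) + 1, "linear")
#' curve_estimation(0:5, 3 * exp(0.5 * (0:5)), "exponential")
curve_estimation <- function(x, y,
                             family = c("linear", "exponential",
                                        "logarithmic")) {
  family <- match.arg(family)
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (family == "exponential" && any(y <= 0)) {
    stop("exponential family requires positive responses", call. = FALSE)
  }
  if (family == "logarithmic" && any(x <= 0)) {
    stop("logarithmic family requires positive predictors", call. = FALSE)
  }
  xt <- if (family == "logarithmic") log(x) else x
  yt <- if (family == "exponential") log(y) else y
  if (stats::var(xt) == 0) {
    stop("degenerate predictor: zero variance", call. = FALSE)
  }
  fit <- stats::lm(yt ~ xt)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((yt - mean(yt))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  r2 <- min(max(r2, 0), 1)
  f <- if (r2 >= 1 - 1e-12) 1e12 else r2 * (n - 2) / (1 - r2)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  ab <- switch(family,
               linear = c(a = unname(cf[2]), b = unname(cf[1])),
               exponential = c(a = exp(unname(cf[1])), b = unname(cf[2])),
               logarithmic = c(a = unname(cf[2]), b = unname(cf[1])))
  structure(list(family = family, a = ab[["a"]], b = ab[["b"]],
                 r_squared = r2, f_stat = f, df = c(1, n - 2),
                 p_value = p, n = n, lm_fit = fit),
            class = "curve_fit")
}

#' Best-fitting curve family
#'
#' Fits every applicable family (exponential is skipped for
#' nonpositive responses, logarithmic for nonpositive predictors) and
#' returns the fit maximising R^2.
#'
#' @inheritParams curve_estimation
#' @return A `curve_fit` (the winner); the full list of candidate fits
#'   is attached as attribute `"candidates"`.
#' @export
best_curve <- function(x, y) {
  fams <- c("linear",
            if (all(y > 0, na.rm = TRUE)) "exponential",
            if (all(x > 0, na.rm = TRUE)) "logarithmic")
  fits <- lapply(fams, function(f) curve_estimation(x, y, f))
  names(fits) <- fams
  best <- fits[[which.max(vapply(fits, `[[`, 0, "r_squared"))]]
  attr(best, "candidates") <- fits
  best
}

#' @export
print.curve_fit <- function(x, ...) {
  eq <- switch(x$family,
               linear = sprintf("y = %.4g x + %.4g", x$a, x$b),
               exponential = sprintf("y = %.4g e^(%.4g x)", x$a, x$b),
               logarithmic = sprintf("y = %.4g ln(x) + %.4g", x$a, x$b))
  cat(sprintf("%s fit: %s\n", x$family, eq))
  cat(sprintf("  R^2 = %.4f, F(%d,%d) = %.4g, p = %.4g (n = %d)\n",
              x$r_squared, x$df[1], x$df[2], x$f_stat, x$p_value, x$n))
  invisible(x)
}

#' @export
coef.curve_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.curve_fit <- function(object, newdata, ...) {
  x <- if (missing(newdata)) stats::model.frame(object$lm_fit)$xt
       else newdata
  switch(object$family,
         linear = object$a * x + object$b,
         exponential = object$a * exp(object$b * x),
         logarithmic = object$a * log(x) + object$b)
}

#' Spearman rank correlation with tie correction
#'
#' Pearson correlation of average ranks (the tie-corrected rank
#' correlation) with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param a,b numeric vectors of equal length (at least 3).
#' @return List with `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_rho(1:4, c(4, 3, 2, 1))
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("rank correlation is undefined for a constant input", call. = FALSE)
  }
  rho <- stats::cor(rank(a), rank(b))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Mann-Whitney U test (normal approximation)
#'
#' Two-sample rank test returning the U statistic of the first sample
#' together with the tie-corrected normal approximation for z and the
#' two-sided p-value, the appropriate regime for the 10,000-replicate
#' batches this package compares. Sign convention: z is negative when
#' the first sample's ranks are lower than the second's.
#'
#' @param a,b numeric samples (non-empty).
#' @return List with `U` (first sample), `z`, `p`, `n` (= `c(n_a,
#'   n_b)`). The identity `U_a + U_b = n_a * n_b` holds, with
#'   `U_b = n_a * n_b - U_a`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, z < 0
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both samples must be non-empty", call. = FALSE)
  n <- na + nb
  rk <- rank(c(a, b))
  ra <- sum(rk[seq_len(na)])
  U <- ra - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    # all observations tied: no evidence of difference
    return(list(U = U, z = 0, p = 1, n = c(na, nb)))
  }
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)), n = c(na, nb))
}
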