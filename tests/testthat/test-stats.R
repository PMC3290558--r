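# independent normal-equations oracle for least squares on (x, y)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

test_that("curve estimation recovers exact relationships in all families", {
  x <- 1:5
  lin <- curve_estimation(x, 2 * x + 1, "linear")
  expect_equal(unname(coef(lin)), c(2, 1), tolerance = 1e-12)
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$df, c(1, 3))

  xe <- 0:5
  ex <- curve_estimation(xe, 3 * exp(0.5 * xe), "exponential")
  expect_equal(unname(coef(ex)), c(3, 0.5), tolerance = 1e-10)
  expect_equal(ex$r_squared, 1)

  xl <- c(1, 2, 4, 8, 16)
  lg <- curve_estimation(xl, 2.5 * log(xl) - 1, "logarithmic")
  expect_equal(unname(coef(lg)), c(2.5, -1), tolerance = 1e-10)
  expect_equal(lg$r_squared, 1)
})

test_that("noisy linear fits match the normal-equations oracle exactly", {
  set.seed(101)
  x <- seq(0, 0.85, length.out = 6)
  y <- 19.293 * x + 0.6889 + rnorm(6, sd = 0.5)
  fit <- curve_estimation(x, y, "linear")
  ora <- unname(ols_oracle(x, y))
  expect_equal(fit$b, ora[1], tolerance = 1e-12)
  expect_equal(fit$a, ora[2], tolerance = 1e-12)
  # F statistic identity F = R^2 (n-2) / (1 - R^2)
  expect_equal(fit$f_stat,
               fit$r_squared * 4 / (1 - fit$r_squared), tolerance = 1e-12)
  expect_equal(fit$p_value,
               stats::pf(fit$f_stat, 1, 4, lower.tail = FALSE))
})

test_that("curve estimation is invariant to reordering and caps collinear F", {
  set.seed(7)
  x <- runif(8); y <- 3 * x + rnorm(8)
  perm <- sample(8)
  a <- curve_estimation(x, y, "linear")
  b <- curve_estimation(x[perm], y[perm], "linear")
  expect_equal(coef(a), coef(b), tolerance = 1e-12)
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-12)
  col <- curve_estimation(1:4, 2 * (1:4), "linear")
  expect_true(is.finite(col$f_stat))
  expect_equal(col$r_squared, 1)
})

test_that("curve estimation rejects degenerate inputs", {
  expect_error(curve_estimation(1:2, 1:2, "linear"), "at least 3")
  expect_error(curve_estimation(1:4, c(-1, 1, 2, 3), "exponential"),
               "positive responses")
  expect_error(curve_estimation(c(0, 1, 2), 1:3, "logarithmic"),
               "positive predictors")
  expect_error(curve_estimation(rep(2, 4), 1:4, "linear"), "zero variance")
})

test_that("best_curve picks the maximum-R^2 family", {
  x <- seq(0.1, 2, length.out = 8)
  y <- 2 * exp(1.3 * x)
  best <- best_curve(x, y)
  expect_identical(best$family, "exponential")
  cands <- attr(best, "candidates")
  expect_true(all(best$r_squared >=
                    vapply(cands, `[[`, 0, "r_squared") - 1e-12))
})

test_that("predict inverts the fitted transformations", {
  x <- seq(0.5, 3, length.out = 6)
  fit <- curve_estimation(x, 4 * exp(0.7 * x), "exponential")
  expect_equal(predict(fit, x), 4 * exp(0.7 * x), tolerance = 1e-8)
})

test_that("spearman_rho matches hand-enumerated average ranks under ties", {
  expect_equal(spearman_rho(1:4, 1:4)$rho, 1)
  expect_equal(spearman_rho(1:4, 4:1)$rho, -1)
  # hand oracle: ranks of (1,2,2,4) are (1, 2.5, 2.5, 4); Pearson
  # correlation of those ranks with ranks of (2,1,3,4) = (2,1,3,4)
  a <- c(1, 2, 2, 4); b <- c(2, 1, 3, 4)
  hand <- stats::cor(c(1, 2.5, 2.5, 4), c(2, 1, 3, 4))
  got <- spearman_rho(a, b)
  expect_equal(got$rho, hand, tolerance = 1e-12)
  ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 4), 1:4), "constant")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  base <- spearman_rho(a, b)$rho
  expect_equal(spearman_rho(exp(a), b)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_rho(a, b^3)$rho, base, tolerance = 1e-12)
})

test_that("mann_whitney matches enumeration and the established implementation", {
  # all 9 cross pairs of (1,2,3) x (4,5,6) favour the second sample
  got <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_lt(got$z, 0)
  # U_a + U_b = n_a * n_b
  set.seed(11)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U, 40 * 35)
  # cross-check U against wilcox.test and p against its
  # tie-corrected normal approximation
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  got <- mann_whitney(a, b)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("identical samples give z near zero and p near one", {
  x <- c(1, 2, 3, 4, 5)
  got <- mann_whitney(x, x)
  expect_equal(got$z, 0, tolerance = 1e-12)
  expect_equal(got$p, 1, tolerance = 1e-12)
})
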