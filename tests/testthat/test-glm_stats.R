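test_that("closed-form logistic fits are exact: intercept-only and single binary predictor", {
  # 25% positives: intercept = logit(0.25)
  fit <- fit_logistic(c(1, 1, 0, 0, 0, 0, 0, 0), data.frame())
  expect_equal(unname(fit$coefficients[1]), qlogis(0.25), tolerance = 1e-6)

  # 2x2 counts [[20,10],[10,20]]: slope = log odds ratio = log 4
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  x <- c(rep(1, 30), rep(0, 30))
  fit2 <- fit_logistic(y, data.frame(x = x))
  expect_equal(unname(fit2$coefficients[2]), log(4), tolerance = 1e-6)
})

test_that("MLE agrees with a brute-force grid-search likelihood oracle on tiny data", {
  # fixed 8-record toy, one predictor
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  x <- c(2.1, -0.3, 1.2, -0.8, 1.5, 0.2, 0.9, -0.7)
  fit <- fit_logistic(y, data.frame(x = x))
  oracle <- grid_logistic_oracle(y, cbind(x = x))
  expect_lt(max(abs(unname(fit$coefficients) - oracle)), 2e-3)

  # random 12-record sets with two predictors
  set.seed(99)
  for (r in 1:3) {
    X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
    yy <- rbinom(12, 1, plogis(0.3 * X[, 1]))
    if (sum(yy) < 2 || sum(yy) > 10) next
    f <- tryCatch(fit_logistic(yy, as.data.frame(X)), error = function(e) NULL)
    if (is.null(f)) next
    if (any(abs(f$coefficients) > 5)) next  # outside the oracle lattice
    o <- grid_logistic_oracle(yy, X)
    expect_lt(max(abs(unname(f$coefficients) - o)), 2e-3)
  }
})

test_that("the AIC identity and complete-case bookkeeping hold for every fit", {
  set.seed(11)
  for (r in 1:5) {
    n <- 60
    X <- data.frame(a = rnorm(n), b = runif(n))
    y <- rbinom(n, 1, plogis(-0.5 + X$a))
    X$a[sample(n, 5)] <- NA
    fit <- fit_logistic(y, X)
    expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * length(fit$coefficients))
    expect_equal(fit$n + fit$n_dropped, n)
    expect_true(all(fit$fitted_probabilities > 0 & fit$fitted_probabilities < 1))
    expect_equal(fit$z_values, fit$coefficients / fit$standard_errors)
  }
})

test_that("z-scaling a predictor rescales its coefficient by the SD and leaves fitted probabilities unchanged", {
  set.seed(12)
  n <- 200
  x <- rlnorm(n, 2, 0.6)
  y <- rbinom(n, 1, plogis(-1 + 0.08 * x))
  raw <- fit_logistic(y, data.frame(x = x))
  z <- (x - mean(x)) / sd(x)
  scaled <- fit_logistic(y, data.frame(x = z))
  expect_equal(unname(scaled$coefficients[2]),
               unname(raw$coefficients[2]) * sd(x), tolerance = 1e-6)
  expect_equal(scaled$fitted_probabilities, raw$fitted_probabilities,
               tolerance = 1e-8)
})

test_that("Wald intervals use the normal quantile half-width and nest across levels", {
  y <- c(rep(1, 30), rep(0, 15), rep(1, 15), rep(0, 30))
  x <- rep(c(1, 0), each = 45)
  fit <- fit_logistic(y, data.frame(x = x))
  ci95 <- wald_ci(fit, 0.95)
  expect_equal(ci95$half_width, qnorm(0.975) * fit$standard_errors,
               ignore_attr = TRUE)
  # se 0.29 reports as +/- 0.57 at two decimals (the published convention)
  expect_equal(round(qnorm(0.975) * 0.29, 2), 0.57)
  ci999 <- wald_ci(fit, 0.999)
  expect_true(all(ci999$low <= ci95$low & ci999$high >= ci95$high))
})

test_that("VIF is 1 for orthogonal predictors, 4/3 at correlation 0.5, infinite for aliased columns", {
  e1 <- c(1, -1, 0, 0, 1, -1, 0, 0)
  e2 <- c(0, 0, 1, -1, 0, 0, 1, -1)
  v <- vif_report(data.frame(a = e1, b = e2))
  expect_equal(unname(v), c(1, 1))
  x2 <- 0.5 * e1 + sqrt(0.75) * e2  # exact sample correlation 0.5
  v2 <- vif_report(data.frame(a = e1, b = x2))
  expect_equal(unname(v2), c(4 / 3, 4 / 3), tolerance = 1e-12)

  v3 <- vif_report(data.frame(a = e1, b = e2, c = e1))
  expect_true(is.infinite(v3[["a"]]) && is.infinite(v3[["c"]]))
  expect_true(any(grepl("a~c|c~a", attr(v3, "aliased"))))

  # independent cross-check against car's implementation
  set.seed(3)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  X$c <- 0.6 * X$a + rnorm(50, sd = 0.5)
  y <- rnorm(50)
  ref <- car::vif(lm(y ~ a + b + c, data = X))
  expect_equal(unname(vif_report(X)), unname(ref), tolerance = 1e-10)
})

test_that("Pearson chi-squared matches the textbook formula without continuity correction", {
  a <- rep(c("x", "y"), each = 30)
  b <- rep(c("u", "v", "u", "v"), c(15, 15, 15, 15))
  ct <- chisq_association(a, b)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 1)

  a2 <- rep(c("x", "y"), each = 40)
  b2 <- rep(c("u", "v", "u", "v"), c(30, 10, 10, 30))
  ct2 <- chisq_association(a2, b2)
  expect_equal(ct2$statistic, 20)
  expect_equal(ct2$df, 1)

  set.seed(21)
  for (r in 1:10) {
    aa <- sample(c("x", "y"), 60, replace = TRUE)
    bb <- sample(c("u", "v"), 60, replace = TRUE)
    if (any(dim(table(aa, bb)) < 2)) next
    expect_equal(chisq_association(aa, bb)$statistic,
                 chisq_textbook(table(aa, bb)), tolerance = 1e-12)
  }

  expect_error(chisq_association(rep("x", 10), rep(c("u", "v"), 5)),
               "2 observed levels")
})

test_that("complete separation raises a typed error instead of divergent estimates", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(seq(-2, -0.5, length.out = 10), seq(0.5, 2, length.out = 10))
  expect_error(fit_logistic(y, data.frame(x = x)),
               class = "mossrisk_separation")
})

test_that("binned residuals average near zero and mostly sit inside the 2 SE band for a well-specified model", {
  expect_error(binned_residuals(fit_logistic(c(1, 1, 0, 0), data.frame()), 1),
               "at least 2")
  set.seed(31)
  inside <- 0L; total <- 0L
  for (r in 1:30) {
    x <- rnorm(300)
    y <- rbinom(300, 1, plogis(-0.5 + x))
    fit <- fit_logistic(y, data.frame(x = x))
    br <- binned_residuals(fit, 10)
    # residuals of an intercept-bearing logistic fit sum to zero
    expect_equal(sum(br$mean_residual * br$n), 0, tolerance = 1e-6)
    inside <- inside + sum(abs(br$mean_residual) <= br$se2)
    total <- total + nrow(br)
  }
  expect_gte(inside / total, 0.9)
})
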