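#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic fit of a 0/1 response on a predictor table,
#' with Wald standard errors. Records with any missing predictor or
#' response are dropped (complete cases, count reported), which is why two
#' models fitted from the same trait matrix can use different n. Complete
#' separation is surfaced as a typed error (`mossrisk_separation`) rather
#' than divergent estimates, since small trait tables make separation
#' likely.
#'
#' @param response Numeric 0/1 vector (or logical).
#' @param design Data frame of predictors (numeric, or character/factor
#'   which are expanded by treatment contrasts). May have zero columns for
#'   an intercept-only fit.
#' @return A `glm_fit`: list with `predictor_names`, `coefficients`,
#'   `standard_errors`, `z_values`, `p_values`, `log_likelihood`, `aic`
#'   (identically `-2 logLik + 2 k`), `n`, `n_dropped`, `df_residual`,
#'   `fitted_probabilities`, `converged`, `response` and the underlying
#'   `stats::glm` object in `$glm`.
#' @export
#' @examples
#' fit <- fit_logistic(c(1, 1, 0, 0, 0, 0, 0, 0), data.frame())
#' fit$coefficients  # logit(0.25)
fit_logistic <- function(response, design = data.frame()) {
  response <- as.numeric(response)
  if (!all(response %in% c(0, 1) | is.na(response))) {
    stop("response must be 0/1", call. = FALSE)
  }
  if (ncol(design) > 0) stopifnot(nrow(design) == length(response))
  df <- if (ncol(design) > 0) {
    cbind(.y = response, as.data.frame(design))
  } else {
    data.frame(.y = response)
  }
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (sum(df$.y == 1) < 2 || sum(df$.y == 0) < 2) {
    stop("need at least 2 records in each class after dropping incomplete ",
         "cases", call. = FALSE)
  }
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) {
    stop("logistic fit did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  }
  # complete separation: some fitted values pinned to 0/1 with exploding
  # coefficients
  mu <- stats::fitted(fit)
  eps <- 1e-8
  pinned <- any(mu < eps | mu > 1 - eps)
  if (pinned && any(abs(stats::coef(fit)[-1]) > 12, na.rm = TRUE)) {
    cond <- structure(
      class = c("mossrisk_separation", "error", "condition"),
      list(message = "complete or quasi-complete separation detected",
           call = NULL))
    stop(cond)
  }
  est <- summary(fit)$coefficients
  ll <- as.numeric(stats::logLik(fit))
  structure(list(
    predictor_names = rownames(est),
    coefficients = est[, "Estimate"],
    standard_errors = est[, "Std. Error"],
    z_values = est[, "z value"],
    p_values = est[, "Pr(>|z|)"],
    log_likelihood = ll,
    aic = -2 * ll + 2 * nrow(est),
    n = nrow(df),
    n_dropped = n_dropped,
    df_residual = fit$df.residual,
    fitted_probabilities = unname(mu),
    converged = fit$converged,
    response = df$.y,
    glm = fit
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("Binary logistic fit: n =", x$n, " AIC =", round(x$aic, 2), "\n")
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    se = round(x$standard_errors, 4),
                    z = round(x$z_values, 2),
                    p = signif(x$p_values, 3))
  print(tab)
  invisible(x)
}

#' Wald confidence intervals for a logistic fit
#'
#' Symmetric intervals `estimate +/- z_(level) * se`, reported with the
#' half-width so results can be printed in the `estimate +/- CI`
#' convention.
#'
#' @param fit A [fit_logistic()] result.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Data frame with `term`, `estimate`, `half_width`, `low`, `high`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(level > 0, level < 1)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  hw <- zq * fit$standard_errors
  data.frame(term = fit$predictor_names,
             estimate = unname(fit$coefficients),
             half_width = unname(hw),
             low = unname(fit$coefficients - hw),
             high = unname(fit$coefficients + hw),
             row.names = NULL)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) where R^2_j comes from regressing predictor j on
#' all the others. VIF is exactly 1 for orthogonal predictors. Exact
#' collinearity is reported as an infinite VIF together with the name of a
#' culprit predictor it aliases.
#'
#' @param design Data frame or matrix of at least two numeric predictors,
#'   each with positive variance.
#' @return Named numeric vector of VIFs (>= 1). An attribute `aliased`
#'   names culprit pairs when infinite VIFs occur.
#' @export
vif_report <- function(design) {
  X <- as.matrix(as.data.frame(design))
  storage.mode(X) <- "double"
  if (ncol(X) < 2) stop("need at least 2 predictors", call. = FALSE)
  v <- apply(X, 2, stats::var)
  if (any(v <= 0)) {
    stop("predictor(s) with zero variance: ",
         paste(colnames(X)[v <= 0], collapse = ", "), call. = FALSE)
  }
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  aliased <- character()
  for (j in seq_len(ncol(X))) {
    f <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(f$residuals^2) / (stats::var(X[, j]) * (nrow(X) - 1))
    if (r2 > 1 - 1e-12) {
      out[j] <- Inf
      cors <- abs(stats::cor(X[, j], X[, -j, drop = FALSE]))
      aliased <- c(aliased, paste0(colnames(X)[j], "~",
                                   colnames(X)[-j][which.max(cors)]))
    } else {
      out[j] <- 1 / (1 - r2)
    }
  }
  if (length(aliased)) attr(out, "aliased") <- aliased
  out
}

#' Pearson chi-squared test of association between two binary traits
#'
#' Pearson's chi-squared without continuity correction on the 2x2 table of
#' paired non-missing observations (df = 1).
#'
#' @param a,b Vectors coercible to factors; pairs with any missing value
#'   are dropped.
#' @return List of class `contingency_test` with `statistic`, `df`,
#'   `p_value` and the observed `table`.
#' @export
chisq_association <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  tab <- table(a[keep], b[keep])
  if (any(dim(tab) < 2)) stop("each trait needs at least 2 observed levels",
                              call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected cell count of zero", call. = FALSE)
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, table = tab),
            class = "contingency_test")
}

#' @export
print.contingency_test <- function(x, ...) {
  cat(sprintf("Pearson chi-squared(%d) = %.2f, p = %.4g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Binned residuals for a logistic fit
#'
#' Records are sorted by fitted probability and split into near-equal bins;
#' per bin the mean fitted probability, the mean raw residual
#' (observed - fitted) and a +/- 2 SE band are returned. For a
#' well-specified model about 95% of bin means fall inside the band.
#'
#' @param fit A [fit_logistic()] result.
#' @param n_bins Number of bins (>= 2 and <= n).
#' @return Data frame with `bin`, `n`, `mean_fitted`, `mean_residual`,
#'   `se2` (the half-width of the +/- 2 SE band).
#' @export
binned_residuals <- function(fit, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  if (n_bins > fit$n) stop("n_bins exceeds number of records", call. = FALSE)
  ord <- order(fit$fitted_probabilities)
  p <- fit$fitted_probabilities[ord]
  r <- fit$response[ord] - p
  bins <- cut(seq_along(p), breaks = n_bins, labels = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    i <- bins == b
    data.frame(bin = b, n = sum(i), mean_fitted = mean(p[i]),
               mean_residual = mean(r[i]),
               se2 = 2 * stats::sd(r[i]) / sqrt(sum(i)))
  }))
  out
}
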