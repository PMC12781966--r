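#' Fit an ordinary least-squares model on cohort variables
#'
#' Classical multiple linear regression on the complete cases of the listed
#' variables: coefficients minimise the residual sum of squares, standard
#' errors come from the unbiased error-variance estimate, and 95\% limits use
#' t quantiles on `n - k` degrees of freedom. Binary and categorical
#' variables enter as treatment-coded indicators against their declared
#' reference level. Variance inflation factors are attached for every
#' non-intercept term when the model has at least two of them.
#'
#' @param data A `cohort_tbl`, or a plain data frame with `meta` supplied.
#' @param vars Character vector of predictor variable names.
#' @param outcome Outcome variable name; defaults to the metadata's outcome.
#' @param meta Metadata tibble (only needed when `data` is not a `cohort_tbl`).
#' @return An `ols_fit` object; see [tidy.ols_fit()] and [glance.ols_fit()].
#' @export
fit_ols <- function(data, vars, outcome = NULL, meta = NULL) {
  meta <- meta %||% var_meta_of(data)
  outcome <- outcome %||% meta$name[meta$role == "outcome"]
  d <- build_design(data, meta, vars, outcome)
  fit_ols_design(d$X, d$y, term_var = d$term_var, outcome = outcome,
                 blocks = d$blocks)
}

# Core fit on a prebuilt design matrix (intercept in column 1).
fit_ols_design <- function(X, y, term_var = NULL, outcome = "y", blocks = NULL) {
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) abort(sprintf("need n > k (n = %d, k = %d parameters).", n, k))
  qr_x <- qr(X)
  if (qr_x$rank < k) {
    culprit <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):k]]
    abort(paste0("design matrix is rank deficient; collinear term(s): ",
                 paste(culprit, collapse = ", ")))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  df <- n - k
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  crit <- qt(0.975, df)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / df else 0

  coefs <- tibble::tibble(
    term = colnames(X),
    variable = term_var %||% colnames(X),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(tval),
    p.value = unname(pval),
    conf.low = unname(beta - crit * se),
    conf.high = unname(beta + crit * se)
  )
  vifs <- if (k >= 3L) vif_design(X) else
    setNames(rep(NA_real_, k - 1L), colnames(X)[-1L])
  coefs$vif <- c(NA_real_, unname(vifs[coefs$term[-1L]]))

  structure(
    list(coefficients = coefs, residuals = resid, fitted = fitted,
         rss = rss, sigma = sqrt(sigma2), n = n, k = k,
         r.squared = r2, adj.r.squared = adj_r2,
         aic = if (rss > 0) aic_from_rss(rss, n, k) else NA_real_,
         outcome = outcome, blocks = blocks),
    class = "ols_fit"
  )
}

#' Gaussian AIC of a fitted model
#'
#' Uses the full Gaussian log-likelihood convention,
#' `AIC = n log(RSS/n) + n log(2*pi) + n + 2k`, with `k` the number of mean
#' parameters including the intercept. Additive constants cancel when
#' comparing models on the same data, so elimination decisions are unaffected
#' by the convention; keeping them makes the value equal
#' `-2 * maximised log-likelihood + 2k`.
#'
#' @param fit An `ols_fit`.
#' @return The AIC (errors on a perfect fit, where the log-likelihood is
#'   unbounded).
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  aic_from_rss(fit$rss, fit$n, fit$k)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing design column
#' `j` on all remaining columns. Perfectly collinear columns report `Inf`
#' rather than erroring, so the diagnostic itself can flag them.
#'
#' @param data A `cohort_tbl` or data frame with `meta`.
#' @param vars At least two predictor variable names.
#' @param meta Metadata tibble when `data` is not a `cohort_tbl`.
#' @return Named numeric vector of VIFs, one per design column.
#' @export
vif <- function(data, vars, meta = NULL) {
  meta <- meta %||% var_meta_of(data)
  outcome <- meta$name[meta$role == "outcome"]
  if (length(vars) < 2L) abort("VIF needs at least two terms.")
  d <- build_design(data, meta, vars, outcome)
  vif_design(d$X)
}

vif_design <- function(X) {
  terms <- colnames(X)[-1L]
  out <- setNames(numeric(length(terms)), terms)
  for (j in seq_along(terms)) {
    col_id <- j + 1L
    xj <- X[, col_id]
    others <- X[, -col_id, drop = FALSE]
    rss <- rss_of(others, xj)
    tss <- sum((xj - mean(xj))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 0
    out[[j]] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' @describeIn fit_ols Coefficient table: term, estimate, standard error,
#'   t statistic, p value, 95\% limits and VIF.
#' @param x,object An `ols_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ols_fit <- function(x, ...) x$coefficients

#' @describeIn fit_ols One-row fit summary: `r.squared`, `adj.r.squared`,
#'   `sigma`, `AIC`, `rss`, `nobs`, `k`.
#' @exportS3Method generics::glance
glance.ols_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
                 sigma = x$sigma, AIC = x$aic, rss = x$rss,
                 nobs = x$n, k = x$k)
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> %s ~ %d term(s), n = %d, R2 = %.3f (adj %.3f)\n",
              x$outcome, x$k - 1L, x$n, x$r.squared, x$adj.r.squared))
  print(x$coefficients, n = Inf)
  invisible(x)
}
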