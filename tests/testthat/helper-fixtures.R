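# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths: normal equations via solve(), log-likelihood via
# dnorm(), elimination via stats::step() on lm objects.

# Small mixed-type cohort used by the I/O and summary tests.
make_mixed_cohort <- function() {
  meta <- dplyr::bind_rows(
    var_meta("hba1c", "outcome", "continuous"),
    var_meta("age", "forced", "continuous"),
    var_meta("sex", "forced", "binary", levels = c("Male", "Female")),
    var_meta("genotype", "forced", "dose", recode = c(GG = 0, AG = 1, AA = 2)),
    var_meta("region", "candidate", "categorical",
             levels = c("AUA", "NWU", "ROU"), reference_level = "AUA"),
    var_meta("smoker", "candidate", "binary", levels = c("No", "Yes"))
  )
  data <- tibble::tibble(
    hba1c = c(5.4, 6.1, 7.2),
    age = c(41, 52, 63),
    sex = c("Male", "Female", "Female"),
    genotype = c("GG", "AG", "AA"),
    region = c("AUA", "NWU", "ROU"),
    smoker = c("No", "No", "Yes")
  )
  list(data = data, meta = meta, cohort = cohort(data, meta))
}

# Continuous-only cohort for regression tests: y on `p` candidate predictors
# (optionally some forced), with declared true coefficients.
make_reg_cohort <- function(n, p, beta = rep(0, p), sigma = 1,
                            forced = character(), seed = 1) {
  vars <- paste0("x", seq_len(p))
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, vars))
    y <- drop(X %*% beta) + rnorm(n, 0, sigma)
  })
  data <- tibble::as_tibble(as.data.frame(X))
  data$y <- y
  meta <- dplyr::bind_rows(
    var_meta("y", "outcome", "continuous"),
    purrr::map_dfr(vars, function(v) {
      var_meta(v, if (v %in% forced) "forced" else "candidate", "continuous")
    })
  )
  # keep y positive so the outcome validity check passes
  data$y <- data$y - min(data$y) + 1
  cohort(data, meta)
}

# Independent OLS oracle: normal equations.
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Independent AIC oracle: -2 * maximised Gaussian log-likelihood + 2k with
# the MLE variance RSS/n.
oracle_aic <- function(X, y) {
  beta <- oracle_ols(X, y)
  res <- y - drop(X %*% beta)
  n <- length(y)
  s2 <- sum(res^2) / n
  ll <- sum(dnorm(y, drop(X %*% beta), sqrt(s2), log = TRUE))
  -2 * ll + 2 * ncol(X)
}

# Likelihood-ratio partial-test p-value for dropping `drop_var` from an lm
# formula fit; the chi-square(1) upper-tail convention.
oracle_partial_p <- function(data, outcome, vars, drop_var) {
  kept <- setdiff(vars, drop_var)
  f_full <- stats::as.formula(paste(outcome, "~", paste(vars, collapse = "+")))
  f_red <- stats::as.formula(paste(outcome, "~",
                                   if (length(kept)) paste(kept, collapse = "+")
                                   else "1"))
  lr <- 2 * (as.numeric(stats::logLik(lm(f_full, data))) -
               as.numeric(stats::logLik(lm(f_red, data))))
  pchisq(lr, df = 1, lower.tail = FALSE)
}
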