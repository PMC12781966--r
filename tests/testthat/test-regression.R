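test_that("exact fits and degenerate outcomes behave classically", {
  meta <- dplyr::bind_rows(var_meta("y", "outcome", "continuous"),
                           var_meta("x", "candidate", "continuous"))
  d <- cohort(tibble::tibble(x = 1:5, y = 2 * (1:5)), meta)
  fit <- fit_ols(d, "x")
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "x"], 2,
               tolerance = 1e-12)
  expect_equal(fit$r.squared, 1)

  const <- cohort(tibble::tibble(x = c(1, 2, 4, 7), y = rep(6, 4)), meta)
  cfit <- fit_ols(const, "x")
  expect_equal(cfit$coefficients$estimate,
               c(6, 0), tolerance = 1e-12)
})

test_that("coefficients match the normal-equations oracle on random instances", {
  worst <- 0
  for (s in 1:200) {
    co <- make_reg_cohort(20, 3, beta = c(0.5, -1, 0), sigma = 1, seed = s)
    fit <- fit_ols(co, paste0("x", 1:3))
    X <- cbind(1, as.matrix(tibble::as_tibble(co)[paste0("x", 1:3)]))
    expected <- oracle_ols(X, co$y)
    worst <- max(worst, max(abs(fit$coefficients$estimate - expected)))
  }
  expect_lt(worst, 1e-10)
})

test_that("AIC equals the likelihood oracle and carries the +2 penalty", {
  co <- make_reg_cohort(10, 2, beta = c(1, 0), sigma = 0.5, seed = 3)
  fit <- fit_ols(co, c("x1", "x2"))
  X <- cbind(1, as.matrix(tibble::as_tibble(co)[c("x1", "x2")]))
  expect_equal(model_aic(fit), oracle_aic(X, co$y), tolerance = 1e-8)

  # a predictor orthogonal to the current residuals leaves RSS unchanged,
  # so adding it raises AIC by exactly 2
  base <- lm(y ~ x1, data = tibble::as_tibble(co))
  z <- withr::with_seed(4, rnorm(10))
  x_null <- residuals(lm(z ~ cbind(1, co$x1, residuals(base))))
  d2 <- tibble::as_tibble(co)[, c("y", "x1")]
  d2$x_null <- as.numeric(x_null)
  meta2 <- dplyr::bind_rows(var_meta("y", "outcome", "continuous"),
                            var_meta("x1", "candidate", "continuous"),
                            var_meta("x_null", "candidate", "continuous"))
  co2 <- cohort(d2, meta2)
  f_small <- fit_ols(co2, "x1")
  f_big <- fit_ols(co2, c("x1", "x_null"))
  expect_equal(f_big$rss, f_small$rss, tolerance = 1e-10)
  expect_equal(model_aic(f_big) - model_aic(f_small), 2, tolerance = 1e-8)

  # identical RSS and k give identical AIC (determinism)
  expect_identical(model_aic(fit), model_aic(fit))
})

test_that("AIC errors on a perfect fit instead of returning -Inf", {
  meta <- dplyr::bind_rows(var_meta("y", "outcome", "continuous"),
                           var_meta("x", "candidate", "continuous"))
  d <- cohort(tibble::tibble(x = 1:5, y = 2 * (1:5)), meta)
  fit <- fit_ols(d, "x")
  expect_error(model_aic(fit), "RSS")
})

test_that("VIF matches the closed form and flags exact collinearity", {
  # predictors orthogonal to each other and to the intercept: all VIF = 1
  Q <- qr.Q(qr(cbind(1, matrix(withr::with_seed(8, rnorm(40 * 3)), 40, 3))))
  X <- Q[, 2:4]
  d <- tibble::as_tibble(as.data.frame(X)) |> setNames(c("x1", "x2", "x3"))
  d$y <- withr::with_seed(9, runif(40, 1, 2))
  meta <- dplyr::bind_rows(var_meta("y", "outcome", "continuous"),
                           purrr::map_dfr(paste0("x", 1:3), var_meta,
                                          role = "candidate", vtype = "continuous"))
  co <- cohort(d, meta)
  expect_equal(unname(vif(co, paste0("x", 1:3))), rep(1, 3), tolerance = 1e-8)

  # two predictors with sample correlation exactly 0.9: VIF = 1/(1 - 0.81)
  withr::with_seed(10, {
    a <- scale(rnorm(60))[, 1]
    b <- scale(residuals(lm(rnorm(60) ~ a)))[, 1]
  })
  x2 <- 0.9 * a + sqrt(1 - 0.81) * b
  d2 <- tibble::tibble(x1 = a, x2 = x2, y = runif(60, 5, 7))
  meta2 <- dplyr::bind_rows(var_meta("y", "outcome", "continuous"),
                            var_meta("x1", "candidate", "continuous"),
                            var_meta("x2", "candidate", "continuous"))
  v <- vif(cohort(d2, meta2), c("x1", "x2"))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-6)

  # duplicated column: infinite VIF, not an exception
  d3 <- dplyr::mutate(d2, x2 = x1)
  v3 <- vif(cohort(d3, meta2), c("x1", "x2"))
  expect_true(all(is.infinite(v3)))
})

test_that("rank-deficient designs error and name a collinear term", {
  d <- tibble::tibble(x1 = c(1, 2, 3, 4, 5), x2 = c(2, 4, 6, 8, 10),
                      y = c(1, 2, 2, 3, 5))
  meta <- dplyr::bind_rows(var_meta("y", "outcome", "continuous"),
                           var_meta("x1", "candidate", "continuous"),
                           var_meta("x2", "candidate", "continuous"))
  expect_error(fit_ols(cohort(d, meta), c("x1", "x2")), "x2")
})

test_that("backward elimination with no candidates returns the forced model", {
  co <- make_reg_cohort(30, 2, beta = c(1, 0.5), forced = c("x1", "x2"), seed = 6)
  sel <- backward_eliminate(co)
  expect_setequal(sel$selected, c("x1", "x2"))
  expect_equal(nrow(sel$path), 0L)
})

test_that("single-candidate decisions follow the 0.157 partial-test threshold", {
  # strong candidate (partial p << 0.157): retained
  strong <- make_reg_cohort(50, 1, beta = 1, sigma = 1, seed = 31)
  p_strong <- oracle_partial_p(tibble::as_tibble(strong), "y", "x1", "x1")
  expect_lt(p_strong, 0.01)
  expect_true("x1" %in% backward_eliminate(strong)$selected)

  # pure-noise candidate with a mid-range partial p: removed
  noise <- make_reg_cohort(50, 1, beta = 0, sigma = 1, seed = 23)
  p_noise <- oracle_partial_p(tibble::as_tibble(noise), "y", "x1", "x1")
  expect_gt(p_noise, 0.3)
  sel <- backward_eliminate(noise)
  expect_equal(sel$selected, character(0))
  expect_equal(sel$path$removed, "x1")
})

test_that("elimination path strictly decreases AIC and never drops forced terms", {
  for (s in c(2, 12, 22)) {
    co <- make_reg_cohort(80, 6, beta = c(1, 0.5, 0, 0, 0, 0),
                          forced = c("x1", "x2"), seed = s)
    sel <- backward_eliminate(co)
    expect_true(all(c("x1", "x2") %in% sel$selected))
    if (nrow(sel$path)) {
      expect_true(all(sel$path$aic_after < sel$path$aic_before))
    }
    expect_lte(model_aic(sel$fit),
               model_aic(fit_ols(co, paste0("x", 1:6))) + 1e-9)
  }
})

test_that("selection is invariant to candidate ordering", {
  co <- make_reg_cohort(60, 5, beta = c(0.8, 0, 0.4, 0, 0), seed = 44)
  meta <- var_meta_of(co)
  s1 <- backward_eliminate(co, model_spec("y", candidates = paste0("x", 1:5)),
                           meta = meta)
  s2 <- backward_eliminate(co, model_spec("y", candidates = paste0("x", 5:1)),
                           meta = meta)
  expect_setequal(s1$selected, s2$selected)
})

test_that("categorical candidates are removed or retained as whole blocks", {
  withr::with_seed(77, {
    n <- 120
    region <- sample(c("A", "B", "C"), n, replace = TRUE)
    x <- rnorm(n)
    y <- 6 + 0.8 * x + rnorm(n)
  })
  d <- tibble::tibble(y = y, x = x, region = region)
  meta <- dplyr::bind_rows(
    var_meta("y", "outcome", "continuous"),
    var_meta("x", "forced", "continuous"),
    var_meta("region", "candidate", "categorical", levels = c("A", "B", "C"))
  )
  sel <- backward_eliminate(cohort(d, meta))
  terms <- sel$fit$coefficients$term
  has_b <- "region_B" %in% terms
  has_c <- "region_C" %in% terms
  expect_equal(has_b, has_c)
  if (!"region" %in% sel$selected) {
    expect_equal(sel$path$removed, "region")
  }
})
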