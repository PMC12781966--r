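test_that("RMSD ratio matches direct arithmetic and is scale invariant", {
  expect_equal(rmsd_ratio(rep(1.3, 50), 1.3, 0.2), 0)
  expect_equal(rmsd_ratio(c(0, 2), 1, 1), 1)
  b <- c(0, 0, 0.4, 0.7)
  expect_equal(rmsd_ratio(3 * b, 3 * 0.5, 3 * 0.1), rmsd_ratio(b, 0.5, 0.1),
               tolerance = 1e-12)
  expect_error(rmsd_ratio(numeric(0), 1, 1), "empty")
  expect_error(rmsd_ratio(b, 0.5, 0), "positive")
})

test_that("relative conditional bias handles both signs of the global estimate", {
  expect_equal(rc_bias(c(1, 1, 1), 1), 0)
  expect_equal(rc_bias(c(1.4, 1.6), 1), 50)
  expect_equal(rc_bias(c(-0.4, -0.6), -1), -50)
  expect_error(rc_bias(numeric(0), 1), "selected")
  expect_error(rc_bias(c(1, 2), 0), "zero")
})

test_that("standardized coefficients rescale by the SD ratio", {
  expect_equal(standardized_beta(0.7, 2, 2), 0.7)
  expect_equal(standardized_beta(0, 3, 1), 0)
  expect_equal(standardized_beta(0.5, 4, 2), 1)
  expect_error(standardized_beta(1, 0, 1), "sd_x")
  expect_error(standardized_beta(1, 1, -2), "sd_y")
})

test_that("selected-model frequency counts exact set matches", {
  ref <- c("a", "b")
  expect_equal(selected_model_frequency(rep(list(c("b", "a")), 8), ref), 100)
  expect_equal(selected_model_frequency(rep(list("a"), 8), ref), 0)
  sets <- c(list(c("a", "b")), rep(list(c("a", "c")), 999))
  expect_equal(selected_model_frequency(sets, ref), 0.1)
})

test_that("bootstrap summaries match a hand-rolled loop on shared indices", {
  co <- make_reg_cohort(40, 3, beta = c(0.8, 0, 0), sigma = 1,
                        forced = "x1", seed = 19)
  B <- 10L
  res <- bootstrap_stability(co, B = B, seed = 99, folds = 5,
                             keep_indices = TRUE)
  d <- tibble::as_tibble(co)
  terms <- c("(Intercept)", "x1", "x2", "x3")
  coefs <- matrix(0, B, 4, dimnames = list(NULL, terms))
  sets <- vector("list", B)
  for (b in seq_len(B)) {
    db <- d[res$indices[b, ], ]
    full <- lm(y ~ x1 + x2 + x3, data = db)
    red <- stats::step(full, scope = list(lower = ~x1),
                       direction = "backward", trace = 0, k = 2)
    cc <- coef(red)
    coefs[b, names(cc)] <- cc
    sets[[b]] <- setdiff(names(cc), "(Intercept)")
  }
  glob <- lm(y ~ x1 + x2 + x3, data = d)
  sg <- summary(glob)$coefficients
  for (tm in terms) {
    row <- res$summary[res$summary$term == tm, ]
    expect_equal(row$inclusion_frequency,
                 100 * mean(coefs[, tm] != 0 | tm == "(Intercept)"))
    expect_equal(row$beta_b, median(coefs[, tm]), tolerance = 1e-10)
    expect_equal(c(row$pct_2_5, row$pct_97_5),
                 unname(quantile(coefs[, tm], c(0.025, 0.975), type = 7)),
                 tolerance = 1e-10)
    expect_equal(row$rmsd_ratio,
                 sqrt(mean((coefs[, tm] - sg[tm, 1])^2)) / sg[tm, 2],
                 tolerance = 1e-8)
    selected <- coefs[, tm] != 0
    if (any(selected) && tm != "(Intercept)") {
      expect_equal(row$rc_bias_pct,
                   100 * (mean(coefs[selected, tm]) / sg[tm, 1] - 1),
                   tolerance = 1e-8)
    }
  }
  expect_equal(res$selected_model_frequency_pct,
               selected_model_frequency(sets, res$selection$selected))
})

test_that("stability invariants hold on a synthetic cohort", {
  co <- generate_cohort(generator_config(n = 130, seed = 8))
  res <- bootstrap_stability(co, B = 40, seed = 12)
  td <- tidy(res)
  expect_equal(td$inclusion_frequency[td$forced], rep(100, sum(td$forced)))
  expect_true(all(td$pct_2_5 <= td$beta_b + 1e-12))
  expect_true(all(td$beta_b <= td$pct_97_5 + 1e-12))
  low <- td$inclusion_frequency < 50
  expect_true(all(td$beta_b[low] == 0))
  # majority-sign property above 50% inclusion
  over <- which(td$inclusion_frequency > 50 & !td$forced & td$beta_b != 0)
  for (j in over) {
    tm <- td$term[j]
    sel <- res$included[, tm]
    maj <- sign(sum(sign(res$coefficients[sel, tm])))
    expect_equal(sign(td$beta_b[j]), maj)
  }
})

test_that("identical seeds give bit-identical stability results", {
  co <- generate_cohort(generator_config(n = 90, seed = 77))
  r1 <- bootstrap_stability(co, B = 25, seed = 5)
  r2 <- bootstrap_stability(co, B = 25, seed = 5)
  expect_identical(r1, r2)
  r3 <- bootstrap_stability(co, B = 25, seed = 6)
  expect_false(identical(r1$coefficients, r3$coefficients))
})

test_that("degenerate resamples are redrawn and a high rate warns", {
  d <- tibble::tibble(
    y = withr::with_seed(3, runif(20, 5, 7)),
    x = withr::with_seed(4, rnorm(20)),
    rare = rep(c("Yes", rep("No", 19)))
  )
  meta <- dplyr::bind_rows(
    var_meta("y", "outcome", "continuous"),
    var_meta("x", "forced", "continuous"),
    var_meta("rare", "candidate", "binary", levels = c("No", "Yes"))
  )
  co <- cohort(d, meta)
  expect_warning(res <- bootstrap_stability(co, B = 20, seed = 2, folds = 5),
                 "redrawn")
  expect_gt(res$redraws, 0)
  # B stayed exact despite redraws
  expect_equal(nrow(res$coefficients), 20L)
})

test_that("calibration slope is 1 on noiseless data and near 1 at scale", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), y = 2 * c(1, 2, 3, 4) + 1e-9)
  meta <- dplyr::bind_rows(var_meta("y", "outcome", "continuous"),
                           var_meta("x", "forced", "continuous"))
  co <- cohort(d, meta)
  sel <- backward_eliminate(co)
  expect_equal(global_shrinkage(co, sel, folds = 4, seed = 1), 1,
               tolerance = 1e-6)

  big <- make_reg_cohort(5000, 1, beta = 1, sigma = 1, seed = 55)
  sel_big <- backward_eliminate(big)
  expect_lt(abs(global_shrinkage(big, sel_big, folds = 10, seed = 2) - 1), 0.05)
})
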