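#' Bootstrap stability investigation of backward elimination
#'
#' Repeats AIC backward elimination (with the same forced covariate set)
#' across `B` bootstrap resamples of the analysis sample, recording each
#' term's coefficient with zero substituted whenever the term is not
#' selected in a resample. From the resulting B-by-terms coefficient matrix
#' it reports, per term:
#'
#' * the bootstrap inclusion frequency (BIF, percent of resamples selected;
#'   exactly 100 for forced variables and the intercept),
#' * the final bootstrap estimate: the median of the per-resample
#'   coefficients including zeros, with 2.5th/97.5th percentile limits
#'   (linear interpolation between order statistics, quantile type 7),
#' * the standardized bootstrap estimate (scaled by the full-sample SDs of
#'   the design column and the outcome),
#' * the RMSD ratio: root-mean-squared deviation of the per-resample
#'   coefficients (zeros included) about the global-model estimate, divided
#'   by the global-model standard error (values above 1 signal variability
#'   added by selection),
#' * the relative conditional (RC) bias: percent deviation of the mean
#'   coefficient, conditional on selection, from the global-model estimate.
#'
#' Globally it reports the selected-model frequency (percent of resamples
#' whose selected variable set equals the original selected set) and a
#' cross-validated shrinkage factor (calibration slope) for the selected
#' model. Resamples whose design is degenerate (a constant indicator or a
#' rank-deficient matrix) are redrawn so that `B` stays exact; a redraw rate
#' above 5\% triggers a warning. Everything is reproducible from `seed`.
#'
#' @param data A `cohort_tbl` or data frame with `meta`; complete cases on
#'   the model variables are used.
#' @param spec A [model_spec()]; defaults to [spec_from_meta()].
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed governing resampling and the shrinkage folds.
#' @param meta Metadata when `data` is not a `cohort_tbl`.
#' @param folds Folds for the shrinkage calibration slope (default 10).
#' @param keep_indices Keep the resample index matrix (for audits/tests).
#' @return A `stability` object; `tidy()` gives the per-term table,
#'   `glance()` the global quantities, `autoplot()` an inclusion-frequency
#'   chart.
#' @export
bootstrap_stability <- function(data, spec = NULL, B = 1000L, seed = 1L,
                                meta = NULL, folds = 10L,
                                keep_indices = FALSE) {
  meta <- meta %||% var_meta_of(data)
  spec <- spec %||% spec_from_meta(meta)
  if (B < 2L) abort("B must be at least 2.")
  d <- build_design(data, meta, c(spec$forced, spec$candidates), spec$outcome)
  X <- d$X; y <- d$y; blocks <- d$blocks; n <- d$n
  p <- ncol(X)
  terms <- colnames(X)

  global_fit <- fit_ols_design(X, y, term_var = d$term_var,
                               outcome = spec$outcome, blocks = blocks)
  orig <- backward_core(X, y, blocks, spec$forced)
  selected_fit <- fit_ols_design(X[, orig$cols, drop = FALSE], y,
                                 term_var = d$term_var[orig$cols],
                                 outcome = spec$outcome)
  selection <- structure(list(selected = orig$selected, fit = selected_fit,
                              path = orig$path, spec = spec),
                         class = "selection")

  coefs <- matrix(0, nrow = B, ncol = p, dimnames = list(NULL, terms))
  included <- matrix(FALSE, nrow = B, ncol = p, dimnames = list(NULL, terms))
  selections <- vector("list", B)
  indices <- if (keep_indices) matrix(0L, nrow = B, ncol = n) else NULL
  redraws <- 0L

  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        if (resample_ok(Xb)) break
        redraws <- redraws + 1L
      }
      yb <- y[idx]
      res <- backward_core(Xb, yb, blocks, spec$forced)
      beta <- .lm.fit(Xb[, res$cols, drop = FALSE], yb)$coefficients
      coefs[b, res$cols] <- beta
      included[b, res$cols] <- TRUE
      selections[[b]] <- res$selected
      if (keep_indices) indices[b, ] <- idx
    }
  })
  if (redraws > 0.05 * B) {
    warn(sprintf("%d degenerate resample(s) redrawn (> 5%% of B = %d).",
                 redraws, B))
  }

  sd_y <- sd(y)
  g <- global_fit$coefficients
  summary <- purrr::map_dfr(seq_len(p), function(j) {
    term <- terms[[j]]
    bj <- coefs[, j]
    sel <- included[, j]
    beta_g <- g$estimate[[j]]
    se_g <- g$std.error[[j]]
    bif <- 100 * mean(sel)
    beta_b <- unname(median(bj))
    pcts <- unname(quantile(bj, c(0.025, 0.975), type = 7))
    sd_x <- sd(X[, j])
    tibble::tibble(
      term = term,
      variable = d$term_var[[j]],
      forced = d$term_var[[j]] %in% c("(Intercept)", spec$forced),
      beta_global = beta_g,
      se_global = se_g,
      inclusion_frequency = bif,
      beta_b = beta_b,
      pct_2_5 = pcts[[1L]],
      pct_97_5 = pcts[[2L]],
      std_beta_b = if (term == "(Intercept)") NA_real_ else
        standardized_beta(beta_b, sd_x, sd_y),
      rmsd_ratio = rmsd_ratio(bj, beta_g, se_g),
      rc_bias_pct = if (beta_g == 0 || !any(sel)) NA_real_ else
        rc_bias(bj[sel], beta_g)
    )
  })

  shrinkage <- global_shrinkage(d$data, selection, folds = folds,
                                seed = derive_seed(seed, 7919L), meta = meta)

  structure(
    list(summary = summary, global_fit = global_fit, selection = selection,
         coefficients = coefs, included = included, selections = selections,
         indices = indices, B = B, seed = seed, n = n,
         redraws = redraws, shrinkage_factor = shrinkage,
         selected_model_frequency_pct =
           selected_model_frequency(selections, orig$selected)),
    class = "stability"
  )
}

# A resample is usable when no non-intercept column is constant and the
# design has full column rank.
resample_ok <- function(Xb) {
  p <- ncol(Xb)
  for (j in 2:p) {
    cj <- Xb[, j]
    if (all(cj == cj[[1L]])) return(FALSE)
  }
  qr(Xb)$rank == p
}

#' RMSD ratio of bootstrap coefficients about the global estimate
#'
#' `sqrt(mean((b_i - beta_global)^2)) / se_global`, with the zero-substituted
#' coefficients included. Invariant to rescaling all three arguments by the
#' same positive constant.
#'
#' @param boot_coeffs Per-resample coefficients (zeros included).
#' @param beta_global Global-model coefficient estimate.
#' @param se_global Global-model standard error (> 0).
#' @return The ratio (dimensionless).
#' @export
rmsd_ratio <- function(boot_coeffs, beta_global, se_global) {
  if (!length(boot_coeffs)) abort("empty coefficient vector.")
  check_scalar_number(beta_global, "beta_global")
  if (!is_number(se_global) || se_global <= 0) abort("se_global must be positive.")
  sqrt(mean((boot_coeffs - beta_global)^2)) / se_global
}

#' Relative conditional bias of a selected coefficient
#'
#' `100 * (mean(boot_coeffs_selected_only) / beta_global - 1)`: how far the
#' average coefficient, among resamples where the variable survived
#' selection, sits from the global-model estimate, in percent.
#'
#' @param boot_coeffs_selected_only Coefficients from resamples where the
#'   variable was selected (non-empty).
#' @param beta_global Non-zero global-model estimate.
#' @return Percent bias (`NA` is never returned; degenerate cases error).
#' @export
rc_bias <- function(boot_coeffs_selected_only, beta_global) {
  if (!length(boot_coeffs_selected_only)) abort("no selected resamples.")
  check_scalar_number(beta_global, "beta_global")
  if (beta_global == 0) abort("RC bias is undefined at a zero global estimate.")
  100 * (mean(boot_coeffs_selected_only) / beta_global - 1)
}

#' Standardize a regression coefficient
#'
#' `beta * sd_x / sd_y`: the outcome-SD change per predictor-SD change,
#' making effect sizes comparable across predictors.
#'
#' @param beta Unstandardized coefficient.
#' @param sd_x,sd_y Positive standard deviations of predictor and outcome.
#' @return The standardized coefficient.
#' @export
standardized_beta <- function(beta, sd_x, sd_y) {
  if (!is_number(sd_x) || sd_x <= 0) abort("sd_x must be positive.")
  if (!is_number(sd_y) || sd_y <= 0) abort("sd_y must be positive.")
  beta * sd_x / sd_y
}

#' Selected-model frequency
#'
#' Percent of resamples whose selected variable set is exactly the reference
#' set (order-insensitive).
#'
#' @param resample_selections List of character vectors of selected variables.
#' @param reference Character vector: the original selected set.
#' @return Percent in `[0, 100]`.
#' @export
selected_model_frequency <- function(resample_selections, reference) {
  if (!length(resample_selections)) abort("no resample selections supplied.")
  ref <- sort(unique(reference))
  hits <- vapply(resample_selections,
                 function(s) identical(sort(unique(s)), ref), logical(1))
  100 * mean(hits)
}

#' Global shrinkage factor (cross-validated calibration slope)
#'
#' Refits the selected model on each cross-validation training split,
#' assembles the out-of-fold linear predictor, and reports the slope of the
#' outcome regressed on that predictor. A slope of 1 means predictions are
#' well calibrated; values below 1 quantify overfitting of the selected
#' model.
#'
#' @param data A `cohort_tbl` or data frame with `meta`.
#' @param selection A [backward_eliminate()] result.
#' @param folds Number of folds (default 10); `folds = n` gives
#'   leave-one-out.
#' @param seed Optional seed for the fold assignment.
#' @param meta Metadata when `data` is not a `cohort_tbl`.
#' @return The calibration slope.
#' @export
global_shrinkage <- function(data, selection, folds = 10L, seed = NULL,
                             meta = NULL) {
  meta <- meta %||% var_meta_of(data)
  if (folds < 2L) abort("folds must be at least 2.")
  spec <- selection$spec
  d <- build_design(data, meta, selection$selected, spec$outcome)
  X <- d$X; y <- d$y; n <- d$n
  folds <- min(folds, n)
  assign_folds <- function() sample(rep(seq_len(folds), length.out = n))
  fold_id <- if (is.null(seed)) assign_folds() else with_seed(seed, assign_folds())
  lp <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    beta <- .lm.fit(X[!test, , drop = FALSE], y[!test])$coefficients
    lp[test] <- X[test, , drop = FALSE] %*% beta
  }
  if (var(lp) < 1e-12) abort("cross-validated linear predictor is constant.")
  unname(cov(y, lp) / var(lp))
}

#' @describeIn bootstrap_stability Per-term stability table.
#' @param x,object A `stability` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.stability <- function(x, ...) x$summary

#' @describeIn bootstrap_stability One-row global summary: `B`, `seed`, `n`,
#'   redraw count, shrinkage factor, selected-model frequency, and the
#'   global/selected model R-squared values.
#' @exportS3Method generics::glance
glance.stability <- function(x, ...) {
  tibble::tibble(
    B = x$B, seed = x$seed, nobs = x$n, redraws = x$redraws,
    shrinkage_factor = x$shrinkage_factor,
    selected_model_frequency_pct = x$selected_model_frequency_pct,
    r.squared_global = x$global_fit$r.squared,
    adj.r.squared_global = x$global_fit$adj.r.squared,
    r.squared_selected = x$selection$fit$r.squared,
    adj.r.squared_selected = x$selection$fit$adj.r.squared
  )
}

#' @describeIn bootstrap_stability Inclusion-frequency bar chart with the
#'   60\% "meaningful variable" reporting threshold marked.
#' @exportS3Method ggplot2::autoplot
autoplot.stability <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  df$term <- stats::reorder(df$term, df$inclusion_frequency)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inclusion_frequency, y = .data$term,
                                   fill = .data$forced)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 60, linetype = "dashed") +
    ggplot2::labs(x = "bootstrap inclusion frequency (%)", y = NULL,
                  fill = "forced") +
    ggplot2::xlim(0, 100)
}

#' @export
print.stability <- function(x, ...) {
  cat(sprintf("<stability> B = %d resamples, n = %d, seed = %s\n",
              x$B, x$n, format(x$seed)))
  cat(sprintf("  shrinkage factor %.3f; selected-model frequency %.1f%%; %d redraw(s)\n",
              x$shrinkage_factor, x$selected_model_frequency_pct, x$redraws))
  print(x$summary, n = Inf)
  invisible(x)
}
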