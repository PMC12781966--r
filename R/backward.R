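#' Backward elimination by AIC with a forced covariate set
#'
#' Starting from the global model (all forced and candidate variables), the
#' candidate whose removal lowers the AIC the most is dropped, repeatedly,
#' until no removal lowers the AIC. Forced variables (and the intercept) are
#' never considered for removal, and categorical variables leave or stay as
#' whole indicator blocks. For a single-parameter removal this AIC rule is
#' equivalent to retaining the term when its likelihood-ratio partial test
#' p-value is below `1 - pchisq(2, 1)`, approximately 0.157.
#'
#' Ties (two removals giving equal AIC within 1e-9) are broken by removing
#' the term with the smaller absolute t statistic in the current fit, then
#' lexicographically by name, so elimination paths are reproducible.
#'
#' @param data A `cohort_tbl` or data frame with `meta`.
#' @param spec A [model_spec()]; defaults to [spec_from_meta()] roles.
#' @param meta Metadata tibble when `data` is not a `cohort_tbl`.
#' @return A `selection` object: `selected` (variable names, forced always
#'   included), `fit` (the selected model's `ols_fit`), and `path`, a tibble
#'   of removals with the AIC before and after each step (strictly
#'   decreasing).
#' @export
backward_eliminate <- function(data, spec = NULL, meta = NULL) {
  meta <- meta %||% var_meta_of(data)
  spec <- spec %||% spec_from_meta(meta)
  d <- build_design(data, meta, c(spec$forced, spec$candidates), spec$outcome)
  res <- backward_core(d$X, d$y, d$blocks, spec$forced)
  fit <- fit_ols_design(d$X[, res$cols, drop = FALSE], d$y,
                        term_var = d$term_var[res$cols], outcome = spec$outcome)
  structure(
    list(selected = res$selected, fit = fit, path = res$path, spec = spec),
    class = "selection"
  )
}

# Elimination engine on a prebuilt design. `blocks` maps variable name ->
# design column indices; the intercept block is never removable.
backward_core <- function(X, y, blocks, forced) {
  n <- nrow(X)
  current <- names(blocks)
  removable <- setdiff(current, c("(Intercept)", forced))
  cols <- sort(unlist(blocks[current], use.names = FALSE))
  aic_cur <- aic_from_rss(rss_of(X[, cols, drop = FALSE], y), n, length(cols))
  path <- list()
  step <- 0L

  while (length(removable)) {
    cand_aic <- vapply(removable, function(v) {
      keep <- sort(unlist(blocks[setdiff(current, v)], use.names = FALSE))
      rss <- rss_of(X[, keep, drop = FALSE], y)
      if (rss <= 0) return(Inf)  # never "improve" onto a perfect fit
      aic_from_rss(rss, n, length(keep))
    }, numeric(1))
    best <- min(cand_aic)
    if (!(best < aic_cur - 1e-12)) break
    tied <- removable[cand_aic <= best + 1e-9]
    drop_var <- if (length(tied) > 1L) break_tie(X, y, blocks, current, tied) else tied
    step <- step + 1L
    aic_new <- cand_aic[[drop_var]]
    path[[step]] <- tibble::tibble(step = step, removed = drop_var,
                                   aic_before = aic_cur, aic_after = aic_new)
    current <- setdiff(current, drop_var)
    removable <- setdiff(removable, drop_var)
    aic_cur <- aic_new
  }
  cols <- sort(unlist(blocks[current], use.names = FALSE))
  list(selected = setdiff(current, "(Intercept)"), cols = cols,
       path = if (step) dplyr::bind_rows(path) else
         tibble::tibble(step = integer(), removed = character(),
                        aic_before = double(), aic_after = double()))
}

# Tie-break: remove the block whose largest |t| in the current fit is
# smallest; remaining ties resolve lexicographically.
break_tie <- function(X, y, blocks, current, tied) {
  cols <- sort(unlist(blocks[current], use.names = FALSE))
  Xc <- X[, cols, drop = FALSE]
  qr_x <- qr(Xc)
  beta <- qr.coef(qr_x, y)
  resid <- y - drop(Xc %*% beta)
  df <- nrow(Xc) - ncol(Xc)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(chol2inv(qr.R(qr_x))))
  tt <- abs(beta / se)
  names(tt) <- colnames(Xc)
  stat <- vapply(tied, function(v) {
    ids <- colnames(X)[blocks[[v]]]
    max(tt[ids])
  }, numeric(1))
  tied <- tied[order(stat, tied)]
  tied[[1L]]
}

#' @describeIn backward_eliminate Coefficient table of the selected model.
#' @param x,object A `selection`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.selection <- function(x, ...) tidy(x$fit)

#' @describeIn backward_eliminate One-row summary: selected/global term
#'   counts, AIC, R-squared.
#' @exportS3Method generics::glance
glance.selection <- function(x, ...) {
  dplyr::mutate(glance(x$fit),
                n_selected = length(x$selected),
                n_removed = nrow(x$path), .before = 1L)
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection> %d variable(s) retained (%d removed by AIC)\n",
              length(x$selected), nrow(x$path)))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
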