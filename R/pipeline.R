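#' Run the full analysis pipeline on one cohort
#'
#' Orchestrates the stages end to end: optional within-domain imputation of
#' scale scores from item-level tables, complete-case restriction on the
#' model variables, the global model (all candidates), the selected model
#' (AIC backward elimination with forced covariates), and the bootstrap
#' stability investigation. Variables with a bootstrap inclusion frequency
#' above 60\% are flagged as meaningful in the manifest (a reporting rule,
#' not a model-selection step).
#'
#' @param data A `cohort_tbl`.
#' @param spec A [model_spec()]; defaults to the metadata roles.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param folds Folds for the shrinkage factor.
#' @param impute Apply within-domain imputation where item tables are given.
#' @param item_tables Named list (by score variable) of item-response data
#'   frames for [within_domain_impute()].
#' @param scale_defs Named list (same names) of [scale_def()] objects.
#' @param policy An [impute_policy()].
#' @return A `pipeline_run`: `global_fit`, `selection`, `stability`,
#'   `imputation` (per-scale logs), and `manifest`.
#' @export
run_pipeline <- function(data, spec = NULL, B = 1000L, seed = 1L, folds = 10L,
                         impute = TRUE, item_tables = NULL, scale_defs = NULL,
                         policy = impute_policy()) {
  meta <- var_meta_of(data)
  spec <- spec %||% spec_from_meta(meta)

  imputation <- list()
  if (impute && length(item_tables)) {
    if (is.null(scale_defs) || !all(names(item_tables) %in% names(scale_defs))) {
      abort("every item table needs a matching entry in `scale_defs`.")
    }
    for (nm in names(item_tables)) {
      imp <- within_domain_impute(item_tables[[nm]], scale_defs[[nm]],
                                  policy = policy)
      data[[nm]] <- imp$score
      imputation[[nm]] <- imp
    }
  }

  stab <- bootstrap_stability(data, spec, B = B, seed = seed, meta = meta,
                              folds = folds)
  flagged <- unique(stab$summary$variable[
    stab$summary$inclusion_frequency > 60 & stab$summary$term != "(Intercept)"])

  manifest <- list(
    config_hash = rlang::hash(list(spec, B, seed, folds, impute,
                                   names(item_tables))),
    seed = seed, B = B, folds = folds,
    n_analyzed = stab$n,
    variables_imputed = names(imputation),
    flagged_over_60pct = flagged,
    redraws = stab$redraws,
    version = as.character(utils::packageVersion("bootsel"))
  )

  structure(
    list(global_fit = stab$global_fit, selection = stab$selection,
         stability = stab, imputation = imputation, manifest = manifest,
         spec = spec),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pipeline_run> n = %d analyzed, B = %d, seed = %s\n",
              m$n_analyzed, m$B, format(m$seed)))
  cat("  flagged (> 60% inclusion):",
      if (length(m$flagged_over_60pct)) paste(m$flagged_over_60pct, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Run the pipeline within strata of a categorical variable
#'
#' An independent pipeline is run per stratum level. The stratum variable is
#' dropped from the forced and candidate sets inside its own strata (it is
#' constant there). Levels whose complete-case count does not exceed the
#' global parameter count are skipped with a warning.
#'
#' @inheritParams run_pipeline
#' @param stratum Name of a binary/categorical stratifying variable.
#' @param ... Passed on to [run_pipeline()].
#' @return Named list of `pipeline_run` objects, one per usable level.
#' @export
run_stratified <- function(data, stratum, spec = NULL, ...) {
  meta <- var_meta_of(data)
  spec <- spec %||% spec_from_meta(meta)
  sv <- data[[stratum]]
  if (is.null(sv)) abort(sprintf("stratum variable '%s' not found.", stratum))
  if (!is.factor(sv)) abort("stratum variable must be binary or categorical.")
  seen <- unique(as.character(sv[!is.na(sv)]))
  if (length(seen) < 2L) {
    abort(sprintf("stratum variable '%s' is constant; nothing to stratify.", stratum))
  }
  inner_spec <- model_spec(spec$outcome,
                           forced = setdiff(spec$forced, stratum),
                           candidates = setdiff(spec$candidates, stratum))
  n_params <- 1L + length(inner_spec$forced) + length(inner_spec$candidates)
  out <- list()
  for (lv in base::levels(sv)) {
    rows <- !is.na(sv) & sv == lv
    sub <- data[rows, , drop = FALSE]
    vars_used <- c(inner_spec$forced, inner_spec$candidates, inner_spec$outcome)
    n_cc <- sum(complete.cases(tibble::as_tibble(sub)[, vars_used]))
    if (n_cc <= n_params) {
      warn(sprintf("stratum '%s' skipped: %d complete case(s) for %d parameters.",
                   lv, n_cc, n_params))
      next
    }
    sub <- cohort(tibble::as_tibble(sub), meta)
    out[[lv]] <- run_pipeline(sub, spec = inner_spec, ...)
  }
  out
}

#' Compare bootstrap inclusion frequencies across two runs
#'
#' Sensitivity companion: given a run with imputation and a complete-case
#' run (or any two runs over the same variables), reports the per-term
#' inclusion-frequency difference.
#'
#' @param run_a,run_b `pipeline_run` or `stability` objects.
#' @return Tibble with `term`, both frequencies and `bif_diff` (a minus b).
#' @export
compare_sensitivity <- function(run_a, run_b) {
  ta <- if (inherits(run_a, "pipeline_run")) tidy(run_a$stability) else tidy(run_a)
  tb <- if (inherits(run_b, "pipeline_run")) tidy(run_b$stability) else tidy(run_b)
  dplyr::full_join(
    dplyr::select(ta, "term", bif_a = "inclusion_frequency"),
    dplyr::select(tb, "term", bif_b = "inclusion_frequency"),
    by = "term"
  ) |>
    dplyr::mutate(bif_diff = .data$bif_a - .data$bif_b)
}
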