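# Internal design-matrix machinery shared by the fitting, elimination and
# bootstrap code. Categorical variables expand to treatment-coded indicator
# columns against their declared reference level and are always selected or
# removed as one block.

#' Specify the modelling roles of a variable set
#'
#' @param outcome Outcome variable name.
#' @param forced Variables retained in every model (never eliminated).
#' @param candidates Variables subject to backward elimination.
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome, forced = character(), candidates = character()) {
  forced <- as.character(forced)
  candidates <- as.character(candidates)
  if (length(intersect(forced, candidates))) {
    abort("forced and candidate sets must be disjoint.")
  }
  if (outcome %in% c(forced, candidates)) {
    abort("the outcome cannot appear among forced or candidate variables.")
  }
  structure(list(outcome = outcome, forced = forced, candidates = candidates),
            class = "model_spec")
}

#' Derive a model specification from cohort metadata roles
#'
#' @param meta A metadata tibble (see [var_meta()]).
#' @return A [model_spec()] using the declared `outcome`/`forced`/`candidate`
#'   roles.
#' @export
spec_from_meta <- function(meta) {
  validate_meta(meta)
  model_spec(outcome = meta$name[meta$role == "outcome"],
             forced = meta$name[meta$role == "forced"],
             candidates = meta$name[meta$role == "candidate"])
}

# Build X (with intercept), y, and the variable -> column-index block map for
# the complete-case subsample on `vars` + outcome.
build_design <- function(data, meta, vars, outcome) {
  meta <- meta[match(c(outcome, vars), meta$name), , drop = FALSE]
  if (anyNA(meta$name)) {
    abort(paste0("variable(s) missing from metadata: ",
                 paste(setdiff(c(outcome, vars), meta$name[!is.na(meta$name)]),
                       collapse = ", ")))
  }
  use <- complete.cases(data[, c(outcome, vars), drop = FALSE])
  data <- data[use, , drop = FALSE]
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  blocks <- list(`(Intercept)` = 1L)
  term_var <- c("(Intercept)")
  idx <- 1L
  for (v in vars) {
    m <- meta[meta$name == v, ]
    if (m$vtype %in% c("continuous", "dose")) {
      idx <- idx + 1L
      cols[[v]] <- as.numeric(data[[v]])
      blocks[[v]] <- idx
      term_var <- c(term_var, v)
    } else {
      lv <- base::levels(data[[v]])
      non_ref <- lv[-1L]
      ids <- integer(0)
      for (l in non_ref) {
        idx <- idx + 1L
        nm <- paste0(v, "_", l)
        cols[[nm]] <- as.numeric(data[[v]] == l)
        ids <- c(ids, idx)
        term_var <- c(term_var, v)
      }
      blocks[[v]] <- ids
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, y = as.numeric(data[[outcome]]), blocks = blocks,
       term_var = term_var, rows = which(use), n = n, data = data)
}

# Gaussian AIC from a residual sum of squares; k counts mean parameters
# (intercept included). Full log-likelihood constants are kept so the value
# matches -2 * maximised Gaussian log-likelihood + 2k.
aic_from_rss <- function(rss, n, k) {
  if (rss <= 0) abort("AIC is undefined at RSS = 0 (perfect fit).")
  n * log(rss / n) + n * log(2 * pi) + n + 2 * k
}

rss_of <- function(X, y) {
  fit <- .lm.fit(X, y)
  sum(fit$residuals^2)
}
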