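#' Descriptive summary of a cohort table
#'
#' Produces the usual epidemiological "Table 1": mean (SD), median (IQR) and
#' range for continuous variables, counts and percentages for binary and
#' categorical variables, overall and optionally within strata. Percentages
#' are computed on non-missing values, rounded to the nearest whole percent
#' and printed with a fixed one-decimal style (207 of 349 renders as
#' `"59.0%"`).
#'
#' @param x A `cohort_tbl` built with [cohort()] or [read_cohort()].
#' @param strata Optional name of a binary/categorical stratifying variable;
#'   summaries are then produced for the pooled sample and per stratum level.
#'   An empty stratum level is reported with `n = 0` and no statistics.
#' @return A tibble with one row per continuous variable (or per level of a
#'   categorical variable) and per stratum, holding `n`, `n_missing`, `mean`,
#'   `sd`, `median`, `iqr`, `min`, `max`, `count`, `percent` and a formatted
#'   `percent_label`.
#' @export
summarize_cohort <- function(x, strata = NULL) {
  meta <- var_meta_of(x)
  if (nrow(x) == 0L) abort("cannot summarise an empty cohort.")
  groups <- list(overall = rep(TRUE, nrow(x)))
  if (!is.null(strata)) {
    if (!strata %in% names(x)) abort(sprintf("stratum variable '%s' not found.", strata))
    sv <- x[[strata]]
    if (!is.factor(sv)) abort("stratum variable must be binary or categorical.")
    for (lv in levels(sv)) {
      groups[[lv]] <- !is.na(sv) & sv == lv
    }
  }
  vars <- meta[meta$role != "id", , drop = FALSE]
  rows <- purrr::map_dfr(names(groups), function(gname) {
    keep <- groups[[gname]]
    purrr::map_dfr(seq_len(nrow(vars)), function(i) {
      nm <- vars$name[[i]]
      if (!is.null(strata) && nm == strata && gname != "overall") return(NULL)
      col <- x[[nm]][keep]
      summarize_one(nm, vars$vtype[[i]], col, gname)
    })
  })
  rows
}

summarize_one <- function(name, vtype, col, stratum) {
  n_total <- length(col)
  n_missing <- sum(is.na(col))
  obs <- col[!is.na(col)]
  base <- tibble::tibble(
    stratum = stratum, variable = name, level = NA_character_,
    n = length(obs), n_missing = n_missing,
    mean = NA_real_, sd = NA_real_, median = NA_real_, iqr = NA_real_,
    min = NA_real_, max = NA_real_,
    count = NA_integer_, percent = NA_real_, percent_label = NA_character_
  )
  if (length(obs) == 0L) return(base)
  if (vtype %in% c("continuous", "dose")) {
    base$mean <- mean(obs)
    base$sd <- sd(obs)
    base$median <- median(obs)
    base$iqr <- unname(quantile(obs, 0.75) - quantile(obs, 0.25))
    base$min <- min(obs)
    base$max <- max(obs)
    base
  } else {
    purrr::map_dfr(levels(col), function(lv) {
      row <- base
      row$level <- lv
      row$count <- sum(obs == lv)
      row$percent <- 100 * row$count / length(obs)
      row$percent_label <- format_percent(row$percent)
      row
    })
  }
}
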