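#' Define a multi-item psychosocial instrument
#'
#' Captures the structure needed to score a Likert-type questionnaire: its
#' item columns, the per-item response range, which items are reverse-coded,
#' and whether the instrument score is the sum or the mean of item responses.
#' The attainable score range is derived from the response range (e.g. a
#' 10-item instrument on a 1-4 coding sums to 10-40, the Rosenberg
#' self-esteem range; a 17-item instrument on 1-5 sums to 17-85, the general
#' self-efficacy range).
#'
#' @param name Instrument identifier.
#' @param items Character vector of item column names, in order.
#' @param response_min,response_max Integer bounds of a single item response.
#' @param reverse_items Subset of `items` whose responses are reflected
#'   (`r` becomes `response_min + response_max - r`) before aggregation, so
#'   that higher scores always point in the instrument's stated direction.
#' @param aggregation `"sum"` (default) or `"mean"`.
#' @return A `scale_def` object.
#' @export
#' @examples
#' rosenberg <- scale_def("self_esteem", paste0("rse", 1:10), 1, 4,
#'                        reverse_items = paste0("rse", c(2, 5, 6, 8, 9)))
#' rosenberg$score_min  # 10
#' rosenberg$score_max  # 40
scale_def <- function(name, items, response_min, response_max,
                      reverse_items = character(), aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  items <- as.character(items)
  if (anyDuplicated(items)) abort("scale items must be unique.")
  if (!all(reverse_items %in% items)) {
    abort("reverse_items must be a subset of items.")
  }
  if (response_min >= response_max) abort("response_min must be below response_max.")
  k <- length(items)
  agg <- if (aggregation == "sum") function(v) sum(v) else function(v) mean(v)
  structure(
    list(name = name, items = items,
         response_min = response_min, response_max = response_max,
         reverse_items = as.character(reverse_items),
         aggregation = aggregation,
         score_min = agg(rep(response_min, k)),
         score_max = agg(rep(response_max, k))),
    class = "scale_def"
  )
}

# Reverse-code declared items; input and output are respondent x item matrices.
apply_reverse <- function(mat, def) {
  if (length(def$reverse_items)) {
    rv <- def$reverse_items
    mat[, rv] <- def$response_min + def$response_max - mat[, rv]
  }
  mat
}

item_matrix <- function(item_table, def) {
  missing_cols <- setdiff(def$items, names(item_table))
  if (length(missing_cols)) {
    abort(paste0("item table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  mat <- as.matrix(item_table[, def$items, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- which(!is.na(mat) & (mat < def$response_min | mat > def$response_max),
               arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("response out of range [%s, %s] for item '%s' (row %d).",
                  def$response_min, def$response_max,
                  def$items[bad[1L, 2L]], bad[1L, 1L]))
  }
  mat
}

#' Score an instrument from its item responses
#'
#' Reverse-coded items are reflected first, then responses are aggregated
#' (sum or mean per the definition). A respondent with any missing item
#' receives a missing score here; partial-response handling belongs to
#' [within_domain_impute()].
#'
#' @param item_table Data frame with one row per respondent and the
#'   definition's item columns.
#' @param def A [scale_def()].
#' @return Numeric vector of scores, `NA` where any item is missing.
#' @export
score_scale <- function(item_table, def) {
  mat <- apply_reverse(item_matrix(item_table, def), def)
  scores <- if (def$aggregation == "sum") rowSums(mat) else rowMeans(mat)
  as.numeric(scores)
}

#' Imputation policy for partially missing instrument scores
#'
#' Imputation is applied only when the cohort-level missingness rate of the
#' score falls inside a band (default 5--10\%): below the band the handful of
#' incomplete respondents are left to complete-case deletion; above it the
#' score is considered too incomplete to patch item-by-item.
#'
#' @param min_band,max_band Bounds of the cohort missingness band (fractions).
#' @param min_observed_fraction Minimum fraction of a respondent's items that
#'   must be observed for that respondent to be imputed (default 0.5, the
#'   conventional half-scale rule).
#' @return An `impute_policy` object.
#' @export
impute_policy <- function(min_band = 0.05, max_band = 0.10,
                          min_observed_fraction = 0.5) {
  if (!(min_band > 0 && min_band <= max_band && max_band < 1)) {
    abort("require 0 < min_band <= max_band < 1.")
  }
  if (!(min_observed_fraction > 0 && min_observed_fraction <= 1)) {
    abort("require 0 < min_observed_fraction <= 1.")
  }
  structure(list(min_band = min_band, max_band = max_band,
                 min_observed_fraction = min_observed_fraction),
            class = "impute_policy")
}

#' Within-domain (person-mean) imputation of instrument scores
#'
#' Completes partially answered instruments by replacing each missing item
#' with the mean of that respondent's observed items on the same instrument,
#' after reverse-coding. A respondent is only imputed when at least
#' `min_observed_fraction` of their items are observed; others keep a missing
#' score. The whole step is gated on the cohort missingness rate lying inside
#' the policy band -- outside it, scores pass through unchanged.
#'
#' Imputation is idempotent and imputed scores always lie inside the
#' instrument's attainable range.
#'
#' @param item_table Data frame of item responses, one row per respondent.
#' @param def A [scale_def()].
#' @param policy An [impute_policy()].
#' @param cohort_missing_rate Fraction of respondents with an incomplete
#'   instrument; computed from `item_table` when `NULL`.
#' @return A list of class `scale_imputation`: `score` (completed score
#'   vector), `applied` (was the band condition met), `missing_rate`,
#'   `items` (the completed item table, on the original response coding),
#'   and `log`, a tibble recording every imputed cell (`row`, `item`,
#'   `value` on the reverse-coded scale).
#' @export
within_domain_impute <- function(item_table, def, policy = impute_policy(),
                                 cohort_missing_rate = NULL) {
  mat <- apply_reverse(item_matrix(item_table, def), def)
  incomplete <- rowSums(is.na(mat)) > 0L
  rate <- cohort_missing_rate %||% mean(incomplete)
  applied <- rate >= policy$min_band && rate <= policy$max_band

  log <- tibble::tibble(row = integer(), item = character(), value = double())
  if (applied && any(incomplete)) {
    k <- ncol(mat)
    for (r in which(incomplete)) {
      obs <- !is.na(mat[r, ])
      if (sum(obs) / k >= policy$min_observed_fraction && sum(obs) > 0L) {
        fill <- mean(mat[r, obs])
        miss_items <- which(!obs)
        mat[r, miss_items] <- fill
        log <- dplyr::bind_rows(log, tibble::tibble(
          row = r, item = def$items[miss_items], value = fill))
      }
    }
  }
  scores <- if (def$aggregation == "sum") rowSums(mat) else rowMeans(mat)
  completed <- apply_reverse(mat, def)  # reflection is its own inverse
  completed <- tibble::as_tibble(as.data.frame(completed))
  structure(list(score = as.numeric(scores), applied = applied,
                 missing_rate = rate, items = completed,
                 log = log, scale = def$name),
            class = "scale_imputation")
}

#' @export
print.scale_imputation <- function(x, ...) {
  cat(sprintf("<scale_imputation> %s: missing rate %.1f%%, %s, %d cell(s) imputed\n",
              x$scale, 100 * x$missing_rate,
              if (x$applied) "band met" else "outside band (no imputation)",
              nrow(x$log)))
  invisible(x)
}
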