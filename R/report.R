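#' Render the stability results as a publication-shaped table
#'
#' One row per model term, in the conventional layout: global-model estimate
#' with 95\% limits, bootstrap inclusion frequency, selected-model estimate
#' with limits (blank for terms eliminated from the selected model), RMSD
#' ratio, RC bias, and the final bootstrap estimate with its 2.5th/97.5th
#' percentiles and standardized value. Numbers are rounded to 3 decimals in
#' the rendered table only; the underlying objects keep full precision.
#'
#' @param x A `pipeline_run` or `stability` object.
#' @param path Optional CSV output path.
#' @param markdown_path Optional path for a markdown rendering.
#' @return The rendered tibble.
#' @export
render_stability_table <- function(x, path = NULL, markdown_path = NULL) {
  stab <- if (inherits(x, "pipeline_run")) x$stability else x
  stopifnot(inherits(stab, "stability"))
  sel <- tidy(stab$selection$fit)
  g <- tidy(stab$global_fit)
  tab <- tidy(stab) |>
    dplyr::left_join(
      dplyr::select(sel, "term", beta_selected = "estimate",
                    sel_conf.low = "conf.low", sel_conf.high = "conf.high"),
      by = "term"
    ) |>
    dplyr::mutate(global_2_5 = g$conf.low[match(.data$term, g$term)],
                  global_97_5 = g$conf.high[match(.data$term, g$term)]) |>
    dplyr::transmute(
      term = .data$term,
      beta_global = round(.data$beta_global, 3),
      global_2_5 = round(.data$global_2_5, 3),
      global_97_5 = round(.data$global_97_5, 3),
      inclusion_frequency = round(.data$inclusion_frequency, 3),
      beta_selected = round(.data$beta_selected, 3),
      sel_2_5 = round(.data$sel_conf.low, 3),
      sel_97_5 = round(.data$sel_conf.high, 3),
      rmsd_ratio = round(.data$rmsd_ratio, 3),
      rc_bias_pct = round(.data$rc_bias_pct, 3),
      beta_b = round(.data$beta_b, 3),
      pct_2_5 = round(.data$pct_2_5, 3),
      pct_97_5 = round(.data$pct_97_5, 3),
      std_beta_b = round(.data$std_beta_b, 3)
    )
  if (!is.null(path)) readr::write_csv(tab, path, na = "")
  if (!is.null(markdown_path)) writeLines(markdown_table(tab), markdown_path)
  tab
}

# Minimal pipe-table markdown rendering.
markdown_table <- function(df) {
  cells <- vapply(df, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- ""
    out
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep(" --- ", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, body)
}

#' Write all pipeline outputs to a directory
#'
#' Emits `global_model.csv`, `selected_model.csv`, `stability.csv`,
#' `stability.md` and `manifest.json` (full precision in the JSON; rounding
#' only in the rendered tables).
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "pipeline_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(run$global_fit), file.path(dir, "global_model.csv"), na = "")
  readr::write_csv(tidy(run$selection$fit), file.path(dir, "selected_model.csv"), na = "")
  render_stability_table(run, path = file.path(dir, "stability.csv"),
                         markdown_path = file.path(dir, "stability.md"))
  manifest <- c(run$manifest, as.list(glance(run$stability)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
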