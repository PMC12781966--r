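#' Declare metadata for one analysis variable
#'
#' Each column of a cohort table carries a role (how the modelling stage
#' treats it) and a type (how it enters the design matrix). Categorical
#' variables declare their level set and a reference level; genotype-style
#' dose variables are continuous but restricted to \{0, 1, 2\} copies of the
#' minor allele, matching additive genetic coding.
#'
#' @param name Column name (unique within a cohort).
#' @param role One of `"outcome"`, `"forced"`, `"candidate"`, `"id"`,
#'   `"stratum"`. Forced variables are exempt from backward elimination and
#'   appear in every bootstrap resample's model.
#' @param vtype One of `"continuous"`, `"binary"`, `"categorical"`, `"dose"`.
#' @param levels Character vector of allowed levels (binary/categorical).
#' @param reference_level Reference category absorbed into the intercept;
#'   defaults to the first level.
#' @param recode Optional named vector mapping raw strings to numeric doses,
#'   e.g. `c(GG = 0, AG = 1, AA = 2)` for an additive genotype.
#'
#' @return A one-row tibble; bind rows of these to form a metadata table.
#' @export
#' @examples
#' var_meta("hba1c", "outcome", "continuous")
#' var_meta("genotype", "forced", "dose", recode = c(GG = 0, AG = 1, AA = 2))
var_meta <- function(name, role, vtype,
                     levels = NULL, reference_level = NULL, recode = NULL) {
  role <- match.arg(role, c("outcome", "forced", "candidate", "id", "stratum"))
  vtype <- match.arg(vtype, c("continuous", "binary", "categorical", "dose"))
  if (vtype %in% c("binary", "categorical")) {
    if (is.null(levels)) {
      if (vtype == "binary") levels <- c("No", "Yes")
      else abort(sprintf("categorical variable '%s' must declare `levels`.", name))
    }
    if (vtype == "binary" && length(levels) != 2L) {
      abort(sprintf("binary variable '%s' must have exactly 2 levels.", name))
    }
    levels <- as.character(levels)
    if (anyDuplicated(levels)) {
      abort(sprintf("duplicate levels declared for '%s'.", name))
    }
    reference_level <- reference_level %||% levels[[1L]]
    if (!reference_level %in% levels) {
      abort(sprintf("reference_level '%s' of '%s' is not among its levels.",
                    reference_level, name))
    }
  } else {
    levels <- NULL
    reference_level <- NA_character_
  }
  tibble::tibble(
    name = as.character(name),
    role = role,
    vtype = vtype,
    reference_level = as.character(reference_level),
    levels = list(levels),
    recode = list(recode)
  )
}

validate_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  needed <- c("name", "role", "vtype", "reference_level", "levels", "recode")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) {
    abort(paste0("metadata table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$name)) {
    abort("variable names in metadata must be unique.")
  }
  n_outcome <- sum(meta$role == "outcome")
  if (n_outcome != 1L) {
    abort(sprintf("exactly one variable must have role = 'outcome' (found %d).",
                  n_outcome))
  }
  invisible(meta)
}

#' Read variable metadata from a YAML or JSON file
#'
#' The file holds a top-level `variables:` list; each entry supplies the
#' fields of [var_meta()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` metadata file.
#' @return A metadata tibble.
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  vars <- raw[["variables"]] %||% raw
  meta <- purrr::map_dfr(vars, function(v) {
    recode <- v$recode
    if (!is.null(recode)) recode <- unlist(recode)
    var_meta(v$name, v$role, v$vtype,
             levels = unlist(v$levels),
             reference_level = v$reference_level,
             recode = recode)
  })
  validate_meta(meta)
}

#' Write variable metadata to YAML
#'
#' @param meta A metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta <- function(meta, path) {
  validate_meta(meta)
  vars <- purrr::pmap(meta, function(name, role, vtype, reference_level,
                                     levels, recode) {
    v <- list(name = name, role = role, vtype = vtype)
    if (!is.null(levels)) {
      v$levels <- as.list(levels)
      v$reference_level <- reference_level
    }
    if (!is.null(recode)) v$recode <- as.list(recode)
    v
  })
  yaml::write_yaml(list(variables = vars), path)
  invisible(path)
}

#' Assemble a typed cohort table
#'
#' Binds a per-participant data frame to its variable metadata, recodes and
#' type-checks every column, and returns a tibble carrying the metadata as an
#' attribute. Missing values must be `NA` (CSV readers map empty cells and
#' `"NA"` there).
#'
#' Validation enforced here: every metadata variable present as a column, no
#' undeclared columns, categorical values within declared levels (error names
#' the offending row), dose values in \{0, 1, 2\}, and strictly positive
#' outcome values where observed (HbA1c is a percentage of total hemoglobin).
#'
#' @param data A data frame of participant records.
#' @param meta A metadata tibble built from [var_meta()] rows or [read_meta()].
#' @return A `cohort_tbl` tibble; retrieve metadata with [var_meta_of()].
#' @export
cohort <- function(data, meta) {
  validate_meta(meta)
  data <- tibble::as_tibble(data)
  unknown <- setdiff(names(data), meta$name)
  if (length(unknown)) {
    abort(paste0("column(s) not declared in metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  outcome <- meta$name[meta$role == "outcome"]
  if (!outcome %in% names(data)) {
    abort(sprintf("outcome column '%s' is missing from the data.", outcome))
  }
  absent <- setdiff(meta$name, names(data))
  if (length(absent)) {
    abort(paste0("declared column(s) absent from the data: ",
                 paste(absent, collapse = ", ")))
  }

  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[[i]]
    vtype <- meta$vtype[[i]]
    recode <- meta$recode[[i]]
    col <- data[[nm]]
    if (!is.null(recode)) {
      raw <- as.character(col)
      as_num <- suppressWarnings(as.numeric(raw))
      mapped <- raw %in% names(recode)
      already <- !is.na(as_num) & as_num %in% recode
      known <- mapped | already | is.na(raw)
      if (!all(known)) {
        bad <- which(!known)[[1L]]
        abort(sprintf("row %d: value '%s' of '%s' not in recode map.",
                      bad, raw[[bad]], nm))
      }
      col <- ifelse(mapped, unname(recode[raw]), as_num)
    }
    if (vtype %in% c("continuous", "dose")) {
      col <- suppressWarnings(as.numeric(as.character(col)))
      if (vtype == "dose") {
        ok <- is.na(col) | col %in% c(0, 1, 2)
        if (!all(ok)) {
          abort(sprintf("row %d: dose value of '%s' must be 0, 1 or 2.",
                        which(!ok)[[1L]], nm))
        }
      }
    } else {
      lv <- meta$levels[[i]]
      raw <- as.character(col)
      ok <- raw %in% lv | is.na(raw)
      if (!all(ok)) {
        bad <- which(!ok)[[1L]]
        abort(sprintf("row %d: value '%s' of '%s' not among declared levels (%s).",
                      bad, raw[[bad]], nm, paste(lv, collapse = ", ")))
      }
      ref <- meta$reference_level[[i]]
      col <- factor(raw, levels = c(ref, setdiff(lv, ref)))
    }
    data[[nm]] <- col
  }

  out_vals <- data[[outcome]]
  if (any(!is.na(out_vals) & out_vals <= 0)) {
    abort(sprintf("outcome '%s' must be strictly positive where observed.",
                  outcome))
  }

  structure(data, meta = meta, class = c("cohort_tbl", class(data)))
}

#' Retrieve the variable metadata of a cohort table
#'
#' @param x A `cohort_tbl`.
#' @return The metadata tibble attached by [cohort()].
#' @export
var_meta_of <- function(x) {
  meta <- attr(x, "meta", exact = TRUE)
  if (is.null(meta)) abort("`x` carries no variable metadata; build it with cohort().")
  meta
}

#' Read a cohort CSV together with its metadata file
#'
#' Empty cells and the literal string `"NA"` are treated as missing. All
#' typing, recoding (e.g. genotype strings to additive dose) and validation
#' are delegated to [cohort()].
#'
#' @param path Path to the participant CSV (header row required).
#' @param meta_path Path to the YAML/JSON metadata file.
#' @return A `cohort_tbl`.
#' @export
read_cohort <- function(path, meta_path) {
  if (!file.exists(path)) abort(sprintf("data file not found: %s", path))
  meta <- read_meta(meta_path)
  data <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          na = c("", "NA"), progress = FALSE)
  cohort(data, meta)
}

#' Write a cohort table (and optionally its metadata) to disk
#'
#' Factor columns are written as their level labels; a round trip through
#' [read_cohort()] reproduces the table value-for-value.
#'
#' @param x A `cohort_tbl`.
#' @param path Output CSV path.
#' @param meta_path Optional YAML path for the metadata.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, meta_path = NULL) {
  meta <- var_meta_of(x)
  out <- tibble::as_tibble(x)
  for (nm in names(out)) {
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  readr::write_csv(out, path, na = "")
  if (!is.null(meta_path)) write_meta(meta, meta_path)
  invisible(path)
}

#' Classify HbA1c values into glycemic categories
#'
#' Applies the standard clinical cutpoints: values of 6.5\% or more indicate
#' diabetes, 5.7\% up to (but excluding) 6.5\% indicate prediabetes, and
#' anything below 5.7\% is classified as normal. Both boundaries are inclusive
#' on their lower side.
#'
#' @param value Numeric vector of HbA1c percentages; must be positive.
#' @return A factor with levels `normal`, `prediabetes`, `diabetes`.
#' @export
#' @examples
#' classify_hba1c(c(5.4, 5.7, 6.49, 6.5))
classify_hba1c <- function(value) {
  if (!is.numeric(value)) abort("HbA1c values must be numeric.")
  if (any(!is.na(value) & value <= 0)) {
    abort("HbA1c values must be strictly positive.")
  }
  out <- ifelse(is.na(value), NA_character_,
                ifelse(value >= 6.5, "diabetes",
                       ifelse(value >= 5.7, "prediabetes", "normal")))
  factor(out, levels = c("normal", "prediabetes", "diabetes"))
}
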