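#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the structure of a Samoan adult cohort assembled for
#' HbA1c correlate analysis: n = 349 participants, 53\% female, an additive
#' genotype dose with population frequencies 0.43/0.40/0.17 for 0/1/2 minor
#' allele copies, anthropometry (BMI mean 36.1 SD 7.9, abdominal
#' circumference correlated with BMI at r = 0.9), psychosocial scale scores
#' on their instrument ranges, three standardized dietary pattern scores, and
#' behavioural/demographic variables at realistic prevalences. The outcome is
#' linear in the covariates: default true coefficients are at the scale of
#' published HbA1c effects (age 0.020 per year, genotype dose -0.339 per A
#' copy, abdominal circumference 0.035 per cm, stress 0.032, social support
#' 0.320, self-efficacy -0.024, mixed-traditional diet -0.120; all other
#' candidates 0), with Gaussian noise of SD 0.54 so the marginal HbA1c SD is
#' about 0.9 and an intercept of 0.70 centring HbA1c near 6.0\%.
#'
#' @param n Sample size.
#' @param seed Integer seed.
#' @param intercept Outcome-model intercept (HbA1c \%).
#' @param true_coefficients Named numeric vector of per-variable effects;
#'   binary effects apply to the non-reference indicator, categorical effects
#'   are keyed `"variable_level"`.
#' @param noise_sd Residual SD of the outcome model (> 0).
#' @param hba1c_floor Lower clamp on generated HbA1c (default 4.0\%).
#' @param genotype_probs Probabilities of dose 0/1/2 (sum to 1).
#' @param sex_prob_female Probability of female sex.
#' @param correlation Tibble/data frame with columns `var1`, `var2`, `r`
#'   declaring pairwise correlations among continuous covariates (the
#'   implied matrix must be positive definite).
#' @param missing_rates Named per-variable missing fractions for
#'   [inject_missingness()]; defaults put 5--10\% missingness on the
#'   scale-score variables an imputation stage should see.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 349L, seed = 1L,
                             intercept = 0.70,
                             true_coefficients = NULL,
                             noise_sd = 0.54,
                             hba1c_floor = 4.0,
                             genotype_probs = c(0.43, 0.40, 0.17),
                             sex_prob_female = 0.53,
                             correlation = NULL,
                             missing_rates = NULL) {
  if (abs(sum(genotype_probs) - 1) > 1e-8 || length(genotype_probs) != 3L) {
    abort("genotype_probs must be 3 probabilities summing to 1.")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive.")
  true_coefficients <- true_coefficients %||% c(
    age = 0.020, genotype = -0.339, abdominal_circumference = 0.035,
    stress = 0.032, social_support = 0.320, self_efficacy = -0.024,
    diet_mixed_traditional = -0.120
  )
  correlation <- correlation %||% tibble::tibble(
    var1 = "bmi", var2 = "abdominal_circumference", r = 0.9
  )
  missing_rates <- missing_rates %||% c(
    household_assets = 0.06, sf8_physical = 0.055, sf8_mental = 0.055,
    stress = 0.07, social_conflict = 0.08, social_support = 0.06
  )
  structure(
    list(n = as.integer(n), seed = as.integer(seed), intercept = intercept,
         true_coefficients = true_coefficients, noise_sd = noise_sd,
         hba1c_floor = hba1c_floor, genotype_probs = genotype_probs,
         sex_prob_female = sex_prob_female, correlation = correlation,
         missing_rates = missing_rates,
         variables = default_variable_table(sex_prob_female)),
    class = "generator_config"
  )
}

# Covariate distribution table: continuous rows carry mean/sd and the
# instrument/plausibility range the draw is clipped to; binary rows a
# prevalence; categorical rows level probabilities.
default_variable_table <- function(sex_prob_female) {
  cont <- function(name, role, mean, sd, min, max) {
    tibble::tibble(name = name, role = role, vtype = "continuous",
                   mean = mean, sd = sd, min = min, max = max,
                   p = NA_real_, levels = list(NULL), probs = list(NULL))
  }
  bin <- function(name, role, p, levels = c("No", "Yes")) {
    tibble::tibble(name = name, role = role, vtype = "binary",
                   mean = NA_real_, sd = NA_real_, min = NA_real_,
                   max = NA_real_, p = p, levels = list(levels),
                   probs = list(NULL))
  }
  dplyr::bind_rows(
    cont("age", "forced", 51.3, 9.8, 30, 73),
    bin("sex", "forced", sex_prob_female, c("Male", "Female")),
    cont("bmi", "forced", 36.1, 7.9, 20, 77),
    tibble::tibble(name = "genotype", role = "forced", vtype = "dose",
                   mean = NA_real_, sd = NA_real_, min = NA_real_,
                   max = NA_real_, p = NA_real_, levels = list(NULL),
                   probs = list(NULL)),
    cont("abdominal_circumference", "candidate", 113.7, 16.4, 76, 179),
    cont("fat_mass_index", "candidate", 14.0, 5.9, 1.9, 42.3),
    cont("education", "candidate", 11.3, 2.7, 0, 19),
    cont("household_assets", "candidate", 7.9, 3.9, 0, 18),
    bin("partnered", "candidate", 0.83),
    cont("sf8_physical", "candidate", 43.8, 8.3, 0, 100),
    cont("sf8_mental", "candidate", 46.7, 9.6, 0, 100),
    cont("self_efficacy", "candidate", 52.8, 5.6, 17, 85),
    cont("social_support", "candidate", 3.9, 0.5, 1, 5),
    cont("self_esteem", "candidate", 30.7, 3.9, 10, 40),
    cont("stress", "candidate", 17.8, 5.6, 0, 40),
    cont("social_conflict", "candidate", 12.0, 4.0, 6, 30),
    cont("discrimination", "candidate", 4.0, 5.0, 0, 50),
    cont("food_security", "candidate", 0.35, 1.25, 0, 27),
    bin("alcohol", "candidate", 0.09),
    bin("smoker", "candidate", 0.40),
    bin("mvpa_active", "candidate", 0.29),
    tibble::tibble(name = "region", role = "candidate", vtype = "categorical",
                   mean = NA_real_, sd = NA_real_, min = NA_real_,
                   max = NA_real_, p = NA_real_,
                   levels = list(c("AUA", "NWU", "ROU")),
                   probs = list(c(0.21, 0.39, 0.40))),
    cont("diet_mixed_traditional", "candidate", 0, 1, -Inf, Inf),
    cont("diet_modern", "candidate", 0, 1, -Inf, Inf),
    cont("diet_health_conscious", "candidate", 0, 1, -Inf, Inf)
  )
}

#' Generate a synthetic cohort table
#'
#' Draws covariates from the configured distributions (continuous variables
#' jointly normal under the declared correlation pairs, then clipped to their
#' score ranges), assembles the outcome as
#' `HbA1c = intercept + sum(true_coefficients * x) + N(0, noise_sd)`,
#' clamped below at `hba1c_floor`, and returns a fully typed [cohort()] with
#' roles set for downstream modelling. The generating truth (intercept,
#' coefficient vector, noise SD) is attached as the `ground_truth` attribute.
#'
#' @param config A [generator_config()].
#' @return A `cohort_tbl` of `config$n` rows.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  vars <- config$variables
  n <- config$n
  with_seed(config$seed, {
    cont <- vars[vars$vtype == "continuous", , drop = FALSE]
    Z <- draw_correlated(n, cont$name, config$correlation)
    data <- tibble::tibble(.rows = n)
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      data[[v$name]] <- switch(
        v$vtype,
        continuous = pmin(pmax(v$mean + v$sd * Z[, v$name], v$min), v$max),
        dose = sample(0:2, n, replace = TRUE, prob = config$genotype_probs),
        binary = {
          lv <- v$levels[[1L]]
          factor(lv[1L + rbinom(n, 1L, v$p)], levels = lv)
        },
        categorical = {
          lv <- v$levels[[1L]]
          factor(sample(lv, n, replace = TRUE, prob = v$probs[[1L]]), levels = lv)
        }
      )
    }
    lp <- rep(config$intercept, n)
    tc <- config$true_coefficients
    for (key in names(tc)) {
      if (key %in% vars$name) {
        v <- vars[vars$name == key, ]
        xv <- data[[key]]
        x <- if (v$vtype %in% c("continuous", "dose")) as.numeric(xv)
        else as.numeric(xv == base::levels(xv)[-1L][1L])
        lp <- lp + tc[[key]] * x
      } else {
        hit <- purrr::detect(vars$name, function(nm) startsWith(key, paste0(nm, "_")))
        if (is.null(hit)) abort(sprintf("true coefficient '%s' matches no variable.", key))
        level <- sub(paste0("^", hit, "_"), "", key)
        lp <- lp + tc[[key]] * as.numeric(data[[hit]] == level)
      }
    }
    data[["hba1c"]] <- pmax(lp + rnorm(n, 0, config$noise_sd), config$hba1c_floor)
  })

  meta <- dplyr::bind_rows(
    var_meta("hba1c", "outcome", "continuous"),
    purrr::map_dfr(seq_len(nrow(vars)), function(i) {
      v <- vars[i, ]
      var_meta(v$name, v$role, v$vtype, levels = v$levels[[1L]])
    })
  )
  out <- cohort(data[, meta$name], meta)
  attr(out, "ground_truth") <- list(
    intercept = config$intercept,
    coefficients = config$true_coefficients,
    noise_sd = config$noise_sd,
    seed = config$seed
  )
  out
}

# Draw n x length(vars) standard normals with the declared pairwise
# correlations (identity elsewhere).
draw_correlated <- function(n, vars, correlation) {
  p <- length(vars)
  R <- diag(p)
  dimnames(R) <- list(vars, vars)
  if (!is.null(correlation) && nrow(correlation)) {
    for (i in seq_len(nrow(correlation))) {
      v1 <- correlation$var1[[i]]; v2 <- correlation$var2[[i]]
      if (!all(c(v1, v2) %in% vars)) {
        abort(sprintf("correlation pair (%s, %s) names unknown continuous variables.",
                      v1, v2))
      }
      R[v1, v2] <- R[v2, v1] <- correlation$r[[i]]
    }
  }
  ch <- tryCatch(chol(R), error = function(e)
    abort("declared correlation matrix is not positive definite."))
  Z <- matrix(rnorm(n * p), n, p) %*% ch
  colnames(Z) <- vars
  Z
}

#' Set values missing completely at random
#'
#' Each named variable has its cells independently blanked at the stated
#' rate. By default the outcome and forced covariates are protected (their
#' rates are ignored with a warning), since the modelling stage requires
#' them observed.
#'
#' @param table A `cohort_tbl`.
#' @param rates Named fractions in `[0, 1)`.
#' @param seed Integer seed.
#' @param protect Protect outcome/forced variables (default `TRUE`).
#' @return The table with injected missing values.
#' @export
inject_missingness <- function(table, rates, seed = 1L, protect = TRUE) {
  meta <- var_meta_of(table)
  if (any(rates >= 1) || any(rates < 0)) abort("rates must lie in [0, 1).")
  unknown <- setdiff(names(rates), meta$name)
  if (length(unknown)) {
    abort(paste0("rates name unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  if (protect) {
    shielded <- intersect(names(rates), meta$name[meta$role %in% c("outcome", "forced")])
    if (length(shielded)) {
      warn(paste0("ignoring missingness rates on protected variable(s): ",
                  paste(shielded, collapse = ", ")))
      rates <- rates[setdiff(names(rates), shielded)]
    }
  }
  with_seed(seed, {
    for (nm in names(rates)) {
      hit <- runif(nrow(table)) < rates[[nm]]
      table[[nm]][hit] <- NA
    }
  })
  table
}

#' Generate a food-frequency table with planted block structure
#'
#' Food-group intakes are built from `n_blocks` latent factors: groups in the
#' same block share a latent factor with within-block correlation
#' `within_block_r` (zero correlation across blocks), giving the pattern
#' extraction step a known structure to recover. Total energy intake is
#' positively correlated with overall intake.
#'
#' @param n Participants.
#' @param n_groups Number of food groups (must be divisible by `n_blocks`).
#' @param n_blocks Number of latent dietary patterns planted.
#' @param within_block_r Within-block correlation in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list: `groups` (participants-by-groups tibble), `energy`
#'   (kcal/day vector), and `blocks` (tibble mapping group to planted block).
#' @export
generate_ffq <- function(n = 349L, n_groups = 12L, n_blocks = 3L,
                         within_block_r = 0.8, seed = 1L) {
  if (n_groups %% n_blocks != 0L) {
    abort("n_groups must be divisible by n_blocks.")
  }
  if (within_block_r < 0 || within_block_r >= 1) {
    abort("within_block_r must lie in [0, 1).")
  }
  per <- n_groups %/% n_blocks
  block_of <- rep(seq_len(n_blocks), each = per)
  group_names <- paste0("group", sprintf("%02d", seq_len(n_groups)))
  with_seed(seed, {
    latent <- matrix(rnorm(n * n_blocks), n, n_blocks)
    noise <- matrix(rnorm(n * n_groups), n, n_groups)
    z <- sqrt(within_block_r) * latent[, block_of, drop = FALSE] +
      sqrt(1 - within_block_r) * noise
    groups <- 10 + 3 * z  # weekly serving frequency scale
    colnames(groups) <- group_names
    energy <- 2000 + 15 * rowSums(z) + rnorm(n, 0, 150)
    energy <- pmax(energy, 800)
  })
  list(groups = tibble::as_tibble(groups), energy = energy,
       blocks = tibble::tibble(group = group_names, block = block_of))
}

#' Generate item-level responses for a multi-item instrument
#'
#' Each respondent has a latent trait; item responses are the trait plus
#' item noise, discretised onto the response range. Cells can then be
#' blanked completely at random, giving the imputation step realistic input.
#'
#' @param n Respondents.
#' @param def A [scale_def()].
#' @param cell_missing_rate Per-cell MCAR missingness fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble of item responses, one row per respondent.
#' @export
generate_scale_items <- function(n, def, cell_missing_rate = 0, seed = 1L) {
  if (cell_missing_rate < 0 || cell_missing_rate >= 1) {
    abort("cell_missing_rate must lie in [0, 1).")
  }
  k <- length(def$items)
  span <- def$response_max - def$response_min
  with_seed(seed, {
    trait <- rnorm(n)
    raw <- trait + matrix(rnorm(n * k, 0, 0.8), n, k)
    resp <- round(def$response_min + span * stats::pnorm(raw / sqrt(1 + 0.64)))
    resp <- pmin(pmax(resp, def$response_min), def$response_max)
    if (cell_missing_rate > 0) {
      resp[matrix(runif(n * k) < cell_missing_rate, n, k)] <- NA
    }
  })
  colnames(resp) <- def$items
  tibble::as_tibble(resp)
}
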