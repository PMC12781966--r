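#' Collapse food-frequency items into food groups
#'
#' Food items are summed within user-declared groups (grouping reflects
#' nutrient profile and culinary use and is study-specific, so it is always
#' supplied, never inferred).
#'
#' @param ffq Data frame, one row per participant, one column per food item.
#' @param map Named list: group name to character vector of item columns.
#'   Groups must be disjoint and every mapped item must exist in `ffq`.
#' @return Tibble of participants by groups (summed frequencies).
#' @export
group_foods <- function(ffq, map) {
  items <- unlist(map, use.names = FALSE)
  if (anyDuplicated(items)) abort("food groups must be disjoint.")
  missing_items <- setdiff(items, names(ffq))
  if (length(missing_items)) {
    abort(paste0("mapped item(s) absent from the FFQ table: ",
                 paste(missing_items, collapse = ", ")))
  }
  purrr::map_dfc(map, function(cols) {
    rowSums(as.matrix(ffq[, cols, drop = FALSE]))
  })
}

#' Energy-adjust group intakes by the residual method
#'
#' For each food group, intake is regressed on total energy intake and
#' replaced by its residual re-centred at the mean-energy prediction, i.e.
#' `adjusted = intake - slope * (energy - mean(energy))`. Adjusted intakes
#' are exactly uncorrelated with energy and unchanged by adding a constant
#' to the energy column.
#'
#' @param intake Data frame of per-participant group intakes.
#' @param energy Positive numeric vector of total energy intakes.
#' @return Tibble of adjusted intakes with an `energy_adjustment` attribute
#'   (per-group intercept/slope and the mean energy used).
#' @export
energy_adjust <- function(intake, energy) {
  intake <- tibble::as_tibble(intake)
  n <- nrow(intake)
  if (length(energy) != n) abort("`energy` must have one value per participant.")
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    abort("total energy intake must be positive and finite for all participants.")
  }
  if (n < 3L) abort("the residual method needs at least 3 participants.")
  if (var(energy) == 0) abort("energy has zero variance; the residual method is undefined.")
  e_bar <- mean(energy)
  e_c <- energy - e_bar
  sxx <- sum(e_c^2)
  fits <- purrr::map_dfr(names(intake), function(g) {
    y <- intake[[g]]
    slope <- sum(e_c * (y - mean(y))) / sxx
    tibble::tibble(group = g, intercept = mean(y) - slope * e_bar, slope = slope)
  })
  adjusted <- purrr::map_dfc(seq_along(intake), function(j) {
    intake[[j]] - fits$slope[[j]] * e_c
  })
  names(adjusted) <- names(intake)
  attr(adjusted, "energy_adjustment") <-
    dplyr::mutate(fits, mean_energy = e_bar)
  adjusted
}

#' Extract dietary pattern factors by the principal component method
#'
#' Principal components of the food-group correlation matrix are extracted in
#' descending eigenvalue order; the first `n_factors` are rotated with an
#' orthogonal (varimax) criterion so that each rotated factor loads cleanly
#' on a subset of groups. The number retained is a parameter (chosen in
#' practice from the scree plot, eigenvalues and explained variance, all of
#' which the model reports). Each factor's sign is fixed so its
#' largest-magnitude loading is positive, and rotated factors are ordered by
#' decreasing explained variance, making the output deterministic.
#'
#' @param adjusted_table Participants-by-groups table of (energy-adjusted)
#'   intakes; no missing cells; more participants than groups.
#' @param n_factors Number of factors to retain (default 3).
#' @param rotation `"varimax"` or `"none"`.
#' @return A `dietary_patterns` model holding rotated and unrotated loadings,
#'   all eigenvalues with the proportion of variance explained, the rotation
#'   matrix, the group centring/scaling, and the score scaling fixed on the
#'   fitting sample.
#' @export
extract_patterns <- function(adjusted_table, n_factors = 3L,
                             rotation = c("varimax", "none")) {
  rotation <- match.arg(rotation)
  X <- as.matrix(tibble::as_tibble(adjusted_table))
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("adjusted intake table must have no missing cells.")
  if (nrow(X) <= ncol(X)) abort("need more participants than food groups.")
  groups <- colnames(X)
  R <- cor(X)
  eig <- eigen(R, symmetric = TRUE)
  rank_tol <- 1e-10 * max(eig$values)
  if (n_factors > sum(eig$values > rank_tol)) {
    abort("n_factors exceeds the rank of the group correlation matrix.")
  }
  lambda <- eig$values
  L <- eig$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(n_factors)]), n_factors)
  rot <- diag(n_factors)
  L_rot <- L
  if (rotation == "varimax" && n_factors > 1L) {
    vm <- varimax(L, normalize = TRUE, eps = 1e-10)
    rot <- unclass(vm$rotmat)
    L_rot <- L %*% rot
  }
  # deterministic sign and order
  flip <- apply(L_rot, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  L_rot <- sweep(L_rot, 2L, flip, `*`)
  rot <- sweep(rot, 2L, flip, `*`)
  ss <- colSums(L_rot^2)
  ord <- order(ss, decreasing = TRUE)
  L_rot <- L_rot[, ord, drop = FALSE]
  rot <- rot[, ord, drop = FALSE]
  factor_names <- paste0("factor", seq_len(n_factors))
  dimnames(L_rot) <- list(groups, factor_names)

  centers <- colMeans(X)
  scales <- apply(X, 2L, sd)
  if (any(scales == 0)) abort("a food group has zero variance; drop it before extraction.")
  # regression-method scoring weights: F = Z R^{-1} Lambda
  weights <- solve(R, L_rot)
  Z <- sweep(sweep(X, 2L, centers), 2L, scales, `/`)
  F_raw <- Z %*% weights
  score_center <- colMeans(F_raw)
  score_scale <- apply(F_raw, 2L, sd)

  structure(
    list(groups = groups, n_factors = n_factors, rotation = rotation,
         loadings = L_rot,
         unrotated_loadings = `dimnames<-`(L, list(groups, factor_names)),
         rotation_matrix = rot,
         eigenvalues = lambda,
         prop_variance = lambda / length(lambda),
         energy_adjustment = attr(adjusted_table, "energy_adjustment"),
         group_center = centers, group_scale = scales,
         score_weights = weights,
         score_center = score_center, score_scale = score_scale),
    class = "dietary_patterns"
  )
}

#' @export
print.dietary_patterns <- function(x, ...) {
  cat(sprintf("<dietary_patterns> %d factor(s) over %d food groups (%s rotation)\n",
              x$n_factors, length(x$groups), x$rotation))
  cat(sprintf("  variance explained by retained components: %.1f%%\n",
              100 * sum(x$prop_variance[seq_len(x$n_factors)])))
  invisible(x)
}

#' Score participants on fitted dietary patterns
#'
#' Applies regression-method factor scoring with the rotated loadings, then
#' standardises with the centre/scale fixed on the fitting sample, so that
#' fitting-sample scores have mean 0 and SD 1 per factor and higher scores
#' mean greater adherence to the pattern.
#'
#' @param model A [extract_patterns()] fit.
#' @param adjusted_table Participants-by-groups table on the same groups.
#' @return Tibble of factor scores (one column per retained factor).
#' @export
score_patterns <- function(model, adjusted_table) {
  X <- as.matrix(tibble::as_tibble(adjusted_table))
  missing_groups <- setdiff(model$groups, colnames(X))
  if (length(missing_groups)) {
    abort(paste0("table lacks food group(s): ", paste(missing_groups, collapse = ", ")))
  }
  X <- X[, model$groups, drop = FALSE]
  storage.mode(X) <- "double"
  Z <- sweep(sweep(X, 2L, model$group_center), 2L, model$group_scale, `/`)
  F_raw <- Z %*% model$score_weights
  scores <- sweep(sweep(F_raw, 2L, model$score_center), 2L, model$score_scale, `/`)
  tibble::as_tibble(scores)
}

#' @describeIn extract_patterns Tidy the rotated loadings into a long tibble.
#' @param x A `dietary_patterns` model.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dietary_patterns <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "group") |>
    tidyr::pivot_longer(-"group", names_to = "factor", values_to = "loading")
}

#' @describeIn extract_patterns One-row model summary (factors retained,
#'   variance explained).
#' @exportS3Method generics::glance
glance.dietary_patterns <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$groups),
    n_factors = x$n_factors,
    rotation = x$rotation,
    prop_variance_retained = sum(x$prop_variance[seq_len(x$n_factors)])
  )
}

#' @describeIn extract_patterns Loadings bar chart, one panel per factor.
#' @param object A `dietary_patterns` model.
#' @exportS3Method ggplot2::autoplot
autoplot.dietary_patterns <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$loading, y = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$factor)) +
    ggplot2::labs(x = "rotated loading", y = NULL)
}
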