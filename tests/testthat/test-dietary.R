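test_that("residual-method energy adjustment matches hand least squares", {
  # perfectly linear intake on energy: every residual is 0, prediction at
  # mean energy is 2, so every adjusted value is 2
  adj <- energy_adjust(tibble::tibble(g = c(1, 2, 3)), energy = c(1, 2, 3))
  expect_equal(adj$g, rep(2, 3))

  # zero sample covariance with energy: adjustment is the identity
  adj0 <- energy_adjust(tibble::tibble(g = c(4, 6, 4)), energy = c(1, 2, 3))
  expect_equal(adj0$g, c(4, 6, 4))
})

test_that("adjusted intakes are uncorrelated with energy and shift-invariant", {
  withr::with_seed(5, {
    energy <- runif(80, 1500, 3500)
    intake <- tibble::tibble(a = 2 + 0.001 * energy + rnorm(80),
                             b = rnorm(80, 10))
  })
  adj <- energy_adjust(intake, energy)
  expect_lt(abs(cor(adj$a, energy)), 1e-10)
  expect_lt(abs(cor(adj$b, energy)), 1e-10)
  shifted <- energy_adjust(intake, energy + 500)
  expect_equal(as.matrix(adj), as.matrix(shifted))
  expect_error(energy_adjust(intake, rep(2000, 80)), "zero variance")
  expect_error(energy_adjust(intake[1:2, ], energy[1:2]), "3 participants")
  expect_error(energy_adjust(intake, -energy), "positive")
})

test_that("food grouping validates the map and sums item frequencies", {
  ffq <- tibble::tibble(taro = c(1, 2), bread = c(3, 4), fish = c(5, 6))
  out <- group_foods(ffq, list(staples = c("taro", "bread"), protein = "fish"))
  expect_equal(out$staples, c(4, 6))
  expect_equal(out$protein, c(5, 6))
  expect_error(group_foods(ffq, list(a = "taro", b = c("taro", "fish"))), "disjoint")
  expect_error(group_foods(ffq, list(a = "coconut")), "coconut")
})

test_that("eigenvalues match an independent decomposition and sum to the trace", {
  ffq <- generate_ffq(n = 200, seed = 21)
  adj <- energy_adjust(ffq$groups, ffq$energy)
  model <- extract_patterns(adj, n_factors = 3)
  # independent oracle: singular values of the standardized data matrix
  Z <- scale(as.matrix(adj))
  sv <- svd(Z)$d
  expect_equal(model$eigenvalues, sv^2 / (nrow(Z) - 1), tolerance = 1e-8)
  expect_equal(sum(model$eigenvalues), ncol(adj), tolerance = 1e-8)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
})

test_that("rotation is orthonormal and preserves the reconstructed correlation", {
  ffq <- generate_ffq(n = 300, seed = 3)
  adj <- energy_adjust(ffq$groups, ffq$energy)
  model <- extract_patterns(adj, n_factors = 3)
  R <- model$rotation_matrix
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-8)
  L <- model$unrotated_loadings
  Lr <- model$loadings
  expect_equal(Lr %*% t(Lr), L %*% t(L), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("planted 3-block structure is recovered with block-aligned loadings", {
  ffq <- generate_ffq(n = 600, n_groups = 12, n_blocks = 3,
                      within_block_r = 0.8, seed = 9)
  adj <- energy_adjust(ffq$groups, ffq$energy)
  model <- extract_patterns(adj, n_factors = 3)
  abs_load <- abs(model$loadings)
  # each factor's dominant block outweighs its cross-block loadings
  dominant <- integer(3)
  for (f in 1:3) {
    block_means <- tapply(abs_load[, f], ffq$blocks$block, mean)
    dominant[f] <- which.max(block_means)
    expect_gt(max(block_means), max(block_means[-which.max(block_means)]) * 2)
  }
  # the three factors pick up three distinct blocks
  expect_setequal(dominant, 1:3)
})

test_that("uncorrelated groups give leading eigenvalues near 1", {
  ffq <- generate_ffq(n = 5000, n_groups = 12, n_blocks = 3,
                      within_block_r = 0, seed = 13)
  adj <- energy_adjust(ffq$groups, ffq$energy)
  model <- extract_patterns(adj, n_factors = 3)
  expect_lt(abs(model$eigenvalues[1] - 1), 0.15)
})

test_that("factor scores are standardized, centred and deterministic", {
  ffq <- generate_ffq(n = 250, seed = 31)
  adj <- energy_adjust(ffq$groups, ffq$energy)
  model <- extract_patterns(adj, n_factors = 3)
  scores <- score_patterns(model, adj)
  expect_equal(ncol(scores), 3L)
  for (j in 1:3) {
    expect_lt(abs(mean(scores[[j]])), 1e-8)
    expect_lt(abs(sd(scores[[j]]) - 1), 1e-8)
  }
  # participant exactly at the sample-mean intakes scores 0 on every factor
  at_mean <- tibble::as_tibble(as.list(colMeans(as.matrix(adj))))
  expect_equal(unlist(score_patterns(model, at_mean)), rep(0, 3),
               tolerance = 1e-8, ignore_attr = TRUE)
  # identical rows get identical scores
  two <- adj[c(1, 1), ]
  s2 <- score_patterns(model, two)
  expect_equal(s2[1, ], s2[2, ])
  expect_error(score_patterns(model, adj[, -1]), "group01")
})

test_that("scores are invariant to per-group linear rescaling", {
  ffq <- generate_ffq(n = 200, seed = 17)
  adj <- energy_adjust(ffq$groups, ffq$energy)
  rescaled <- adj
  rescaled$group01 <- 3.2 * rescaled$group01 + 40
  rescaled$group07 <- 0.1 * rescaled$group07 - 5
  m1 <- extract_patterns(adj, n_factors = 3)
  m2 <- extract_patterns(rescaled, n_factors = 3)
  expect_equal(as.matrix(score_patterns(m1, adj)),
               as.matrix(score_patterns(m2, rescaled)), tolerance = 1e-8)
})

test_that("single-factor extraction needs no rotation and guards its rank", {
  ffq <- generate_ffq(n = 150, seed = 2)
  adj <- energy_adjust(ffq$groups, ffq$energy)
  m_rot <- extract_patterns(adj, n_factors = 1, rotation = "varimax")
  m_none <- extract_patterns(adj, n_factors = 1, rotation = "none")
  expect_equal(score_patterns(m_rot, adj), score_patterns(m_none, adj))
  expect_error(extract_patterns(adj, n_factors = 50), "rank")
})
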