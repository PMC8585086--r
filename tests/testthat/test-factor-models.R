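test_that("principal axis recovers exact one-factor structure to 1e-6", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  R <- exact_structure_R(matrix(lam, ncol = 1))
  fit <- principal_axis(R, 1)
  expect_lt(max(abs(abs(fit$loadings) - lam)), 1e-6)
  # reproduction of off-diagonals
  Rhat <- tcrossprod(fit$loadings)
  off <- upper.tri(R)
  expect_lt(max(abs(R[off] - Rhat[off])), 1e-6)
})

test_that("principal axis flags degenerate and exact two-factor inputs correctly", {
  fit <- principal_axis(diag(6), 1)
  expect_lt(max(fit$communality), 1e-6)

  L <- cbind(c(0.8, 0.7, 0.6, 0, 0, 0), c(0, 0, 0, 0.75, 0.65, 0.55))
  R <- exact_structure_R(L)
  fit2 <- principal_axis(R, 2)
  al <- mcri:::align_factors(fit2$loadings, L)
  expect_true(all(al$congruence > 1 - 1e-8))
  expect_lt(max(abs(al$loadings - L)), 1e-6)

  expect_error(principal_axis(matrix(c(2, 0, 0, 2), 2), 1), "unit diagonal")
})

test_that("promax returns a proper oblique solution", {
  # perfect simple structure: output equals input up to sign/permutation
  L <- cbind(c(0.8, 0.7, 0.6, 0, 0, 0), c(0, 0, 0, 0.75, 0.65, 0.55))
  fm <- promax_rotate(L)
  al <- mcri:::align_factors(fm$loadings, L)
  expect_lt(max(abs(al$loadings - L)), 1e-6)
  expect_lt(max(abs(fm$phi - diag(2))), 0.02)

  # invariants on a correlated-structure fit
  Phi <- matrix(c(1, 0.5, 0.5, 1), 2)
  L2 <- cbind(c(0.7, 0.6, 0.65, 0.1, 0, 0.1), c(0.05, 0, 0.1, 0.7, 0.6, 0.55))
  R <- exact_structure_R(L2, Phi)
  fm2 <- promax_rotate(principal_axis(R, 2)$loadings)
  expect_equal(fm2$phi, t(fm2$phi))
  expect_equal(diag(fm2$phi), c(PA1 = 1, PA2 = 1))
  expect_true(all(eigen(fm2$phi, only.values = TRUE)$values > 0))
  # structure = pattern %*% phi
  expect_lt(max(abs(fm2$structure - fm2$loadings %*% fm2$phi)), 1e-8)
  # rotation preserves communalities
  expect_lt(max(abs(fm2$communality -
                      rowSums(principal_axis(R, 2)$loadings^2))), 1e-6)
})

test_that("promax agrees with the reference implementation in stats", {
  set.seed(9)
  Phi <- matrix(c(1, 0.54, 0.54, 1), 2)
  L <- default_loadings()[final_items(), ]
  R <- exact_structure_R(L, Phi)
  unrot <- principal_axis(R, 2)$loadings
  mine <- promax_rotate(unrot)
  ref <- stats::promax(unrot)
  ref_load <- unclass(ref$loadings)
  al <- mcri:::align_factors(mine$loadings, ref_load)
  expect_lt(max(abs(al$loadings - ref_load)), 1e-4)
  ref_phi <- solve(crossprod(ref$rotmat))
  expect_equal(abs(mine$phi[1, 2]), abs(ref_phi[1, 2]), tolerance = 1e-4)
})

test_that("parallel analysis counts eigenvalues against the random reference", {
  set.seed(10)
  z <- matrix(rnorm(500 * 23), 500, 23)
  ev <- eigen(cor(z), only.values = TRUE)$values
  expect_equal(parallel_analysis(rep(100, 23), 500, 23, reps = 50)$n_factors, 23L)
  expect_equal(parallel_analysis(rep(0.01, 23), 500, 23, reps = 50)$n_factors, 0L)
  expect_error(parallel_analysis(ev, 500, 23, reps = 10), "50")
  # upper-quantile comparator returns 0 on pure noise
  expect_equal(parallel_analysis(ev, 500, 23, reps = 100,
                                 quantile_ref = 0.95)$n_factors, 0L)
})

test_that("VSS peaks at one factor for exact one-factor structure", {
  lam <- c(0.8, 0.7, 0.6, 0.5, 0.65, 0.75)
  R <- exact_structure_R(matrix(lam, ncol = 1))
  v1 <- suppressWarnings(vss_criterion(R, 3, complexity = 1))
  expect_equal(v1$n_factors, 1L)
  expect_true(all(v1$vss <= 1 + 1e-12))
  v2 <- suppressWarnings(vss_criterion(R, 3, complexity = 2))
  expect_equal(v2$n_factors, 1L)
  expect_error(vss_criterion(R, 0), ">= 1")
})

test_that("pruning drops sub-threshold items, retains ties, requires refit", {
  # hand-built model: v4 sits exactly at the 0.3 threshold, v5 below it
  L <- cbind(c(0.7, 0.6, 0.65, 0.30, 0.25, 0.05),
             c(0.05, 0, 0.1, 0.0, 0.05, 0.72))
  rownames(L) <- paste0("v", 1:6)
  phi <- matrix(c(1, 0.4, 0.4, 1), 2)
  fm <- list(loadings = L, phi = phi, structure = L %*% phi,
             communality = rowSums((L %*% phi) * L),
             uniqueness = 1 - rowSums((L %*% phi) * L), items = rownames(L))
  class(fm) <- "factor_model"
  out <- prune_items(fm)
  kept <- retained_items(out$subset)
  expect_true(out$refit_required)
  expect_false("v5" %in% kept)          # planted max loading 0.25
  expect_true("v4" %in% kept)           # exactly at the 0.3 threshold
  expect_equal(out$subset$status[out$subset$item == "v5"], "low-loading")

  # all loadings comfortably above threshold: identity subset, no refit
  L2 <- cbind(c(0.7, 0.6, 0.65, 0, 0, 0), c(0, 0, 0, 0.72, 0.6, 0.55))
  rownames(L2) <- paste0("w", 1:6)
  fm2 <- promax_rotate(principal_axis(exact_structure_R(L2), 2)$loadings)
  out2 <- prune_items(fm2)
  expect_false(out2$refit_required)
  expect_equal(retained_items(out2$subset), rownames(L2))
})

test_that("pruning refuses to empty a factor", {
  L <- cbind(c(0.7, 0.65, 0.6, 0.6), c(0.1, 0.05, 0.1, 0.25))
  rownames(L) <- paste0("v", 1:4)
  fm <- list(loadings = L, phi = diag(2), structure = L,
             communality = rowSums(L^2), uniqueness = 1 - rowSums(L^2),
             items = rownames(L))
  class(fm) <- "factor_model"
  expect_error(prune_items(fm), "empty factor")
})
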