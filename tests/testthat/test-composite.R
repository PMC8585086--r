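test_that("Bartlett scores reduce to identity for a trivial model", {
  fm <- list(loadings = diag(2), phi = diag(2), structure = diag(2),
             communality = c(0, 0), uniqueness = c(1, 1),
             items = c("a", "b"))
  rownames(fm$loadings) <- c("a", "b")
  class(fm) <- "factor_model"
  z <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(bartlett_scores(z, fm)), unname(z))
  z[2, 1] <- NA
  expect_error(bartlett_scores(z, fm), "impute")
})

test_that("uniqueness under the published loadings matches the hand computation", {
  L <- default_loadings()
  Phi <- matrix(c(1, 0.54, 0.54, 1), 2)
  h2 <- rowSums((L %*% Phi) * L)
  # EQ-5D mobility: 0.53^2 + 0.05^2 + 2*0.53*0.05*0.54 = 0.312
  expect_equal(unname(h2["EQ5D_Mobility"]), 0.312, tolerance = 5e-4)
  expect_equal(unname(1 - h2["EQ5D_Mobility"]), 0.688, tolerance = 5e-4)
})

test_that("Bartlett estimation is conditionally unbiased on model data", {
  # slope of estimated on true factor ~ 1 at n = 5000
  sim <- simulate_cohort(static_config(n_patients = 1000), seed = 17)
  fit <- suppressWarnings(mcri(sim$cohort, seed = 17))
  sc <- suppressMessages(predict(fit, sim$cohort))
  i <- match(paste(sc$patient_id, sc$visit),
             paste(sim$latent$patient_id, sim$latent$visit))
  s_dis <- coef(lm(sc$disability ~ sim$latent$disability[i]))[2]
  s_dep <- coef(lm(sc$distress ~ sim$latent$distress[i]))[2]
  expect_lt(abs(s_dis - 1), 0.05)
  expect_lt(abs(s_dep - 1), 0.05)
})

test_that("0-100 scaling anchors, midpoint and clipping", {
  s <- c(2, 5, 8)
  expect_equal(scale_0_100(s), c(0, 50, 100))
  expect_warning(out <- scale_0_100(9, bounds = c(2, 8)), "clipped")
  expect_equal(out, 100)
  expect_error(scale_0_100(rep(1, 3)), "degenerate")
})

test_that("composite PCA has its closed-form behavior on degenerate inputs", {
  set.seed(18)
  g <- rnorm(500)
  perfect <- data.frame(disability = g, distress = 2 * g + 1,
                        nprs = -3 * g, pmi = g / 2)
  cm <- fit_composite(perfect)
  expect_equal(cm$eigenvalues[1], 4)
  expect_equal(abs(unname(cm$weights)), rep(0.5, 4))
  expect_equal(cm$explained, 1)
  expect_equal(sum(cm$eigenvalues), 4)  # trace conservation

  # two perfectly tied blocks -> unstable first component -> error
  g2 <- rep(c(1, -1), 250)
  h2 <- rep(c(1, 1, -1, -1), 125)   # exactly orthogonal to g2
  tied <- data.frame(disability = g2, distress = g2, nprs = h2, pmi = h2)
  expect_error(fit_composite(tied), "tied")
})

test_that("scoring is monotone, anchored and idempotent", {
  sim <- simulate_cohort(cohort_config(n_patients = 120), seed = 19)
  fit <- suppressWarnings(mcri(sim$cohort, seed = 19))
  sc <- suppressMessages(predict(fit, sim$cohort))
  expect_true(all(sc$mcri >= 0 & sc$mcri <= 10))
  expect_equal(min(sc$mcri), 0)   # derivation-sample minimum maps to 0
  expect_equal(max(sc$mcri), 10)

  # identical records except higher NPRS score strictly lower
  rec <- as.data.frame(sim$cohort[which(sim$cohort$visit == "M0" &
                                          complete.cases(as.data.frame(sim$cohort[, fit$factor_model$items])))[1], ])
  rec2 <- rec
  rec$nprs <- 3; rec2$nprs <- 9
  rec$pgic <- rec2$pgic <- NA
  two <- rbind(rec, rec2)
  two$visit <- c("M0", "M3")  # keep (patient, visit) keys unique
  s2 <- suppressMessages(predict(fit, two))
  expect_lt(s2$mcri[2], s2$mcri[1])

  # re-scoring reproduces itself exactly
  sc2 <- suppressMessages(predict(fit, sim$cohort))
  expect_identical(sc, sc2)
})

test_that("higher symptom burden lowers the index in every construct", {
  sim <- simulate_cohort(cohort_config(n_patients = 120), seed = 20)
  fit <- suppressWarnings(mcri(sim$cohort, seed = 20))
  w <- coef(fit)
  expect_true(all(w < 0))
  expect_named(w, c("disability", "distress", "nprs", "pmi"))
})

test_that("a saved index reloads and scores bit-identically", {
  sim <- simulate_cohort(cohort_config(n_patients = 100), seed = 21)
  fit <- suppressWarnings(mcri(sim$cohort, seed = 21))
  path <- tempfile(fileext = ".json")
  write_mcri(fit, path)
  back <- read_mcri(path)
  s1 <- suppressMessages(predict(fit, sim$cohort))
  s2 <- suppressMessages(predict(back, sim$cohort))
  expect_identical(s1$mcri, s2$mcri)
  expect_identical(s1$disability, s2$disability)
})
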