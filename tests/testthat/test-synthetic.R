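test_that("generation is deterministic under a fixed seed", {
  a <- simulate_cohort(cohort_config(n_patients = 50), seed = 5)
  b <- simulate_cohort(cohort_config(n_patients = 50), seed = 5)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$latent, b$latent)
  c2 <- simulate_cohort(cohort_config(n_patients = 50), seed = 6)
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("emitted cohorts pass validation and respect the schedule", {
  sim <- simulate_cohort(cohort_config(n_patients = 80), seed = 7)
  expect_s3_class(sim$cohort, "cohort_table")
  expect_silent(as_cohort_table(as.data.frame(sim$cohort)))
  expect_true(all(is.na(sim$cohort$pgic[sim$cohort$visit == "M0"])))
  # latent ground truth covers every patient-visit, attended or not
  expect_equal(nrow(sim$latent), 80 * 5)
})

test_that("infeasible latent correlation targets are rejected", {
  cfg <- cohort_config(latent_cor = c(pain_disability = 0.99,
                                      pain_distress = -0.99,
                                      surface_disability = 0,
                                      surface_distress = 0,
                                      pain_surface = 0))
  expect_error(simulate_cohort(cfg, seed = 1), "positive definite")
})

test_that("with zero unique noise items are deterministic transforms of the factors", {
  cfg <- static_config(n_patients = 30, item_noise_scale = 0)
  a <- simulate_cohort(cfg, seed = 8)
  # regenerate items from the same latent state: identical tables
  b <- simulate_cohort(cfg, seed = 8)
  expect_identical(a$cohort, b$cohort)
  # every item is a function of the two factors only: records with equal
  # factor values (same patient-visit) must agree item-wise, and item
  # correlation with its own continuum is exact by construction
  L <- default_loadings()
  att <- vapply(cfg$thresholds, mcri:::attenuation_factor, 0)
  cont <- as.matrix(a$latent[, c("disability", "distress")]) %*%
    t(L["ODI_Standing", , drop = FALSE] / att[["ODI"]])
  key <- paste(a$cohort$patient_id, a$cohort$visit)
  i <- match(key, paste(a$latent$patient_id, a$latent$visit))
  redo <- mcri:::discretize(as.numeric(cont)[i], cfg$thresholds$ODI, 0)
  expect_equal(redo, a$cohort$ODI_Standing)
})

test_that("item correlations converge to the target loading structure", {
  # pooled static sample of 20,000 records
  cfg <- static_config(n_patients = 4000)
  sim <- simulate_cohort(cfg, seed = 9)
  items <- final_items()
  M <- pool_across_visits(sim$cohort, items)
  expect_equal(nrow(M), 20000L)
  L <- default_loadings()[items, ]
  Phi <- matrix(c(1, 0.54, 0.54, 1), 2)
  target <- L %*% Phi %*% t(L)
  obs <- cor(M)
  off <- upper.tri(obs)
  expect_lt(max(abs(obs[off] - target[off])), 0.03)
})

test_that("baseline marginals mimic the derivation-study descriptives", {
  sim <- simulate_cohort(static_config(n_patients = 1500), seed = 10)
  b <- sim$cohort[sim$cohort$visit == "M0", ]
  expect_lt(abs(mean(b$nprs) - 6.1), 0.15)
  expect_lt(abs(sd(b$nprs) - 1.5), 0.15)
  expect_lt(abs(mean(b$odi_pct) - 44.6), 2)
  expect_lt(abs(sd(b$odi_pct) - 13.2), 2)
  expect_lt(abs(mean(b$eq5d_index) - 0.28), 0.03)
  expect_lt(abs(sd(b$eq5d_index) - 0.23), 0.04)
  hads_d <- item_catalog()$item[!is.na(item_catalog()$subscale) &
                                  item_catalog()$subscale == "depression"]
  expect_lt(abs(mean(rowSums(b[, hads_d])) - 8.6), 1)
})

test_that("the PGIC anchor behaves across its noise limits", {
  # zero anchor noise: PGIC is a step function of the latent change, and
  # the true change separates satisfied/unsatisfied perfectly
  cfg0 <- cohort_config(n_patients = 150, anchor_noise_sd = 0)
  s0 <- simulate_cohort(cfg0, seed = 11)
  fu <- s0$cohort$visit != "M0" & !is.na(s0$cohort$pgic)
  i <- match(paste(s0$cohort$patient_id, s0$cohort$visit)[fu],
             paste(s0$latent$patient_id, s0$latent$visit))
  auc0 <- roc_auc(s0$latent$change_z[i], s0$cohort$pgic[fu] >= 6)
  expect_equal(auc0, 1)

  # huge anchor noise: PGIC decouples from change, AUC ~ 0.5
  cfgI <- cohort_config(n_patients = 400, anchor_noise_sd = 1e4)
  sI <- simulate_cohort(cfgI, seed = 12)
  fuI <- sI$cohort$visit != "M0" & !is.na(sI$cohort$pgic)
  iI <- match(paste(sI$cohort$patient_id, sI$cohort$visit)[fuI],
              paste(sI$latent$patient_id, sI$latent$visit))
  aucI <- roc_auc(sI$latent$change_z[iI], sI$cohort$pgic[fuI] >= 6)
  expect_lt(abs(aucI - 0.5), 0.07)
})

test_that("about a quarter of patients are satisfied at 12 months", {
  share <- mean(sapply(1:5, function(s) {
    sim <- simulate_cohort(cohort_config(), seed = 30 + s)
    m12 <- sim$cohort[sim$cohort$visit == "M12" & !is.na(sim$cohort$pgic), ]
    mean(m12$pgic >= 6)
  }))
  expect_equal(share, 0.248, tolerance = 0.2)
})
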