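test_that("PGIC dichotomization splits at 6", {
  expect_false(dichotomize_pgic(5))
  expect_true(dichotomize_pgic(6))
  expect_true(dichotomize_pgic(7))
  expect_true(is.na(dichotomize_pgic(NA)))
  expect_error(dichotomize_pgic(0), "1-7")
})

test_that("confusion metrics classify at 'change >= cutoff' and count everything", {
  ch <- c(-2, -1, 0, 1, 2, 3)
  sat <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  res <- confusion_metrics(ch, sat, 0.5)
  expect_equal(c(res$tp, res$fn, res$fp, res$tn), c(3, 0, 0, 3))
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$n, 6)
  res2 <- confusion_metrics(ch, sat, 2)        # boundary included as improved
  expect_equal(res2$tp, 2)
  expect_error(confusion_metrics(ch, rep(TRUE, 6), 0), "both")
})

test_that("AUC equals the all-pairs Mann-Whitney count exactly, ties included", {
  set.seed(22)
  for (i in 1:10) {
    x <- sample(0:5, 30, replace = TRUE)      # heavy ties
    y <- runif(30) < 0.4
    if (!any(y) || all(y)) next
    u <- 0
    for (a in x[y]) for (b in x[!y]) u <- u + (a > b) + 0.5 * (a == b)
    expect_identical(roc_auc(x, y), u / (sum(y) * sum(!y)))
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # invariant under strictly monotone transforms
  x <- rnorm(40); y <- runif(40) < 0.5
  expect_equal(roc_auc(x, y), roc_auc(exp(x), y))
  # uninformative changes
  set.seed(23)
  expect_lt(abs(roc_auc(rnorm(4000), runif(4000) < 0.3) - 0.5), 0.03)
})

test_that("AUC agrees with the independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(24)
  x <- c(rnorm(60, 1), rnorm(80))
  y <- rep(c(TRUE, FALSE), c(60, 80))
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = x,
                                        quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(x, y), ref, tolerance = 1e-12)
})

test_that("the optimal cutoff maximizes Youden over an exhaustive scan", {
  res <- optimal_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$cutoff, 2.5)
  expect_equal(res$sensitivity + res$specificity, 2)

  set.seed(25)
  for (i in 1:10) {
    x <- round(rnorm(40), 1)
    y <- runif(40) < plogis(x)
    if (!any(y) || all(y)) next
    best <- optimal_cutoff(x, y)
    grid <- c(-Inf, sort(unique(x)) - 1e-9, sort(unique(x)) + 1e-9, Inf)
    scan <- sapply(grid, function(cut) {
      r <- confusion_metrics(x, y, cut)
      r$sensitivity + r$specificity
    })
    expect_gte(best$sensitivity + best$specificity, max(scan) - 1e-12)
    expect_gte(best$sensitivity + best$specificity - 1, 0)  # Youden never negative
  }
})

test_that("Jonckheere-Terpstra matches its reduction and enumeration oracles", {
  # two groups: one-sided Mann-Whitney normal approximation
  set.seed(26)
  x <- rnorm(12); y <- rnorm(14, 0.8)
  jt <- jonckheere_terpstra(c(x, y), rep(1:2, c(12, 14)))
  w <- wilcox.test(y, x, alternative = "greater", exact = FALSE,
                   correct = TRUE)
  expect_equal(jt$p_value, w$p.value, tolerance = 1e-10)

  # perfectly ordered tiny groups: JT maximal, exact p = 1/90
  jt2 <- jonckheere_terpstra(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2),
                             exact = TRUE)
  expect_equal(jt2$statistic, 12)
  expect_equal(jt2$p_value, 1 / 90)

  # all observations equal: centered statistic, p = 0.5
  jt3 <- jonckheere_terpstra(rep(2, 9), rep(1:3, each = 3))
  expect_equal(jt3$z, 0)
  expect_equal(jt3$p_value, 0.5)

  expect_error(jonckheere_terpstra(1:5, rep(1, 5)), "2 non-empty")
})

test_that("the JT normal approximation tracks the exact permutation p", {
  set.seed(27)
  grp <- rep(1:3, c(4, 4, 3))
  for (i in 1:5) {
    vals <- rnorm(11)                          # tie-free lattice
    ex <- jonckheere_terpstra(vals, grp, exact = TRUE)
    no <- jonckheere_terpstra(vals, grp)
    expect_lt(abs(ex$p_value - no$p_value), 0.01)
  }
  for (i in 1:3) {
    vals <- sample(1:4, 11, replace = TRUE)    # coarse tied lattice
    ex <- jonckheere_terpstra(vals, grp, exact = TRUE)
    no <- jonckheere_terpstra(vals, grp)
    expect_lt(abs(ex$p_value - no$p_value), 0.05)
  }
})

test_that("change records pair follow-ups with baseline in improvement orientation", {
  sc <- data.frame(patient_id = c("A", "A", "B", "B"),
                   visit = c("M0", "M3", "M0", "M12"),
                   mcri = c(4, 6, 5, 4.5),
                   odi_pct = c(50, 40, 60, 70),
                   eq5d_index = c(0.2, 0.4, 0.3, 0.25),
                   nprs = c(7, 4, 6, 7),
                   hads_total = c(20, 12, 25, 27),
                   pmi = c(1000, 400, 800, 900),
                   pgic = c(NA, 6, NA, 3))
  ch <- change_records(sc)
  a3 <- ch[ch$patient_id == "A" & ch$interval == "M0-M3", ]
  expect_equal(a3$mcri, 2)      # followup - baseline
  expect_equal(a3$odi, 10)      # baseline - followup
  expect_equal(a3$eq5d, 0.2)
  expect_equal(a3$nprs, 3)
  expect_equal(a3$hads, 8)
  expect_equal(a3$pmi, 600)
  expect_true(a3$satisfied)
  b12 <- ch[ch$patient_id == "B" & ch$interval == "M0-M12", ]
  expect_equal(b12$mcri, -0.5)
  expect_false(b12$satisfied)
})

test_that("the per-visit correlation report carries the published sign pattern", {
  sim <- simulate_cohort(cohort_config(), seed = 28)
  fit <- suppressWarnings(mcri(sim$cohort, seed = 28))
  sc <- suppressMessages(predict(fit, sim$cohort, na_action = "na"))
  rep0 <- correlation_report(sc, "M0")
  expect_equal(diag(rep0$rho), rep(1, 6), ignore_attr = TRUE)
  expect_lt(rep0$rho["mcri", "odi"], 0)
  expect_lt(rep0$rho["mcri", "nprs"], 0)
  expect_lt(rep0$rho["mcri", "hads"], 0)
  expect_lt(rep0$rho["mcri", "pmi"], 0)
  expect_gt(rep0$rho["mcri", "eq5d"], 0)
  expect_true(all(rep0$stars[c("odi", "nprs"), "mcri"] == "***"))
})

test_that("the index correlates with each instrument more strongly than the instruments do pairwise", {
  wins <- sapply(1:3, function(s) {
    sim <- simulate_cohort(cohort_config(), seed = 40 + s)
    fit <- suppressWarnings(mcri(sim$cohort, seed = s))
    sc <- suppressMessages(predict(fit, sim$cohort, na_action = "na"))
    r <- correlation_report(sc, "M12")$rho
    # every instrument pair correlates more weakly than the stronger of
    # the two instruments' correlations with the index
    ins <- colnames(r)[-1]
    ok <- TRUE
    for (a in seq_along(ins)[-length(ins)]) for (b in seq(a + 1, length(ins)))
      ok <- ok && abs(r[ins[a], ins[b]]) <
        max(abs(r["mcri", ins[a]]), abs(r["mcri", ins[b]]))
    ok
  })
  expect_gte(sum(wins), 2)
})
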