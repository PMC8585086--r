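#' Fit the Multidimensional Clinical Response Index
#'
#' Runs the full index derivation on a longitudinal cohort: pre-specified
#' clinical item reduction (29 to 26 items), pooled exploratory factor
#' analysis (principal-axis factoring with promax rotation) with
#' adequacy and factor-count diagnostics (KMO, parallel analysis, VSS),
#' pruning of items loading below the threshold on every factor, a refit
#' on the retained items, Bartlett factor-score extraction, and a
#' correlation-matrix PCA of the four constructs (functional disability,
#' depression/anxiety, NPRS, PMI) whose oriented first component -
#' min-max scaled to [0, 10] over the pooled derivation sample - is the
#' MCRI (0 = worst, 10 = best pain-related health).
#'
#' All standardization statistics and scaling bounds are frozen into the
#' returned object so follow-up data can be scored without refitting
#' (see \code{\link{predict.mcri}}).
#'
#' @param data a \code{cohort_table} (or data frame in the cohort
#'   layout).
#' @param n_factors number of factors, fixed to the published choice of 2.
#' @param loading_threshold pruning threshold (items strictly below it on
#'   all factors are dropped; default 0.3).
#' @param promax_power promax exponent (default 4).
#' @param parallel_reps replicates for parallel analysis (default 100).
#' @param max_vss_factors largest factor count scanned by VSS (default 4).
#' @param seed RNG seed for the parallel-analysis replicates.
#' @return an object of class \code{mcri}; see
#'   \code{\link{summary.mcri}}.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config(n_patients = 60), seed = 7)
#' fit <- mcri(sim$cohort, parallel_reps = 50)
#' print(fit)
#' head(predict(fit, sim$cohort))
mcri <- function(data, n_factors = 2L, loading_threshold = 0.3,
                 promax_power = 4, parallel_reps = 100L,
                 max_vss_factors = 4L, seed = 1L) {
  cl <- match.call()
  table <- if (inherits(data, "cohort_table")) data else as_cohort_table(data)
  table <- add_pmi(table)
  catalog <- item_catalog()

  subset26 <- apply_clinical_reduction(catalog)
  items26 <- retained_items(subset26)
  M26 <- pool_across_visits(table, items26)
  R26 <- stats::cor(M26)

  set.seed(seed)
  kmo26 <- kmo(R26)

  efa1 <- promax_rotate(principal_axis(R26, n_factors)$loadings,
                        power = promax_power)
  pruned <- prune_items(efa1, R26, threshold = loading_threshold)
  items_final <- retained_items(pruned$subset)

  M <- pool_across_visits(table, items_final)
  R <- stats::cor(M)
  fm <- promax_rotate(principal_axis(R, n_factors)$loadings,
                      power = promax_power)
  kmo_final <- kmo(R)
  # factor-count diagnostics on the final item set, as in the published
  # derivation
  eig <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  pa_verdict <- parallel_analysis(eig, nrow(M), ncol(M), reps = parallel_reps)
  vss_verdict <- suppressWarnings(vss_criterion(R, max_vss_factors))

  # label factors by instrument content: the factor dominated by ODI/EQ-5D
  # items is functional disability, the HADS-dominated one distress
  dom <- max.col(abs(fm$loadings), ties.method = "first")
  odi_like <- grepl("^(ODI|EQ5D)_", items_final)
  f_dis <- which.max(vapply(seq_len(n_factors),
                            function(f) sum(odi_like & dom == f), 0))
  ord <- c(f_dis, setdiff(seq_len(n_factors), f_dis))
  fm$loadings <- fm$loadings[, ord, drop = FALSE]
  fm$structure <- fm$structure[, ord, drop = FALSE]
  fm$phi <- fm$phi[ord, ord, drop = FALSE]
  # orient factors so higher score = worse symptom burden
  for (f in seq_len(n_factors)) {
    if (sum(fm$loadings[, f]) < 0) {
      fm$loadings[, f] <- -fm$loadings[, f]
      fm$structure[, f] <- -fm$structure[, f]
      fm$phi[f, -f] <- -fm$phi[f, -f]
      fm$phi[-f, f] <- -fm$phi[-f, f]
    }
  }
  colnames(fm$loadings) <- colnames(fm$structure) <-
    c("disability", "distress")[seq_len(n_factors)]
  dimnames(fm$phi) <- list(colnames(fm$loadings), colnames(fm$loadings))

  item_means <- colMeans(M)
  item_sds <- apply(M, 2, stats::sd)

  constructs <- .mcri_constructs(table, fm, item_means, item_sds)
  comp <- fit_composite(constructs)
  bounds100 <- list(disability = range(constructs$disability, na.rm = TRUE),
                    distress = range(constructs$distress, na.rm = TRUE))

  obj <- list(call = cl,
              factor_model = fm,
              composite = comp,
              item_means = item_means, item_sds = item_sds,
              bounds100 = bounds100,
              trail = c(catalog = nrow(catalog),
                        clinical = length(items26),
                        final = length(items_final)),
              subsets = list(clinical = subset26, pruned = pruned$subset),
              kmo = c(initial = kmo26$overall, final = kmo_final$overall),
              parallel_analysis = pa_verdict$n_factors,
              vss = vss_verdict$n_factors,
              n_pooled = nrow(M),
              n_constructs = comp$n)
  class(obj) <- "mcri"
  obj
}

# Construct scores (disability, distress, nprs, pmi) for every record
# complete on the model items + NPRS + surfaces; NA elsewhere.
.mcri_constructs <- function(table, fm, item_means, item_sds) {
  it <- as.matrix(table[, fm$items, drop = FALSE])
  ok <- stats::complete.cases(it) & !is.na(table$nprs) & !is.na(table$pmi)
  out <- data.frame(patient_id = table$patient_id,
                    visit = table$visit,
                    disability = NA_real_, distress = NA_real_,
                    nprs = table$nprs, pmi = table$pmi,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    z <- scale(it[ok, , drop = FALSE], item_means, item_sds)
    sc <- bartlett_scores(z, fm)
    out$disability[ok] <- sc[, "disability"]
    out$distress[ok] <- sc[, "distress"]
  }
  out$nprs[!ok] <- NA
  out$pmi[!ok] <- NA
  out
}

#' Score a cohort with a fitted index
#'
#' Applies the frozen scoring pipeline (item standardization, Bartlett
#' factor scores, construct standardization, stored PC weights, stored
#' [0, 10] scaling) to new records. Scoring never refits anything;
#' re-scoring the derivation sample reproduces the scores seen at fit
#' time.
#'
#' @param object a fitted \code{mcri} object.
#' @param newdata a \code{cohort_table} (or cohort-layout data frame).
#' @param na_action \code{"omit"} (default) drops records incomplete on
#'   the required inputs with a message; \code{"na"} keeps them with
#'   \code{NA} scores.
#' @param ... unused.
#' @return data frame with \code{patient_id}, \code{visit}, the [0, 100]
#'   construct scores \code{disability_100} and \code{distress_100}, the
#'   raw constructs, \code{pmi}, \code{pgic} (copied through) and
#'   \code{mcri} in [0, 10].
#' @export
predict.mcri <- function(object, newdata, na_action = c("omit", "na"), ...) {
  na_action <- match.arg(na_action)
  table <- if (inherits(newdata, "cohort_table")) newdata
           else as_cohort_table(newdata)
  table <- add_pmi(table)
  con <- .mcri_constructs(table, object$factor_model,
                          object$item_means, object$item_sds)
  ok <- stats::complete.cases(con[, c("disability", "distress", "nprs", "pmi")])
  mcri_score <- rep(NA_real_, nrow(con))
  if (any(ok)) mcri_score[ok] <- apply_composite(con[ok, ], object$composite)
  d100 <- i100 <- rep(NA_real_, nrow(con))
  if (any(ok)) {
    d100[ok] <- scale_0_100(con$disability[ok], object$bounds100$disability)
    i100[ok] <- scale_0_100(con$distress[ok], object$bounds100$distress)
  }
  out <- data.frame(patient_id = con$patient_id, visit = con$visit,
                    disability = con$disability, distress = con$distress,
                    disability_100 = d100, distress_100 = i100,
                    nprs = con$nprs, pmi = con$pmi,
                    odi_pct = table$odi_pct, eq5d_index = table$eq5d_index,
                    hads_total = table$hads_total, pgic = table$pgic,
                    mcri = mcri_score, stringsAsFactors = FALSE)
  if (na_action == "omit") {
    n_drop <- sum(!ok)
    if (n_drop > 0)
      message(n_drop, " record(s) incomplete on the index inputs were skipped")
    out <- out[ok, ]
    rownames(out) <- NULL
  }
  out
}

#' @export
print.mcri <- function(x, ...) {
  cat("Multidimensional Clinical Response Index fit\n")
  cat(sprintf("  item trail: %d -> %d (clinical reduction) -> %d (loading < 0.3 pruned)\n",
              x$trail["catalog"], x$trail["clinical"], x$trail["final"]))
  cat(sprintf("  KMO: %.2f (26 items), %.2f (final); parallel analysis: %d factor(s); VSS: %d\n",
              x$kmo["initial"], x$kmo["final"], x$parallel_analysis, x$vss))
  cat(sprintf("  inter-factor correlation: %.2f\n", x$factor_model$phi[1, 2]))
  cat(sprintf("  first PC explains %.1f%% of the 4 constructs (eigenvalue %.2f)\n",
              100 * x$composite$explained, x$composite$eigenvalues[1]))
  cat(sprintf("  pooled records: %d (EFA), %d (composite)\n",
              x$n_pooled, x$n_constructs))
  invisible(x)
}

#' Summarize a fitted index
#'
#' @param object a fitted \code{mcri} object.
#' @param digits rounding for display.
#' @param ... unused.
#' @return \code{object}, invisibly.
#' @export
summary.mcri <- function(object, digits = 2, ...) {
  print(object)
  cat("\nPattern loadings (promax):\n")
  print(round(object$factor_model$loadings, digits))
  cat("\nComposite weights (higher MCRI = better health):\n")
  print(round(object$composite$weights, 3))
  cat(sprintf("\nEigenvalues of the construct correlation matrix: %s\n",
              paste(round(object$composite$eigenvalues, 3), collapse = ", ")))
  invisible(object)
}

#' @export
coef.mcri <- function(object, ...) object$composite$weights

#' Construct-score distributions per visit
#'
#' Boxplots of the [0, 100] construct scores and the [0, 10] MCRI by
#' visit for a scored cohort, mirroring the violin-plot style summary of
#' the derivation study.
#'
#' @param x a fitted \code{mcri} object.
#' @param newdata cohort to score and display.
#' @param ... passed to \code{boxplot}.
#' @return invisibly, the scored data frame.
#' @export
plot.mcri <- function(x, newdata, ...) {
  sc <- predict(x, newdata)
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::boxplot(disability_100 ~ visit, sc, main = "Functional disability",
                    ylab = "score /100", ...)
  graphics::boxplot(distress_100 ~ visit, sc, main = "Depression/anxiety",
                    ylab = "score /100", ...)
  graphics::boxplot(mcri ~ visit, sc, main = "MCRI", ylab = "score /10", ...)
  invisible(sc)
}
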