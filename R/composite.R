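#' Bartlett factor scores
#'
#' Weighted-least-squares factor score estimates for an oblique factor
#' model: \code{scores = (L' Psi^-1 L)^-1 L' Psi^-1 z} with \code{L} the
#' pattern matrix and \code{Psi} the uniquenesses. Conditionally unbiased
#' for the true factors. No imputation: every row must be complete.
#'
#' @param z matrix of standardized item responses (observations x items),
#'   columns matching \code{model$items}.
#' @param model a \code{factor_model}.
#' @return observations x factors score matrix.
#' @export
bartlett_scores <- function(z, model) {
  z <- as.matrix(z)
  if (!all(model$items %in% colnames(z)))
    stop("z lacks model items: ",
         paste(setdiff(model$items, colnames(z)), collapse = ", "))
  z <- z[, model$items, drop = FALSE]
  if (anyNA(z)) stop("missing item responses; Bartlett scoring does not impute")
  psi <- model$uniqueness
  if (any(psi <= 0)) stop("nonpositive uniqueness")
  L <- model$loadings
  LtP <- t(L / psi)                        # L' Psi^-1
  M <- LtP %*% L
  if (rcond(M) < 1e-12) stop("singular L' Psi^-1 L")
  t(solve(M, LtP %*% t(z)))
}

#' Min-max scaling to [0, 100]
#'
#' Affine map sending the derivation-sample minimum to 0 and maximum to
#' 100, used to put factor scores on an interpretable reporting scale.
#' New values outside the derivation bounds are clipped with a warning.
#'
#' @param scores numeric vector.
#' @param bounds length-2 \code{c(min, max)} from the derivation sample;
#'   default \code{range(scores)}.
#' @return scaled scores in [0, 100].
#' @export
scale_0_100 <- function(scores, bounds = range(scores, na.rm = TRUE)) {
  if (diff(bounds) <= 0) stop("degenerate scaling bounds")
  out <- (scores - bounds[1]) / diff(bounds) * 100
  n_clip <- sum(out < 0 | out > 100, na.rm = TRUE)
  if (n_clip > 0)
    warning(n_clip, " score(s) outside derivation bounds were clipped")
  pmin(pmax(out, 0), 100)
}

#' Fit the composite index over the four constructs
#'
#' Z-scores the four construct columns (functional disability and
#' depression/anxiety factor scores, NPRS, PMI) on the pooled derivation
#' sample, eigendecomposes their correlation matrix, and takes the first
#' principal component as the composite. The sign is oriented so that a
#' higher composite means better health (all four symptom-burden
#' constructs then carry negative weights). The derivation-sample
#' composite range is stored so the index maps onto [0, 10].
#'
#' @param constructs data frame or matrix with columns
#'   \code{disability}, \code{distress}, \code{nprs}, \code{pmi};
#'   incomplete rows are dropped.
#' @return \code{composite_model} list: \code{center}, \code{scale},
#'   \code{weights} (unit norm), \code{eigenvalues}, \code{explained}
#'   (share of the first component), \code{range} (raw composite
#'   derivation range), \code{n}.
#' @export
fit_composite <- function(constructs) {
  X <- as.matrix(constructs[, c("disability", "distress", "nprs", "pmi")])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= ncol(X)) stop("not enough complete construct rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl <= 0)) stop("constant construct column")
  Z <- scale(X, ctr, scl)
  R <- stats::cor(Z)
  e <- eigen(R, symmetric = TRUE)
  if (e$values[1] - e$values[2] < 1e-8)
    stop("first principal component unstable: tied leading eigenvalues")
  v <- e$vectors[, 1]
  if (sum(v) > 0) v <- -v                  # higher composite = better health
  names(v) <- colnames(X)
  raw <- as.numeric(Z %*% v)
  out <- list(center = ctr, scale = scl, weights = v,
              eigenvalues = e$values, explained = e$values[1] / ncol(X),
              range = range(raw), n = nrow(X))
  class(out) <- "composite_model"
  out
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("Composite model: first PC explains %.1f%% (eigenvalue %.2f) of %d constructs\n",
              100 * x$explained, x$eigenvalues[1], length(x$weights)))
  cat("Weights (oriented so higher composite = better health):\n")
  print(round(x$weights, 3))
  invisible(x)
}

# Raw composite -> [0,10] with derivation-range min-max; clips new data.
scale_0_10 <- function(raw, model) {
  out <- (raw - model$range[1]) / diff(model$range) * 10
  n_clip <- sum(out < 0 | out > 10, na.rm = TRUE)
  if (n_clip > 0)
    warning(n_clip, " composite value(s) outside derivation bounds were clipped")
  pmin(pmax(out, 0), 10)
}

# Applies a frozen composite model to a construct matrix (columns
# disability, distress, nprs, pmi); rows must be complete.
apply_composite <- function(constructs, model) {
  X <- as.matrix(constructs[, names(model$weights)])
  if (anyNA(X)) stop("missing construct values")
  Z <- scale(X, model$center, model$scale)
  scale_0_10(as.numeric(Z %*% model$weights), model)
}
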