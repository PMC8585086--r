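# Single-level confirmatory factor analysis by maximum likelihood.
#
# The model is Sigma = Lambda Psi_f Lambda' + Theta with a fixed zero/free
# loading layout, one anchor loading per factor fixed to 1, a free factor
# covariance matrix and free diagonal uniquenesses. The discrepancy
# F_ML = log|Sigma| - log|S| + tr(S Sigma^-1) - p is minimized with
# analytic gradients; chi-square = (n-1) * F at the optimum.

#' Confirmatory factor analysis fit with RMSEA and CFI
#'
#' Fits a two-(or more-)factor CFA with maximum likelihood on a sample
#' covariance (or correlation) matrix and returns fit indices: the
#' chi-square test, RMSEA with a 90\% interval from inverting the
#' noncentral chi-square cdf, and CFI against the independence baseline.
#'
#' @param S sample covariance matrix (positive definite).
#' @param pattern named list mapping factor names to character vectors of
#'   item names (columns of S); the first item of each factor anchors the
#'   scale with its loading fixed to 1.
#' @param n sample size behind S.
#' @param conf RMSEA interval coverage (default 0.90).
#' @return object of class \code{cfa_fit}: \code{chisq}, \code{df},
#'   \code{p_value}, \code{rmsea}, \code{rmsea_ci}, \code{cfi},
#'   \code{loadings}, \code{factor_cov}, \code{uniqueness}, \code{n},
#'   \code{fmin}, \code{converged}.
#' @export
cfa_fit <- function(S, pattern, n, conf = 0.90) {
  S <- as.matrix(S)
  p <- ncol(S)
  items <- colnames(S)
  if (is.null(items)) stop("S needs column names matching the pattern")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("S is not positive definite")
  if (length(pattern) != 2L) stop("pattern must define exactly 2 factors")
  if (!all(unlist(pattern) %in% items)) stop("pattern names unknown in S")

  f1 <- match(pattern[[1]], items); f2 <- match(pattern[[2]], items)
  free1 <- f1[-1L]; free2 <- f2[-1L]
  n_free <- length(free1) + length(free2) + 3L + p
  df <- p * (p + 1) / 2 - n_free
  if (df < 1L) stop("model is not overidentified")

  build <- function(theta) {
    L <- matrix(0, p, 2)
    L[f1[1L], 1] <- 1; L[f2[1L], 2] <- 1
    i <- 0L
    L[free1, 1] <- theta[i + seq_along(free1)]; i <- i + length(free1)
    L[free2, 2] <- theta[i + seq_along(free2)]; i <- i + length(free2)
    a <- theta[i + 1L]; b <- theta[i + 2L]; cc <- theta[i + 3L]; i <- i + 3L
    Pf <- matrix(c(exp(2 * a), tanh(cc) * exp(a + b),
                   tanh(cc) * exp(a + b), exp(2 * b)), 2, 2)
    Th <- exp(2 * theta[i + seq_len(p)])
    list(L = L, Pf = Pf, Th = Th, a = a, b = b, cc = cc)
  }
  objgrad <- function(theta) {
    m <- build(theta)
    Sigma <- m$L %*% m$Pf %*% t(m$L) + diag(m$Th, p)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(list(objective = 1e10, gradient = rep(0, length(theta))))
    Sinv <- chol2inv(ch)
    f <- 2 * sum(log(diag(ch))) - determinant(S, logarithm = TRUE)$modulus +
      sum(Sinv * S) - p
    G <- Sinv %*% (Sigma - S) %*% Sinv
    GLP <- G %*% m$L %*% m$Pf
    M <- t(m$L) %*% G %*% m$L
    g <- c(2 * GLP[free1, 1], 2 * GLP[free2, 2],
           2 * m$Pf[1, 1] * M[1, 1] + 2 * M[1, 2] * m$Pf[1, 2],
           2 * m$Pf[2, 2] * M[2, 2] + 2 * M[1, 2] * m$Pf[1, 2],
           2 * M[1, 2] * exp(m$a + m$b) * (1 - tanh(m$cc)^2),
           2 * diag(G) * m$Th)
    list(objective = as.numeric(f), gradient = g)
  }
  start <- c(rep(1, length(free1) + length(free2)),
             log(sqrt(0.3 * S[f1[1L], f1[1L]])),
             log(sqrt(0.3 * S[f2[1L], f2[1L]])),
             atanh(0.4), log(sqrt(0.5 * diag(S))))
  opt <- stats::nlminb(start,
                       function(th) objgrad(th)$objective,
                       function(th) objgrad(th)$gradient,
                       control = list(iter.max = 2000L, eval.max = 4000L))
  gn <- sqrt(sum(objgrad(opt$par)$gradient^2))
  if (opt$objective >= 1e9 || gn > 1e-3 * (1 + abs(opt$objective)) * 100)
    stop(sprintf("CFA optimizer failed (gradient norm %.3e)", gn))
  m <- build(opt$par)
  fmin <- max(opt$objective, 0)
  chisq <- (n - 1) * fmin
  pval <- stats::pchisq(chisq, df, lower.tail = FALSE)
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  rmsea_ci <- c(.ncp_bound(chisq, df, 1 - (1 - conf) / 2),
                .ncp_bound(chisq, df, (1 - conf) / 2))
  rmsea_ci <- sqrt(pmax(rmsea_ci, 0) / (df * (n - 1)))

  fb <- sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus
  chisq_b <- (n - 1) * as.numeric(fb)
  df_b <- p * (p - 1) / 2
  cfi <- 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)

  dimnames(m$L) <- list(items, names(pattern))
  out <- list(chisq = as.numeric(chisq), df = df, p_value = pval,
              rmsea = rmsea, rmsea_ci = rmsea_ci, cfi = cfi,
              loadings = m$L, factor_cov = m$Pf,
              uniqueness = stats::setNames(m$Th, items),
              n = n, fmin = as.numeric(fmin),
              converged = opt$convergence == 0)
  class(out) <- "cfa_fit"
  out
}

# Noncentrality parameter lambda with pchisq(x, df, ncp = lambda) = prob;
# 0 when even ncp = 0 gives a smaller cdf.
.ncp_bound <- function(x, df, prob) {
  if (stats::pchisq(x, df) < prob) return(0)
  hi <- max(x, 1)
  while (stats::pchisq(x, df, ncp = hi) > prob) hi <- hi * 2
  stats::uniroot(function(l) stats::pchisq(x, df, ncp = l) - prob,
                 c(0, hi), tol = 1e-8)$root
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("CFA (ML, single level): chi-square = %.2f, df = %d, p = %.3g\n",
              x$chisq, x$df, x$p_value))
  cat(sprintf("RMSEA = %.3f (90%% CI %.3f-%.3f), CFI = %.3f, n = %d\n",
              x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2], x$cfi, x$n))
  invisible(x)
}
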