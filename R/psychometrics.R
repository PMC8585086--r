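#' Cronbach's alpha
#'
#' Internal-consistency reliability of a set of items on complete
#' observations: \code{alpha = k/(k-1) * (1 - sum(item variances) /
#' var(item sum))}.
#'
#' @param x numeric matrix or data frame, observations x items; rows with
#'   any missing value are dropped (available-case).
#' @return alpha (scalar).
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2L || nrow(x) < 2L) stop("need >= 2 items and >= 2 observations")
  vt <- stats::var(rowSums(x))
  if (vt <= 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vt)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall and per-item MSA from the anti-image (partial) correlations:
#' \code{MSA = sum r^2 / (sum r^2 + sum partial r^2)} over off-diagonal
#' elements, partials taken from the inverse correlation matrix.
#'
#' @param R correlation matrix (symmetric, unit diagonal, p >= 3).
#' @return list with \code{overall} and named per-item \code{msa}.
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (p < 3L || !isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("R must be a symmetric correlation matrix with p >= 3")
  Rinv <- tryCatch(solve(R), error = function(e) stop("singular correlation matrix"))
  d <- 1 / sqrt(diag(Rinv))
  partial <- -Rinv * tcrossprod(d)          # anti-image correlations
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(partial[off]^2)
  if (r2 + q2 < 1e-12) stop("KMO undefined: all correlations are zero")
  item <- vapply(seq_len(p), function(i) {
    ri <- sum(R[i, -i]^2); qi <- sum(partial[i, -i]^2)
    ri / (ri + qi)
  }, 0)
  names(item) <- colnames(R)
  list(overall = r2 / (r2 + q2), msa = item)
}

#' Repeated-measures correlation
#'
#' Common within-subject association between two longitudinal measures,
#' computed ANCOVA-style: both variables are centered on subject means
#' and correlated, with error degrees of freedom \code{N - k - 1} (N
#' paired observations, k subjects). The confidence interval uses the
#' Fisher z transform with standard error \code{1/sqrt(df - 1)}.
#'
#' @param x,y numeric vectors.
#' @param subject subject identifier, same length.
#' @param conf confidence level (default 0.95).
#' @return list with \code{estimate}, \code{conf_low}, \code{conf_high},
#'   \code{df}, \code{p_value}, \code{n}, \code{method}.
#' @export
rm_correlation <- function(x, y, subject, conf = 0.95) {
  ok <- stats::complete.cases(x, y, subject)
  x <- x[ok]; y <- y[ok]; subject <- as.character(subject[ok])
  keep <- subject %in% names(which(table(subject) >= 2L))
  if (!any(keep)) stop("no subject has >= 2 paired visits")
  x <- x[keep]; y <- y[keep]; subject <- subject[keep]
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  if (sum(xc^2) < 1e-12 || sum(yc^2) < 1e-12)
    stop("no within-subject variance")
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  n <- length(x)
  k <- length(unique(subject))
  df <- n - k - 1L
  if (df < 1L) stop("not enough within-subject degrees of freedom")
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  zse <- 1 / sqrt(df - 1)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  ci <- tanh(z + c(-1, 1) * stats::qnorm(1 - (1 - conf) / 2) * zse)
  list(estimate = r, conf_low = ci[1], conf_high = ci[2], df = df,
       p_value = p, n = n, method = "repeated-measures")
}

#' Spearman correlation with Fisher-z confidence interval
#'
#' Spearman's rho on average ranks (ties shared), with the large-sample
#' 95\% interval \code{tanh(atanh(rho) +/- z / sqrt(n - 3))}.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @param conf confidence level (default 0.95).
#' @return list with \code{estimate}, \code{conf_low}, \code{conf_high},
#'   \code{n}, \code{p_value}, \code{method}.
#' @export
spearman_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(z + c(-1, 1) * q / sqrt(n - 3))
  p <- 2 * stats::pnorm(-abs(z) * sqrt(n - 3))
  list(estimate = rho, conf_low = ci[1], conf_high = ci[2], n = n,
       p_value = p, method = "spearman")
}
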