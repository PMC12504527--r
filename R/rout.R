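# ROUT outlier detection for a single group of values (constant model):
# robust location fit via iteratively reweighted least squares with
# Lorentzian weights, residual scale from the robust standard deviation of
# the residuals (RSDR), and an FDR-controlled step-up test of the residual
# p-values at rate Q.

#' ROUT outlier detection (robust fit + FDR residual test)
#'
#' Fits a robust location to the sample (IRLS with Lorentzian weights
#' `1 / (1 + (residual / RSDR)^2)`, started at the median), estimates the
#' residual scale as the robust standard deviation of the residuals
#' (`RSDR = P68 * N / (N - K)` with `P68` the 68.27th percentile of the
#' absolute residuals and `K = 1` fitted parameter), converts residuals to
#' two-tailed p-values via `t = residual / RSDR` on `N - K` degrees of
#' freedom, and flags outliers by Benjamini-Hochberg step-up at rate
#' `Q` percent. Values whose residuals all stay within one RSDR are never
#' flagged. A constant sample yields no flags.
#'
#' @param values numeric sample, n >= 3.
#' @param Q false-discovery rate in percent (default 1, the conventional
#'   setting).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   fitted location.
#' @param p68 percentile defining the robust scale (default 68.27, the
#'   Gaussian one-sigma coverage).
#' @return A list: `cleaned` (values with outliers removed), `outliers`
#'   (integer indices flagged), `center` (robust location), `rsdr`,
#'   `p_values`.
#' @examples
#' rout_outliers(c(1, 2, 3, 2, 1, 100))$outliers # 6
#' @export
rout_outliers <- function(values, Q = 1, max_iter = 100L, tol = 1e-9,
                          p68 = 68.27) {
  n <- length(values)
  if (n < 3L) stop("ROUT needs at least 3 values")
  if (Q <= 0 || Q > 100) stop("Q is a percentage in (0, 100]")
  K <- 1L
  rsdr_of <- function(res)
    quantile(abs(res), p68 / 100, names = FALSE, type = 7) * n / (n - K)

  center <- median(values)
  if (all(values == center))
    return(list(cleaned = values, outliers = integer(0), center = center,
                rsdr = 0, p_values = rep(1, n)))
  for (it in seq_len(max_iter)) {
    res <- values - center
    rsdr <- rsdr_of(res)
    if (rsdr <= 0) break
    w <- 1 / (1 + (res / rsdr)^2)
    new_center <- sum(w * values) / sum(w)
    if (abs(new_center - center) < tol * (1 + abs(center))) {
      center <- new_center
      break
    }
    center <- new_center
  }
  res <- values - center
  rsdr <- rsdr_of(res)
  if (rsdr <= 0) {
    # majority of points coincide with the fit: any non-zero residual is
    # infinitely many robust SDs out
    p <- ifelse(res == 0, 1, 0)
  } else {
    p <- 2 * pt(-abs(res) / rsdr, df = n - K)
  }
  flagged <- which(p.adjust(p, method = "BH") < Q / 100)
  list(
    cleaned = if (length(flagged)) values[-flagged] else values,
    outliers = flagged,
    center = center,
    rsdr = rsdr,
    p_values = p
  )
}
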