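# A-priori power analysis for the multiple-regression R^2 test, via the
# noncentral F distribution.

#' Power of the overall regression F test at a given sample size
#'
#' For a fixed-model multiple regression with `n_predictors` predictors and
#' Cohen effect size `f2 = R2 / (1 - R2)`, the overall F statistic under the
#' alternative follows a noncentral F with `df1 = n_predictors`,
#' `df2 = N - n_predictors - 1` and noncentrality `lambda = f2 * N`
#' (the convention of standard power software; `lambda_convention =
#' "error_df"` uses `lambda = f2 * (df2 + 1)` instead).
#'
#' @param n total sample size.
#' @param f2 effect size (> 0).
#' @param n_predictors number of predictors (>= 1).
#' @param alpha test level in (0, 1).
#' @param lambda_convention `"total_n"` (default) or `"error_df"`.
#' @return achieved power in (0, 1).
#' @export
regression_power <- function(n, f2, n_predictors, alpha = 0.05,
                             lambda_convention = c("total_n", "error_df")) {
  lambda_convention <- match.arg(lambda_convention)
  df1 <- n_predictors
  df2 <- n - n_predictors - 1
  abort_if(any(df2 < 1), "regression_power: n too small for the model")
  lambda <- if (lambda_convention == "total_n") f2 * n else f2 * (df2 + 1)
  fcrit <- qf(1 - alpha, df1, df2)
  pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimal sample size for a target regression power
#'
#' Searches N upward from `n_predictors + 2` until the noncentral-F power of
#' the overall R^2 test first reaches `power`. With the default medium
#' effect `f2 = 0.3`, `alpha = 0.05`, `power = 0.9` and 4 predictors this
#' gives N = 57.
#'
#' @param f2 effect size (> 0).
#' @param alpha test level in (0, 1).
#' @param power target power in (0, 1).
#' @param n_predictors number of predictors (>= 1).
#' @param lambda_convention see [regression_power()].
#' @param n_max search ceiling.
#' @return smallest integer N reaching the target power.
#' @examples
#' required_sample_size(f2 = 0.3, alpha = 0.05, power = 0.9, n_predictors = 4)
#' @export
required_sample_size <- function(f2, alpha = 0.05, power = 0.9, n_predictors,
                                 lambda_convention = "total_n", n_max = 1e6) {
  abort_if(f2 <= 0, "required_sample_size: f2 must be > 0")
  abort_if(alpha <= 0 || alpha >= 1, "required_sample_size: alpha must be in (0, 1)")
  abort_if(power <= 0 || power >= 1, "required_sample_size: power must be in (0, 1)")
  abort_if(n_predictors < 1, "required_sample_size: n_predictors must be >= 1")
  n <- n_predictors + 2
  while (n <= n_max) {
    if (regression_power(n, f2, n_predictors, alpha, lambda_convention) >= power) {
      return(as.integer(n))
    }
    n <- n + 1
  }
  stop("required_sample_size: target power not attainable within n_max", call. = FALSE)
}

#' Monte-Carlo check of regression power
#'
#' Simulates `reps` datasets of size `n` with `n_predictors` independent
#' standard-normal predictors and true `R2 = f2 / (1 + f2)`, fits the
#' regression, and returns the rejection rate of the overall F test — an
#' independent simulation estimate of [regression_power()].
#'
#' @param n sample size per replicate.
#' @param f2 effect size.
#' @param n_predictors number of predictors.
#' @param alpha test level.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return estimated power (rejection proportion).
#' @export
mc_regression_power <- function(n, f2, n_predictors, alpha = 0.05,
                                reps = 10000, seed = 1) {
  r2 <- f2 / (1 + f2)
  b <- sqrt(r2 / n_predictors)
  sigma <- sqrt(1 - r2)
  df1 <- n_predictors
  df2 <- n - n_predictors - 1
  fcrit <- qf(1 - alpha, df1, df2)
  withr::with_seed(seed, {
    rejections <- vapply(seq_len(reps), function(i) {
      X <- matrix(rnorm(n * n_predictors), n, n_predictors)
      y <- X %*% rep(b, n_predictors) + rnorm(n, sd = sigma)
      qx <- qr(cbind(1, X))
      res <- qr.resid(qx, y)
      rss <- sum(res^2)
      tss <- sum((y - mean(y))^2)
      fstat <- ((tss - rss) / df1) / (rss / df2)
      fstat > fcrit
    }, logical(1))
    mean(rejections)
  })
}
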