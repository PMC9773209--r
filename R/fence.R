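# Outlier fencing and descriptive statistics.

#' Adjust outliers to the quartiles using a k x IQR fence
#'
#' Per column, values below `Q1 - k*IQR` are set to `Q1` and values above
#' `Q3 + k*IQR` are set to `Q3` (a conservative screen for unsupervised
#' online data; values exactly on a fence are retained). Quartiles use
#' linear interpolation between order statistics (R's default type-7
#' quantiles).
#'
#' @param table data frame of numeric measure columns.
#' @param k fence multiplier (default 3).
#' @param cols columns to screen; defaults to all numeric columns.
#' @param quantile_type quantile algorithm passed to [stats::quantile()].
#' @return list with `table` (adjusted copy) and `report` (class
#'   `fence_report`): per-column `Q1`, `Q3`, `IQR`, the `adjusted_cells`
#'   data frame (row, column, old, new), and `n_adjusted`.
#' @examples
#' fence_adjust(data.frame(x = c(1:10, 1000)))$report$n_adjusted # 1
#' @export
fence_adjust <- function(table, k = 3, cols = NULL, quantile_type = 7) {
  if (is.null(cols)) {
    cols <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  summaries <- data.frame(column = cols, Q1 = NA_real_, Q3 = NA_real_,
                          IQR = NA_real_, stringsAsFactors = FALSE)
  cells <- list()
  out <- table
  for (j in seq_along(cols)) {
    col <- cols[j]
    x <- table[[col]]
    ok <- !is.na(x)
    abort_if(sum(ok) < 4,
             sprintf("fence_adjust: column '%s' needs >= 4 non-missing values", col))
    q <- quantile(x[ok], c(0.25, 0.75), type = quantile_type, names = FALSE)
    iqr <- q[2] - q[1]
    summaries$Q1[j] <- q[1]; summaries$Q3[j] <- q[2]; summaries$IQR[j] <- iqr
    lo <- which(ok & x < q[1] - k * iqr)
    hi <- which(ok & x > q[2] + k * iqr)
    if (length(lo) + length(hi) > 0) {
      cells[[col]] <- data.frame(
        row = c(lo, hi), column = col,
        old = x[c(lo, hi)],
        new = c(rep(q[1], length(lo)), rep(q[2], length(hi))),
        stringsAsFactors = FALSE
      )
      out[[col]][lo] <- q[1]
      out[[col]][hi] <- q[2]
    }
  }
  adjusted <- if (length(cells)) do.call(rbind, c(cells, make.row.names = FALSE)) else
    data.frame(row = integer(0), column = character(0), old = numeric(0),
               new = numeric(0))
  report <- structure(list(summaries = summaries, k = k,
                           adjusted_cells = adjusted,
                           n_adjusted = nrow(adjusted),
                           n_screened = length(cols) * nrow(table)),
                      class = "fence_report")
  list(table = out, report = report)
}

#' @export
print.fence_report <- function(x, ...) {
  cat(sprintf("<fence_report: k = %g, %d of %d screened observations adjusted>\n",
              x$k, x$n_adjusted, x$n_screened))
  invisible(x)
}

#' Descriptive statistics for one measure
#'
#' Mean, sample SD (n-1), range, adjusted Fisher-Pearson skewness (G1) and
#' excess kurtosis (G2; normal data gives 0).
#'
#' @param x numeric vector (>= 3 non-missing values; nonzero variance for
#'   skew/kurtosis).
#' @return named list: `mean`, `sd`, `min`, `max`, `skew`, `kurtosis`, `n`.
#' @export
describe <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  abort_if(n < 3, "describe: need at least 3 values")
  m2 <- mean((x - mean(x))^2)
  abort_if(m2 == 0, "describe: zero variance, skew/kurtosis undefined")
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  list(mean = mean(x), sd = sd(x), min = min(x), max = max(x),
       skew = G1, kurtosis = G2, n = n)
}

#' Descriptive table for a set of measures
#'
#' @param table data frame.
#' @param cols columns to describe (default: all numeric).
#' @return tibble with one row per measure: mean, sd, min, max, skew,
#'   kurtosis.
#' @export
describe_table <- function(table, cols = NULL) {
  if (is.null(cols)) cols <- names(table)[vapply(table, is.numeric, logical(1))]
  dplyr::bind_rows(lapply(cols, function(col) {
    d <- describe(table[[col]])
    tibble::tibble(measure = col, mean = d$mean, sd = d$sd, min = d$min,
                   max = d$max, skew = d$skew, kurtosis = d$kurtosis)
  }))
}
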