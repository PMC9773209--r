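# Omnibus and pairwise comparisons across sentence conditions, and the
# correlation screen between cognitive/linguistic measures and condition
# scores.

check_groups <- function(values, groups, min_per_group = 2) {
  abort_if(length(values) != length(groups),
           "values and groups must have equal length")
  g <- split(values, groups)
  abort_if(length(g) < 2, "need at least 2 groups")
  sizes <- vapply(g, length, integer(1))
  abort_if(any(sizes < min_per_group),
           sprintf("each group needs >= %d values", min_per_group))
  g
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group center. The classic
#' Levene test centers on the group mean (default); `center = "median"`
#' gives the Brown-Forsythe variant.
#'
#' @param values numeric outcome vector.
#' @param groups group labels, same length as `values`.
#' @param center `"mean"` (classic) or `"median"`.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- check_groups(values, groups)
  centers <- vapply(g, if (center == "mean") mean else median, numeric(1))
  groups <- factor(groups)
  absdev <- abs(values - centers[as.character(groups)])
  fit <- stats::anova(lm(absdev ~ groups))
  list(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1])
}

#' Welch's heteroscedasticity-robust one-way ANOVA
#'
#' Welch's F with Welch-Satterthwaite denominator degrees of freedom, via
#' [stats::oneway.test()] with `var.equal = FALSE`.
#'
#' @inheritParams levene_test
#' @return object of class `anova_result`: `F`, `df1`, `df2` (fractional),
#'   `p`, and a `groups` tibble of per-group n, mean, variance.
#' @export
welch_anova <- function(values, groups) {
  g <- check_groups(values, groups)
  vars <- vapply(g, var, numeric(1))
  abort_if(any(vars == 0), "welch_anova: zero-variance group")
  fit <- oneway.test(values ~ factor(groups), var.equal = FALSE)
  structure(list(
    F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
    df2 = unname(fit$parameter[2]), p = unname(fit$p.value),
    groups = tibble::tibble(group = names(g),
                            n = vapply(g, length, integer(1)),
                            mean = vapply(g, mean, numeric(1)),
                            variance = vars)
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Welch one-way ANOVA: F(%g, %.1f) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Pairwise Welch t-tests with Benjamini-Hochberg correction
#'
#' Two-sided Welch t-tests (no equal-variance assumption) for every
#' unordered pair of groups; p-values are adjusted over all `choose(g, 2)`
#' comparisons by the BH step-up procedure.
#'
#' @inheritParams levene_test
#' @return list with symmetric matrices `p_raw` and `p_adjusted`, and a
#'   tidy `pairs` tibble.
#' @export
pairwise_welch_bh <- function(values, groups) {
  g <- check_groups(values, groups)
  nm <- names(g)
  combos <- utils::combn(nm, 2)
  raw <- apply(combos, 2, function(pr) {
    t.test(g[[pr[1]]], g[[pr[2]]], var.equal = FALSE)$p.value
  })
  adj <- p.adjust(raw, method = "BH")
  p_raw <- p_adj <- matrix(NA_real_, length(nm), length(nm),
                           dimnames = list(nm, nm))
  for (k in seq_len(ncol(combos))) {
    i <- combos[1, k]; j <- combos[2, k]
    p_raw[i, j] <- p_raw[j, i] <- raw[k]
    p_adj[i, j] <- p_adj[j, i] <- adj[k]
  }
  list(p_raw = p_raw, p_adjusted = p_adj,
       pairs = tibble::tibble(group1 = combos[1, ], group2 = combos[2, ],
                              p_raw = raw, p_adjusted = adj))
}

#' Pearson correlation screen
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from the t
#' transform (unadjusted, as conventional for a screening table).
#'
#' @param table data frame.
#' @param cols columns to correlate (default: all numeric).
#' @return list with symmetric matrices `r` (unit diagonal) and `p`.
#' @export
correlation_screen <- function(table, cols = NULL) {
  if (is.null(cols)) cols <- names(table)[vapply(table, is.numeric, logical(1))]
  m <- length(cols)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(cols, cols))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      x <- table[[cols[i]]]; y <- table[[cols[j]]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      abort_if(n < 3, sprintf("correlation_screen: < 3 complete pairs for %s/%s",
                              cols[i], cols[j]))
      abort_if(sd(x[ok]) == 0 || sd(y[ok]) == 0,
               sprintf("correlation_screen: zero variance in %s or %s",
                       cols[i], cols[j]))
      rij <- cor(x[ok], y[ok])
      tstat <- rij * sqrt((n - 2) / (1 - rij^2))
      r[i, j] <- r[j, i] <- rij
      p[i, j] <- p[j, i] <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
    }
  }
  list(r = r, p = p)
}

#' Bonferroni-adjusted alpha level
#'
#' @param base_alpha nominal test level.
#' @param m number of comparisons (>= 1).
#' @return `base_alpha / m` (e.g. 0.05 / 24 = 0.00208).
#' @export
bonferroni_alpha <- function(base_alpha, m) {
  abort_if(m < 1, "bonferroni_alpha: m must be >= 1")
  base_alpha / m
}
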