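# Normalized-predictor linear models, purposeful predictor selection with a
# delta-beta reinstatement check, and model diagnostics.

#' Fit a linear model with z-scored (normalized) predictors
#'
#' Predictors are standardized to mean 0, SD 1 before ordinary least
#' squares, so each coefficient is the change in the outcome per 1 SD of the
#' predictor. 95% confidence intervals come from the t distribution.
#'
#' @param table data frame.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names; may include
#'   interaction terms written as `"a:b"` (the product of the two z-scored
#'   columns).
#' @param normalize z-score the predictors (default TRUE).
#' @param conf_level confidence level for coefficient intervals.
#' @return object of class `model_fit`: `coefficients` tibble (term, beta,
#'   ci_low, ci_high, t, p), `r_squared`, `adj_r_squared`, `f_statistic`,
#'   `f_df1`, `f_df2`, `f_p`, `n`, the underlying `lm`, and `residuals`.
#' @export
fit_model <- function(table, outcome, predictors, normalize = TRUE,
                      conf_level = 0.95) {
  abort_if(length(predictors) == 0, "fit_model: empty predictor set")
  base_vars <- unique(unlist(strsplit(predictors, ":", fixed = TRUE)))
  dat <- table[, c(outcome, base_vars)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  abort_if(nrow(dat) < length(predictors) + 2,
           "fit_model: too few complete cases for the model")
  if (normalize) {
    for (v in base_vars) {
      s <- sd(dat[[v]])
      abort_if(is.na(s) || s == 0, sprintf("fit_model: predictor '%s' is constant", v))
      dat[[v]] <- (dat[[v]] - mean(dat[[v]])) / s
    }
  }
  for (tm in predictors[grepl(":", predictors, fixed = TRUE)]) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    dat[[tm]] <- dat[[vars[1]]] * dat[[vars[2]]]
  }
  X <- as.matrix(dat[, predictors, drop = FALSE])
  abort_if(qr(cbind(1, X))$rank < ncol(X) + 1,
           "fit_model: rank-deficient design (collinear predictors)")
  # interaction terms carry ':' in their names; give lm syntactic columns
  safe <- make.names(gsub(":", "_x_", predictors, fixed = TRUE), unique = TRUE)
  fml_dat <- data.frame(.y = dat[[outcome]], X)
  names(fml_dat) <- c(".y", safe)
  fit <- lm(.y ~ ., data = fml_dat)
  sm <- summary(fit)
  ci <- confint(fit, level = conf_level)
  terms_out <- rownames(sm$coefficients)
  idx <- match(terms_out, safe)
  terms_out[!is.na(idx)] <- predictors[idx[!is.na(idx)]]
  coefs <- tibble::tibble(
    term = terms_out,
    beta = unname(sm$coefficients[, 1]),
    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
    t = unname(sm$coefficients[, 3]), p = unname(sm$coefficients[, 4])
  )
  structure(list(
    outcome = outcome, predictors = predictors, coefficients = coefs,
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(sm$fstatistic[1]),
    f_df1 = unname(sm$fstatistic[2]), f_df2 = unname(sm$fstatistic[3]),
    f_p = pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
             lower.tail = FALSE),
    n = nrow(dat), lm = fit, residuals = resid(fit), data = dat
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Linear model for '%s' (n = %d): R2 = %.3f, adj R2 = %.3f, F(%g, %g) = %.2f, p = %.4g\n",
              x$outcome, x$n, x$r_squared, x$adj_r_squared, x$f_df1, x$f_df2,
              x$f_statistic, x$f_p))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Purposeful selection of regression predictors
#'
#' Starts from the saturated model and iteratively removes the non-hypothesis
#' predictor with the largest p-value above `p_stay`. After each removal the
#' retained coefficients are compared with the previous model: if any changes
#' by more than `delta_beta_max` (relative), the removed predictor is
#' reinstated as a confounder and locked in. Once no predictor can be
#' removed, pairwise interactions among the survivors are tested one at a
#' time and kept only if significant at `alpha_interaction`.
#'
#' The removal direction is that of the purposeful-selection literature:
#' predictors leave when their p-value exceeds `p_stay`.
#' `literal_direction = TRUE` flips the criterion (removal when p < `p_stay`)
#' to reproduce a literal reading sometimes seen in applied reports.
#'
#' @param table data frame.
#' @param outcome outcome column name.
#' @param saturated character vector: the full predictor set.
#' @param hypothesis_set predictors never removed regardless of p (subset of
#'   `saturated`).
#' @param p_stay removal threshold on the predictor p-value (default 0.25).
#' @param delta_beta_max relative coefficient-change threshold for
#'   reinstating a confounder (default 0.20).
#' @param alpha_interaction significance level for interaction screening.
#' @param check_interactions test pairwise interactions among survivors.
#' @param literal_direction invert the removal criterion (see above).
#' @return list with `final` (predictor set), `fit` (the final
#'   [fit_model()]), and `audit` (tibble of every step taken).
#' @export
purposeful_selection <- function(table, outcome, saturated,
                                 hypothesis_set = character(0),
                                 p_stay = 0.25, delta_beta_max = 0.20,
                                 alpha_interaction = 0.05,
                                 check_interactions = TRUE,
                                 literal_direction = FALSE) {
  abort_if(length(saturated) == 0, "purposeful_selection: empty saturated set")
  abort_if(!all(hypothesis_set %in% saturated),
           "purposeful_selection: hypothesis_set must be a subset of saturated")
  current <- saturated
  locked <- character(0)
  audit <- list()
  note <- function(action, predictor, detail) {
    audit[[length(audit) + 1]] <<- tibble::tibble(
      step = length(audit) + 1, action = action, predictor = predictor,
      detail = detail)
  }
  fit <- fit_model(table, outcome, current)

  repeat {
    pvals <- fit$coefficients[match(current, fit$coefficients$term), ]
    removable <- setdiff(current, c(hypothesis_set, locked))
    if (length(removable) == 0) break
    pr <- pvals[pvals$term %in% removable, ]
    candidates <- if (literal_direction) pr[pr$p < p_stay, ] else pr[pr$p > p_stay, ]
    if (nrow(candidates) == 0) break
    drop_term <- candidates$term[which.max(candidates$p)]
    reduced <- setdiff(current, drop_term)
    if (length(reduced) == 0) break
    new_fit <- fit_model(table, outcome, reduced)
    old_b <- fit$coefficients$beta[match(reduced, fit$coefficients$term)]
    new_b <- new_fit$coefficients$beta[match(reduced, new_fit$coefficients$term)]
    rel_change <- abs(new_b - old_b) / pmax(abs(old_b), .Machine$double.eps)
    if (any(rel_change > delta_beta_max)) {
      locked <- c(locked, drop_term)
      note("reinstate", drop_term,
           sprintf("max delta-beta %.1f%% > %.0f%%: confounder locked in",
                   100 * max(rel_change), 100 * delta_beta_max))
    } else {
      current <- reduced
      fit <- new_fit
      note("remove", drop_term,
           sprintf("p = %.3f %s %.2f; max delta-beta %.1f%%",
                   max(candidates$p), if (literal_direction) "<" else ">",
                   p_stay, 100 * max(rel_change)))
    }
  }

  if (check_interactions && length(current) >= 2) {
    combos <- utils::combn(current, 2)
    for (k in seq_len(ncol(combos))) {
      tm <- paste(combos[1, k], combos[2, k], sep = ":")
      trial <- tryCatch(fit_model(table, outcome, c(current, tm)),
                        error = function(e) NULL)
      if (is.null(trial)) next
      p_int <- trial$coefficients$p[trial$coefficients$term == tm]
      if (length(p_int) == 1 && !is.na(p_int) && p_int < alpha_interaction) {
        current <- c(current, tm)
        fit <- trial
        note("keep_interaction", tm, sprintf("p = %.4f < %.2f", p_int, alpha_interaction))
      } else {
        note("drop_interaction", tm, sprintf("p = %.4f >= %.2f", p_int, alpha_interaction))
      }
    }
  }
  list(final = current, fit = fit, audit = dplyr::bind_rows(audit))
}

#' Regression diagnostics: collinearity, heteroscedasticity, normality
#'
#' Variance inflation factors (`1 / (1 - R2_j)` from regressing each
#' predictor on the others), the studentized Breusch-Pagan test
#' ([lmtest::bptest()]), and a Shapiro-Wilk test on the residuals.
#'
#' @param fit a [fit_model()] result with >= 2 predictors.
#' @return object of class `diagnostics_report`: `vif` (named vector),
#'   `bp_statistic`, `bp_p`, `shapiro_statistic`, `shapiro_p`.
#' @export
diagnostics <- function(fit) {
  abort_if(!inherits(fit, "model_fit"), "diagnostics: need a model_fit")
  preds <- fit$predictors
  abort_if(length(preds) < 2, "diagnostics: VIF needs >= 2 predictors")
  X <- fit$data[, preds, drop = FALSE]
  names(X) <- make.names(gsub(":", "_x_", preds, fixed = TRUE), unique = TRUE)
  vif <- vapply(seq_along(preds), function(i) {
    v <- names(X)[i]
    r2 <- summary(lm(X[[v]] ~ ., data = X[, -i, drop = FALSE]))$r.squared
    abort_if(r2 > 1 - 1e-12,
             sprintf("diagnostics: perfect collinearity at '%s'", preds[i]))
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- preds
  bp <- lmtest::bptest(fit$lm, studentize = TRUE)
  sw <- shapiro.test(fit$residuals)
  structure(list(vif = vif, bp_statistic = unname(bp$statistic),
                 bp_p = unname(bp$p.value),
                 shapiro_statistic = unname(sw$statistic),
                 shapiro_p = unname(sw$p.value)),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("VIF: %s\n", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                                 collapse = ", ")))
  cat(sprintf("Studentized Breusch-Pagan: BP = %.3f, p = %.4g\n",
              x$bp_statistic, x$bp_p))
  cat(sprintf("Shapiro-Wilk on residuals: W = %.3f, p = %.4g\n",
              x$shapiro_statistic, x$shapiro_p))
  invisible(x)
}
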