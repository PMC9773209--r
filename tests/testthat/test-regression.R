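sim_table <- function(n, betas, noise_sd = 1, seed = 1, corr = 0) {
  withr::with_seed(seed, {
    k <- length(betas)
    sigma <- matrix(corr, k, k); diag(sigma) <- 1
    X <- MASS::mvrnorm(n, rep(0, k), sigma)
    colnames(X) <- paste0("x", seq_len(k))
    y <- drop(X %*% betas) + rnorm(n, sd = noise_sd)
    data.frame(y = y, X)
  })
}

test_that("fit_model with one z-scored predictor matches the bivariate identity", {
  tab <- sim_table(200, betas = 2, seed = 3)
  fit <- fit_model(tab, "y", "x1")
  r <- cor(tab$y, tab$x1)
  expect_equal(fit$coefficients$beta[fit$coefficients$term == "x1"],
               r * sd(tab$y), tolerance = 1e-10)
  # intercept is the outcome mean when the predictor is centered
  expect_equal(fit$coefficients$beta[1], mean(tab$y), tolerance = 1e-10)
  expect_equal(fit$r_squared, r^2, tolerance = 1e-10)
  expect_lte(fit$adj_r_squared, fit$r_squared)
  # the CI brackets the estimate
  cf <- fit$coefficients
  expect_true(all(cf$ci_low <= cf$beta & cf$beta <= cf$ci_high))
})

test_that("betas on z-scored predictors are invariant to affine predictor rescaling", {
  tab <- sim_table(100, betas = c(1.5, -0.7), seed = 5)
  fit1 <- fit_model(tab, "y", c("x1", "x2"))
  tab2 <- tab
  tab2$x1 <- 100 + 7 * tab$x1
  tab2$x2 <- -3 * tab$x2
  fit2 <- fit_model(tab2, "y", c("x1", "x2"))
  expect_equal(abs(fit2$coefficients$beta), abs(fit1$coefficients$beta),
               tolerance = 1e-10)
})

test_that("duplicated predictors raise a rank-deficiency error", {
  tab <- sim_table(50, betas = 1, seed = 7)
  tab$x_dup <- tab$x1
  expect_error(fit_model(tab, "y", c("x1", "x_dup")), "rank-deficient")
})

test_that("purposeful selection removes planted null predictors", {
  # under the null the predictor p-value is uniform, so the p > 0.25 rule
  # removes it in 75% of datasets; check the rate and that a stricter
  # threshold removes more often
  removed <- vapply(1:40, function(s) {
    tab <- sim_table(500, betas = c(1, 0.8, 0), seed = 100 + s)
    sel <- purposeful_selection(tab, "y", c("x1", "x2", "x3"),
                                hypothesis_set = c("x1", "x2"),
                                check_interactions = FALSE)
    !("x3" %in% sel$final)
  }, logical(1))
  expect_lt(abs(mean(removed) - 0.75), 0.2)
  removed_strict <- vapply(1:40, function(s) {
    tab <- sim_table(500, betas = c(1, 0.8, 0), seed = 100 + s)
    sel <- purposeful_selection(tab, "y", c("x1", "x2", "x3"),
                                hypothesis_set = c("x1", "x2"),
                                p_stay = 0.05, check_interactions = FALSE)
    !("x3" %in% sel$final)
  }, logical(1))
  expect_gt(mean(removed_strict), 0.85)
  expect_gte(mean(removed_strict), mean(removed))
})

test_that("hypothesis-set predictors are never removed regardless of p", {
  tab <- sim_table(200, betas = c(1, 0, 0), seed = 11)
  sel <- purposeful_selection(tab, "y", c("x1", "x2", "x3"),
                              hypothesis_set = c("x2", "x3"),
                              check_interactions = FALSE)
  expect_true(all(c("x2", "x3") %in% sel$final))
})

test_that("a planted confounder is reinstated by the delta-beta check", {
  for (s in 1:20) {
    tab <- confounded_table(900 + s)
    sel <- purposeful_selection(tab, "y", c("x1", "x2"),
                                hypothesis_set = "x1",
                                check_interactions = FALSE)
    # x2's own p exceeds 0.25, so removal is attempted; the > 20% shift in
    # beta(x1) forces reinstatement and locks x2 in
    expect_true("x2" %in% sel$final)
    expect_true(any(sel$audit$action == "reinstate" &
                      sel$audit$predictor == "x2"))
  }
})

test_that("significant interactions among survivors are kept, null ones dropped", {
  withr::with_seed(13, {
    n <- 400
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- x1 + x2 + 1.5 * x1 * x2 + rnorm(n)
    tab <- data.frame(y = y, x1 = x1, x2 = x2)
  })
  sel <- purposeful_selection(tab, "y", c("x1", "x2"),
                              hypothesis_set = c("x1", "x2"))
  expect_true("x1:x2" %in% sel$final)
  withr::with_seed(17, {
    tab0 <- data.frame(x1 = rnorm(400), x2 = rnorm(400))
    tab0$y <- tab0$x1 + tab0$x2 + rnorm(400)
  })
  sel0 <- purposeful_selection(tab0, "y", c("x1", "x2"),
                               hypothesis_set = c("x1", "x2"))
  expect_false("x1:x2" %in% sel0$final)
})

test_that("VIF is 1 for orthogonal predictors and matches car otherwise", {
  withr::with_seed(19, {
    # columns orthogonal to the intercept and to each other, so they stay
    # orthogonal after z-scoring
    X <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100, 3))))[, 2:4]
    tab <- data.frame(y = rnorm(100), x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
  })
  fit <- fit_model(tab, "y", c("x1", "x2", "x3"))
  dg <- diagnostics(fit)
  expect_equal(unname(dg$vif), rep(1, 3), tolerance = 1e-8)
  skip_if_not_installed("car")
  tab2 <- sim_table(120, betas = c(1, 1, 0), seed = 23, corr = 0.5)
  fit2 <- fit_model(tab2, "y", c("x1", "x2", "x3"))
  dg2 <- diagnostics(fit2)
  oracle <- car::vif(fit2$lm)
  expect_equal(unname(dg2$vif), unname(oracle), tolerance = 1e-8)
})

test_that("Breusch-Pagan and Shapiro-Wilk hold their nominal type-I rates", {
  withr::with_seed(29, {
    reps <- 1000
    ps <- t(vapply(seq_len(reps), function(i) {
      tab <- sim_table(63, betas = c(1, 0.5), noise_sd = 1, seed = 5000 + i)
      fit <- fit_model(tab, "y", c("x1", "x2"))
      dg <- diagnostics(fit)
      c(bp = dg$bp_p, sw = dg$shapiro_p)
    }, numeric(2)))
    expect_lt(abs(mean(ps[, "bp"] < 0.05) - 0.05), 0.025)
    expect_lt(abs(mean(ps[, "sw"] < 0.05) - 0.05), 0.025)
  })
})
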