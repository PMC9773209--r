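test_that("synthetic sentences have the configured length, determinism, and formants", {
  spec <- sentence_spec(duration_s = 1.5, sample_rate = 16000, seed = 5)
  s1 <- synth_sentence(spec, sentence_id = "s9")
  s2 <- synth_sentence(spec, sentence_id = "s9")
  expect_equal(length(s1$audio$samples), round(1.5 * 16000))
  expect_identical(s1$audio$samples, s2$audio$samples)
  expect_identical(s1$keywords, s2$keywords)
  expect_length(s1$keywords$keywords, 4)

  # PSD peaks near each configured formant
  est <- welch_psd(s1$audio, nfft = 2048)
  for (f in spec$formants_hz) {
    near <- est$freq > f - 50 & est$freq < f + 50
    away <- est$freq > f + 150 & est$freq < f + 350
    expect_gt(max(est$psd[near]), max(est$psd[away]))
  }
  expect_error(sentence_spec(f0_hz = 600, formants_hz = 500), "f0")
})

test_that("study_design instantiates 6 conditions x 60 sentences", {
  d <- study_design()
  expect_equal(nrow(d), 360)
  expect_equal(length(unique(d$condition)), 6)
  expect_equal(as.integer(table(d$condition)), rep(60L, 6))
  expect_equal(length(unique(d$sentence_id)), 360)
})

test_that("simulated abilities reproduce the configured correlation structure", {
  corr <- matrix(0.2, 4, 4); diag(corr) <- 1
  co <- simulate_cohort(cohort_spec(n = 5000, ability_corr = corr, seed = 2))
  z <- attr(co, "abilities")
  expect_lt(max(abs(cor(z) - corr)), 0.05)
})

test_that("null effects give near-zero ability-score correlations", {
  betas0 <- default_betas() * 0
  co <- simulate_cohort(cohort_spec(n = 2000, betas = betas0, seed = 3))
  z <- attr(co, "abilities")
  for (cond in names(default_condition_means())) {
    expect_lt(abs(cor(z[, "working_memory"], co[[cond]])), 0.1)
  }
})

test_that("cohort measures stay inside their defined ranges", {
  co <- simulate_cohort(cohort_spec(n = 1000, seed = 7))
  expect_true(all(co$rst_percent >= 0 & co$rst_percent <= 100))
  expect_true(all(co$dst_percentile > 0 & co$dst_percentile < 100))
  expect_true(all(co$stroop_interference > 0))
  expect_true(all(co$lextale_percent <= 100))
  for (cond in names(default_condition_means())) {
    expect_true(all(co[[cond]] >= 0 & co[[cond]] <= 100))
  }
  expect_equal(length(screened_measures()), 17)
  expect_true(all(screened_measures() %in% names(co)))
})

test_that("invalid cohort specifications are rejected", {
  bad_corr <- matrix(0.99, 4, 4); diag(bad_corr) <- 1; bad_corr[1, 2] <- -0.99
  bad_corr[2, 1] <- -0.99
  expect_error(cohort_spec(ability_corr = bad_corr), "positive-definite")
  expect_error(cohort_spec(residual_sd = 0), "residual_sd")
  expect_error(cohort_spec(condition_means = c(a = 120)), "\\[0, 100\\]")
})

test_that("OLS on generated cohorts recovers the betas within 2 SE (>= 93%)", {
  predictors <- c("rst_percent", "lextale_percent", "stroop_interference",
                  "stroop_speed_ms")
  truth <- default_betas()["presto_noise", ]
  hits <- vapply(1:200, function(s) {
    co <- simulate_cohort(cohort_spec(n = 63, seed = 4000 + s))
    fit <- fit_model(co, "presto_noise", predictors)
    cf <- fit$coefficients[match(predictors, fit$coefficients$term), ]
    se <- (cf$ci_high - cf$ci_low) / (2 * qt(0.975, fit$n - length(predictors) - 1))
    abs(cf$beta - truth) <= 2 * se
  }, logical(4))
  expect_gte(mean(hits), 0.93)
})

test_that("generator typos are always accepted by the scorer (rule closure)", {
  withr::with_seed(47, {
    words <- c("attack", "butter", "don't", "take", "oath", "puzzle", "ribbon")
    for (rep in 1:200) {
      w <- sample(words, 1)
      t <- keyword_typo(w)
      expect_true(keyword_matches(w, t), label = paste(w, "->", t))
    }
  })
})

test_that("scored percent depends on p_report only, not on typos", {
  withr::with_seed(51, {
    kls <- lapply(1:500, function(i)
      list(sentence_id = paste0("s", i),
           keywords = sample(c("attack", "butter", "ribbon", "take", "oath"), 4)))
  })
  tr <- simulate_transcripts(kls, p_report = 0.6, p_typo = 0.5, seed = 99)
  results <- lapply(seq_along(kls), function(i)
    score_response(kls[[i]], tr$transcript[i]))
  pct <- 100 * sum(vapply(results, `[[`, integer(1), "n_correct")) /
    sum(vapply(results, `[[`, integer(1), "n_keywords"))
  # binomial sd of the pooled percent at 2000 keywords is ~1.1
  expect_lt(abs(pct - 60), 4)
  # degenerate probabilities
  tr1 <- simulate_transcripts(kls[1:20], 1, 0, seed = 1)
  r1 <- vapply(1:20, function(i)
    score_response(kls[[i]], tr1$transcript[i])$n_correct, integer(1))
  expect_equal(sum(r1), 80)
  tr0 <- simulate_transcripts(kls[1:20], 0, 0, seed = 1)
  expect_true(all(tr0$transcript == ""))
})

test_that("transcripts are deterministic in the seed", {
  kls <- list(list(sentence_id = "s1", keywords = c("attack", "oath")))
  a <- simulate_transcripts(kls, 0.5, 0.5, seed = 7)
  b <- simulate_transcripts(kls, 0.5, 0.5, seed = 7)
  expect_identical(a, b)
})

test_that("the configured condition ordering is recovered at n = 63", {
  # noise > silent within each set, high > low context, for nearly all seeds
  ok <- vapply(1:40, function(s) {
    co <- simulate_cohort(cohort_spec(n = 63, seed = 7000 + s))
    m <- colMeans(co[, names(default_condition_means())])
    long <- data.frame(
      score = unlist(co[, names(default_condition_means())]),
      condition = rep(names(default_condition_means()), each = nrow(co)))
    wa <- welch_anova(long$score, long$condition)
    all(m["rspin_high_noise"] > m["rspin_high_silent"],
        m["rspin_low_noise"] > m["rspin_low_silent"],
        m["presto_noise"] > m["presto_silent"],
        m["rspin_high_silent"] > m["rspin_low_silent"],
        m["rspin_high_noise"] > m["rspin_low_noise"],
        wa$p < 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
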