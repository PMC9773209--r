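rst_rows <- function(targets_by_seq, responses) {
  dplyr::bind_rows(lapply(seq_along(targets_by_seq), function(s) {
    tibble::tibble(participant_id = "P1", task = "rst",
                   item_id = paste0("seq", s), condition = targets_by_seq[[s]],
                   response = responses[s], correct = NA, rt_ms = NA_real_,
                   timeout = FALSE)
  }))
}

test_that("reading span counts recalled targets in any order", {
  trials <- rst_rows(list(c("ball", "tree"), c("oath", "witness")),
                     c("tree ball", "witness"))
  expect_equal(score_rst(trials), 75) # 3 of 4, reverse order counted
  all_ok <- rst_rows(list(c("ball", "tree")), "ball tree")
  expect_equal(score_rst(all_ok), 100)
  none <- rst_rows(list(c("ball", "tree")), "")
  expect_equal(score_rst(none), 0)
  # a single typed token cannot satisfy two identical targets
  dup <- rst_rows(list(c("ball", "ball")), "ball")
  expect_equal(score_rst(dup), 50)
})

dst_rows <- function(task, correct_by_trial) {
  lens <- rep(2:(1 + length(correct_by_trial) / 2), each = 2)
  tibble::tibble(participant_id = "P1", task = task,
                 item_id = paste0(task, seq_along(correct_by_trial)),
                 condition = paste0(lens, "-", rep(1:2, length(lens) / 2)),
                 response = "digits", correct = correct_by_trial,
                 rt_ms = NA_real_, timeout = FALSE)
}

test_that("digit span stops a direction after both trials of a length fail", {
  # forward: both length-3 trials wrong -> length 4+ excluded from total
  fwd <- dst_rows("dst_forward", c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  bwd <- dst_rows("dst_backward", c(TRUE, FALSE, TRUE, TRUE))
  res <- score_digit_span(dplyr::bind_rows(fwd, bwd))
  expect_equal(res$total_correct, 2 + 3) # forward 2 (stop at len 3), backward 3
  expect_true(is.na(res$percentile))     # no norm table supplied
  # one of two wrong at a length: the direction continues
  fwd2 <- dst_rows("dst_forward", c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(score_digit_span(fwd2)$total_correct, 3)
})

test_that("digit span percentile comes from the norm table lookup", {
  all_ok <- dst_rows("dst_forward", rep(TRUE, 16))
  norms <- data.frame(total_correct = c(0, 10, 16), percentile = c(1, 50, 99))
  expect_equal(score_digit_span(all_ok, norms)$percentile, 99)
  some <- dst_rows("dst_forward", c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(score_digit_span(some, norms)$percentile, 1) # total 2 -> row 0
})

stroop_rows <- function(cond, rt, correct = TRUE) {
  tibble::tibble(participant_id = "P1", task = "stroop",
                 item_id = paste0(cond, seq_along(rt)), condition = cond,
                 response = "key", correct = correct, rt_ms = rt,
                 timeout = FALSE)
}

test_that("Stroop interference is the CW/C correct-RT ratio", {
  trials <- dplyr::bind_rows(stroop_rows("CW", c(550, 650)),
                             stroop_rows("C", c(450, 550)),
                             stroop_rows("W", c(400, 420)))
  res <- score_stroop(trials)
  expect_equal(res$interference, 600 / 500)
  expect_equal(res$speed_ms, 410)
  # identical RTs give interference exactly 1
  same <- dplyr::bind_rows(stroop_rows("CW", rep(500, 3)),
                           stroop_rows("C", rep(500, 3)),
                           stroop_rows("W", rep(500, 3)))
  expect_equal(score_stroop(same)$interference, 1)
  # incorrect trials are excluded from both means
  with_bad <- dplyr::bind_rows(trials,
                               stroop_rows("CW", 5000, correct = FALSE),
                               stroop_rows("C", 1, correct = FALSE))
  expect_equal(score_stroop(with_bad)$interference, 600 / 500)
  expect_error(score_stroop(stroop_rows("CW", 500)), "no correct 'C'")
})

test_that("Stroop interference is invariant to uniform RT rescaling", {
  trials <- dplyr::bind_rows(stroop_rows("CW", c(550, 650)),
                             stroop_rows("C", c(450, 550)),
                             stroop_rows("W", c(400, 420)))
  scaled <- dplyr::mutate(trials, rt_ms = rt_ms * 3.7)
  expect_equal(score_stroop(scaled)$interference,
               score_stroop(trials)$interference)
})

flanker_rows <- function(cond, rt, correct = TRUE) {
  tibble::tibble(participant_id = "P1", task = "flanker",
                 item_id = paste0(cond, seq_along(rt)), condition = cond,
                 response = "key", correct = correct, rt_ms = rt,
                 timeout = FALSE)
}

test_that("flanker interference is the incongruent-minus-congruent mean RT", {
  trials <- dplyr::bind_rows(flanker_rows("incongruent", c(540, 560)),
                             flanker_rows("congruent", c(490, 510)))
  expect_equal(score_flanker(trials), 50)
  equal <- dplyr::bind_rows(flanker_rows("incongruent", c(500, 500)),
                            flanker_rows("congruent", c(500, 500)))
  expect_equal(score_flanker(equal), 0)
  faster <- dplyr::bind_rows(flanker_rows("incongruent", 480),
                             flanker_rows("congruent", 500))
  expect_equal(score_flanker(faster), -20) # negative interference permitted
  shifted <- dplyr::mutate(trials, rt_ms = rt_ms + 123)
  expect_equal(score_flanker(shifted), 50) # invariant to constant shifts
})

lex_rows <- function(cond, correct, rt, timeout = FALSE) {
  tibble::tibble(participant_id = "P1", task = "lextale",
                 item_id = paste0(cond, seq_along(correct)), condition = cond,
                 response = "j", correct = correct, rt_ms = rt,
                 timeout = timeout)
}

test_that("LexTALE accuracy is the class-balanced average", {
  trials <- dplyr::bind_rows(
    lex_rows("word", rep(TRUE, 40), rep(700, 40)),
    lex_rows("nonword", rep(c(TRUE, FALSE), each = 10), rep(800, 20)))
  res <- score_lextale(trials)
  expect_equal(res$percent, (100 + 50) / 2)
  expect_equal(res$word_rt_ms, 700)
  all_ok <- dplyr::bind_rows(lex_rows("word", rep(TRUE, 4), rep(600, 4)),
                             lex_rows("nonword", rep(TRUE, 2), rep(650, 2)))
  expect_equal(score_lextale(all_ok)$percent, 100)
})

test_that("doubling nonword count at fixed accuracy leaves the percent unchanged", {
  half <- dplyr::bind_rows(
    lex_rows("word", rep(TRUE, 10), rep(700, 10)),
    lex_rows("nonword", rep(c(TRUE, FALSE), 5), rep(800, 10)))
  double <- dplyr::bind_rows(
    lex_rows("word", rep(TRUE, 10), rep(700, 10)),
    lex_rows("nonword", rep(c(TRUE, FALSE), 10), rep(800, 20)))
  expect_equal(score_lextale(half)$percent, score_lextale(double)$percent)
})

test_that("LexTALE timeouts score incorrect and leave the RT mean", {
  trials <- dplyr::bind_rows(
    lex_rows("word", c(TRUE, TRUE, TRUE), c(600, 800, 2000),
             timeout = c(FALSE, FALSE, TRUE)),
    lex_rows("nonword", c(TRUE, TRUE), c(700, 700)))
  res <- score_lextale(trials)
  expect_equal(res$word_rt_ms, 700)              # timeout excluded from RT
  expect_equal(res$percent, (100 * 2 / 3 + 100) / 2) # and scored incorrect
})

test_that("score_cognitive assembles the seven measures per participant", {
  co <- simulate_cohort(cohort_spec(n = 2, seed = 8))
  log <- dplyr::bind_rows(
    simulate_trial_log(co[1, ], seed = 1, participant_id = "P001"),
    simulate_trial_log(co[2, ], seed = 2, participant_id = "P002"))
  out <- score_cognitive(log, synthetic_dst_norms())
  expect_equal(nrow(out), 2)
  expect_true(all(c("rst_percent", "dst_percentile", "stroop_interference",
                    "stroop_speed_ms", "flanker_interference_ms",
                    "lextale_percent", "lextale_word_rt_ms") %in% names(out)))
  expect_true(all(out$rst_percent >= 0 & out$rst_percent <= 100))
  expect_true(all(out$stroop_interference > 0))
  # the generator's RT shifts make the filtered means land on target
  expect_equal(out$stroop_interference, co$stroop_interference[1:2],
               tolerance = 1e-10)
  expect_equal(out$flanker_interference_ms, co$flanker_interference_ms[1:2],
               tolerance = 1e-10)
})
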