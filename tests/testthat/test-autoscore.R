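test_that("transcript normalization lowercases, strips punctuation, keeps contractions", {
  expect_equal(normalize_transcript("The  Ball bounced."), c("the", "ball", "bounced"))
  expect_equal(normalize_transcript("don't"), "don't")
  expect_equal(normalize_transcript(""), character(0))
  expect_equal(normalize_transcript("well-known 42 'quote'"),
               c("well", "known", "quote"))
})

test_that("the spelling-tolerance rules accept exactly the stated variants", {
  expect_true(keyword_matches("attack", "atack"))   # double letter dropped
  expect_true(keyword_matches("take", "tkae"))      # adjacent transposition
  expect_false(keyword_matches("oath", "oat"))      # no rule produces this
  expect_true(keyword_matches("don't", "dont"))     # apostrophe omitted
  expect_true(keyword_matches("dont", "do'nt"))     # apostrophe inserted
  expect_false(keyword_matches("attack", "atak"))   # would need two rules
  rules_off <- scoring_rules(double_letter = FALSE, transposition = FALSE,
                             apostrophe = FALSE)
  expect_false(keyword_matches("attack", "atack", rules_off))
  expect_true(keyword_matches("attack", "attack", rules_off))
  custom <- scoring_rules(custom_spellings = list(gauge = c("gage")))
  expect_true(keyword_matches("gauge", "gage", custom))
})

test_that("keyword_matches agrees with the exhaustive variant oracle", {
  withr::with_seed(23, {
    for (rep in 1:150) {
      kw <- random_keyword(sample(3:8, 1))
      if (runif(1) < 0.3) { # sprinkle in apostrophe keywords
        pos <- sample(nchar(kw) - 1, 1)
        kw <- paste0(substr(kw, 1, pos), "'", substr(kw, pos + 1, nchar(kw)))
      }
      variants <- oracle_variants(kw)
      for (v in variants) {
        expect_true(keyword_matches(kw, v), label = paste(kw, "->", v))
      }
      # random perturbations not in the variant set must be rejected
      for (i in 1:5) {
        cand <- random_keyword(sample(3:8, 1))
        expect_equal(keyword_matches(kw, cand), cand %in% variants,
                     label = paste(kw, "vs", cand))
      }
    }
  })
})

test_that("scoring is an order-independent injective assignment", {
  kws <- list(sentence_id = "s1", keywords = c("witness", "took", "solemn", "oath"))
  expect_equal(score_response(kws, "the witness took a solemn oath")$n_correct, 4)
  expect_equal(score_response(kws, "oath solemn took witness")$n_correct, 4)
  expect_equal(score_response(kws, "")$n_correct, 0)
  # duplicate keywords consume distinct tokens
  dup <- list(sentence_id = "s2", keywords = c("ball", "ball"))
  expect_equal(score_response(dup, "ball")$n_correct, 1)
  expect_equal(score_response(dup, "ball ball")$n_correct, 2)
})

test_that("matching equals the brute-force assignment oracle on random cases", {
  withr::with_seed(31, {
    vocab <- c("ball", "bal", "attack", "atack", "take", "tkae", "oath",
               "oat", "dont", "don't", "tree", "stream")
    for (rep in 1:60) {
      kws <- sample(vocab, sample(1:4, 1), replace = TRUE)
      tokens <- sample(vocab, sample(0:4, 1), replace = TRUE)
      got <- score_response(list(sentence_id = "x", keywords = kws),
                            paste(tokens, collapse = " "))$n_correct
      expect_equal(got, oracle_max_match(kws, tokens),
                   label = paste(paste(kws, collapse = "+"), "|",
                                 paste(tokens, collapse = " ")))
    }
  })
})

test_that("adding a transcript token never decreases the score", {
  withr::with_seed(37, {
    kws <- list(sentence_id = "s", keywords = c("witness", "solemn", "oath"))
    base_tokens <- c("witness", "solemn")
    base <- score_response(kws, paste(base_tokens, collapse = " "))$n_correct
    for (extra in c("oath", "tree", "oat", "solem")) {
      grown <- score_response(kws, paste(c(base_tokens, extra), collapse = " "))$n_correct
      expect_gte(grown, base)
    }
  })
})

test_that("condition aggregation pools keywords, not sentence means", {
  r1 <- score_response(list(sentence_id = "a", keywords = c("w", "x", "y", "z")),
                       "w x")
  r2 <- score_response(list(sentence_id = "b", keywords = c("p", "q", "r", "s")),
                       "p q r s")
  design <- data.frame(sentence_id = c("a", "b"), condition = c("c1", "c1"))
  expect_equal(unname(aggregate_condition(list(r1, r2), design)), 75)
  expect_equal(unname(aggregate_condition(list(r1, r2), design, "mean")), 75)
  r3 <- score_response(list(sentence_id = "a", keywords = c("w", "x", "y")), "w")
  expect_equal(unname(aggregate_condition(list(r3, r2), design)),
               100 * 5 / 7) # pooled, not mean of 33.3 and 100
  # error paths: unmapped sentence and empty condition
  expect_error(aggregate_condition(list(r1), data.frame(sentence_id = "zz",
                                                        condition = "c1")),
               "not in design")
  design2 <- data.frame(sentence_id = c("a", "b"), condition = c("c1", "c2"))
  expect_error(aggregate_condition(list(r1), design2), "no scored sentences")
})

test_that("score_transcripts produces bounded percentages per participant", {
  kw <- data.frame(sentence_id = c("s1", "s2"), condition = c("c1", "c2"),
                   keyword_1 = c("witness", "ball"),
                   keyword_2 = c("oath", "tree"), stringsAsFactors = FALSE)
  resp <- data.frame(participant_id = c("P1", "P1"),
                     sentence_id = c("s1", "s2"),
                     transcript = c("the witness swore an oath", "ball"),
                     stringsAsFactors = FALSE)
  out <- score_transcripts(kw, resp)
  expect_equal(nrow(out), 2)
  expect_true(all(out$percent_correct >= 0 & out$percent_correct <= 100))
  expect_equal(out$percent_correct[out$condition == "c1"], 100)
  expect_equal(out$percent_correct[out$condition == "c2"], 50)
})
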