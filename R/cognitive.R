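# Scoring of the cognitive / linguistic battery from trial-level logs:
# reading span (complex working memory), digit span forward+backward (simple
# working memory, norm-referenced percentile), Stroop (inhibitory control +
# processing speed), flanker (response inhibition), LexTALE (lexical
# knowledge + lexical access speed).
#
# Trial-log layout (one row per trial):
#   participant_id, task, item_id, condition, response, correct, rt_ms, timeout
# Task-specific use of `condition`:
#   rst           target word; `response` holds the typed recall for the
#                 sequence in `item_id`
#   dst_forward / "<len>-<trial>" sequence length and trial index ("3-1")
#   dst_backward
#   stroop        "W" | "C" | "CW"
#   flanker       "congruent" | "incongruent"
#   lextale       "word" | "nonword"

#' Score the reading span task
#'
#' Percent of target words recalled in any order (case-insensitive exact
#' match, no typo tolerance). Each RST row carries one target word in
#' `condition` and the typed recall for its sequence in `response`; within a
#' sequence each typed token can satisfy at most one target.
#'
#' @param trials data frame of `task == "rst"` rows.
#' @return percent correct in \[0, 100\].
#' @export
score_rst <- function(trials) {
  trials <- trials[trials$task == "rst", , drop = FALSE]
  abort_if(nrow(trials) == 0, "score_rst: no reading-span trials")
  total <- nrow(trials)
  n_correct <- sum(vapply(split(trials, trials$item_id), function(seq_df) {
    targets <- tolower(seq_df$condition)
    tokens <- normalize_transcript(seq_df$response[1])
    hits <- 0L
    for (tg in targets) {
      j <- match(tg, tokens)
      if (!is.na(j)) {
        hits <- hits + 1L
        tokens <- tokens[-j]
      }
    }
    hits
  }, integer(1)))
  100 * n_correct / total
}

#' Score digit span forward + backward with a normative percentile lookup
#'
#' Two trials per sequence length per direction; a direction ends once both
#' trials of a length are incorrect (later trials in that direction are
#' excluded). The total is forward + backward correct trials; the percentile
#' is looked up in a user-supplied monotone norm table (`NA` when absent).
#'
#' @param trials data frame of `task %in% c("dst_forward", "dst_backward")`
#'   rows; `condition` is `"<length>-<trial>"`.
#' @param norm_table optional data frame with columns `total_correct` and
#'   `percentile`; the largest tabulated `total_correct` not exceeding the
#'   observed total is used.
#' @return list with `total_correct` and `percentile`.
#' @export
score_digit_span <- function(trials, norm_table = NULL) {
  trials <- trials[trials$task %in% c("dst_forward", "dst_backward"), , drop = FALSE]
  abort_if(nrow(trials) == 0, "score_digit_span: no digit-span trials")
  parts <- strsplit(as.character(trials$condition), "-", fixed = TRUE)
  trials$len <- as.integer(vapply(parts, `[`, character(1), 1))
  trials$idx <- as.integer(vapply(parts, `[`, character(1), 2))
  abort_if(anyNA(trials$len) || anyNA(trials$idx),
           "score_digit_span: condition must be '<length>-<trial>'")

  count_direction <- function(df) {
    df <- df[order(df$len, df$idx), ]
    total <- 0L
    for (len in sort(unique(df$len))) {
      pair <- df[df$len == len, ]
      total <- total + sum(pair$correct)
      if (!any(pair$correct)) break # both wrong: direction ends here
    }
    total
  }
  total <- sum(vapply(split(trials, trials$task), count_direction, integer(1)))
  percentile <- NA_real_
  if (!is.null(norm_table)) {
    nt <- norm_table[order(norm_table$total_correct), ]
    eligible <- nt$total_correct <= total
    abort_if(!any(eligible), "score_digit_span: total below norm table range")
    percentile <- nt$percentile[max(which(eligible))]
  }
  list(total_correct = as.integer(total), percentile = percentile)
}

#' Score the Stroop task
#'
#' Interference is the ratio of mean correct reaction time on incongruent
#' color-word (CW) items to color-only (C) items; processing speed is the
#' mean correct reaction time on word (W) items. Incorrect trials are
#' excluded from all means.
#'
#' @param trials data frame of `task == "stroop"` rows with `condition` in
#'   `{"W", "C", "CW"}`.
#' @return list with `interference` (CW/C ratio) and `speed_ms`.
#' @export
score_stroop <- function(trials) {
  trials <- trials[trials$task == "stroop", , drop = FALSE]
  mean_rt <- function(cond) {
    ok <- trials$condition == cond & trials$correct
    abort_if(!any(ok), sprintf("score_stroop: no correct '%s' trials", cond))
    mean(trials$rt_ms[ok])
  }
  list(interference = mean_rt("CW") / mean_rt("C"), speed_ms = mean_rt("W"))
}

#' Score the flanker task
#'
#' Mean correct incongruent reaction time minus mean correct congruent
#' reaction time, in ms (may be negative).
#'
#' @param trials data frame of `task == "flanker"` rows with `condition` in
#'   `{"congruent", "incongruent"}`.
#' @return interference in ms.
#' @export
score_flanker <- function(trials) {
  trials <- trials[trials$task == "flanker", , drop = FALSE]
  mean_rt <- function(cond) {
    ok <- trials$condition == cond & trials$correct
    abort_if(!any(ok), sprintf("score_flanker: no correct '%s' trials", cond))
    mean(trials$rt_ms[ok])
  }
  mean_rt("incongruent") - mean_rt("congruent")
}

#' Score the LexTALE lexical decision task
#'
#' Accuracy is the class-balanced average of percent correct on real words
#' and on non-words (so unequal item counts do not bias the score); lexical
#' access speed is the mean reaction time over correctly identified,
#' non-timeout real words. Timeouts are counted incorrect.
#'
#' @param trials data frame of `task == "lextale"` rows with `condition` in
#'   `{"word", "nonword"}`.
#' @return list with `percent` and `word_rt_ms`.
#' @export
score_lextale <- function(trials) {
  trials <- trials[trials$task == "lextale", , drop = FALSE]
  abort_if(nrow(trials) == 0, "score_lextale: no lextale trials")
  timeout <- if ("timeout" %in% names(trials)) {
    isTRUE_v <- trials$timeout %in% TRUE
    isTRUE_v
  } else rep(FALSE, nrow(trials))
  correct <- trials$correct & !timeout
  cls_acc <- function(cond) {
    ok <- trials$condition == cond
    abort_if(!any(ok), sprintf("score_lextale: no '%s' items", cond))
    100 * mean(correct[ok])
  }
  pct <- (cls_acc("word") + cls_acc("nonword")) / 2
  word_ok <- trials$condition == "word" & correct
  abort_if(!any(word_ok), "score_lextale: no correct real-word trials for RT")
  list(percent = pct, word_rt_ms = mean(trials$rt_ms[word_ok]))
}

#' Compute the seven cognitive/linguistic measures for every participant
#'
#' @param trials trial-log data frame (all tasks, all participants).
#' @param norm_table optional digit-span norm table, see
#'   [score_digit_span()].
#' @return tibble with one row per participant: `rst_percent`,
#'   `dst_percentile`, `stroop_interference`, `stroop_speed_ms`,
#'   `flanker_interference_ms`, `lextale_percent`, `lextale_word_rt_ms`.
#' @export
score_cognitive <- function(trials, norm_table = NULL) {
  out <- lapply(split(trials, trials$participant_id), function(df) {
    dst <- score_digit_span(df, norm_table)
    stroop <- score_stroop(df)
    lex <- score_lextale(df)
    tibble::tibble(
      participant_id = df$participant_id[1],
      rst_percent = score_rst(df),
      dst_percentile = dst$percentile,
      stroop_interference = stroop$interference,
      stroop_speed_ms = stroop$speed_ms,
      flanker_interference_ms = score_flanker(df),
      lextale_percent = lex$percent,
      lextale_word_rt_ms = lex$word_rt_ms
    )
  })
  dplyr::bind_rows(out)
}
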