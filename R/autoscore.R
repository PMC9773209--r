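# Keyword autoscoring of typed transcripts under strict spelling-tolerance
# rules: exact match, single double-letter omission, single adjacent
# transposition, single apostrophe insertion/omission, plus a custom
# acceptable-spelling list. One rule application per token, no chaining.

#' Scoring rules for transcript autoscoring
#'
#' @param double_letter accept a keyword with exactly one doubled letter
#'   reduced to a single letter ("atack" for "attack").
#' @param transposition accept exactly one adjacent-letter swap ("tkae" for
#'   "take").
#' @param apostrophe accept one apostrophe inserted or omitted ("dont" for
#'   "don't").
#' @param collapse_double_space collapse runs of whitespace in transcripts.
#' @param custom_spellings named list mapping a keyword to a character vector
#'   of additionally accepted spellings.
#' @return object of class `scoring_rules`.
#' @export
scoring_rules <- function(double_letter = TRUE, transposition = TRUE,
                          apostrophe = TRUE, collapse_double_space = TRUE,
                          custom_spellings = list()) {
  structure(list(double_letter = double_letter, transposition = transposition,
                 apostrophe = apostrophe,
                 collapse_double_space = collapse_double_space,
                 custom_spellings = custom_spellings),
            class = "scoring_rules")
}

#' Normalize a typed transcript into tokens
#'
#' Lowercases, strips punctuation/digits/hyphens (keeping intra-word
#' apostrophes), collapses whitespace runs, and splits into tokens.
#'
#' @param text free-text transcript (character scalar).
#' @return character vector of tokens; empty input gives `character(0)`.
#' @examples
#' normalize_transcript("The  Ball bounced.") # "the" "ball" "bounced"
#' @export
normalize_transcript <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[^a-z']+", " ", x)          # punctuation, digits, hyphens -> space
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens <- gsub("^'+|'+$", "", tokens)  # apostrophes only survive intra-word
  tokens[nzchar(tokens)]
}

#' Does a typed token count as a given keyword?
#'
#' True iff the candidate equals the keyword exactly, or equals it under
#' exactly one application of an enabled rule: one doubled letter reduced to
#' a single letter, one adjacent-pair swap, one apostrophe inserted or
#' removed, or membership in the keyword's custom spelling list. Rules are
#' never chained.
#'
#' @param keyword normalized keyword token.
#' @param candidate normalized transcript token.
#' @param rules a [scoring_rules()].
#' @return logical.
#' @examples
#' keyword_matches("attack", "atack")  # TRUE (double-letter omission)
#' keyword_matches("take", "tkae")     # TRUE (adjacent transposition)
#' keyword_matches("oath", "oat")      # FALSE
#' @export
keyword_matches <- function(keyword, candidate, rules = scoring_rules()) {
  if (identical(keyword, candidate)) return(TRUE)
  kw <- strsplit(keyword, "")[[1]]
  cd <- strsplit(candidate, "")[[1]]
  nk <- length(kw); nc <- length(cd)

  if (rules$double_letter && nc == nk - 1) {
    for (i in which(kw[-nk] == kw[-1])) {
      if (identical(kw[-i], cd)) return(TRUE)
    }
  }
  if (rules$transposition && nc == nk && nk >= 2) {
    diffs <- which(kw != cd)
    if (length(diffs) == 2 && diffs[2] == diffs[1] + 1 &&
        kw[diffs[1]] == cd[diffs[2]] && kw[diffs[2]] == cd[diffs[1]]) {
      return(TRUE)
    }
  }
  if (rules$apostrophe) {
    if (nc == nk - 1) { # apostrophe omitted from keyword
      for (i in which(kw == "'")) {
        if (identical(kw[-i], cd)) return(TRUE)
      }
    }
    if (nc == nk + 1) { # apostrophe inserted by the typist
      for (i in which(cd == "'")) {
        if (identical(cd[-i], kw)) return(TRUE)
      }
    }
  }
  custom <- rules$custom_spellings[[keyword]]
  if (!is.null(custom) && candidate %in% custom) return(TRUE)
  FALSE
}

#' Score one transcript against a sentence's keyword list
#'
#' Order-independent maximum bipartite matching between keywords and
#' transcript tokens under [keyword_matches()]; each transcript token can
#' satisfy at most one keyword (a single typed "ball" scores one of
#' `c("ball", "ball")`).
#'
#' @param keywords character vector of keyword tokens, or a list with
#'   elements `sentence_id` and `keywords`.
#' @param transcript free-text typed response.
#' @param rules a [scoring_rules()].
#' @param sentence_id optional sentence identifier carried into the result.
#' @return object of class `score_result`: `sentence_id`, `n_keywords`,
#'   `n_correct`, and `matched` (data frame keyword/token assignment).
#' @export
score_response <- function(keywords, transcript, rules = scoring_rules(),
                           sentence_id = NA_character_) {
  if (is.list(keywords) && !is.null(keywords$keywords)) {
    sentence_id <- keywords$sentence_id %||% sentence_id
    keywords <- keywords$keywords
  }
  abort_if(length(keywords) == 0, "score_response: empty keyword list")
  keywords <- tolower(keywords)
  tokens <- normalize_transcript(transcript)
  nk <- length(keywords); nt <- length(tokens)

  matched <- data.frame(keyword = character(0), token = character(0),
                        stringsAsFactors = FALSE)
  n_correct <- 0L
  if (nt > 0) {
    adj <- outer(seq_len(nk), seq_len(nt), Vectorize(function(i, j) {
      keyword_matches(keywords[i], tokens[j], rules)
    }))
    edges <- which(adj, arr.ind = TRUE)
    if (nrow(edges) > 0) {
      g <- igraph::make_bipartite_graph(
        types = c(rep(FALSE, nk), rep(TRUE, nt)),
        edges = as.vector(t(cbind(edges[, 1], nk + edges[, 2])))
      )
      mm <- igraph::max_bipartite_match(g)
      assign_to <- mm$matching[seq_len(nk)]
      hit <- !is.na(assign_to)
      n_correct <- sum(hit)
      matched <- data.frame(keyword = keywords[hit],
                            token = tokens[assign_to[hit] - nk],
                            stringsAsFactors = FALSE)
    }
  }
  structure(list(sentence_id = sentence_id, n_keywords = nk,
                 n_correct = as.integer(n_correct), matched = matched),
            class = "score_result")
}

#' Aggregate score results into percent correct per condition
#'
#' Pooled aggregation (the default): per condition,
#' `100 * sum(n_correct) / sum(n_keywords)` over all sentences assigned to
#' it. `method = "mean"` instead averages per-sentence percentages.
#'
#' @param results list of [score_response()] results.
#' @param design data frame with columns `sentence_id` and `condition`
#'   mapping every scored sentence to exactly one condition.
#' @param method `"pooled"` (default) or `"mean"`.
#' @return named numeric vector of percent correct per condition.
#' @export
aggregate_condition <- function(results, design, method = c("pooled", "mean")) {
  method <- match.arg(method)
  ids <- vapply(results, `[[`, character(1), "sentence_id")
  cond <- design$condition[match(ids, design$sentence_id)]
  abort_if(anyNA(cond),
           sprintf("aggregate_condition: sentences not in design: %s",
                   paste(unique(ids[is.na(cond)]), collapse = ", ")))
  nc <- vapply(results, `[[`, integer(1), "n_correct")
  nk <- vapply(results, `[[`, integer(1), "n_keywords")
  conditions <- unique(design$condition)
  missing <- setdiff(conditions, cond)
  abort_if(length(missing) > 0,
           sprintf("aggregate_condition: no scored sentences for condition(s): %s",
                   paste(missing, collapse = ", ")))
  out <- if (method == "pooled") {
    100 * tapply(nc, cond, sum) / tapply(nk, cond, sum)
  } else {
    tapply(100 * nc / nk, cond, mean)
  }
  out[conditions]
}

#' Score a table of transcripts against a keyword table
#'
#' Vectorized front end over [score_response()] and [aggregate_condition()]:
#' one row of output per participant x condition, percent of keywords
#' correctly identified.
#'
#' @param keywords data frame with columns `sentence_id`, `condition`, and
#'   `keyword_1 ... keyword_k` (ragged; `NA`/empty cells ignored).
#' @param responses data frame with columns `participant_id`, `sentence_id`,
#'   `transcript`.
#' @param rules a [scoring_rules()].
#' @param method aggregation method, see [aggregate_condition()].
#' @return tibble with columns `participant_id`, `condition`,
#'   `percent_correct`.
#' @export
score_transcripts <- function(keywords, responses, rules = scoring_rules(),
                              method = "pooled") {
  kw_cols <- grep("^keyword", names(keywords), value = TRUE)
  abort_if(length(kw_cols) == 0, "score_transcripts: no keyword_* columns")
  kw_list <- lapply(seq_len(nrow(keywords)), function(i) {
    kws <- as.character(unlist(keywords[i, kw_cols]))
    kws <- kws[!is.na(kws) & nzchar(kws)]
    list(sentence_id = as.character(keywords$sentence_id[i]), keywords = kws)
  })
  names(kw_list) <- vapply(kw_list, `[[`, character(1), "sentence_id")
  design <- data.frame(sentence_id = as.character(keywords$sentence_id),
                       condition = keywords$condition,
                       stringsAsFactors = FALSE)
  out <- lapply(split(responses, responses$participant_id), function(df) {
    results <- lapply(seq_len(nrow(df)), function(i) {
      sid <- as.character(df$sentence_id[i])
      abort_if(is.null(kw_list[[sid]]),
               sprintf("score_transcripts: unknown sentence_id '%s'", sid))
      score_response(kw_list[[sid]], df$transcript[i], rules)
    })
    pct <- aggregate_condition(results, design[design$sentence_id %in%
                                                 df$sentence_id, ], method)
    tibble::tibble(participant_id = df$participant_id[1],
                   condition = names(pct), percent_correct = as.numeric(pct))
  })
  dplyr::bind_rows(out)
}
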