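# Synthetic stand-ins for the non-deposited study materials: speech-like
# sentence audio (harmonic source + formant resonators + syllabic envelope),
# pseudo-keyword lists, simulated cohorts with known latent abilities, typed
# transcripts with rule-covered typos, and trial-level task logs.

# Fixed pseudo-keyword vocabulary (common English content words).
.word_bank <- c(
  "witness", "took", "solemn", "oath", "ball", "bounced", "river", "garden",
  "window", "table", "doctor", "letter", "mountain", "yellow", "silver",
  "market", "danger", "summer", "winter", "morning", "evening", "travel",
  "bottle", "kitchen", "animal", "forest", "bridge", "camera", "castle",
  "circle", "coffee", "copper", "corner", "cotton", "course", "cousin",
  "dinner", "dollar", "dragon", "engine", "family", "farmer", "finger",
  "flower", "friend", "future", "glass", "grass", "ground", "hammer",
  "handle", "happy", "harbor", "hollow", "honey", "island", "jacket",
  "ladder", "lantern", "lemon", "little", "meadow", "member", "metal",
  "middle", "minute", "mirror", "monkey", "muscle", "needle", "number",
  "orange", "paper", "pencil", "people", "pepper", "picture", "pillow",
  "planet", "pocket", "puzzle", "rabbit", "ribbon", "rocket", "saddle",
  "sailor", "school", "season", "shadow", "shelter", "shoulder", "singer",
  "sister", "soldier", "spider", "spirit", "stable", "station", "stomach",
  "street", "sugar", "supper", "temple", "thunder", "ticket", "tiger",
  "timber", "tunnel", "valley", "village", "wagon", "water", "weather",
  "don't", "can't", "won't", "butter", "attack", "dinner", "arrow"
)

#' Specification for a synthetic sentence
#'
#' A speech-like stand-in for recorded sentences: a harmonic pulse train at
#' `f0_hz` shaped by a bank of formant resonators and amplitude-modulated by
#' a raised-cosine syllabic envelope. Defaults give a 2 s utterance at
#' 16 kHz with formants on harmonics of f0 (so spectral peaks sit exactly at
#' the configured formants) and a 4 Hz syllable rate (about 8 syllables per
#' sentence, matching conversational sentence material).
#'
#' @param duration_s duration in seconds (> 0).
#' @param f0_hz fundamental frequency.
#' @param formants_hz resonance center frequencies (all above f0, below
#'   Nyquist).
#' @param syllable_rate_hz envelope modulation rate.
#' @param sample_rate sampling rate in Hz.
#' @param seed integer seed.
#' @return object of class `sentence_spec`.
#' @export
sentence_spec <- function(duration_s = 2, f0_hz = 100,
                          formants_hz = c(500, 1500, 2500),
                          syllable_rate_hz = 4, sample_rate = 16000,
                          seed = 1) {
  abort_if(duration_s <= 0, "sentence_spec: duration_s must be > 0")
  abort_if(syllable_rate_hz <= 0, "sentence_spec: syllable_rate_hz must be > 0")
  abort_if(f0_hz >= min(formants_hz) || max(formants_hz) >= sample_rate / 2,
           "sentence_spec: need f0 < min formant < Nyquist")
  structure(list(duration_s = duration_s, f0_hz = f0_hz,
                 formants_hz = formants_hz,
                 syllable_rate_hz = syllable_rate_hz,
                 sample_rate = sample_rate, seed = seed),
            class = "sentence_spec")
}

# Two-pole resonator (center frequency f, bandwidth bw) applied recursively.
resonate <- function(x, f, bw, sr) {
  r <- exp(-pi * bw / sr)
  theta <- 2 * pi * f / sr
  as.numeric(stats::filter(x * (1 - r), c(2 * r * cos(theta), -r^2),
                           method = "recursive"))
}

#' Synthesize a speech-like sentence and its pseudo-keyword list
#'
#' @param spec a [sentence_spec()].
#' @param n_keywords number of pseudo-keywords to draw (default 4, about the
#'   content-word count of short test sentences).
#' @param sentence_id identifier attached to the keyword list.
#' @return list with `audio` (an [audio_signal()]) and `keywords` (list with
#'   `sentence_id`, `keywords`). Deterministic for a fixed seed.
#' @export
synth_sentence <- function(spec, n_keywords = 4, sentence_id = "s1") {
  n <- round(spec$duration_s * spec$sample_rate)
  sr <- spec$sample_rate
  # glottal-like pulse train at f0
  src <- numeric(n)
  src[unique(pmin(n, 1 + round(seq(0, n - 1, by = sr / spec$f0_hz))))] <- 1
  shaped <- rowSums(sapply(spec$formants_hz, function(f) resonate(src, f, 80, sr)))
  t <- (0:(n - 1)) / sr
  env <- 0.5 * (1 - cos(2 * pi * spec$syllable_rate_hz * t))
  x <- shaped * env
  x <- 0.9 * x / max(abs(x))
  keywords <- withr::with_seed(
    derive_seed(spec$seed, paste0("kw/", sentence_id)),
    sample(.word_bank, n_keywords)
  )
  list(audio = audio_signal(x, sr),
       keywords = list(sentence_id = sentence_id, keywords = keywords))
}

#' The six-condition interrupted-speech study design
#'
#' Two interruption types (silent gap, noise burst) crossed with three
#' sentence sets (high-context, low-context, everyday), `n_per_condition`
#' sentences each — 360 source sentences by default.
#'
#' @param n_per_condition sentences per condition (default 60).
#' @return tibble with columns `sentence_id`, `sentence_set`,
#'   `interruption`, `condition`.
#' @export
study_design <- function(n_per_condition = 60) {
  sets <- c("rspin_high", "rspin_low", "presto")
  interruptions <- c("silent", "noise")
  grid <- expand.grid(interruption = interruptions, sentence_set = sets,
                      idx = seq_len(n_per_condition),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$sentence_set, grid$interruption, grid$idx), ]
  tibble::tibble(
    sentence_id = sprintf("s%03d", seq_len(nrow(grid))),
    sentence_set = grid$sentence_set,
    interruption = grid$interruption,
    condition = paste(grid$sentence_set, grid$interruption, sep = "_")
  )
}

#' Default per-condition mean percent-correct scores
#'
#' The configured generative condition means (percent of keywords correctly
#' identified): noise-burst conditions above their silent-gap counterparts,
#' high context above low context, everyday (PRESTO-like) material lowest.
#'
#' @return named numeric vector over the six conditions.
#' @export
default_condition_means <- function() {
  c(rspin_high_silent = 48.3, rspin_high_noise = 60.1,
    rspin_low_silent = 42.4, rspin_low_noise = 50.4,
    presto_silent = 27.6, presto_noise = 43.1)
}

#' Default ability-to-condition effect sizes
#'
#' Percent-correct change per 1 SD of each latent ability, per condition.
#' Working memory is the strongest, most consistent effect; lexical
#' knowledge matters most for silent-gap material; inhibition (negative:
#' higher interference, lower scores) acts mostly in noise; processing speed
#' (negative: slower, lower scores) mostly in silence.
#'
#' @return 6 x 4 matrix (conditions x abilities).
#' @export
default_betas <- function() {
  m <- rbind(
    rspin_high_silent = c(3.01, 2.40, -0.66, -1.21),
    rspin_high_noise  = c(3.51, 0.47, -1.42, -0.69),
    rspin_low_silent  = c(0.76, 1.47, -1.45, -1.67),
    rspin_low_noise   = c(2.28, 0.34, -2.09, -1.35),
    presto_silent     = c(2.16, 2.48, -0.18, -2.48),
    presto_noise      = c(2.98, 1.55, -2.17, -1.74)
  )
  colnames(m) <- c("working_memory", "lexical_knowledge", "inhibition",
                   "processing_speed")
  m
}

#' Specification of a simulated cohort
#'
#' Latent abilities are multivariate standard normal with correlation
#' `ability_corr`; each condition score is a linear function of the
#' abilities plus Gaussian noise, clipped to \[0, 100\]; observed task
#' measures are fixed monotone (affine, range-clamped) maps of the abilities
#' calibrated to published task means and SDs.
#'
#' @param n number of participants (default 63).
#' @param ability_corr 4 x 4 correlation matrix among the latent abilities
#'   (symmetric positive-definite, unit diagonal); default has modest 0.2
#'   pairwise correlations.
#' @param condition_means named vector of mean percent per condition.
#' @param betas 6 x 4 matrix of effects (percent per 1 SD of ability).
#' @param residual_sd residual SD of condition scores in percent.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 63, ability_corr = NULL,
                        condition_means = default_condition_means(),
                        betas = default_betas(), residual_sd = 7.5,
                        seed = 1) {
  if (is.null(ability_corr)) {
    ability_corr <- matrix(0.2, 4, 4)
    diag(ability_corr) <- 1
  }
  abort_if(!isSymmetric(unname(ability_corr)) ||
             any(abs(diag(ability_corr) - 1) > 1e-12),
           "cohort_spec: ability_corr must be symmetric with unit diagonal")
  abort_if(any(eigen(ability_corr, symmetric = TRUE, only.values = TRUE)$values <= 0),
           "cohort_spec: ability_corr must be positive-definite")
  abort_if(any(condition_means < 0 | condition_means > 100),
           "cohort_spec: condition_means must lie in [0, 100]")
  abort_if(residual_sd <= 0, "cohort_spec: residual_sd must be > 0")
  abort_if(!all(rownames(betas) == names(condition_means)),
           "cohort_spec: betas rows must match condition_means names")
  structure(list(n = n, ability_names = colnames(betas),
                 ability_corr = ability_corr,
                 condition_means = condition_means, betas = betas,
                 residual_sd = residual_sd, seed = seed),
            class = "cohort_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a participant cohort with known latent abilities
#'
#' @param spec a [cohort_spec()].
#' @return tibble with one row per participant: `participant_id`,
#'   demographics (`age`, `education`, three SSQ self-report scales), the
#'   seven cognitive/linguistic measures, and the six condition scores.
#'   Ground truth is attached as attributes `abilities` (n x 4 latent
#'   matrix) and `betas`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  abort_if(!inherits(spec, "cohort_spec"), "simulate_cohort: need a cohort_spec")
  n <- spec$n
  withr::with_seed(spec$seed, {
    z <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = spec$ability_corr)
    colnames(z) <- spec$ability_names
    eps <- matrix(rnorm(n * 6, sd = spec$residual_sd), n, 6)
    scores <- sweep(z %*% t(spec$betas), 2, spec$condition_means, `+`) + eps
    scores <- clamp(scores, 0, 100)
    tab <- tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      age = round(clamp(rnorm(n, 42, 12), 22, 63)),
      education = round(clamp(rnorm(n, 15.4, 2.8), 8, 24)),
      ssq_speech = clamp(rnorm(n, 8.4, 1.4), 0, 10),
      ssq_spatial = clamp(rnorm(n, 7.7, 1.5), 0, 10),
      ssq_qualities = clamp(rnorm(n, 8.6, 1.2), 0, 10),
      # fixed monotone maps from the latent abilities (documented constants)
      rst_percent = clamp(73.5 + 14.3 * z[, "working_memory"], 0, 100),
      dst_percentile = clamp(72.6 + 28.6 * z[, "working_memory"], 0.1, 99.9),
      stroop_interference = pmax(1.35 + 0.26 * z[, "inhibition"], 0.5),
      stroop_speed_ms = pmax(804.9 + 156.9 * z[, "processing_speed"], 250),
      flanker_interference_ms = 41 + 23.7 * z[, "inhibition"],
      lextale_percent = clamp(88.7 + 9.4 * z[, "lexical_knowledge"], 0, 100),
      lextale_word_rt_ms = pmax(754.3 + 125.5 * z[, "processing_speed"], 250)
    )
    for (j in seq_along(spec$condition_means)) {
      tab[[names(spec$condition_means)[j]]] <- scores[, j]
    }
    attr(tab, "abilities") <- z
    attr(tab, "betas") <- spec$betas
    tab
  })
}

#' The measures screened for outliers
#'
#' The seventeen reported measures subjected to the IQR fence: education,
#' the three SSQ scales, the seven cognitive/linguistic measures, and the
#' six condition scores. Age is eligibility-bounded at recruitment and is
#' not screened.
#'
#' @return character vector of 17 column names.
#' @export
screened_measures <- function() {
  c("education", "ssq_speech", "ssq_spatial", "ssq_qualities",
    "rst_percent", "dst_percentile", "stroop_interference",
    "stroop_speed_ms", "flanker_interference_ms", "lextale_percent",
    "lextale_word_rt_ms", names(default_condition_means()))
}

#' Apply one scoring-rule-covered typo to a word
#'
#' Draws uniformly among every variant reachable by a single application of
#' the scorer's tolerance rules (double-letter omission, adjacent
#' transposition, apostrophe insertion/omission); returns the word unchanged
#' if no rule applies. Every emitted typo is accepted by
#' [keyword_matches()] under the default rules (generator-scorer closure).
#'
#' @param word a lowercase keyword token.
#' @return a corrupted (or unchanged) token.
#' @export
keyword_typo <- function(word) {
  ch <- strsplit(word, "")[[1]]
  n <- length(ch)
  variants <- character(0)
  for (i in which(ch[-n] == ch[-1])) {            # drop one of a double letter
    variants <- c(variants, paste(ch[-i], collapse = ""))
  }
  if (n >= 2) {                                    # adjacent transposition
    for (i in which(ch[-n] != ch[-1])) {
      sw <- ch; sw[c(i, i + 1)] <- sw[c(i + 1, i)]
      variants <- c(variants, paste(sw, collapse = ""))
    }
  }
  if (any(ch == "'")) {                            # drop an apostrophe
    for (i in which(ch == "'")) {
      variants <- c(variants, paste(ch[-i], collapse = ""))
    }
  } else if (n >= 2) {                             # insert one inside
    for (i in seq_len(n - 1)) {
      variants <- c(variants, paste(c(ch[1:i], "'", ch[(i + 1):n]), collapse = ""))
    }
  }
  variants <- setdiff(unique(variants), word)
  if (length(variants) == 0) return(word)
  variants[sample.int(length(variants), 1)]
}

#' Simulate typed transcripts for a set of keyword lists
#'
#' Each keyword is reported independently with probability `p_report`;
#' reported keywords are corrupted with probability `p_typo` by exactly one
#' typo drawn from the scorer's tolerance rules (double-letter omission,
#' adjacent transposition, apostrophe insertion/omission), so the expected
#' autoscore depends only on `p_report`.
#'
#' @param keyword_lists list of keyword lists (each with `sentence_id` and
#'   `keywords`).
#' @param p_report probability a keyword is typed at all.
#' @param p_typo probability a typed keyword carries a typo.
#' @param seed integer seed.
#' @param participant_id id attached to the output rows.
#' @return tibble with columns `participant_id`, `sentence_id`,
#'   `transcript`.
#' @export
simulate_transcripts <- function(keyword_lists, p_report, p_typo, seed,
                                 participant_id = "P001") {
  abort_if(p_report < 0 || p_report > 1 || p_typo < 0 || p_typo > 1,
           "simulate_transcripts: probabilities must be in [0, 1]")
  withr::with_seed(seed, {
    rows <- lapply(keyword_lists, function(kl) {
      kws <- kl$keywords
      typed <- character(0)
      for (kw in kws) {
        if (runif(1) <= p_report && p_report > 0) {
          typed <- c(typed, if (runif(1) < p_typo) keyword_typo(kw) else kw)
        }
      }
      tibble::tibble(participant_id = participant_id,
                     sentence_id = kl$sentence_id,
                     transcript = paste(typed, collapse = " "))
    })
    dplyr::bind_rows(rows)
  })
}

#' Synthetic digit-span norm table
#'
#' A stand-in normative lookup (total correct out of 32 to percentile) built
#' from a normal approximation centered at 17 correct with SD 5. Synthetic:
#' not the published norms, which must be supplied by the user for real
#' scoring.
#'
#' @return data frame with columns `total_correct`, `percentile`.
#' @export
synthetic_dst_norms <- function() {
  total <- 0:32
  data.frame(total_correct = total,
             percentile = clamp(round(100 * stats::pnorm((total - 17) / 5), 1),
                                0.1, 99.9))
}

#' Simulate a trial-level task log realizing target measures
#'
#' Builds reading-span, digit-span, Stroop, flanker, and LexTALE trials for
#' one participant such that [score_cognitive()] approximately recovers the
#' supplied target measures (reaction-time draws are mean-shifted so filtered
#' means match exactly; accuracy-based measures are rounded to the nearest
#' attainable count). One incorrect catch trial per reaction-time condition
#' exercises the scorers' exclusion rules.
#'
#' @param targets one-row data frame (or list) with the seven measure
#'   columns of [score_cognitive()].
#' @param seed integer seed.
#' @param participant_id id for the log rows.
#' @return tibble in the trial-log layout of [score_cognitive()].
#' @export
simulate_trial_log <- function(targets, seed = 1, participant_id = "P001") {
  withr::with_seed(seed, {
    rows <- list()
    add <- function(task, item_id, condition, response, correct, rt_ms,
                    timeout = FALSE) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        participant_id = participant_id, task = task, item_id = item_id,
        condition = condition, response = response, correct = correct,
        rt_ms = rt_ms, timeout = timeout)
    }
    # reading span: 20 sequences x 3 target words
    n_seq <- 20; per_seq <- 3
    words <- sample(.word_bank[!grepl("'", .word_bank)], n_seq * per_seq,
                    replace = TRUE)
    n_recall <- round(targets$rst_percent / 100 * n_seq * per_seq)
    recalled <- seq_along(words) <= n_recall
    for (s in seq_len(n_seq)) {
      idx <- ((s - 1) * per_seq + 1):(s * per_seq)
      resp <- paste(rev(words[idx][recalled[idx]]), collapse = " ")
      for (i in idx) {
        add("rst", sprintf("seq%02d", s), words[i], resp, recalled[i], NA_real_)
      }
    }
    # digit span: lengths 2..9, two trials per length per direction
    total_target <- synthetic_dst_norms()
    tt <- max(total_target$total_correct[total_target$percentile <=
                                           targets$dst_percentile], 0)
    per_dir <- c(ceiling(tt / 2), floor(tt / 2))
    for (d in 1:2) {
      task <- c("dst_forward", "dst_backward")[d]
      n_ok <- min(per_dir[d], 16)
      k <- 0
      for (len in 2:9) {
        for (trial in 1:2) {
          k <- k + 1
          ok <- k <= n_ok
          add(task, sprintf("%s-%d-%d", task, len, trial),
              sprintf("%d-%d", len, trial), "digits", ok, NA_real_)
        }
        if (k >= n_ok + 2) break # both trials of a length failed: task ends
      }
    }
    # Stroop: 25 trials per condition; correct-trial RT means shifted exact
    shift <- function(x, target) x - mean(x) + target
    c_mean <- 600
    for (cond in c("W", "C", "CW")) {
      target_mean <- switch(cond, W = targets$stroop_speed_ms, C = c_mean,
                            CW = c_mean * targets$stroop_interference)
      rt <- shift(rnorm(24, target_mean, 60), target_mean)
      for (i in 1:24) add("stroop", sprintf("stroop-%s-%02d", cond, i), cond,
                         "key", TRUE, rt[i])
      add("stroop", sprintf("stroop-%s-25", cond), cond, "key", FALSE,
          target_mean + 2000)
    }
    # flanker: 45 + 45
    base_rt <- 500
    for (cond in c("congruent", "incongruent")) {
      target_mean <- if (cond == "congruent") base_rt else
        base_rt + targets$flanker_interference_ms
      rt <- shift(rnorm(44, target_mean, 40), target_mean)
      for (i in 1:44) add("flanker", sprintf("flanker-%s-%02d", cond, i),
                         cond, "key", TRUE, rt[i])
      add("flanker", sprintf("flanker-%s-45", cond), cond, "key", FALSE,
          target_mean + 1500)
    }
    # LexTALE: 40 words + 20 nonwords; one timeout word trial
    acc <- targets$lextale_percent / 100
    w_ok <- round(39 * acc); n_ok <- round(20 * acc)
    rt_w <- shift(rnorm(w_ok, targets$lextale_word_rt_ms, 80),
                  targets$lextale_word_rt_ms)
    for (i in 1:39) {
      ok <- i <= w_ok
      add("lextale", sprintf("lex-w-%02d", i), "word", "j", ok,
          if (ok) rt_w[i] else 1900)
    }
    add("lextale", "lex-w-40", "word", "", FALSE, 2000, timeout = TRUE)
    for (i in 1:20) add("lextale", sprintf("lex-n-%02d", i), "nonword", "k",
                        i <= n_ok, rnorm(1, 900, 80))
    dplyr::bind_rows(rows)
  })
}

#' Simulate a complete study: cohort, keyword lists, transcripts, trial logs
#'
#' Ties the generators together under one master seed: a cohort with latent
#' abilities, a keyword list per designed sentence, per-participant typed
#' transcripts whose report probability per sentence equals the
#' participant's latent condition score (so autoscoring recovers the
#' cohort's condition scores in expectation), and per-participant trial
#' logs realizing the cohort's cognitive measures.
#'
#' @param design a [study_design()] table.
#' @param cohort a [cohort_spec()].
#' @param seed master integer seed.
#' @param p_typo typo probability for transcripts.
#' @return list with `design`, `cohort` (the [simulate_cohort()] tibble),
#'   `keywords` (list per sentence), `transcripts`, `trial_log`,
#'   `dst_norms`.
#' @export
simulate_study <- function(design = study_design(), cohort = cohort_spec(),
                           seed = 1, p_typo = 0.2) {
  cohort$seed <- derive_seed(seed, "cohort")
  tab <- simulate_cohort(cohort)
  keywords <- lapply(seq_len(nrow(design)), function(i) {
    withr::with_seed(derive_seed(seed, paste0("kw/", design$sentence_id[i])),
                     list(sentence_id = design$sentence_id[i],
                          keywords = sample(.word_bank, 4)))
  })
  names(keywords) <- design$sentence_id
  transcripts <- dplyr::bind_rows(lapply(seq_len(nrow(tab)), function(p) {
    pid <- tab$participant_id[p]
    dplyr::bind_rows(lapply(split(design, design$condition), function(dd) {
      p_report <- tab[[dd$condition[1]]][p] / 100
      simulate_transcripts(keywords[dd$sentence_id], p_report, p_typo,
                           seed = derive_seed(seed, paste0("tr/", pid, "/",
                                                           dd$condition[1])),
                           participant_id = pid)
    }))
  }))
  trial_log <- dplyr::bind_rows(lapply(seq_len(nrow(tab)), function(p) {
    simulate_trial_log(tab[p, ], seed = derive_seed(seed, paste0("log/",
                                                                 tab$participant_id[p])),
                       participant_id = tab$participant_id[p])
  }))
  list(design = design, cohort = tab, keywords = keywords,
       transcripts = transcripts, trial_log = trial_log,
       dst_norms = synthetic_dst_norms())
}
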