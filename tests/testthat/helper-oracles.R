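# Fixtures and independent oracles used across the suite.

make_tone <- function(freq, sr = 8000, dur = 1, amp = 1) {
  audio_signal(amp * sin(2 * pi * freq * (0:(round(dur * sr) - 1)) / sr), sr)
}

small_corpus <- function(n = 3, sr = 16000, dur = 1) {
  lapply(seq_len(n), function(i) {
    synth_sentence(sentence_spec(duration_s = dur, sample_rate = sr, seed = i),
                   sentence_id = paste0("s", i))$audio
  })
}

# Independent gating oracle: evaluate the square wave + ramps per sample,
# directly from the spec of the gating geometry (no segment-map reuse).
oracle_mask <- function(n, sr, rate_hz = 2, duty = 0.5, ramp_ms = 10,
                        speech_first = TRUE) {
  period <- sr / rate_hz
  ramp <- round(ramp_ms / 1000 * sr)
  mask <- numeric(n)
  p <- 0
  repeat {
    b0 <- round(p * period)
    if (b0 >= n) break
    if (speech_first) {
      s <- b0
      e <- min(round((p + duty) * period), n)
    } else {
      s <- round((p + 1 - duty) * period)
      e <- min(round((p + 1) * period), n)
    }
    if (e > s) {
      m <- e - s
      r <- if (2 * ramp > m) floor(m / 2) else ramp
      w <- rep(1, m)
      if (r > 0) {
        up <- 0.5 * (1 - cos(pi * (0:(r - 1)) / r))
        w[1:r] <- up
        w[m:(m - r + 1)] <- up
      }
      mask[(s + 1):e] <- w
    }
    p <- p + 1
  }
  mask
}

# Exhaustive single-rule variant generator for the autoscore oracle.
oracle_variants <- function(kw) {
  ch <- strsplit(kw, "")[[1]]
  n <- length(ch)
  out <- kw
  for (i in which(ch[-n] == ch[-1])) out <- c(out, paste(ch[-i], collapse = ""))
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      sw <- ch; sw[c(i, i + 1)] <- sw[c(i + 1, i)]
      out <- c(out, paste(sw, collapse = ""))
    }
  }
  for (i in which(ch == "'")) out <- c(out, paste(ch[-i], collapse = ""))
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      out <- c(out, paste(c(ch[1:i], "'", ch[(i + 1):n]), collapse = ""))
    }
  }
  unique(out)
}

# Brute-force maximum assignment of keywords to tokens (injective over
# tokens), by recursion over keywords.
oracle_max_match <- function(keywords, tokens, rules = scoring_rules()) {
  search <- function(ki, avail) {
    if (ki > length(keywords)) return(0L)
    res <- search(ki + 1, avail) # skip this keyword
    for (j in which(avail)) {
      if (keyword_matches(keywords[ki], tokens[j], rules)) {
        avail2 <- avail; avail2[j] <- FALSE
        res <- max(res, 1L + search(ki + 1, avail2))
      }
    }
    res
  }
  if (length(tokens) == 0) return(0L)
  search(1, rep(TRUE, length(tokens)))
}

random_keyword <- function(len) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Planted-confounder construction: x2 has a weak direct effect whose p-value
# sits above 0.25 (the noise is residualized against the design, so the
# coefficient estimates equal the true values exactly), yet removing x2
# shifts the x1 coefficient by ~ rho * c2 = 28% > 20%.
confounded_table <- function(seed, n = 150, rho = 0.8, c2 = 0.35, sigma = 3.2) {
  withr::with_seed(seed, {
    x2 <- rnorm(n)
    x1 <- rho * x2 + sqrt(1 - rho^2) * rnorm(n)
    e <- resid(lm(rnorm(n) ~ x1 + x2))
    e <- e / sd(e) * sigma
    data.frame(y = x1 + c2 * x2 + e, x1 = x1, x2 = x2)
  })
}
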