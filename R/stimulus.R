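# Interrupted-speech stimulus construction: square-wave gating with cosine
# ramps, speech-shaped noise by spectral phase randomization, RMS/SNR
# calibration, and linear assembly of silent-gap / noise-burst pairs.

#' Gating specification for interrupted speech
#'
#' Defines the periodic interruption: a square wave at `rate_hz` with a given
#' duty cycle (fraction of each period that is speech). The defaults are the
#' standard interrupted-speech paradigm: 2 Hz, 50% duty (alternating 250 ms
#' speech/silence) with 10 ms raised-cosine on/off ramps.
#'
#' @param rate_hz interruption rate in Hz (> 0).
#' @param duty fraction of each period that is speech, in (0, 1].
#' @param start_phase whether the waveform starts with a speech segment
#'   (`"speech_first"`, default, preserving sentence onsets) or a gap.
#' @param ramp_ms ramp duration in ms; must fit inside half a speech segment.
#' @return object of class `gating_spec`.
#' @export
gating_spec <- function(rate_hz = 2, duty = 0.5,
                        start_phase = c("speech_first", "gap_first"),
                        ramp_ms = 10) {
  start_phase <- match.arg(start_phase)
  abort_if(!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0,
           "gating_spec: rate_hz must be a positive scalar")
  abort_if(!is.numeric(duty) || duty <= 0 || duty > 1,
           "gating_spec: duty must be in (0, 1]")
  abort_if(ramp_ms < 0 || ramp_ms > duty * 1000 / (2 * rate_hz),
           "gating_spec: ramp_ms must be in [0, duty*1000/(2*rate_hz)] so ramps fit in a segment")
  structure(list(rate_hz = rate_hz, duty = duty, start_phase = start_phase,
                 ramp_ms = ramp_ms), class = "gating_spec")
}

#' Build a segment map for square-wave gating
#'
#' Partitions `[0, n_samples)` into alternating speech/gap intervals.
#' Boundaries fall at multiples of `duty * period` and `period` (in samples,
#' rounded to the nearest sample); a final partial segment is truncated at
#' `n_samples`. Intervals are 0-based and half-open `[start, end)`.
#'
#' @param n_samples signal length in samples (>= 1).
#' @param sample_rate sampling rate in Hz.
#' @param spec a [gating_spec()].
#' @return object of class `segment_map`: a list with `intervals` (data frame
#'   with columns `start`, `end`, `label`), `n_samples`, `sample_rate`.
#' @examples
#' make_segment_map(1000, 1000, gating_spec(rate_hz = 2, duty = 0.5))
#' @export
make_segment_map <- function(n_samples, sample_rate, spec = gating_spec()) {
  abort_if(!is.numeric(n_samples) || n_samples < 1,
           "make_segment_map: invalid spec: n_samples must be >= 1")
  abort_if(!is.numeric(sample_rate) || sample_rate <= 0,
           "make_segment_map: invalid spec: sample_rate must be positive")
  abort_if(!inherits(spec, "gating_spec"), "make_segment_map: spec must be a gating_spec")
  n_samples <- as.integer(n_samples)
  period <- sample_rate / spec$rate_hz # samples per period, possibly fractional

  starts <- integer(0); ends <- integer(0); labels <- character(0)
  first <- if (spec$start_phase == "speech_first") "speech" else "gap"
  second <- if (first == "speech") "gap" else "speech"
  frac_first <- if (first == "speech") spec$duty else 1 - spec$duty
  p <- 0
  repeat {
    b0 <- round(p * period)
    if (b0 >= n_samples) break
    b1 <- min(round((p + frac_first) * period), n_samples)
    b2 <- min(round((p + 1) * period), n_samples)
    if (b1 > b0) { starts <- c(starts, b0); ends <- c(ends, b1); labels <- c(labels, first) }
    if (b2 > b1) { starts <- c(starts, b1); ends <- c(ends, b2); labels <- c(labels, second) }
    p <- p + 1
  }
  # merge adjacent intervals with equal labels (arises when duty = 1)
  keep <- c(TRUE, labels[-1] != labels[-length(labels)])
  grp <- cumsum(keep)
  intervals <- data.frame(
    start = as.integer(tapply(starts, grp, min)),
    end = as.integer(tapply(ends, grp, max)),
    label = as.character(tapply(labels, grp, `[`, 1)),
    stringsAsFactors = FALSE
  )
  structure(list(intervals = intervals, n_samples = n_samples,
                 sample_rate = sample_rate),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map: %d intervals over %d samples @ %g Hz>\n",
              nrow(x$intervals), x$n_samples, x$sample_rate))
  print(utils::head(x$intervals, 8))
  invisible(x)
}

#' Swap speech and gap labels of a segment map
#'
#' Used to gate noise into the gaps of the speech gating.
#'
#' @param map a `segment_map`.
#' @return a `segment_map` with labels swapped.
#' @export
complement_map <- function(map) {
  map$intervals$label <- ifelse(map$intervals$label == "speech", "gap", "speech")
  map
}

#' Save / load a segment map as CSV
#'
#' Sidecar format: columns `start_sample,end_sample,label` (0-based,
#' half-open).
#'
#' @param map a `segment_map`.
#' @param path CSV path.
#' @param sample_rate sample rate to attach on reading.
#' @return `path` / a `segment_map`.
#' @export
write_segment_map <- function(map, path) {
  df <- data.frame(start_sample = map$intervals$start,
                   end_sample = map$intervals$end,
                   label = map$intervals$label)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segment_map
#' @export
read_segment_map <- function(path, sample_rate) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  intervals <- data.frame(start = as.integer(df$start_sample),
                          end = as.integer(df$end_sample),
                          label = df$label, stringsAsFactors = FALSE)
  structure(list(intervals = intervals, n_samples = max(intervals$end),
                 sample_rate = sample_rate), class = "segment_map")
}

# Raised-cosine gating mask for one speech interval of length m with ramp
# length ramp (samples). On-ramp w_i = 0.5*(1 - cos(pi*i/ramp)), i = 0..ramp-1
# (so the value half-way into the ramp is exactly 0.5); off-ramp is its
# mirror, ending at exactly 0 on the final sample.
interval_window <- function(m, ramp) {
  w <- rep(1, m)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * (0:(ramp - 1)) / ramp))
    w[seq_len(ramp)] <- up
    w[m:(m - ramp + 1)] <- up
  }
  w
}

#' Gate a signal through a segment map with cosine ramps
#'
#' Gap samples become exactly zero; speech samples pass through unchanged
#' except for raised-cosine on/off ramps of `ramp_ms` at each speech-interval
#' edge. A sentence-final partial speech segment gets its ramp shortened to
#' fit; a ramp that does not fit a full interval is an error.
#'
#' @param signal an [audio_signal()].
#' @param map a `segment_map` with `n_samples == length(signal$samples)`.
#' @param ramp_ms ramp duration in ms.
#' @return gated [audio_signal()].
#' @export
gate_signal <- function(signal, map, ramp_ms = 10) {
  abort_if(!is_audio_signal(signal), "gate_signal: signal must be an audio_signal")
  abort_if(map$n_samples != length(signal$samples),
           "gate_signal: segment map length does not match signal length")
  mask <- gating_mask(map, ramp_ms)
  audio_signal(signal$samples * mask, signal$sample_rate)
}

#' Per-sample gating mask for a segment map
#'
#' @inheritParams gate_signal
#' @return numeric vector of length `map$n_samples` in \[0, 1\].
#' @export
gating_mask <- function(map, ramp_ms = 10) {
  ramp <- round(ramp_ms / 1000 * map$sample_rate)
  mask <- numeric(map$n_samples)
  iv <- map$intervals
  speech <- which(iv$label == "speech")
  last_row <- nrow(iv)
  for (i in speech) {
    m <- iv$end[i] - iv$start[i]
    r <- ramp
    if (2 * r > m) {
      abort_if(i != last_row,
               "gate_signal: invalid spec: ramp longer than half a speech segment")
      r <- floor(m / 2) # final truncated segment: shorten ramp to fit
    }
    mask[(iv$start[i] + 1):iv$end[i]] <- interval_window(m, r)
  }
  mask
}

#' Build a speech-shaped noise model from a sentence corpus
#'
#' Computes the long-term magnitude spectrum of the corpus: with
#' `fft_policy = "concat"` (default, the most literal "combined Fourier
#' transform" reading) one FFT of all sentences concatenated, zero-padded to
#' the next power of two; with `"average"`, per-sentence magnitude spectra at
#' a common FFT length are averaged.
#'
#' @param corpus nonempty list of [audio_signal()]s with a uniform sample rate.
#' @param fft_policy `"concat"` or `"average"`.
#' @return object of class `noise_model`: one-sided linear `magnitude`
#'   spectrum, `fft_length`, `sample_rate`.
#' @export
build_noise_model <- function(corpus, fft_policy = c("concat", "average")) {
  fft_policy <- match.arg(fft_policy)
  abort_if(length(corpus) == 0, "build_noise_model: empty corpus")
  abort_if(!all(vapply(corpus, is_audio_signal, logical(1))),
           "build_noise_model: corpus must be a list of audio_signal")
  rates <- vapply(corpus, function(s) s$sample_rate, numeric(1))
  abort_if(length(unique(rates)) != 1, "build_noise_model: mixed sample rates in corpus")
  sr <- rates[1]
  next_pow2 <- function(n) 2^ceiling(log2(n))
  if (fft_policy == "concat") {
    x <- unlist(lapply(corpus, `[[`, "samples"))
    nfft <- next_pow2(length(x))
    spec <- fft(c(x, numeric(nfft - length(x))))
    mag <- Mod(spec[1:(nfft / 2 + 1)])
  } else {
    nfft <- next_pow2(max(vapply(corpus, function(s) length(s$samples), numeric(1))))
    mags <- sapply(corpus, function(s) {
      sp <- fft(c(s$samples, numeric(nfft - length(s$samples))))
      Mod(sp[1:(nfft / 2 + 1)])
    })
    mag <- rowMeans(mags)
  }
  structure(list(magnitude = mag, fft_length = nfft, sample_rate = sr),
            class = "noise_model")
}

#' Synthesize speech-shaped noise from a noise model
#'
#' Draws uniformly random phases for every spectral component of the model's
#' magnitude spectrum (interpolated onto the target length's frequency grid),
#' imposes Hermitian symmetry, and inverse-transforms, yielding real-valued
#' noise whose long-term spectrum matches the model. Deterministic for a
#' fixed seed.
#'
#' @param model a [build_noise_model()] result.
#' @param n_samples output length (>= 1).
#' @param seed integer seed for the phase draw.
#' @return an [audio_signal()].
#' @export
synthesize_noise <- function(model, n_samples, seed) {
  abort_if(!inherits(model, "noise_model"), "synthesize_noise: invalid model")
  abort_if(n_samples < 1, "synthesize_noise: n_samples must be >= 1")
  n <- as.integer(n_samples)
  sr <- model$sample_rate
  m <- n %/% 2 + 1 # one-sided bins for length n
  f_model <- (seq_along(model$magnitude) - 1) * sr / model$fft_length
  f_target <- (0:(m - 1)) * sr / n
  mag <- approx(f_model, model$magnitude, xout = f_target, rule = 2)$y
  phases <- withr::with_seed(seed, runif(m, 0, 2 * pi))
  phases[1] <- 0
  even <- n %% 2 == 0
  if (even) phases[m] <- 0 # Nyquist bin must be real
  half <- mag * exp(1i * phases)
  half[1] <- 0 # no DC: synthesized noise is zero-mean
  mirror <- if (even) Conj(rev(half[2:(m - 1)])) else Conj(rev(half[2:m]))
  full <- c(half, mirror)
  x <- fft(full, inverse = TRUE) / n
  audio_signal(Re(x), sr)
}

#' Welch-averaged power spectral density estimate
#'
#' Hann-windowed, 50%-overlapping segment-averaged periodogram; used to
#' verify that synthesized noise follows the model spectrum.
#'
#' @param signal an [audio_signal()].
#' @param nfft segment length (power of two recommended).
#' @return list with `freq` (Hz) and `psd` (linear power) of length
#'   `nfft/2 + 1`.
#' @export
welch_psd <- function(signal, nfft = 1024) {
  x <- signal$samples
  sr <- signal$sample_rate
  hop <- nfft / 2
  n_seg <- max(1, floor((length(x) - nfft) / hop) + 1)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / nfft))
  acc <- numeric(nfft / 2 + 1)
  for (k in seq_len(n_seg)) {
    seg <- x[((k - 1) * hop + 1):((k - 1) * hop + nfft)]
    sp <- fft(seg * w)
    acc <- acc + Mod(sp[1:(nfft / 2 + 1)])^2
  }
  list(freq = (0:(nfft / 2)) * sr / nfft, psd = acc / n_seg)
}

#' Bin-average a noise model's power spectrum onto a target frequency grid
#'
#' @param model a `noise_model`.
#' @param freq target frequencies (Hz), e.g. from [welch_psd()].
#' @return mean squared magnitude of the model in each frequency bin.
#' @export
model_psd <- function(model, freq) {
  f_model <- (seq_along(model$magnitude) - 1) * model$sample_rate / model$fft_length
  bins <- findInterval(f_model, c(freq - diff(freq[1:2]) / 2, Inf))
  out <- rep(NA_real_, length(freq))
  agg <- tapply(model$magnitude^2, bins, mean)
  idx <- as.integer(names(agg))
  ok <- idx >= 1 & idx <= length(freq)
  out[idx[ok]] <- agg[ok]
  out
}

#' Correlation between a signal's PSD and a noise model's spectrum
#'
#' Verifies that synthesized noise follows the model: the Welch PSD of the
#' signal and the bin-averaged model power spectrum are both smoothed to a
#' common resolution (`smooth_bins` Welch bins, about 70 Hz at the
#' defaults) and correlated over `band`. Phase-randomized synthesis
#' preserves the long-term spectral envelope; spectral fine structure below
#' the estimator's resolution (window mainlobe smearing of narrow harmonic
#' lines) is deliberately averaged out before comparison.
#'
#' @param model a `noise_model`.
#' @param signal an [audio_signal()] (ideally tens of seconds long).
#' @param nfft Welch segment length.
#' @param smooth_bins width of the moving-average smoother, in bins.
#' @param band frequency band (Hz) over which to correlate.
#' @return Pearson correlation of the smoothed power spectra.
#' @export
spectrum_match <- function(model, signal, nfft = 2048, smooth_bins = 9,
                           band = c(100, 7000)) {
  est <- welch_psd(signal, nfft)
  ref <- model_psd(model, est$freq)
  smooth <- function(x) as.numeric(stats::filter(x, rep(1 / smooth_bins,
                                                        smooth_bins), sides = 2))
  e <- smooth(est$psd)
  r <- smooth(ref)
  keep <- est$freq >= band[1] & est$freq <= band[2] & !is.na(e) & !is.na(r)
  cor(e[keep], r[keep])
}

#' RMS-normalize a signal
#'
#' Pure rescaling so that the RMS over the chosen scope equals `target_rms`.
#' With `scope = "active_segments"` the RMS is computed over the speech
#' intervals of `map` only (the level convention used for interrupted
#' stimuli, where half the waveform is silence by construction).
#'
#' @param signal an [audio_signal()].
#' @param target_rms target RMS amplitude (> 0).
#' @param scope `"whole"` or `"active_segments"`.
#' @param map `segment_map`, required for `scope = "active_segments"`.
#' @return rescaled [audio_signal()].
#' @export
rms_normalize <- function(signal, target_rms,
                          scope = c("whole", "active_segments"), map = NULL) {
  scope <- match.arg(scope)
  current <- if (scope == "whole") {
    rms(signal$samples)
  } else {
    abort_if(is.null(map), "rms_normalize: map required for scope = 'active_segments'")
    rms_over(signal, map, "speech")
  }
  abort_if(current == 0, "rms_normalize: cannot normalize an all-zero signal")
  audio_signal(signal$samples * target_rms / current, signal$sample_rate)
}

#' RMS over the intervals of a map carrying a given label
#'
#' @param signal an [audio_signal()].
#' @param map a `segment_map`.
#' @param label `"speech"` or `"gap"`.
#' @return RMS of the samples inside the labelled intervals.
#' @export
rms_over <- function(signal, map, label = "speech") {
  iv <- map$intervals[map$intervals$label == label, , drop = FALSE]
  abort_if(nrow(iv) == 0, sprintf("rms_over: no '%s' intervals in map", label))
  idx <- unlist(mapply(function(s, e) (s + 1):e, iv$start, iv$end,
                       SIMPLIFY = FALSE))
  rms(signal$samples[idx])
}

#' Assemble a matched silent-gap / noise-burst stimulus pair
#'
#' The sentence is gated by the square wave (silent-gap stimulus, RMS over
#' its speech segments normalized to `rms_target`); speech-shaped noise is
#' synthesized at full stimulus length, gated complementarily into the gaps
#' with the same ramps, and scaled so its active-segment RMS sits
#' `-snr_db` dB above the speech (default -10 dB SNR: noise 10 dB more
#' intense). The noise-burst stimulus is the sample-exact linear sum of the
#' two; because their supports are disjoint, `noise_burst - silent_gap`
#' recovers the gated noise bit-exactly.
#'
#' @param sentence an [audio_signal()] (the clean sentence).
#' @param spec a [gating_spec()].
#' @param model a [build_noise_model()] result at the sentence's sample rate.
#' @param snr_db speech level relative to noise in dB (default -10).
#' @param seed integer seed for the noise phase draw.
#' @param rms_target RMS of the speech over its active segments.
#' @return object of class `stimulus_pair`: `silent_gap`, `noise_burst`
#'   ([audio_signal()]s), `segment_map`, `snr_db`.
#' @export
assemble_pair <- function(sentence, spec = gating_spec(), model, snr_db = -10,
                          seed = 1, rms_target = 0.05) {
  abort_if(!is_audio_signal(sentence), "assemble_pair: sentence must be an audio_signal")
  abort_if(!inherits(model, "noise_model"), "assemble_pair: model must be a noise_model")
  abort_if(sentence$sample_rate != model$sample_rate,
           "assemble_pair: sentence and noise model sample rates differ")
  n <- length(sentence$samples)
  map <- make_segment_map(n, sentence$sample_rate, spec)
  silent_gap <- gate_signal(sentence, map, spec$ramp_ms)
  silent_gap <- rms_normalize(silent_gap, rms_target, "active_segments", map)

  noise <- synthesize_noise(model, n, seed)
  comp <- complement_map(map)
  noise_gated <- gate_signal(noise, comp, spec$ramp_ms)
  noise_rms_target <- rms_target * 10^(-snr_db / 20)
  noise_gated <- rms_normalize(noise_gated, noise_rms_target, "active_segments", comp)

  noise_burst <- audio_signal(silent_gap$samples + noise_gated$samples,
                              sentence$sample_rate)
  structure(list(silent_gap = silent_gap, noise_burst = noise_burst,
                 segment_map = map, snr_db = snr_db),
            class = "stimulus_pair")
}

#' Measure the speech-minus-noise level of a stimulus pair
#'
#' Computes `20*log10(RMS over speech intervals / RMS over noise intervals)`
#' on the noise-burst stimulus — the realized SNR in dB.
#'
#' @param pair a [assemble_pair()] result.
#' @return measured SNR in dB.
#' @export
measure_snr <- function(pair) {
  sp <- rms_over(pair$noise_burst, pair$segment_map, "speech")
  nz <- rms_over(pair$noise_burst, pair$segment_map, "gap")
  20 * log10(sp / nz)
}
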