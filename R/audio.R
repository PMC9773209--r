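# Waveform container and minimal RIFF/WAVE I/O (mono PCM16 / IEEE float32).

#' Construct an audio signal
#'
#' The basic unit all stimulus processing operates on: a finite sampled
#' waveform (nominal amplitude range \[-1, 1\]) with its sample rate.
#'
#' @param samples numeric vector of amplitudes; all values must be finite.
#' @param sample_rate sampling rate in Hz (> 0).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `sample_rate`.
#' @examples
#' tone <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(tone)
#' @export
audio_signal <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  abort_if(length(samples) < 1, "audio_signal: need at least one sample")
  abort_if(!all(is.finite(samples)), "audio_signal: samples must be finite")
  abort_if(!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0,
           "audio_signal: sample_rate must be a positive scalar")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), rms %.4g>\n",
              length(x$samples), x$sample_rate, duration(x), rms(x$samples)))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal an `audio_signal`.
#' @return duration in seconds.
#' @export
duration <- function(signal) length(signal$samples) / signal$sample_rate

is_audio_signal <- function(x) inherits(x, "audio_signal")

#' Read a WAV file
#'
#' Reads mono RIFF/WAVE files encoded as 16-bit PCM or 32-bit IEEE float.
#' Chunks other than `fmt ` and `data` are skipped.
#'
#' @param path path to a `.wav` file.
#' @return an [audio_signal()] with amplitudes scaled to \[-1, 1\] for PCM16.
#' @export
read_wav <- function(path) {
  abort_if(!file.exists(path), sprintf("read_wav: cannot open '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  abort_if(!identical(riff, "RIFF"), "read_wav: not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  abort_if(!identical(wave, "WAVE"), "read_wav: not a WAVE file")

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        channels = readBin(raw_fmt[3:4], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      abort_if(is.null(fmt), "read_wav: data chunk before fmt chunk")
      if (fmt$audio_format == 1 && fmt$bits == 16) {
        raw <- readBin(con, "integer", size / 2, size = 2, endian = "little")
        samples <- raw / 32767
      } else if (fmt$audio_format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "double", size / 4, size = 4, endian = "little")
      } else {
        stop(sprintf("read_wav: unsupported encoding (format %d, %d bit)",
                     fmt$audio_format, fmt$bits), call. = FALSE)
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2)) # skip, pad to even
    }
  }
  abort_if(is.null(samples), "read_wav: no data chunk found")
  abort_if(fmt$channels != 1,
           sprintf("read_wav: only mono supported, got %d channels", fmt$channels))
  audio_signal(samples, fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param signal an [audio_signal()].
#' @param path output path.
#' @param encoding `"float32"` (IEEE float, lossless for R doubles up to
#'   single precision) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, encoding = c("float32", "pcm16")) {
  encoding <- match.arg(encoding)
  abort_if(!is_audio_signal(signal), "write_wav: signal must be an audio_signal")
  n <- length(signal$samples)
  bytes_per <- if (encoding == "float32") 4L else 2L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (encoding == "float32") 3L else 1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(signal$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (encoding == "float32") {
    writeBin(signal$samples, con, size = 4, endian = "little")
  } else {
    x <- pmax(pmin(signal$samples, 1), -1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  }
  invisible(path)
}
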