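#' @importFrom stats approx coef confint cor fft lm mad median model.matrix
#'   oneway.test p.adjust pf pt qf qt quantile resid rnorm runif sd setNames
#'   shapiro.test t.test var
#' @importFrom utils head read.csv write.csv
NULL

#' Root-mean-square of a numeric vector
#'
#' @param x numeric vector.
#' @return RMS value, `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Derive a stable child seed from a master seed and a key
#'
#' Stage and stimulus seeds are derived from one master seed by hashing the
#' key string, so that adding or reordering sentences never changes the noise
#' drawn for another sentence. The hash is a 31-bit polynomial rolling hash,
#' kept below `2^31` so the result is a valid R integer seed.
#'
#' @param master integer master seed.
#' @param key character scalar identifying the stream (e.g. a sentence id).
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(key))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
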