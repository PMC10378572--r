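#' Audio signal container
#'
#' @param samples numeric amplitude vector
#' @param fs sample rate (Hz)
#' @param normalized has the signal been standardized to zero mean, unit
#'   variance?
#' @return an object of class `audio_signal`
#' @export
audio_signal <- function(samples, fs, normalized = FALSE) {
  stopifnot(fs > 0)
  stop_if_not_finite(samples, "audio samples")
  structure(list(samples = samples, fs = fs, normalized = normalized),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio: %d samples @ %g Hz (%.3f s)%s\n", length(x$samples),
              x$fs, length(x$samples) / x$fs,
              if (x$normalized) ", standardized" else ""))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM (8/16/24/32-bit integer)
#' and IEEE float data. Multichannel input is downmixed to mono by
#' averaging. Samples are scaled to `[-1, 1]`.
#'
#' @param path file path
#' @return an `audio_signal`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file", call. = FALSE)
  }
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        fs = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  }
  bits <- fmt$bits
  x <- if (fmt$audio_format == 3) {          # IEEE float
    readBin(data_raw, "double", length(data_raw) / (bits / 8), bits / 8,
            endian = "little")
  } else if (bits == 8) {
    (as.numeric(readBin(data_raw, "integer", length(data_raw), 1,
                        signed = FALSE)) - 128) / 128
  } else if (bits == 16) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (bits == 24) {
    n <- length(data_raw) / 3
    b <- matrix(as.integer(data_raw), 3, n)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else if (bits == 32) {
    readBin(data_raw, "integer", length(data_raw) / 4, 4, signed = TRUE,
            endian = "little") / 2^31
  } else {
    stop(sprintf("unsupported bit depth: %d", bits), call. = FALSE)
  }
  if (fmt$channels > 1) {
    x <- colMeans(matrix(x, fmt$channels))
  }
  audio_signal(x, fmt$fs)
}

#' Write a 16-bit PCM WAV file
#'
#' @param sig an `audio_signal` or numeric vector in `[-1, 1]`
#' @param path output path
#' @param fs sample rate (needed for a bare vector)
#' @return `path`, invisibly
#' @export
write_wav <- function(sig, path, fs = NULL) {
  if (inherits(sig, "audio_signal")) { fs <- sig$fs; x <- sig$samples }
  else x <- sig
  if (is.null(fs)) stop("supply fs", call. = FALSE)
  pcm <- as.integer(pmax(pmin(round(x * 32767), 32767), -32768))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(1), con, 2, endian = "little")    # PCM
  writeBin(as.integer(1), con, 2, endian = "little")    # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little")
  writeBin(as.integer(2), con, 2, endian = "little")
  writeBin(as.integer(16), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

resample_to <- function(x, fs, target_fs) {
  if (fs == target_fs) return(x)
  fi <- round(fs); ti <- round(target_fs)
  g <- reduce_ratio(ti, fi)
  if (max(g) <= 1000) {
    as.numeric(signal::resample(x, g[["n"]], g[["m"]]))
  } else {
    t_in <- (seq_along(x) - 1) / fs
    n_out <- floor(length(x) * target_fs / fs)
    stats::approx(t_in, x, xout = (0:(n_out - 1)) / target_fs, rule = 2)$y
  }
}

#' Load, resample and standardize an audio file
#'
#' Reads a PCM WAV, downmixes to mono, resamples to `target_fs`, and
#' standardizes to zero mean and unit variance.
#'
#' @param path WAV file path
#' @param target_fs target sample rate, default 16 kHz
#' @return a standardized `audio_signal`
#' @export
load_normalize_audio <- function(path, target_fs = 16000) {
  sig <- read_wav(path)
  if (stats::sd(sig$samples) == 0) {
    stop("degenerate signal: silent input", call. = FALSE)
  }
  x <- resample_to(sig$samples, sig$fs, target_fs)
  audio_signal(standardize(x), target_fs, normalized = TRUE)
}

#' Fundamental frequency by autocorrelation
#'
#' Normalized autocorrelation peak search in the 50-500 Hz pitch range
#' with parabolic peak refinement. Fails when no autocorrelation peak
#' exceeds `min_peak` (aperiodic input).
#'
#' @param sig an `audio_signal`
#' @param range pitch search range in Hz
#' @param min_peak minimum normalized autocorrelation at the pitch lag
#' @return f0 estimate in Hz
#' @export
estimate_f0 <- function(sig, range = c(50, 500), min_peak = 0.3) {
  x <- sig$samples - mean(sig$samples)
  fs <- sig$fs
  lag_min <- max(2L, floor(fs / range[2]))
  lag_max <- min(length(x) - 2L, ceiling(fs / range[1]))
  if (lag_max <= lag_min) stop("signal too short for pitch search", call. = FALSE)
  # FFT autocorrelation
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE))[1:(lag_max + 2)]
  ac <- ac / ac[1]
  lags <- lag_min:lag_max
  k <- lags[which.max(ac[lags + 1])]
  peak <- ac[k + 1]
  if (peak < min_peak) stop("no periodicity detected", call. = FALSE)
  # parabolic refinement around the peak
  y1 <- ac[k]; y2 <- ac[k + 1]; y3 <- ac[k + 2]
  denom <- y1 - 2 * y2 + y3
  shift <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  fs / (k + shift)
}

# linear-prediction coefficients (autocorrelation method, Burg estimate)
lpc_coefs <- function(x, order) {
  fit <- stats::ar(x, aic = FALSE, order.max = order, method = "burg",
                   demean = TRUE)
  a <- fit$ar
  if (length(a) < order) a <- c(a, numeric(order - length(a)))
  a
}

inverse_filter_pass <- function(x, a) {
  as.numeric(signal::filter(c(1, -a), 1, x))
}

leaky_integrate <- function(x, rho = 0.99) {
  as.numeric(signal::filter(1, c(1, -rho), x))
}

#' Glottal flow by iterative adaptive inverse filtering
#'
#' Two-pass IAIF: a low-order glottal model and a vocal-tract all-pole
#' model are estimated alternately by linear prediction and removed from
#' the speech signal, and the lip-radiation differentiation is cancelled by
#' leaky integration, leaving an estimate of the glottal volume-velocity
#' waveform. The vocal-tract order is `fs/1000 + 2`; pre-emphasis 0.97.
#' Output is standardized (the absolute flow scale is not recoverable from
#' audio alone).
#'
#' @param sig an `audio_signal` (voiced, sustained vowel)
#' @return a `reference_flow`: data frame with `t` (seconds) and `ug`
#'   (standardized), with attribute `fs`
#' @export
inverse_filter <- function(sig) {
  x <- sig$samples
  if (stats::sd(x) == 0) stop("degenerate signal: silent input", call. = FALSE)
  fs <- sig$fs
  p_vt <- round(fs / 1000) + 2
  xe <- inverse_filter_pass(x, 0.97)           # pre-emphasis
  # pass 1: crude glottal tilt (order 1), then vocal tract
  g1 <- lpc_coefs(xe, 1)
  y1 <- inverse_filter_pass(x, g1)
  a1 <- lpc_coefs(y1, p_vt)
  flow1 <- leaky_integrate(inverse_filter_pass(x, a1))
  # pass 2: refined glottal model (order 4) from the first flow estimate
  g2 <- lpc_coefs(flow1, 4)
  y2 <- leaky_integrate(inverse_filter_pass(x, g2))
  a2 <- lpc_coefs(y2, p_vt)
  flow <- leaky_integrate(inverse_filter_pass(x, a2))
  if (!all(is.finite(flow))) stop("inverse filtering unstable", call. = FALSE)
  out <- data.frame(t = (seq_along(flow) - 1) / fs, ug = standardize(flow))
  attr(out, "fs") <- fs
  class(out) <- c("reference_flow", "data.frame")
  out
}

#' Re-express a reference flow on the oscillator's model-time grid
#'
#' @param flow a `reference_flow` (seconds) or data frame with `t`, flow
#' @param timescale a [time_scale] giving the fundamental frequency
#' @return a `glottal_flow` with `t` in model-time units
#' @export
as_model_flow <- function(flow, timescale) {
  out <- data.frame(t = seconds_to_model(flow$t, timescale), u0 = flow[[2]])
  attr(out, "timescale") <- timescale
  class(out) <- c("glottal_flow", "data.frame")
  out
}
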