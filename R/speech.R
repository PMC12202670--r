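# Speech-proxy synthesis, level calibration, and WAV read/write.
#
# dB SPL convention: levels are computed as 94 + 20*log10(rms * sqrt(2)),
# i.e. a full-scale sine (peak amplitude 1, rms 1/sqrt(2)) measures 94 dB.
# Absolute SPL is a bookkeeping convention; only relative levels matter in
# software.

.ref_rms <- 1 / sqrt(2)   # rms of a full-scale sine; defined as 94 dB SPL
.ref_db <- 94

#' Sound level of a waveform segment in dB SPL
#'
#' @param x Numeric waveform (full scale = +/-1).
#' @return Level in dB SPL under the package convention (full-scale sine =
#'   94 dB).
#' @export
db_spl <- function(x) {
  r <- sqrt(mean(x^2))
  .ref_db + 20 * log10(r / .ref_rms)
}

# running RMS over all windows of `n` samples (hop `hop`); exact at hop = 1
running_rms_max <- function(x, n, hop = 1) {
  cs <- cumsum(c(0, x^2))
  starts <- seq(1, length(x) - n + 1, by = hop)
  sq <- (cs[starts + n] - cs[starts]) / n
  sqrt(max(sq))
}

#' Calibrate a speech waveform so its loudest window sits at a target level
#'
#' Scales the waveform by a single positive factor so that the maximum RMS
#' level over all sliding windows of length `window` ms equals
#' `target_level` dB SPL. The sliding-window search uses a hop of one sample
#' (exact); `hop` can be raised for speed.
#'
#' @param waveform Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param target_level Target level in dB SPL (default 60).
#' @param window Window length in ms (default 100).
#' @param hop Window hop in samples (default 1 = exact).
#' @return List with `waveform` (scaled), `scale` (the multiplier),
#'   `level_before` and `level_after` (dB SPL of the loudest window).
#' @export
calibrate_speech_level <- function(waveform, sample_rate, target_level = 60,
                                   window = 100, hop = 1) {
  if (all(waveform == 0)) stop("silent input: all-zero waveform")
  n <- round(window / 1000 * sample_rate)
  if (n > length(waveform))
    stop("window (", window, " ms) longer than waveform")
  rms_max <- running_rms_max(waveform, n, hop)
  level <- .ref_db + 20 * log10(rms_max / .ref_rms)
  scale <- 10^((target_level - level) / 20)
  list(waveform = waveform * scale, scale = scale,
       level_before = level, level_after = target_level)
}

# Label-conditional consonant onset parameters for the speech proxies.
# delta: onset delay (ms) of the consonant signature after sound onset;
# f_lo/f_hi: noise-burst band (Hz); frac_dur: signature duration (ms);
# amp: relative signature amplitude. Stop consonants (b, t, g, d) get brief
# abrupt broadband bursts; "s" gets longer frication; "r"/"l" get weaker,
# slower formant-glide-like onsets.
speech_proxy_params <- function() {
  data.frame(
    label = c("dad", "bad", "gad", "tad", "sad", "rad", "lad"),
    consonant = c("d", "b", "g", "t", "s", "r", "l"),
    manner = c("stop", "stop", "stop", "stop", "fricative",
               "approximant", "approximant"),
    delta = c(0, 3, 7, 11, 2, 6, 10),
    f_lo = c(3000, 500, 1500, 4000, 5000, 900, 1100),
    f_hi = c(7000, 1800, 3500, 10000, 11000, 2200, 2600),
    sig_dur = c(10, 12, 12, 8, 35, 30, 30),
    amp = c(1.0, 0.85, 0.9, 1.05, 0.7, 0.5, 0.55),
    stringsAsFactors = FALSE
  )
}

#' Speech token labels
#' @return Character vector of the seven consonant-vowel-consonant tokens.
#' @export
speech_labels <- function() speech_proxy_params()$label

# band-limited noise via FFT masking (deterministic given RNG state)
band_noise <- function(n_samp, sr, f_lo, f_hi) {
  x <- stats::rnorm(n_samp)
  sp <- stats::fft(x)
  f <- (seq_len(n_samp) - 1) * sr / n_samp
  f <- pmin(f, sr - f)  # two-sided
  mask <- as.numeric(f >= f_lo & f <= f_hi)
  Re(stats::fft(sp * mask, inverse = TRUE)) / n_samp
}

#' Synthesize a consonant-vowel speech-proxy token
#'
#' A fixture waveform standing in for vocoded natural speech: a
#' label-specific ~40 ms consonant onset signature (band-limited noise burst
#' for stops and frication, tonal glide for approximants) followed by a
#' shared formant-like vowel (~300 ms) and a weak final-stop burst, then
#' calibrated so the loudest 100 ms sits at 60 dB SPL. Deterministic per
#' `(label, seed)`.
#'
#' @param label One of [speech_labels()].
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param seed Integer seed for the noise components.
#' @param target_level Calibration target in dB SPL (default 60).
#' @return A `speech_stimulus`: list with `label`, `waveform`, `sample_rate`,
#'   `consonant_window` (ms), `total_duration` (ms), `manner`.
#' @export
synth_speech_proxy <- function(label, sample_rate = 16000, seed = 1,
                               target_level = 60) {
  pars <- speech_proxy_params()
  i <- match(label, pars$label)
  if (is.na(i)) stop("unknown label '", label, "'; expected one of: ",
                     paste(pars$label, collapse = ", "))
  p <- pars[i, ]
  sr <- sample_rate
  total_ms <- 440
  n_total <- round(total_ms / 1000 * sr)
  with_seed(child_seed(seed, i), {
    wave <- numeric(n_total)
    t_all <- (seq_len(n_total) - 1) / sr

    # consonant signature within the first 40 ms
    i0 <- round(p$delta / 1000 * sr) + 1
    n_sig <- round(p$sig_dur / 1000 * sr)
    if (p$manner == "approximant") {
      # tonal glide rising into the vowel's first formant region
      tt <- (seq_len(n_sig) - 1) / sr
      f_sweep <- seq(p$f_lo, p$f_hi, length.out = n_sig)
      sig <- sin(2 * pi * cumsum(f_sweep) / sr) * p$amp
      env <- sin(pi * seq_len(n_sig) / n_sig)  # gradual on/off
    } else {
      sig <- band_noise(n_sig, sr, p$f_lo, p$f_hi)
      sig <- sig / sqrt(mean(sig^2)) * 0.35 * p$amp
      env <- if (p$manner == "stop") {
        # abrupt broadband onset, rapid decay
        exp(-seq_len(n_sig) / (0.25 * n_sig))
      } else {
        sin(pi * seq_len(n_sig) / n_sig)
      }
    }
    wave[i0:(i0 + n_sig - 1)] <- wave[i0:(i0 + n_sig - 1)] + sig * env

    # shared vowel: f0 harmonics shaped by formant peaks (octave-shifted
    # into the rat hearing range), 40-340 ms, identical construction for all
    # labels apart from broadband aspiration noise drawn from the seed
    v0 <- round(0.040 * sr) + 1
    v1 <- round(0.340 * sr)
    tv <- t_all[v0:v1] - t_all[v0]
    f0 <- 360  # shifted-up fundamental
    formants <- c(1400, 2400, 5200)
    fw <- c(250, 300, 500)
    vowel <- numeric(length(tv))
    for (h in 1:12) {
      fh <- h * f0
      g <- sum(exp(-(fh - formants)^2 / (2 * fw^2)))
      vowel <- vowel + g * sin(2 * pi * fh * tv)
    }
    vowel <- vowel / max(abs(vowel)) * 0.3
    ramp <- pmin(1, tv / 0.015, (max(tv) - tv) / 0.030)
    vowel <- vowel * ramp
    vowel <- vowel + 0.01 * stats::rnorm(length(vowel))
    wave[v0:v1] <- wave[v0:v1] + vowel

    # weak final-stop burst ("d") at ~360 ms
    fb0 <- round(0.360 * sr) + 1
    n_fb <- round(0.010 * sr)
    fb <- band_noise(n_fb, sr, 3000, 7000)
    fb <- fb / sqrt(mean(fb^2)) * 0.12 * exp(-seq_len(n_fb) / (0.3 * n_fb))
    wave[fb0:(fb0 + n_fb - 1)] <- wave[fb0:(fb0 + n_fb - 1)] + fb

    cal <- calibrate_speech_level(wave, sr, target_level = target_level,
                                  window = 100, hop = 8)
    structure(list(label = p$label, consonant = p$consonant,
                   manner = p$manner, waveform = cal$waveform,
                   sample_rate = sr, consonant_window = c(0, 40),
                   total_duration = total_ms, level = target_level,
                   scale = cal$scale),
              class = "speech_stimulus")
  })
}

#' Write a mono waveform to a PCM WAV file
#'
#' Minimal RIFF/WAVE writer (16-bit PCM or 32-bit IEEE float, mono). Written
#' in-package because no WAV codec is otherwise available to the pipeline.
#'
#' @param waveform Numeric vector, full scale +/-1 (clipped for 16-bit).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate, path, bits = 16) {
  stopifnot(bits %in% c(16, 32))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(waveform)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt <- if (bits == 16) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    x <- pmax(-1, pmin(1, waveform))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(waveform), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return List with `waveform` and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  readChar(con, 4)  # WAVE
  sr <- NA_integer_; bits <- NA_integer_; fmt <- NA_integer_
  wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      if (fmt == 1L && bits == 16L) {
        wave <- readBin(con, "integer", sz / 2, size = 2, endian = "little") / 32767
      } else if (fmt == 3L && bits == 32L) {
        wave <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      } else stop("unsupported WAV encoding")
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  list(waveform = wave, sample_rate = sr)
}
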