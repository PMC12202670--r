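# Tone, noise-train, VNS-train and pairing-schedule construction.

#' Construct a single tone-pip stimulus
#'
#' @param frequency Tone frequency in Hz, within 1000--32000.
#' @param level Sound level in dB SPL, within 0--75.
#' @param duration Pip duration in ms (default 25).
#' @return An object of class `tone_stimulus`.
#' @export
tone_stimulus <- function(frequency, level, duration = 25) {
  if (!is.numeric(frequency) || frequency < 1000 || frequency > 32000)
    stop("frequency must lie within [1000, 32000] Hz")
  if (!is.numeric(level) || level < 0 || level > 75)
    stop("level must lie within [0, 75] dB SPL")
  if (duration <= 0) stop("duration must be positive")
  structure(list(frequency = frequency, level = level, duration = duration),
            class = "tone_stimulus")
}

#' Build the tone-pip frequency x level grid
#'
#' Frequencies are log-spaced (inclusive of both endpoints) and levels are an
#' arithmetic sequence. The default grid (81 frequencies from 1 to 32 kHz,
#' 5 dB steps from 0 to 75 dB SPL) follows standard receptive-field mapping
#' practice; both densities are configurable.
#'
#' @param freq_range Length-2 Hz interval (default `c(1000, 32000)`).
#' @param level_range Length-2 dB interval (default `c(0, 75)`).
#' @param n_freqs Number of log-spaced frequencies (>= 2; default 81).
#' @param level_step Level step in dB (default 5).
#' @param duration Pip duration in ms (default 25).
#' @return A `tone_grid`: data.frame with columns `frequency`, `level`,
#'   `duration` (one row per stimulus, frequency varying fastest) and
#'   attributes `freqs` and `levels`.
#' @export
make_tone_grid <- function(freq_range = c(1000, 32000), level_range = c(0, 75),
                           n_freqs = 81, level_step = 5, duration = 25) {
  if (freq_range[1] >= freq_range[2]) stop("freq_range must be increasing")
  if (level_range[1] >= level_range[2]) stop("level_range must be increasing")
  if (n_freqs < 2) stop("n_freqs must be >= 2")
  freqs <- 2^seq(log2(freq_range[1]), log2(freq_range[2]), length.out = n_freqs)
  levels <- seq(level_range[1], level_range[2], by = level_step)
  grid <- expand.grid(frequency = freqs, level = levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$duration <- duration
  structure(grid, freqs = freqs, levels = levels, class = c("tone_grid", "data.frame"))
}

#' Construct a periodic noise-burst train
#'
#' Six 25 ms noise bursts at one of the four supported repetition rates.
#'
#' @param repetition_rate Burst rate in Hz; one of 7.5, 10, 12.5, 15.
#' @return An object of class `noise_burst_train` with fields
#'   `repetition_rate`, `n_bursts`, `burst_duration` and `burst_onsets` (ms).
#' @export
make_noise_train <- function(repetition_rate) {
  supported <- c(7.5, 10, 12.5, 15)
  if (!isTRUE(repetition_rate %in% supported))
    stop("unsupported repetition rate; supported rates (Hz): ",
         paste(supported, collapse = ", "))
  n_bursts <- 6L
  onsets <- (seq_len(n_bursts) - 1) * 1000 / repetition_rate
  structure(list(repetition_rate = repetition_rate, n_bursts = n_bursts,
                 burst_duration = 25, burst_onsets = onsets),
            class = "noise_burst_train")
}

#' Construct the standard VNS pulse train
#'
#' 500 ms train of 16 biphasic pulses (100 us pulse width) at 30 Hz, 0.8 mA,
#' onset-inclusive, so the final pulse falls at 500 ms.
#'
#' @return An object of class `vns_train` with fields `duration` (ms),
#'   `pulse_rate` (Hz), `n_pulses`, `pulse_width_us`, `amplitude_ma`,
#'   `pulse_times` (ms).
#' @export
make_vns_train <- function() {
  n_pulses <- 16L
  pulse_times <- (seq_len(n_pulses) - 1) * 1000 / 30
  structure(list(duration = 500, pulse_rate = 30, n_pulses = n_pulses,
                 pulse_width_us = 100, biphasic = TRUE, amplitude_ma = 0.8,
                 pulse_times = pulse_times),
            class = "vns_train")
}

# Calibrate the rate of a truncated exponential so its mean equals `target`.
# ITIs are a + X where X ~ Exp(rate) truncated to [0, b - a].
trunc_exp_rate <- function(target, lo, hi) {
  span <- hi - lo
  m <- target - lo
  # mean of an exponential truncated to [0, span] lies in (0, span/2)
  if (m <= 0 || m >= span / 2)
    stop("mean_iti is unreachable for truncation bounds [", lo, ", ", hi, "]")
  f <- function(rate) {
    e <- exp(-rate * span)
    (1 / rate - span * e / (1 - e)) - m
  }
  stats::uniroot(f, interval = c(1e-6, 10), tol = 1e-12)$root
}

r_trunc_exp <- function(n, rate, span) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * span))) / rate
}

#' Build a randomized VNS-sound pairing schedule
#'
#' Pairing events are spaced by intertrial intervals drawn from an exponential
#' distribution truncated to `[iti_min, iti_max]` whose rate is calibrated so
#' the truncated mean equals `mean_iti` exactly; a 2.5 h session at a 30 s
#' mean ITI therefore yields about 300 pairings. Silence catch trials are
#' interleaved at `silence_fraction` of all trials. On every pairing event the
#' VNS train onset precedes the sound onset by `vns_lead` ms.
#'
#' @param session_duration Session length in seconds (default 9000 = 2.5 h).
#' @param mean_iti Mean intertrial interval between pairing events, seconds
#'   (default 30). With `iti_scope = "all"` it is instead the mean interval
#'   between consecutive trials of any kind.
#' @param seed Integer seed; the schedule is reproducible per seed.
#' @param vns_lead Lead of VNS onset before sound onset, ms (default 50).
#' @param silence_fraction Fraction of trials that are silence catch trials
#'   (default 0.5).
#' @param iti_min,iti_max Truncation bounds for the ITI distribution, seconds.
#' @param iti_scope `"pairing"` (default): `mean_iti` governs pairing events
#'   only; `"all"`: it governs the joint pairing+silence trial stream.
#' @return A `pairing_schedule`: list with `events` (data.frame: `time` s,
#'   `kind`, `vns_onset` s), counts, and the configuration used.
#' @export
make_pairing_schedule <- function(session_duration = 9000, mean_iti = 30,
                                  seed = 1, vns_lead = 50,
                                  silence_fraction = 0.5,
                                  iti_min = 10, iti_max = 90,
                                  iti_scope = c("pairing", "all")) {
  if (session_duration <= 0) stop("session_duration must be positive")
  if (mean_iti <= 0) stop("mean_iti must be positive")
  iti_scope <- match.arg(iti_scope)
  rate <- trunc_exp_rate(mean_iti, iti_min, iti_max)
  span <- iti_max - iti_min
  with_seed(seed, {
    n_guess <- ceiling(session_duration / iti_min) + 10
    itis <- iti_min + r_trunc_exp(n_guess, rate, span)
    times <- cumsum(itis)
    times <- times[times <= session_duration]
    if (iti_scope == "pairing") {
      pair_times <- times
      n_sil <- if (silence_fraction > 0 && silence_fraction < 1)
        round(length(pair_times) * silence_fraction / (1 - silence_fraction)) else 0L
      sil_times <- sort(stats::runif(n_sil, 0, session_duration))
      ev <- rbind(
        data.frame(time = pair_times,
                   kind = rep("pairing", length(pair_times))),
        if (n_sil > 0) data.frame(time = sil_times,
                                  kind = rep("silence", n_sil))
      )
    } else {
      kind <- ifelse(stats::runif(length(times)) < silence_fraction,
                     "silence", "pairing")
      ev <- data.frame(time = times, kind = kind)
    }
    ev <- ev[order(ev$time), , drop = FALSE]
    # enforce strictly increasing event times (ties broken by a nudge well
    # below the trial timescale)
    while (any(duplicated(ev$time))) {
      ev$time[duplicated(ev$time)] <- ev$time[duplicated(ev$time)] + 1e-6
      ev <- ev[order(ev$time), , drop = FALSE]
    }
    rownames(ev) <- NULL
    ev$vns_onset <- ifelse(ev$kind == "pairing", ev$time - vns_lead / 1000, NA_real_)
    structure(list(events = ev,
                   n_pairings = sum(ev$kind == "pairing"),
                   n_silence = sum(ev$kind == "silence"),
                   session_duration = session_duration, mean_iti = mean_iti,
                   vns_lead = vns_lead, silence_fraction = silence_fraction,
                   iti_scope = iti_scope, seed = seed),
              class = "pairing_schedule")
  })
}
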