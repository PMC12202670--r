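# Temporal-fidelity metrics for noise-burst train responses.

#' Per-burst driven response
#'
#' Mean spikes per trial in a window after each burst onset, minus the
#' spontaneous expectation for an equal-duration window (estimated from the
#' 100 ms pre-stimulus period of the same responses). The default window of
#' 5-45 ms after burst onset never overlaps the next burst's window at any
#' supported rate (inter-burst interval >= 66.7 ms).
#'
#' @param responses A [spike_response_set()] for one train.
#' @param train The matching [make_noise_train()] object.
#' @param burst_window Count window relative to each burst onset, ms
#'   (default `c(5, 45)`).
#' @return Numeric vector of 6 driven counts (spikes/trial).
#' @export
per_burst_driven_response <- function(responses, train,
                                      burst_window = c(5, 45)) {
  ibi <- 1000 / train$repetition_rate
  if (diff(burst_window) > ibi)
    stop("burst_window (", diff(burst_window),
         " ms) overlaps the next burst at ", train$repetition_rate,
         " Hz; it must be <= ", round(ibi, 2), " ms")
  spont <- spont_rate_estimate(responses)
  win_len_s <- diff(burst_window) / 1000
  vapply(train$burst_onsets, function(on) {
    mean_count_in(responses, on + burst_window) - spont * win_len_s
  }, numeric(1))
}

#' Steady-state driven rate of a burst train
#'
#' Mean of the per-burst driven counts from burst three onwards.
#'
#' @param per_burst Numeric vector of 6 per-burst driven counts.
#' @return Spikes/trial.
#' @export
steady_state_rate <- function(per_burst) {
  stopifnot(length(per_burst) == 6)
  mean(per_burst[3:6])
}

#' Vector strength of spike phases relative to a periodic stimulus
#'
#' The resultant length of the pooled spike phases,
#' `vs = (1/n) * sqrt((sum cos)^2 + (sum sin)^2)` with
#' `theta_i = 2*pi*rate*t_i`.
#'
#' @param spike_times Spike times in ms (conventionally pooled over trials
#'   from burst-1 onset through one period after burst-6 onset).
#' @param repetition_rate Stimulus rate, Hz.
#' @return List with `vs` in `[0, 1]` and `n` (spikes used); `vs` is `NA`
#'   when `n == 0`.
#' @export
vector_strength <- function(spike_times, repetition_rate) {
  n <- length(spike_times)
  if (n == 0) return(list(vs = NA_real_, n = 0L))
  theta <- 2 * pi * repetition_rate * spike_times / 1000
  vs <- sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / n
  list(vs = min(vs, 1), n = n)
}

#' Rayleigh statistic
#'
#' `2 * n * vs^2`, the Rayleigh test statistic for non-uniformity of spike
#' phases.
#'
#' @param vs Vector strength in `[0, 1]`.
#' @param n Number of spikes.
#' @return The statistic (>= 0).
#' @export
rayleigh_statistic <- function(vs, n) {
  stopifnot(n >= 1)
  2 * n * vs^2
}

#' Phase-locking classification
#'
#' A site is phase locked when its Rayleigh statistic strictly exceeds 13.8.
#'
#' @param statistic Rayleigh statistic.
#' @param criterion Threshold (default 13.8).
#' @return Logical.
#' @export
classify_phase_locked <- function(statistic, criterion = 13.8) {
  statistic > criterion
}

#' Paired-pulse ratio
#'
#' Driven response to the second burst divided by the first (P2/P1), on
#' spontaneous-corrected counts. Undefined (NA) when P1 <= 0 or, when a
#' standard error for P1 is supplied, when P1 does not exceed
#' `min_snr * p1_se` -- the same 2-SE reliability convention used for FRA
#' significance; a ratio over an unmeasurable first-burst response is not
#' meaningful.
#'
#' @param per_burst Numeric vector of per-burst driven counts.
#' @param p1_se Optional standard error of the first-burst driven count.
#' @param min_snr Reliability criterion in SE units (default 2).
#' @return List with `ppr` (NA when flagged) and `flagged` (logical).
#' @export
paired_pulse_ratio <- function(per_burst, p1_se = NULL, min_snr = 2) {
  stopifnot(length(per_burst) >= 2)
  lim <- if (is.null(p1_se)) 0 else min_snr * p1_se
  if (per_burst[1] <= lim) return(list(ppr = NA_real_, flagged = TRUE))
  list(ppr = per_burst[2] / per_burst[1], flagged = FALSE)
}

#' Temporal summary for one site and one train rate
#'
#' Computes per-burst driven counts, steady-state rate, odd/even steady
#' burst means, vector strength over the analysis interval (burst-1 onset
#' through one period after burst-6 onset, pooled over trials), Rayleigh
#' statistic and phase-lock flag, paired-pulse ratio, and onset latency.
#'
#' @param responses A [spike_response_set()].
#' @param train The matching [make_noise_train()].
#' @param burst_window Per-burst count window, ms (default `c(5, 45)`).
#' @return One-row data.frame with the `TemporalSummary` fields
#'   (`site_id`, `repetition_rate`, `p1`..`p6`, `steady_state_rate`,
#'   `odd_burst_mean`, `even_burst_mean`, `vector_strength`, `n_spikes`,
#'   `rayleigh`, `phase_locked`, `ppr`, `ppr_flagged`, `onset_latency`).
#' @export
temporal_summary <- function(responses, train, burst_window = c(5, 45)) {
  pb <- per_burst_driven_response(responses, train, burst_window)
  interval <- c(train$burst_onsets[1],
                train$burst_onsets[6] + 1000 / train$repetition_rate)
  spikes <- pool_spikes(responses, interval)
  vsr <- vector_strength(spikes, train$repetition_rate)
  ray <- if (vsr$n > 0) rayleigh_statistic(vsr$vs, vsr$n) else NA_real_
  p1_counts <- vapply(responses$trials, function(tr) {
    w <- train$burst_onsets[1] + burst_window
    sum(tr >= w[1] & tr < w[2])
  }, numeric(1))
  p1_se <- stats::sd(p1_counts) / sqrt(length(p1_counts))
  ppr <- paired_pulse_ratio(pb, p1_se = p1_se)
  lat <- estimate_latencies(responses, peak_window = c(0, 75))
  data.frame(site_id = if (is.null(responses$site_id)) NA else responses$site_id,
             repetition_rate = train$repetition_rate,
             p1 = pb[1], p2 = pb[2], p3 = pb[3], p4 = pb[4], p5 = pb[5],
             p6 = pb[6],
             steady_state_rate = steady_state_rate(pb),
             odd_burst_mean = mean(pb[c(3, 5)]),
             even_burst_mean = mean(pb[c(4, 6)]),
             vector_strength = vsr$vs, n_spikes = vsr$n,
             rayleigh = ray,
             phase_locked = !is.na(ray) && classify_phase_locked(ray),
             ppr = ppr$ppr, ppr_flagged = ppr$flagged,
             onset_latency = lat$onset_latency)
}
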