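# Shared fixtures built in code at test time.

# a single generic site row for simulator-level tests
fixture_site <- function(gain = 1, latency = 14.4, cf = 8000, threshold = 20,
                         tuning_width = 0.45, adaptation = 1,
                         odd_burst_suppression = 1, phase_jitter = 0,
                         spont_rate = 5, site_id = "site1") {
  data.frame(site_id = site_id, animal_id = "a1", group = "SAL",
             cf = cf, threshold = threshold, tuning_width = tuning_width,
             latency = latency, log_gain = log(gain), gain = gain,
             adaptation = adaptation,
             odd_burst_suppression = odd_burst_suppression,
             phase_jitter = phase_jitter, spont_rate = spont_rate)
}

# build a spike_response_set from a list of spike-time vectors
fixture_responses <- function(trial_list, stimulus_id = "stim",
                              window = c(-100, 750)) {
  spike_response_set(trial_list, site_id = "site1",
                     stimulus_id = stimulus_id, window = window)
}

# deterministic response set: same spikes every trial
fixture_deterministic <- function(times, n_trials = 20, ...) {
  fixture_responses(rep(list(times), n_trials), ...)
}

# independent oracle for the leave-one-out template classifier: plain-loop
# fold enumeration with explicitly built templates (no shared code with the
# package implementation)
oracle_loo_classifier <- function(trials_a, trials_b, bin = 1,
                                  window = c(0, 40)) {
  edges <- seq(window[1], window[2], by = bin)
  binv <- function(tr) {
    tr <- tr[tr >= window[1] & tr < window[2]]
    tabulate(findInterval(tr, edges), nbins = length(edges) - 1)
  }
  A <- lapply(trials_a, binv); B <- lapply(trials_b, binv)
  n_ok <- 0; n_tot <- 0; ties <- 0
  for (i in seq_along(A)) {
    tmplA <- Reduce(`+`, A[-i]) / (length(A) - 1)
    tmplB <- Reduce(`+`, B) / length(B)
    dA <- sqrt(sum((A[[i]] - tmplA)^2)); dB <- sqrt(sum((A[[i]] - tmplB)^2))
    if (dA == dB) ties <- ties + 1 else n_ok <- n_ok + (dA < dB)
    n_tot <- n_tot + 1
  }
  for (i in seq_along(B)) {
    tmplB <- Reduce(`+`, B[-i]) / (length(B) - 1)
    tmplA <- Reduce(`+`, A) / length(A)
    dB <- sqrt(sum((B[[i]] - tmplB)^2)); dA <- sqrt(sum((B[[i]] - tmplA)^2))
    if (dA == dB) ties <- ties + 1 else n_ok <- n_ok + (dB < dA)
    n_tot <- n_tot + 1
  }
  list(percent_correct_excl_ties = 100 * n_ok / n_tot, ties = ties,
       n_folds = n_tot)
}
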