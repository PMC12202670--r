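# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministically maps `(seed, k)` to a new seed in `[1, 2^31 - 2]` so that
#' loops over sites/stimuli can give each simulation call its own reproducible
#' stream without consuming the caller's RNG state.
#'
#' @param seed Integer master seed.
#' @param k Integer index (>= 0).
#' @return A single integer seed.
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k),
            length(k) == 1)
  # multiplicative hash mod a prime below 2^31; the double-precision
  # intermediate product stays well under 2^53 so the arithmetic is exact
  p <- 2147483587
  x <- (abs(seed) %% p) * 48271 %% p
  as.integer((x + abs(k)) %% p) + 1L
}

# run expr with a local RNG state seeded at `seed`; restores the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Pool spike times across trials
#'
#' @param responses A [spike_response_set()].
#' @param window Optional numeric length-2 interval (ms); only spikes inside
#'   `[window[1], window[2])` are returned.
#' @return Numeric vector of spike times (ms), pooled over trials.
#' @export
pool_spikes <- function(responses, window = NULL) {
  x <- unlist(responses$trials, use.names = FALSE)
  if (length(x) == 0) return(numeric(0))
  if (!is.null(window)) x <- x[x >= window[1] & x < window[2]]
  x
}

# mean spikes per trial in [w1, w2)
mean_count_in <- function(responses, window) {
  n <- vapply(responses$trials,
              function(tr) sum(tr >= window[1] & tr < window[2]), numeric(1))
  mean(n)
}

#' Peri-stimulus time histogram
#'
#' Bins pooled spike times into fixed-width bins.
#'
#' @param spike_times Numeric vector of spike times (ms).
#' @param window Length-2 interval (ms) covered by the histogram.
#' @param bin Bin width in ms (default 1).
#' @return A data.frame with columns `time` (bin left edge, ms) and `count`.
#' @export
psth <- function(spike_times, window, bin = 1) {
  edges <- seq(window[1], window[2], by = bin)
  if (utils::tail(edges, 1) < window[2]) edges <- c(edges, utils::tail(edges, 1) + bin)
  counts <- graphics::hist(spike_times[spike_times >= edges[1] & spike_times < utils::tail(edges, 1)],
                           breaks = edges, plot = FALSE)$counts
  data.frame(time = edges[-length(edges)], count = counts)
}

#' Estimate the spontaneous firing rate from pre-stimulus activity
#'
#' Uses the 100 ms window preceding stimulus onset, pooled over trials.
#'
#' @param responses A [spike_response_set()] or list of them.
#' @param window Pre-stimulus interval in ms (default `c(-100, 0)`).
#' @return Rate in spikes/s.
#' @export
spont_rate_estimate <- function(responses, window = c(-100, 0)) {
  if (inherits(responses, "spike_response_set")) responses <- list(responses)
  n_spk <- 0; n_tr <- 0
  for (r in responses) {
    n_spk <- n_spk + sum(vapply(r$trials,
      function(tr) sum(tr >= window[1] & tr < window[2]), numeric(1)))
    n_tr <- n_tr + length(r$trials)
  }
  dur_s <- diff(window) / 1000
  if (n_tr == 0) return(0)
  n_spk / (n_tr * dur_s)
}
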