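# Speech-window response measures and the leave-one-out template classifier.

#' Speech-window driven activity and latencies
#'
#' Spontaneous-corrected mean spikes per trial in the consonant (1-40 ms),
#' vowel (default 40-340 ms) and full (0-400 ms) windows, plus onset and
#' peak latency by the same pooled-PSTH rule used for tones.
#'
#' @param responses A [spike_response_set()] for one site x one token.
#' @param label Token label (taken from the response set when omitted).
#' @param consonant_window,vowel_window,full_window Windows in ms.
#' @return One-row data.frame (`speech_response_summary`): `site_id`,
#'   `label`, `consonant_activity`, `vowel_activity`, `full_activity`
#'   (spikes/trial), `onset_latency`, `peak_latency` (ms).
#' @export
speech_window_activity <- function(responses, label = NULL,
                                   consonant_window = c(1, 40),
                                   vowel_window = c(40, 340),
                                   full_window = c(0, 400)) {
  if (is.null(label)) label <- sub("^speech_", "", responses$stimulus_id)
  spont <- spont_rate_estimate(responses)
  drv <- function(w) mean_count_in(responses, w) - spont * diff(w) / 1000
  lat <- estimate_latencies(responses, peak_window = c(0, 75))
  data.frame(site_id = if (is.null(responses$site_id)) NA else responses$site_id,
             label = label,
             consonant_activity = drv(consonant_window),
             vowel_activity = drv(vowel_window),
             full_activity = drv(full_window),
             onset_latency = lat$onset_latency,
             peak_latency = lat$peak_latency)
}

# bin one response set into a trials x bins count matrix; bins are
# left-closed [t, t + bin), matching the package's window conventions
bin_trials <- function(responses, window, bin) {
  edges <- seq(window[1], window[2], by = bin)
  t(vapply(responses$trials, function(tr) {
    tr <- tr[tr >= window[1] & tr < window[2]]
    tabulate(findInterval(tr, edges), nbins = length(edges) - 1)
  }, numeric(length(edges) - 1)))
}

#' Leave-one-out PSTH template classifier for a token pair
#'
#' For each held-out trial, each label's template is the mean binned PSTH
#' over that label's remaining trials (all trials of the other label are
#' used); the held-out trial is assigned to the label whose template lies at
#' the smaller Euclidean distance from the trial's binned spike vector.
#' Distance ties are broken by a seeded coin flip. With 20 trials per label
#' this scores 40 folds, training on 19 of 20 same-label repeats each time.
#'
#' @param responses_a,responses_b [spike_response_set()]s for the two
#'   labels.
#' @param bin Bin width, ms (default 1).
#' @param window Classification window, ms (default `c(0, 40)`, the
#'   consonant onset window).
#' @param seed Seed for tie-breaking coin flips.
#' @param n_required Required trials per label (default 20; fewer is an
#'   error).
#' @return A `classifier_result`: list with `pair`, `percent_correct`,
#'   `confusion` (2x2 matrix, true x assigned), `n_trials_scored`, `bin`,
#'   `window`.
#' @export
loo_template_classifier <- function(responses_a, responses_b, bin = 1,
                                    window = c(0, 40), seed = 1,
                                    n_required = 20) {
  la <- sub("^speech_", "", as.character(responses_a$stimulus_id))
  lb <- sub("^speech_", "", as.character(responses_b$stimulus_id))
  if (responses_a$n_trials != n_required || responses_b$n_trials != n_required)
    stop("exactly ", n_required, " trials per label required (got ",
         responses_a$n_trials, " and ", responses_b$n_trials, ")")
  if (diff(window) <= 0 || diff(window) < bin) stop("empty classification window")
  A <- bin_trials(responses_a, window, bin)
  B <- bin_trials(responses_b, window, bin)
  n <- n_required
  sumA <- colSums(A); sumB <- colSums(B)
  meanA <- sumA / n; meanB <- sumB / n
  correct <- logical(2 * n)
  assigned_a <- logical(2 * n)
  with_seed(seed, {
    for (i in seq_len(n)) {  # held-out trial from label A
      tA <- (sumA - A[i, ]) / (n - 1)
      dA <- sum((A[i, ] - tA)^2); dB <- sum((A[i, ] - meanB)^2)
      pick_a <- if (dA == dB) stats::runif(1) < 0.5 else dA < dB
      correct[i] <- pick_a; assigned_a[i] <- pick_a
    }
    for (i in seq_len(n)) {  # held-out trial from label B
      tB <- (sumB - B[i, ]) / (n - 1)
      dB <- sum((B[i, ] - tB)^2); dA <- sum((B[i, ] - meanA)^2)
      pick_b <- if (dA == dB) stats::runif(1) < 0.5 else dB < dA
      correct[n + i] <- pick_b; assigned_a[n + i] <- !pick_b
    }
  })
  confusion <- matrix(c(sum(assigned_a[1:n]), n - sum(assigned_a[1:n]),
                        sum(assigned_a[(n + 1):(2 * n)]),
                        n - sum(assigned_a[(n + 1):(2 * n)])),
                      nrow = 2, byrow = TRUE,
                      dimnames = list(true = c(la, lb), assigned = c(la, lb)))
  structure(list(site_id = responses_a$site_id, pair = c(la, lb),
                 percent_correct = 100 * mean(correct),
                 confusion = confusion, n_trials_scored = 2L * n,
                 bin = bin, window = window),
            class = "classifier_result")
}

#' Stop-consonant pairwise classification panel
#'
#' Scores the leave-one-out classifier on all unordered pairs of
#' stop-consonant tokens ("dad", "bad", "gad", "tad") for one site and
#' averages percent correct over the 6 pairs.
#'
#' @param responses_by_label Named list of [spike_response_set()]s, names
#'   including the four stop tokens.
#' @param bin,window,seed Passed to [loo_template_classifier()].
#' @return List with `mean_percent_correct`, and `pairs` (data.frame of the
#'   per-pair results).
#' @export
stop_consonant_panel <- function(responses_by_label, bin = 1,
                                 window = c(0, 40), seed = 1) {
  stops <- c("dad", "bad", "gad", "tad")
  missing <- setdiff(stops, names(responses_by_label))
  if (length(missing) > 0)
    stop("missing stop-consonant responses: ", paste(missing, collapse = ", "))
  combs <- utils::combn(stops, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    res <- loo_template_classifier(responses_by_label[[combs[1, k]]],
                                   responses_by_label[[combs[2, k]]],
                                   bin = bin, window = window,
                                   seed = child_seed(seed, k))
    data.frame(label_a = combs[1, k], label_b = combs[2, k],
               percent_correct = res$percent_correct,
               n_folds = res$n_trials_scored)
  })
  pairs <- do.call(rbind, rows)
  list(mean_percent_correct = mean(pairs$percent_correct), pairs = pairs)
}
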