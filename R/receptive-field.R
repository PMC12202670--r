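# Frequency response areas and per-site receptive-field summaries.

# 3x3 median filter with replicate padding at the borders
median_smooth_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2 || nc < 2) return(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- stats::median(pad[i:(i + 2), j:(j + 2)])
    }
  }
  out
}

#' Build a frequency response area from tone-grid responses
#'
#' For each grid cell, the mean driven count per trial equals the spike
#' count in the evoked window minus the spontaneous expectation for an
#' equal-duration window. The spontaneous rate is estimated from the 100 ms
#' pre-stimulus window pooled over every trial of the grid.
#'
#' @param grid_responses A `tone_grid_responses` object from
#'   [simulate_tone_grid()] (or the same layout built from recorded data).
#' @param evoked_window Evoked-count window in ms after tone onset
#'   (default `c(5, 40)`).
#' @return An `fra` object: list with `freqs`, `levels`, `mean_count`
#'   (frequency x level matrix, spikes/trial, spontaneous-corrected),
#'   `spont_rate` (Hz), `n_trials`, `evoked_window`.
#' @export
build_fra <- function(grid_responses, evoked_window = c(5, 40)) {
  freqs <- grid_responses$freqs; levels <- grid_responses$levels
  n_cells <- length(freqs) * length(levels)
  present <- !vapply(grid_responses$responses, is.null, logical(1))
  if (length(grid_responses$responses) != n_cells || !all(present)) {
    miss <- which(!present)
    stop("missing grid cells at indices: ",
         paste(utils::head(miss, 20), collapse = ", "))
  }
  spont <- spont_rate_estimate(grid_responses$responses)
  win_len_s <- diff(evoked_window) / 1000
  counts <- vapply(grid_responses$responses,
                   function(r) mean_count_in(r, evoked_window), numeric(1))
  m <- matrix(counts - spont * win_len_s, nrow = length(freqs),
              ncol = length(levels))
  structure(list(freqs = freqs, levels = levels, mean_count = m,
                 spont_rate = spont, n_trials = grid_responses$n_trials,
                 evoked_window = evoked_window),
            class = "fra")
}

# Significance mask of the (median-smoothed) FRA. A cell is significant when
# its smoothed driven count exceeds `crit_sd` standard errors of the
# spontaneous-equivalent count. Returns the mask, the smoothed matrix and
# the criterion value.
fra_significance <- function(fra, crit_sd = 2, smooth = TRUE) {
  sm <- if (smooth) median_smooth_3x3(fra$mean_count) else fra$mean_count
  win_len_s <- diff(fra$evoked_window) / 1000
  se0 <- sqrt(fra$spont_rate * win_len_s / fra$n_trials)
  crit <- crit_sd * se0
  list(sig = sm > crit & sm > 0, smoothed = sm, crit = crit)
}

#' Estimate characteristic frequency and threshold from an FRA
#'
#' The threshold is the lowest level at which any (smoothed) FRA cell passes
#' the significance criterion; the characteristic frequency is the
#' significant frequency at that level, ties broken toward the centroid of
#' the full significant response region.
#'
#' @param fra An [build_fra()] object.
#' @param crit_sd Significance criterion in spontaneous SE units (default 2).
#' @param smooth Median-smooth the FRA first (default TRUE).
#' @return List with `responsive` (logical); when responsive, `cf` (Hz),
#'   `threshold` (dB SPL) and the significance mask `sig`.
#' @export
estimate_cf_threshold <- function(fra, crit_sd = 2, smooth = TRUE) {
  fs <- fra_significance(fra, crit_sd = crit_sd, smooth = smooth)
  if (!any(fs$sig)) {
    return(list(responsive = FALSE, cf = NA_real_, threshold = NA_real_,
                sig = fs$sig))
  }
  lev_any <- which(apply(fs$sig, 2, any))
  thr_col <- min(lev_any)
  cand <- which(fs$sig[, thr_col])
  w <- pmax(rowSums(fs$smoothed * fs$sig), 0) + 1e-9 * rowSums(fs$sig)
  centroid <- stats::weighted.mean(log2(fra$freqs), w = w)
  cf_i <- cand[which.min(abs(log2(fra$freqs[cand]) - centroid))]
  list(responsive = TRUE, cf = fra$freqs[cf_i],
       threshold = fra$levels[thr_col], sig = fs$sig)
}

#' Estimate tuning bandwidths above threshold
#'
#' At each of threshold + 10, 20, 30, 40 dB the bandwidth is the octave
#' width `log2(f_hi/f_lo)` of the contiguous significant-response span
#' containing the characteristic frequency, with the band edges linearly
#' interpolated in log-frequency at the criterion crossing between grid
#' columns. Bandwidths whose level row exceeds the top of the level grid
#' are returned as `NA`.
#'
#' @param fra An [build_fra()] object.
#' @param cf,threshold From [estimate_cf_threshold()].
#' @param deltas Levels above threshold to measure at (default
#'   `c(10, 20, 30, 40)`).
#' @param crit_sd Significance criterion (default 2).
#' @param smooth Median-smooth the FRA first (default TRUE).
#' @return Named numeric vector (`bw10`, `bw20`, ...) in octaves; `NA` when
#'   undefined.
#' @export
estimate_bandwidths <- function(fra, cf, threshold,
                                deltas = c(10, 20, 30, 40), crit_sd = 2,
                                smooth = TRUE) {
  fs <- fra_significance(fra, crit_sd = crit_sd, smooth = smooth)
  lf <- log2(fra$freqs)
  out <- stats::setNames(rep(NA_real_, length(deltas)),
                         paste0("bw", deltas))
  cf_i <- which.min(abs(lf - log2(cf)))
  for (d in seq_along(deltas)) {
    lev <- threshold + deltas[d]
    if (lev > max(fra$levels)) next  # undefined above the grid
    j <- which.min(abs(fra$levels - lev))
    sig <- fs$sig[, j]; val <- fs$smoothed[, j]
    if (!sig[cf_i]) {
      out[d] <- if (any(sig)) NA_real_ else NA_real_
      next
    }
    lo <- cf_i; while (lo > 1 && sig[lo - 1]) lo <- lo - 1
    hi <- cf_i; while (hi < length(sig) && sig[hi + 1]) hi <- hi + 1
    # interpolate criterion crossings just outside the run
    f_lo <- if (lo == 1) lf[1] else {
      lf[lo - 1] + (lf[lo] - lf[lo - 1]) *
        (fs$crit - val[lo - 1]) / (val[lo] - val[lo - 1])
    }
    f_hi <- if (hi == length(sig)) lf[length(sig)] else {
      lf[hi] + (lf[hi + 1] - lf[hi]) *
        (fs$crit - val[hi]) / (val[hi + 1] - val[hi])
    }
    out[d] <- f_hi - f_lo
  }
  out
}

#' Estimate onset and peak latency from pooled near-CF responses
#'
#' Pools all trials of the supplied responses (conventionally the 60 dB SPL
#' tones within half an octave of the characteristic frequency) into a 1 ms
#' PSTH. The onset latency is the left edge of the first post-onset bin
#' whose count exceeds the spontaneous mean + `crit_sd` spontaneous SDs for
#' at least `n_consec` consecutive bins; the peak latency is the center of
#' the maximum-count bin within `peak_window`.
#'
#' @param responses A [spike_response_set()] or list of them.
#' @param bin PSTH bin width, ms (default 1).
#' @param crit_sd Onset criterion in spontaneous per-bin SD units (default 2).
#' @param n_consec Consecutive suprathreshold bins required (default 2).
#' @param peak_window Search window for the peak, ms (default `c(0, 75)`).
#' @return List with `onset_latency` and `peak_latency` (ms; `NA` when no
#'   bin passes the criterion) and the pooled `psth`.
#' @export
estimate_latencies <- function(responses, bin = 1, crit_sd = 2, n_consec = 2,
                               peak_window = c(0, 75)) {
  if (inherits(responses, "spike_response_set")) responses <- list(responses)
  if (length(responses) < 1) stop("at least one response set required")
  spikes <- unlist(lapply(responses, pool_spikes), use.names = FALSE)
  pre <- psth(spikes, c(-100, 0), bin = bin)
  post <- psth(spikes, peak_window, bin = bin)
  mu0 <- mean(pre$count); sd0 <- stats::sd(pre$count)
  crit <- mu0 + crit_sd * max(sd0, sqrt(mu0), .Machine$double.eps)
  above <- post$count > crit
  onset <- NA_real_
  if (n_consec > 1) {
    runs <- which(vapply(seq_len(length(above) - n_consec + 1),
                         function(i) all(above[i:(i + n_consec - 1)]), logical(1)))
    if (length(runs) > 0) onset <- post$time[min(runs)]
  } else if (any(above)) onset <- post$time[which(above)[1]]
  peak <- if (sum(post$count) == 0) NA_real_ else
    post$time[which.max(post$count)] + bin / 2
  if (!is.na(onset) && !is.na(peak) && peak < onset) peak <- onset
  list(onset_latency = onset, peak_latency = peak, psth = post)
}

#' Per-animal fractions of sites per one-octave CF bin
#'
#' Partitions 1-32 kHz into the five octave bins 1-2, 2-4, 4-8, 8-16 and
#' 16-32 kHz (half-open `[lo, hi)`, the last closed at 32 kHz) and returns
#' for each animal the fraction of its sites whose CF falls in each bin.
#'
#' @param summaries Data.frame with columns `animal_id` and `cf` (Hz).
#' @return Data.frame: `animal_id`, `octave_bin`, `fraction`; fractions sum
#'   to 1 within animal.
#' @export
octave_bin_fractions <- function(summaries) {
  edges <- 1000 * 2^(0:5)
  labs <- c("1-2", "2-4", "4-8", "8-16", "16-32")
  d <- summaries[!is.na(summaries$cf), , drop = FALSE]
  bin <- cut(d$cf, breaks = edges, labels = labs, right = FALSE,
             include.lowest = FALSE)
  bin[d$cf == edges[6]] <- labs[5]  # close the top bin at 32 kHz
  out <- do.call(rbind, lapply(split(bin, d$animal_id), function(b) {
    tab <- table(factor(b, levels = labs))
    data.frame(octave_bin = labs, fraction = as.numeric(tab) / sum(tab))
  }))
  out$animal_id <- rep(names(split(bin, d$animal_id)), each = length(labs))
  rownames(out) <- NULL
  out[, c("animal_id", "octave_bin", "fraction")]
}

#' Rate-level function near the characteristic frequency
#'
#' Mean driven spikes per tone at each level, restricted to tones within
#' half an octave of the CF.
#'
#' @param grid_responses A `tone_grid_responses` object.
#' @param cf Characteristic frequency, Hz.
#' @param evoked_window Evoked window, ms (default `c(5, 40)`).
#' @param half_octave Frequency half-width in octaves (default 0.5).
#' @return Data.frame with `level` and `driven` (spikes/trial,
#'   spontaneous-corrected).
#' @export
rate_level_function <- function(grid_responses, cf, evoked_window = c(5, 40),
                                half_octave = 0.5) {
  freqs <- grid_responses$freqs; levels <- grid_responses$levels
  near <- which(abs(log2(freqs / cf)) <= half_octave)
  if (length(near) == 0) stop("no grid frequencies within half an octave of cf")
  spont <- spont_rate_estimate(grid_responses$responses)
  win_len_s <- diff(evoked_window) / 1000
  driven <- vapply(seq_along(levels), function(j) {
    idx <- (j - 1) * length(freqs) + near
    mean(vapply(grid_responses$responses[idx],
                function(r) mean_count_in(r, evoked_window), numeric(1))) -
      spont * win_len_s
  }, numeric(1))
  data.frame(level = levels, driven = driven)
}

#' Full receptive-field summary for one site
#'
#' Runs the FRA, CF/threshold, bandwidth, latency and rate-level estimators
#' on one site's tone-grid responses.
#'
#' @param grid_responses A `tone_grid_responses` object.
#' @param evoked_window Evoked window, ms.
#' @param latency_level Level (dB SPL) at which latencies are measured
#'   (default 60).
#' @param crit_sd FRA significance criterion (default 2).
#' @return One-row data.frame (`receptive_field_summary`): `site_id`,
#'   `responsive`, `cf`, `threshold`, `bw10`..`bw40`, `onset_latency`,
#'   `peak_latency`, `spont_rate`, `driven_spikes_near_cf`; the rate-level
#'   table is attached as `attr(, "rate_level")`.
#' @export
site_receptive_field <- function(grid_responses, evoked_window = c(5, 40),
                                 latency_level = 60, crit_sd = 2) {
  fra <- build_fra(grid_responses, evoked_window = evoked_window)
  ct <- estimate_cf_threshold(fra, crit_sd = crit_sd)
  site_id <- grid_responses$site$site_id
  if (is.null(site_id)) site_id <- NA
  if (!ct$responsive) {
    out <- data.frame(site_id = site_id, responsive = FALSE, cf = NA,
                      threshold = NA, bw10 = NA, bw20 = NA, bw30 = NA,
                      bw40 = NA, onset_latency = NA, peak_latency = NA,
                      spont_rate = fra$spont_rate,
                      driven_spikes_near_cf = NA)
    return(structure(out, class = c("receptive_field_summary", "data.frame")))
  }
  bw <- estimate_bandwidths(fra, ct$cf, ct$threshold, crit_sd = crit_sd)
  near <- which(abs(log2(fra$freqs / ct$cf)) <= 0.5)
  lev_j <- which.min(abs(fra$levels - latency_level))
  idx <- (lev_j - 1) * length(fra$freqs) + near
  lat <- estimate_latencies(grid_responses$responses[idx])
  rl <- rate_level_function(grid_responses, ct$cf,
                            evoked_window = evoked_window)
  out <- data.frame(site_id = site_id, responsive = TRUE, cf = ct$cf,
                    threshold = ct$threshold,
                    bw10 = bw[["bw10"]], bw20 = bw[["bw20"]],
                    bw30 = bw[["bw30"]], bw40 = bw[["bw40"]],
                    onset_latency = lat$onset_latency,
                    peak_latency = lat$peak_latency,
                    spont_rate = fra$spont_rate,
                    driven_spikes_near_cf = mean(fra$mean_count[near, ]))
  structure(out, rate_level = rl,
            class = c("receptive_field_summary", "data.frame"))
}
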