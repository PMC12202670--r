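# Synthetic nested-cohort multi-unit spike response simulation.
#
# Responses are inhomogeneous Poisson processes built by superposing a
# homogeneous spontaneous process with evoked alpha-function bumps. Because
# the normalized alpha kernel (t/tau) * exp(1 - t/tau) is a Gamma(shape = 2,
# scale = tau) density, each bump is sampled exactly by drawing a Poisson
# count and Gamma-distributed spike times; no thinning loop is needed and
# the superposition is still an exact inhomogeneous Poisson draw.

#' Group-level effect configuration for the simulator
#'
#' Encodes the effect structure a cohort group imposes on simulated
#' responses. The shipped presets (see [preset_group_configs()]) are
#' qualitative fixtures, not estimates from data.
#'
#' @param group Group label (e.g. "SAL", "VPA", "VPA+VNS").
#' @param gain Multiplier on evoked response amplitude (> 0).
#' @param latency_shift Added onset latency, ms.
#' @param adaptation Per-burst geometric decay factor in (0, 1]; burst k has
#'   relative amplitude `adaptation^(k-1)`. The paired-pulse ratio of the
#'   generating process equals this value.
#' @param odd_burst_suppression Extra multiplier on bursts 3 and 5 (the
#'   "odd" steady-state bursts), in (0, 1].
#' @param phase_jitter SD of Gaussian spike-time jitter applied to evoked
#'   spikes in train/speech responses, ms.
#' @param spont_rate Spontaneous rate, Hz.
#' @param animal_sd,site_sd SDs of the between-animal and between-site
#'   normal random effects on log evoked gain.
#' @return An object of class `group_effect_config`.
#' @export
group_effect_config <- function(group, gain = 1, latency_shift = 0,
                                adaptation = 1, odd_burst_suppression = 1,
                                phase_jitter = 0, spont_rate = 5,
                                animal_sd = 0.15, site_sd = 0.4) {
  stopifnot(gain > 0, adaptation > 0, adaptation <= 1,
            odd_burst_suppression > 0, odd_burst_suppression <= 1,
            phase_jitter >= 0, spont_rate >= 0, animal_sd >= 0, site_sd >= 0)
  structure(list(group = group, gain = gain, latency_shift = latency_shift,
                 adaptation = adaptation,
                 odd_burst_suppression = odd_burst_suppression,
                 phase_jitter = phase_jitter, spont_rate = spont_rate,
                 animal_sd = animal_sd, site_sd = site_sd),
            class = "group_effect_config")
}

#' Preset group configurations
#'
#' Three fixtures encoding the qualitative direction of the study's group
#' effects: controls ("SAL-like"); prenatal-VPA-like degradation (lower
#' evoked gain, +2.5 ms onset latency, suppression of odd steady-state
#' bursts, weaker within-train adaptation hence higher paired-pulse ratio,
#' larger phase jitter); and VNS-pairing-like partial restoration.
#' Magnitudes are fixtures chosen to reproduce effect directions, not
#' estimates.
#'
#' @return Named list of three [group_effect_config()] objects
#'   (`SAL`, `VPA`, `VPA+VNS`).
#' @export
preset_group_configs <- function() {
  list(
    "SAL" = group_effect_config("SAL", gain = 1.0, latency_shift = 0,
                                adaptation = 0.50, odd_burst_suppression = 1,
                                phase_jitter = 4, spont_rate = 5),
    "VPA" = group_effect_config("VPA", gain = 0.4, latency_shift = 2.5,
                                adaptation = 0.85, odd_burst_suppression = 0.6,
                                phase_jitter = 12, spont_rate = 5),
    "VPA+VNS" = group_effect_config("VPA+VNS", gain = 0.7, latency_shift = 0.5,
                                    adaptation = 0.55, odd_burst_suppression = 1,
                                    phase_jitter = 6, spont_rate = 5)
  )
}

#' Realize a nested cohort of recording sites
#'
#' Draws per-site receptive-field parameters and nested lognormal gain
#' random effects: site log-gain = log(group gain) + N(0, animal_sd) shared
#' within animal + N(0, site_sd) per site. Characteristic frequencies are
#' log-uniform on 1-32 kHz.
#'
#' @param configs Named list of [group_effect_config()] (one per group), or a
#'   single config.
#' @param n_animals Animals per group (scalar or vector matching `configs`).
#' @param sites_per_animal Sites recorded per animal (default 30).
#' @param seed Integer seed.
#' @param base_latency_mean,base_latency_sd Baseline onset latency
#'   distribution across sites, ms (before the group latency shift).
#' @return A `cohort` data.frame, one row per site, with realized per-site
#'   simulation parameters (columns `site_id`, `animal_id`, `group`, `cf`,
#'   `threshold`, `tuning_width`, `latency`, `gain`, `adaptation`,
#'   `odd_burst_suppression`, `phase_jitter`, `spont_rate`), and the configs
#'   stored in `attr(, "configs")`.
#' @export
realize_cohort <- function(configs, n_animals = 10, sites_per_animal = 30,
                           seed = 1, base_latency_mean = 14.4,
                           base_latency_sd = 1.2) {
  if (inherits(configs, "group_effect_config")) {
    configs <- stats::setNames(list(configs), configs$group)
  }
  stopifnot(length(configs) >= 1, all(n_animals >= 1), sites_per_animal >= 1)
  if (length(n_animals) == 1) n_animals <- rep(n_animals, length(configs))
  rows <- list()
  with_seed(seed, {
    for (gi in seq_along(configs)) {
      cfg <- configs[[gi]]
      for (a in seq_len(n_animals[gi])) {
        animal_id <- sprintf("%s_a%02d", cfg$group, a)
        re_animal <- stats::rnorm(1, 0, cfg$animal_sd)
        ns <- sites_per_animal
        re_site <- stats::rnorm(ns, 0, cfg$site_sd)
        lat <- stats::rnorm(ns, base_latency_mean, base_latency_sd)
        lat <- pmin(pmax(lat, 10), 20)
        rows[[length(rows) + 1]] <- data.frame(
          site_id = sprintf("%s_s%02d", animal_id, seq_len(ns)),
          animal_id = animal_id,
          group = cfg$group,
          cf = 2^stats::runif(ns, log2(1000), log2(32000)),
          threshold = 5 * round(stats::runif(ns, 5, 35) / 5),
          tuning_width = stats::runif(ns, 0.3, 0.6),
          latency = lat + cfg$latency_shift,
          log_gain = log(cfg$gain) + re_animal + re_site,
          gain = exp(log(cfg$gain) + re_animal + re_site),
          adaptation = cfg$adaptation,
          odd_burst_suppression = cfg$odd_burst_suppression,
          phase_jitter = cfg$phase_jitter,
          spont_rate = cfg$spont_rate,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, configs = configs, seed = seed,
            class = c("cohort", "data.frame"))
}

#' Trial-tagged spike response container
#'
#' @param trials List of sorted numeric spike-time vectors (ms relative to
#'   stimulus onset).
#' @param site_id,stimulus_id Identifiers.
#' @param window Recording window in ms (default `c(-100, 750)`).
#' @return An object of class `spike_response_set`.
#' @export
spike_response_set <- function(trials, site_id = NA, stimulus_id = NA,
                               window = c(-100, 750)) {
  trials <- lapply(trials, function(tr) sort(tr[tr >= window[1] & tr <= window[2]]))
  structure(list(site_id = site_id, stimulus_id = stimulus_id,
                 trials = trials, n_trials = length(trials), window = window),
            class = "spike_response_set")
}

# Draw one response set: homogeneous spontaneous process over `window` plus
# evoked bumps. `bumps` is a data.frame with columns `onset` (ms), `mu`
# (expected spikes/trial), `tau` (ms), `jitter` (ms SD).
sim_response <- function(n_trials, spont_rate, bumps, window = c(-100, 750),
                         site_id = NA, stimulus_id = NA) {
  dur_s <- diff(window) / 1000
  n_spont <- stats::rpois(n_trials, spont_rate * dur_s)
  trials <- lapply(n_spont, function(k) stats::runif(k, window[1], window[2]))
  if (!is.null(bumps) && nrow(bumps) > 0) {
    for (b in seq_len(nrow(bumps))) {
      mu <- bumps$mu[b]
      if (mu <= 0) next
      n_ev <- stats::rpois(n_trials, mu)
      tot <- sum(n_ev)
      if (tot == 0) next
      tms <- bumps$onset[b] + stats::rgamma(tot, shape = 2, scale = bumps$tau[b])
      if (bumps$jitter[b] > 0) tms <- tms + stats::rnorm(tot, 0, bumps$jitter[b])
      idx <- rep(seq_len(n_trials), n_ev)
      sp <- split(tms, factor(idx, levels = seq_len(n_trials)))
      trials <- Map(c, trials, sp)
    }
  }
  spike_response_set(trials, site_id = site_id, stimulus_id = stimulus_id,
                     window = window)
}

# Frequency tuning (Gaussian in log2 frequency) and level drive (hinge at
# threshold, saturating). Drive is exactly 0 below threshold.
tuning_factor <- function(freq, cf, width_oct) {
  exp(-(log2(freq / cf))^2 / (2 * width_oct^2))
}

level_factor <- function(level, threshold) {
  ifelse(level < threshold, 0, tanh((level - threshold + 5) / 15))
}

#' Simulate the response of one site to a tone pip
#'
#' Evoked spikes form an alpha-function bump (Gamma(2, tau) spike-time
#' density) with onset at the site's latency; the expected evoked count
#' scales with the site gain, a Gaussian tuning profile in log-frequency
#' around the characteristic frequency, and a saturating level function
#' that is zero below the site threshold.
#'
#' @param site One-row slice of a [realize_cohort()] data.frame (or a list
#'   with the same fields).
#' @param tone A [tone_stimulus()] or a list with `frequency` and `level`.
#' @param seed Integer seed.
#' @param n_trials Trials to draw (default 20).
#' @param base_evoked Expected evoked spikes/trial at CF, full drive,
#'   gain 1 (default 2.5).
#' @param tau Alpha-kernel time constant, ms (default 5).
#' @param window Recording window, ms.
#' @return A [spike_response_set()].
#' @export
simulate_tone_response <- function(site, tone, seed = 1, n_trials = 20,
                                   base_evoked = 2.5, tau = 5,
                                   window = c(-100, 750)) {
  mu <- base_evoked * site$gain *
    tuning_factor(tone$frequency, site$cf, site$tuning_width) *
    level_factor(tone$level, site$threshold)
  with_seed(seed, sim_response(
    n_trials, site$spont_rate,
    data.frame(onset = site$latency, mu = mu, tau = tau, jitter = 0),
    window = window, site_id = site$site_id,
    stimulus_id = sprintf("tone_%.0fHz_%gdB", tone$frequency, tone$level)))
}

#' Simulate responses to the full tone-pip grid
#'
#' @param site One cohort row.
#' @param grid A [make_tone_grid()] object.
#' @param seed Integer seed (one child seed per grid cell).
#' @param ... Passed to [simulate_tone_response()].
#' @return A `tone_grid_responses` object: list with `freqs`, `levels`,
#'   `responses` (list of [spike_response_set()], frequency varying
#'   fastest), and `site`.
#' @export
simulate_tone_grid <- function(site, grid, seed = 1, ...) {
  freqs <- attr(grid, "freqs"); levels <- attr(grid, "levels")
  responses <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    responses[[i]] <- simulate_tone_response(
      site, list(frequency = grid$frequency[i], level = grid$level[i]),
      seed = child_seed(seed, i), ...)
  }
  structure(list(freqs = freqs, levels = levels, responses = responses,
                 site = site, n_trials = responses[[1]]$n_trials),
            class = "tone_grid_responses")
}

#' Simulate the response of one site to a noise-burst train
#'
#' One evoked bump per burst; burst k has expected count
#' `gain * base_evoked * adaptation^(k-1)`, additionally multiplied by
#' `odd_burst_suppression` on bursts 3 and 5. Evoked spike times are
#' jittered with the site's `phase_jitter` SD.
#'
#' @param site One cohort row.
#' @param train A [make_noise_train()] object.
#' @param seed Integer seed.
#' @param n_trials Trials (default 20).
#' @param base_evoked Expected evoked spikes/trial for the first burst at
#'   gain 1 (default 2.5).
#' @param tau Alpha-kernel time constant, ms.
#' @param window Recording window, ms.
#' @return A [spike_response_set()].
#' @export
simulate_train_response <- function(site, train, seed = 1, n_trials = 20,
                                    base_evoked = 2.5, tau = 5,
                                    window = c(-100, 750)) {
  k <- seq_len(train$n_bursts)
  amp <- site$gain * base_evoked * site$adaptation^(k - 1)
  amp[k %in% c(3, 5)] <- amp[k %in% c(3, 5)] * site$odd_burst_suppression
  bumps <- data.frame(onset = train$burst_onsets + site$latency, mu = amp,
                      tau = tau, jitter = site$phase_jitter)
  with_seed(seed, sim_response(
    n_trials, site$spont_rate, bumps, window = window,
    site_id = site$site_id,
    stimulus_id = sprintf("train_%gHz", train$repetition_rate)))
}

# Label-conditional response micro-pattern for the speech simulator.
# Each label maps to a consonant-onset bump pair (timing offset, amplitude
# split between a sharp release component and a slower transition
# component, overall amplitude factor). `separability` scales the
# label-to-label differences around the across-label mean; 0 collapses all
# labels onto one pattern.

#' Label-conditional consonant response pattern
#'
#' @param label One of [speech_labels()].
#' @param separability Non-negative scale on between-label pattern
#'   differences; 0 makes all labels identical.
#' @return Data.frame of bump parameters (`offset` ms, `amp_frac`,
#'   `tau` ms) for the consonant window.
#' @export
speech_response_pattern <- function(label, separability = 1) {
  base <- data.frame(
    label = c("dad", "bad", "gad", "tad", "sad", "rad", "lad"),
    delta = c(0, 3.5, 7, 11, 5, 8, 12),
    frac1 = c(0.70, 0.55, 0.60, 0.75, 0.35, 0.30, 0.30),
    ampf  = c(1.00, 0.90, 0.95, 1.05, 0.70, 0.50, 0.55)
  )
  i <- match(label, base$label)
  if (is.na(i)) stop("unknown label '", label, "'")
  s <- separability
  delta <- mean(base$delta) + s * (base$delta[i] - mean(base$delta))
  # keep the signature inside the consonant analysis window at any
  # separability (site latencies sit near 10-20 ms post onset)
  delta <- min(max(delta, -9), 20)
  frac1 <- mean(base$frac1) + s * (base$frac1[i] - mean(base$frac1))
  ampf <- mean(base$ampf) + s * (base$ampf[i] - mean(base$ampf))
  frac1 <- min(max(frac1, 0.05), 0.95)
  ampf <- max(ampf, 0.05)
  data.frame(offset = c(delta, delta + 6),
             amp_frac = c(frac1, 1 - frac1) * ampf,
             tau = c(2.5, 3.5))
}

#' Simulate the response of one site to a speech token
#'
#' A label-specific consonant-onset micro-pattern (two evoked bumps inside
#' the 1-40 ms consonant window, see [speech_response_pattern()]) plus a
#' sustained vowel response extending to 400 ms. Site gain and latency
#' effects apply to the whole response; `onset_gain` / `vowel_gain` scale
#' the two components independently.
#'
#' @param site One cohort row.
#' @param speech A `speech_stimulus` (or a list with `label`).
#' @param seed Integer seed.
#' @param n_trials Trials (default 20).
#' @param separability Between-label pattern separation (default 1).
#' @param base_consonant Expected consonant-window evoked spikes/trial at
#'   gain 1 (default 3).
#' @param base_vowel Expected vowel-segment evoked spikes/trial at gain 1
#'   (default 2).
#' @param onset_gain,vowel_gain Extra multipliers on the consonant and vowel
#'   components (default 1).
#' @param window Recording window, ms.
#' @return A [spike_response_set()].
#' @export
simulate_speech_response <- function(site, speech, seed = 1, n_trials = 20,
                                     separability = 1, base_consonant = 3,
                                     base_vowel = 2, onset_gain = 1,
                                     vowel_gain = 1, window = c(-100, 750)) {
  pat <- speech_response_pattern(speech$label, separability)
  mu_c <- base_consonant * site$gain * onset_gain
  bumps <- data.frame(onset = site$latency + pat$offset,
                      mu = mu_c * pat$amp_frac,
                      tau = pat$tau, jitter = site$phase_jitter / 4)
  mu_v <- base_vowel * site$gain * vowel_gain
  with_seed(seed, {
    r <- sim_response(n_trials, site$spont_rate, bumps, window = window,
                      site_id = site$site_id,
                      stimulus_id = paste0("speech_", speech$label))
    # sustained vowel component: uniform evoked spikes over 50-400 ms
    n_v <- stats::rpois(n_trials, mu_v)
    r$trials <- Map(function(tr, k) sort(c(tr, stats::runif(k, 50, 400))),
                    r$trials, n_v)
    r
  })
}

#' Export spike responses as a flat table
#'
#' @param responses A [spike_response_set()] or list of them.
#' @param cohort Optional cohort data.frame to join `animal_id`/`group` on
#'   `site_id`.
#' @return Data.frame with columns `site_id`, `animal_id`, `group`,
#'   `stimulus_id`, `trial`, `spike_time_ms` (one row per spike).
#' @export
spikes_to_table <- function(responses, cohort = NULL) {
  if (inherits(responses, "spike_response_set")) responses <- list(responses)
  out <- lapply(responses, function(r) {
    ns <- lengths(r$trials)
    data.frame(site_id = r$site_id, stimulus_id = r$stimulus_id,
               trial = rep(seq_along(r$trials), ns),
               spike_time_ms = unlist(r$trials, use.names = FALSE))
  })
  out <- do.call(rbind, out)
  if (!is.null(cohort)) {
    out <- merge(out, cohort[, c("site_id", "animal_id", "group")],
                 by = "site_id", sort = FALSE)
    out <- out[, c("site_id", "animal_id", "group", "stimulus_id",
                   "trial", "spike_time_ms")]
  }
  out
}

#' Rebuild spike response sets from a flat table
#'
#' Inverse of [spikes_to_table()] for round-tripping through CSV.
#'
#' @param tab Data.frame with `site_id`, `stimulus_id`, `trial`,
#'   `spike_time_ms`.
#' @param n_trials Trial count per response set (default 20); trials with no
#'   spikes are restored as empty.
#' @param window Recording window, ms.
#' @return List of [spike_response_set()], one per (site, stimulus).
#' @export
table_to_spikes <- function(tab, n_trials = 20, window = c(-100, 750)) {
  key <- interaction(tab$site_id, tab$stimulus_id, drop = TRUE)
  lapply(split(tab, key), function(d) {
    trials <- unname(split(d$spike_time_ms,
                           factor(d$trial, levels = seq_len(n_trials))))
    spike_response_set(trials, site_id = d$site_id[1],
                       stimulus_id = d$stimulus_id[1], window = window)
  })
}
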