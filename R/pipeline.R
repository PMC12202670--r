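# End-to-end convenience wrapper: simulate a cohort's responses and extract
# every per-site metric family.

#' Simulate and analyze a full cohort
#'
#' For every site in the cohort, simulates tone-grid, noise-train and
#' stop-consonant speech responses and extracts receptive-field, temporal
#' and speech metrics. Problem sizes (grid density, rates, labels) are
#' configurable so analyses can be scaled to the time available.
#'
#' @param cohort A [realize_cohort()] data.frame.
#' @param seed Integer seed.
#' @param grid Tone grid (default a 21 x 16 grid over 1-32 kHz / 0-75 dB).
#' @param rates Noise-train repetition rates (default all four).
#' @param labels Speech tokens to run (default the four stop-consonant
#'   tokens).
#' @param run_classifier Score the stop-consonant classifier panel
#'   (default TRUE when all four stop tokens are present).
#' @param ... Passed to the simulators (e.g. `base_evoked`).
#' @return List of data.frames: `rf` (receptive-field summaries + rate-level
#'   attribute columns `driven_60dB`), `temporal` (site x rate), `speech`
#'   (site x label), `classifier` (per site), each carrying `animal_id` and
#'   `group`.
#' @export
analyze_cohort <- function(cohort, seed = 1,
                           grid = make_tone_grid(n_freqs = 21),
                           rates = c(7.5, 10, 12.5, 15),
                           labels = c("dad", "bad", "gad", "tad"),
                           run_classifier = TRUE, ...) {
  trains <- lapply(rates, make_noise_train)
  speeches <- lapply(labels, function(l) list(label = l))
  rf_rows <- list(); temp_rows <- list(); sp_rows <- list(); cl_rows <- list()
  for (si in seq_len(nrow(cohort))) {
    site <- cohort[si, ]
    s0 <- child_seed(seed, si)
    gr <- simulate_tone_grid(site, grid, seed = child_seed(s0, 1))
    rf <- site_receptive_field(gr)
    rl <- attr(rf, "rate_level")
    rf$driven_60dB <- if (!is.null(rl)) rl$driven[rl$level == 60] else NA
    rf$animal_id <- site$animal_id; rf$group <- site$group
    rf_rows[[si]] <- as.data.frame(rf)

    tr <- lapply(seq_along(trains), function(k) {
      resp <- simulate_train_response(site, trains[[k]],
                                      seed = child_seed(s0, 100 + k))
      temporal_summary(resp, trains[[k]])
    })
    tr <- do.call(rbind, tr)
    tr$animal_id <- site$animal_id; tr$group <- site$group
    temp_rows[[si]] <- tr

    resp_by_label <- stats::setNames(lapply(seq_along(speeches), function(k) {
      simulate_speech_response(site, speeches[[k]],
                               seed = child_seed(s0, 200 + k), ...)
    }), labels)
    sw <- do.call(rbind, lapply(labels, function(l)
      speech_window_activity(resp_by_label[[l]], label = l)))
    sw$animal_id <- site$animal_id; sw$group <- site$group
    sp_rows[[si]] <- sw

    if (run_classifier && all(c("dad", "bad", "gad", "tad") %in% labels)) {
      pan <- stop_consonant_panel(resp_by_label, seed = child_seed(s0, 300))
      cl_rows[[si]] <- data.frame(site_id = site$site_id,
                                  animal_id = site$animal_id,
                                  group = site$group,
                                  mean_percent_correct = pan$mean_percent_correct)
    }
  }
  list(rf = do.call(rbind, rf_rows),
       temporal = do.call(rbind, temp_rows),
       speech = do.call(rbind, sp_rows),
       classifier = if (length(cl_rows) > 0) do.call(rbind, cl_rows) else NULL)
}
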