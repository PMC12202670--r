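# helper: grid responses built directly from count specifications
grid_from_counts <- function(freqs, levels, count_fun, n_trials = 20) {
  responses <- list()
  i <- 0
  for (l in levels) for (f in freqs) {
    i <- i + 1
    k <- count_fun(f, l)
    trials <- lapply(seq_len(n_trials),
                     function(t) if (k > 0) seq(10, 30, length.out = k) else numeric(0))
    responses[[i]] <- spike_response_set(trials, site_id = "s",
                                         stimulus_id = paste0(f, "_", l))
  }
  # column-major over (freq fastest) like simulate_tone_grid
  structure(list(freqs = freqs, levels = levels, responses = responses,
                 site = list(site_id = "s"), n_trials = n_trials),
            class = "tone_grid_responses")
}

test_that("zero-spike and spontaneous-only datasets give null FRAs", {
  freqs <- 2^seq(log2(1000), log2(32000), length.out = 9)
  levels <- seq(0, 75, by = 15)
  gz <- grid_from_counts(freqs, levels, function(f, l) 0)
  fra <- build_fra(gz)
  expect_true(all(fra$mean_count == 0))
  expect_equal(fra$spont_rate, 0)
  expect_false(estimate_cf_threshold(fra)$responsive)
  # spontaneous-only simulation: mean driven count ~ 0. The SE of the
  # grand mean combines per-cell count noise (reduced by averaging cells)
  # with the shared spontaneous-rate estimation error (which is not).
  site <- fixture_site(gain = 1e-9, spont_rate = 10)
  grid <- make_tone_grid(n_freqs = 9, level_step = 15)
  n_rep <- 6
  grand <- vapply(seq_len(n_rep), function(k) {
    mean(build_fra(simulate_tone_grid(site, grid, seed = 20 + k))$mean_count)
  }, numeric(1))
  n_cells <- 9 * 6; n_tr_tot <- n_cells * 20
  se_cells <- sqrt(10 * 0.035 / 20) / sqrt(n_cells)
  se_spont <- 0.035 * sqrt(10 / (0.1 * n_tr_tot))
  se_grand <- sqrt(se_cells^2 + se_spont^2) / sqrt(n_rep)
  expect_lt(abs(mean(grand)), 2.5 * se_grand)
})

test_that("missing grid cells are reported", {
  freqs <- c(1000, 4000, 16000); levels <- c(0, 30, 60)
  g <- grid_from_counts(freqs, levels, function(f, l) 1)
  g$responses[[5]] <- NULL
  expect_error(build_fra(g), "missing grid cells")
})

test_that("a single responsive cell pins CF and threshold", {
  freqs <- 2^seq(log2(1000), log2(32000), length.out = 21)
  levels <- seq(0, 75, by = 5)
  # single nonzero cell at (4 kHz, 35 dB); smoothing requires the cell to
  # dominate its 3x3 neighborhood, so give it a strong count without smooth
  g <- grid_from_counts(freqs, levels, function(f, l)
    if (abs(log2(f / 4000)) < 0.01 && l == 35) 5 else 0)
  fra <- build_fra(g)
  ct <- estimate_cf_threshold(fra, smooth = FALSE)
  expect_true(ct$responsive)
  expect_equal(ct$cf, 4000, tolerance = 1e-6)
  expect_equal(ct$threshold, 35)
  # a lone cell disappears under 3x3 median smoothing (isolated-noise guard)
  expect_false(estimate_cf_threshold(fra, smooth = TRUE)$responsive)
  # bandwidth at a row with response in exactly one column is 0 octaves
  bw <- estimate_bandwidths(fra, 4000, 25, deltas = 10, crit_sd = 2,
                            smooth = FALSE)
  expect_lt(abs(bw[["bw10"]]), 0.51)  # within one grid step of zero width
})

test_that("CF and threshold recover the injected site parameters", {
  grid <- make_tone_grid(n_freqs = 21)  # 0.25-octave spacing
  n_sites <- 80
  set.seed(101)
  cf_inj <- 2^runif(n_sites, log2(2000), log2(16000))
  thr_inj <- sample(seq(10, 35, by = 5), n_sites, replace = TRUE)
  ok <- 0
  for (i in seq_len(n_sites)) {
    site <- fixture_site(cf = cf_inj[i], threshold = thr_inj[i])
    gr <- simulate_tone_grid(site, grid, seed = 4000 + i)
    ct <- estimate_cf_threshold(build_fra(gr))
    if (ct$responsive &&
        abs(log2(ct$cf / cf_inj[i])) <= 0.25 + 1e-9 &&
        abs(ct$threshold - thr_inj[i]) <= 5) ok <- ok + 1
  }
  expect_gte(ok / n_sites, 0.9)
})

test_that("null calibration: almost no spontaneous-only site is responsive", {
  grid <- make_tone_grid(n_freqs = 15, level_step = 15)
  responsive <- vapply(1:60, function(i) {
    site <- fixture_site(gain = 1e-9, spont_rate = 5)
    gr <- simulate_tone_grid(site, grid, seed = 7000 + i)
    estimate_cf_threshold(build_fra(gr))$responsive
  }, logical(1))
  expect_lte(mean(responsive), 0.05)
})

test_that("bandwidths track the analytic Gaussian tuning width", {
  # with tuning SD sigma octaves and peak drive amp, the band edges at
  # criterion crit sit at +/- sigma * sqrt(2 log(amp / crit))
  site <- fixture_site(cf = 8000, threshold = 10, tuning_width = 0.5)
  grid <- make_tone_grid(n_freqs = 41)
  bws <- matrix(NA_real_, 30, 4)
  for (i in 1:30) {
    gr <- simulate_tone_grid(site, grid, seed = 8000 + i)
    fra <- build_fra(gr)
    ct <- estimate_cf_threshold(fra)
    if (!ct$responsive) next
    bws[i, ] <- estimate_bandwidths(fra, ct$cf, ct$threshold)
  }
  mbw <- colMeans(bws, na.rm = TRUE)
  se0 <- sqrt(5 * 0.035 / 20)
  for (j in 1:4) {
    lev <- 10 + 10 * j
    amp <- 2.5 * tanh((lev - 10 + 5) / 15)
    analytic <- 2 * 0.5 * sqrt(2 * log(amp / (2 * se0)))
    expect_equal(mbw[j], analytic, tolerance = 0.2)
  }
  # bandwidth is flagged undefined when threshold + delta exceeds the grid
  g2 <- grid_from_counts(attr(grid, "freqs"), seq(0, 75, 5),
                         function(f, l) if (l >= 40) 3 else 0)
  fra2 <- build_fra(g2)
  bw2 <- estimate_bandwidths(fra2, 8000, 40)
  expect_true(is.na(bw2[["bw40"]]))  # 40 + 40 > 75
  expect_false(is.na(bw2[["bw10"]]))
})

test_that("latency estimation: deterministic PSTH and ordering invariant", {
  # deterministic single-bump PSTH peaking at 20 ms
  r <- fixture_deterministic(c(19.2, 19.7, 20.3), n_trials = 30)
  lat <- estimate_latencies(r)
  expect_equal(lat$peak_latency, 19.5)  # centre of the 19-20 ms bin
  expect_lte(lat$onset_latency, lat$peak_latency)
  # onset <= peak over simulated sites
  site <- fixture_site()
  for (k in 1:20) {
    resp <- simulate_tone_response(site, tone_stimulus(8000, 60),
                                   seed = 6000 + k)
    l <- estimate_latencies(resp)
    if (!is.na(l$onset_latency)) expect_lte(l$onset_latency, l$peak_latency)
  }
  # no spikes: latencies undefined
  l0 <- estimate_latencies(fixture_deterministic(numeric(0)))
  expect_true(is.na(l0$onset_latency))
})

test_that("onset latency recovers the injected value near 14.4 ms", {
  lats <- vapply(1:150, function(k) {
    site <- fixture_site(latency = 14.4)
    resp <- lapply(1:5, function(j)
      simulate_tone_response(site, tone_stimulus(8000 * 2^((j - 3) / 4), 60),
                             seed = 9000 + 10 * k + j))
    estimate_latencies(resp)$onset_latency
  }, numeric(1))
  expect_equal(mean(lats, na.rm = TRUE), 14.4, tolerance = 1 / 14.4)
})

test_that("octave bins partition 1-32 kHz with half-open boundaries", {
  d <- data.frame(animal_id = rep(c("a1", "a2"), c(4, 3)),
                  cf = c(1000, 3000, 3500, 31000, 4000, 16000, 32000))
  ob <- octave_bin_fractions(d)
  expect_equal(sort(unique(ob$octave_bin)),
               sort(c("1-2", "2-4", "4-8", "8-16", "16-32")))
  a1 <- ob[ob$animal_id == "a1", ]
  expect_equal(a1$fraction[a1$octave_bin == "2-4"], 0.5)
  expect_equal(sum(a1$fraction), 1)
  # CF exactly 4 kHz goes in the 4-8 bin; 32 kHz closes the top bin
  a2 <- ob[ob$animal_id == "a2", ]
  expect_equal(a2$fraction[a2$octave_bin == "4-8"], 1 / 3)
  expect_equal(a2$fraction[a2$octave_bin == "16-32"], 2 / 3)
  # all CFs at 3 kHz
  ob2 <- octave_bin_fractions(data.frame(animal_id = "x", cf = rep(3000, 5)))
  expect_equal(ob2$fraction, c(0, 1, 0, 0, 0))
})

test_that("rate-level functions are monotone and scale with gain", {
  grid <- make_tone_grid(n_freqs = 5, freq_range = c(4000, 16000))
  rl_mean <- function(gain, n_sites = 25) {
    acc <- 0
    for (i in seq_len(n_sites)) {
      site <- fixture_site(gain = gain, cf = 8000, threshold = 20)
      gr <- simulate_tone_grid(site, grid, seed = 500 * gain + i)
      acc <- acc + rate_level_function(gr, 8000)$driven
    }
    acc / n_sites
  }
  r1 <- rl_mean(1); r05 <- rl_mean(0.5)
  sup <- seq(0, 75, 5) >= 40
  expect_equal(mean(r05[sup] / r1[sup]), 0.5, tolerance = 0.1)
  # monotone nondecreasing within noise: strong rank correlation with level
  expect_gt(stats::cor(seq(0, 75, 5)[seq(0, 75, 5) >= 20], r1[seq(0, 75, 5) >= 20],
                       method = "spearman"), 0.9)
  # subthreshold levels: driven ~ 0
  expect_lt(max(abs(r1[seq(0, 75, 5) < 20])), 0.1)
})

test_that("site summary bookkeeping: analyzed + flagged == input", {
  grid <- make_tone_grid(n_freqs = 9, level_step = 15)
  n <- 12
  summaries <- lapply(1:n, function(i) {
    gain <- if (i <= 4) 1e-9 else 1  # first third non-responsive
    gr <- simulate_tone_grid(fixture_site(gain = gain,
                                          site_id = paste0("s", i)),
                             grid, seed = 300 + i)
    site_receptive_field(gr)
  })
  responsive <- vapply(summaries, function(s) s$responsive, logical(1))
  expect_equal(sum(responsive) + sum(!responsive), n)
  expect_true(all(!is.na(vapply(summaries[responsive],
                                function(s) s$cf, numeric(1)))))
})
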