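# Go/no-go session scoring, success-paired stimulation bookkeeping, and
# repeated measures ANOVA over training weeks.

#' Score a go/no-go behavioral session
#'
#' Replays a time-ordered stream of trials and nose-pokes. A hit is a poke
#' within `hit_window` seconds of a target onset; a correct rejection is a
#' catch (silence or non-target) trial with no poke in its window. A poke
#' on a catch trial, or a poke later than `hit_window` after any sound,
#' triggers a `timeout`-second timeout during which pokes are ignored.
#' Percent correct is `(hits + correct rejections) / total trials * 100`.
#'
#' @param trials Data.frame with `time` (s, sound onset) and `stimulus`
#'   (one of "target", "nontarget", "silence"), time-ordered.
#' @param pokes Numeric vector of poke times (s).
#' @param hit_window Response window, s (3 or 4 per training stage).
#' @param timeout Timeout duration, s (default 6).
#' @return A `behavior_session`: list with `outcomes` (per-trial data.frame),
#'   counts (`hits`, `misses`, `false_alarms`, `correct_rejections`),
#'   `percent_correct`, `n_trials`, `hit_window`.
#' @export
score_go_nogo <- function(trials, pokes, hit_window = 3, timeout = 6) {
  stopifnot(hit_window %in% c(3, 4))
  if (is.unsorted(trials$time, strictly = TRUE))
    stop("trial times must be strictly increasing")
  if (any(diff(trials$time) < hit_window))
    stop("overlapping trials: onsets closer than the hit window")
  pokes <- sort(pokes)
  n <- nrow(trials)
  outcome <- rep(NA_character_, n)
  timeout_until <- -Inf
  timeouts <- 0L
  for (p in pokes) {
    if (p < timeout_until) next  # poke during timeout: no feedback
    i <- findInterval(p, trials$time)
    if (i == 0) next  # poke before the first trial
    t0 <- trials$time[i]
    in_window <- p <= t0 + hit_window
    if (in_window) {
      if (trials$stimulus[i] == "target") {
        if (is.na(outcome[i])) outcome[i] <- "hit"
      } else {
        if (is.na(outcome[i])) outcome[i] <- "false_alarm"
        timeout_until <- p + timeout
        timeouts <- timeouts + 1L
      }
    } else {
      # late poke (> hit_window after the most recent sound): timeout
      timeout_until <- p + timeout
      timeouts <- timeouts + 1L
    }
  }
  unscored <- is.na(outcome)
  outcome[unscored & trials$stimulus == "target"] <- "miss"
  outcome[unscored & trials$stimulus != "target"] <- "correct_rejection"
  hits <- sum(outcome == "hit")
  cr <- sum(outcome == "correct_rejection")
  out <- data.frame(trials, outcome = outcome)
  structure(list(outcomes = out, hits = hits,
                 misses = sum(outcome == "miss"),
                 false_alarms = sum(outcome == "false_alarm"),
                 correct_rejections = cr,
                 n_timeouts = timeouts,
                 percent_correct = 100 * (hits + cr) / n,
                 n_trials = n, hit_window = hit_window),
            class = "behavior_session")
}

#' Detection-training proficiency criterion
#'
#' An animal is proficient once it has four consecutive sessions at or
#' above the criterion percent correct.
#'
#' @param percent_correct Numeric vector of session scores, in order.
#' @param criterion Percent correct criterion (default 75).
#' @param n_sessions Consecutive sessions required (default 4).
#' @return List with `proficient` (logical) and `session_reached` (index of
#'   the last of the qualifying sessions, NA when never reached).
#' @export
proficiency_criterion <- function(percent_correct, criterion = 75,
                                  n_sessions = 4) {
  ok <- percent_correct >= criterion
  if (length(ok) >= n_sessions) {
    for (i in n_sessions:length(ok)) {
      if (all(ok[(i - n_sessions + 1):i]))
        return(list(proficient = TRUE, session_reached = i))
    }
  }
  list(proficient = FALSE, session_reached = NA_integer_)
}

#' Success-paired VNS stimulation log
#'
#' During success-paired training, one stimulation is delivered with each
#' rewarded target hit; the per-session stimulation count is the session's
#' hit count.
#'
#' @param sessions List of `behavior_session` objects (or a numeric vector
#'   of hit counts).
#' @return Data.frame with `session` and `n_stimulations`.
#' @export
success_paired_vns_log <- function(sessions) {
  hits <- if (is.numeric(sessions)) sessions
          else vapply(sessions, function(s) s$hits, numeric(1))
  data.frame(session = seq_along(hits), n_stimulations = hits)
}

#' Two-way repeated measures ANOVA on weekly performance
#'
#' Group x training-week ANOVA with animals as subjects (week as the
#' repeated factor), uncorrected degrees of freedom, and
#' Bonferroni-adjusted pairwise group post hocs within each week.
#'
#' @param data Data.frame with `animal_id`, `group`, `week`,
#'   `percent_correct`; weeks must be balanced within animal.
#' @return List with `anova_table` (term, F, df1, df2, p), `posthoc`
#'   (Bonferroni-adjusted pairwise group comparisons per week), and
#'   `degenerate` (TRUE when the response has no variance, in which case F
#'   values are NA rather than an error).
#' @export
rm_anova <- function(data) {
  data$animal_id <- factor(data$animal_id)
  data$group <- factor(data$group)
  data$week <- factor(data$week)
  tab <- table(data$animal_id, data$week)
  if (any(tab != 1)) stop("weeks must be balanced: one score per animal per week")
  if (stats::var(data$percent_correct) < .Machine$double.eps) {
    return(list(anova_table = data.frame(
      term = c("group", "week", "group:week"),
      F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_),
      posthoc = NULL, degenerate = TRUE))
  }
  fit <- stats::aov(percent_correct ~ group * week + Error(animal_id / week),
                    data = data)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: animal_id"]][[1]])
  within <- as.data.frame(sm[["Error: animal_id:week"]][[1]])
  grab <- function(df, term) {
    i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(df)))
    resid <- grep("Residuals", rownames(df))
    data.frame(term = term, F = df[i, "F value"], df1 = df[i, "Df"],
               df2 = df[resid, "Df"], p = df[i, "Pr(>F)"])
  }
  anova_table <- rbind(grab(between, "group"),
                       grab(within, "week"),
                       grab(within, "group:week"))
  rownames(anova_table) <- NULL
  posthoc <- do.call(rbind, lapply(split(data, data$week), function(d) {
    if (length(unique(d$group)) < 2) return(NULL)
    pt <- stats::pairwise.t.test(d$percent_correct, d$group,
                                 p.adjust.method = "bonferroni")
    m <- pt$p.value
    idx <- which(!is.na(m), arr.ind = TRUE)
    data.frame(week = d$week[1],
               contrast = paste(rownames(m)[idx[, 1]], "-",
                                colnames(m)[idx[, 2]]),
               p_bonferroni = m[idx])
  }))
  rownames(posthoc) <- NULL
  list(anova_table = anova_table, posthoc = posthoc, degenerate = FALSE)
}

#' Simulate weekly go/no-go learning curves
#'
#' A logistic learning curve from near-chance to asymptotic performance,
#' identical across groups by default (matching the study's behavioral
#' outcome of learning without group differences), with animal-level random
#' intercepts and session noise.
#'
#' @param n_per_group Named vector of animals per group.
#' @param weeks Number of training weeks (default 4).
#' @param seed Integer seed.
#' @param start,asymptote Percent correct at week 1 and at asymptote.
#' @param animal_sd,noise_sd Between-animal and residual SDs (percent).
#' @param group_effect Additive per-group offsets (default 0 for all).
#' @return Data.frame with `animal_id`, `group`, `week`, `percent_correct`.
#' @export
simulate_learning_curves <- function(n_per_group = c(SAL = 10, VPA = 10,
                                                     "VPA+VNS" = 8),
                                     weeks = 4, seed = 1, start = 55,
                                     asymptote = 90, animal_sd = 3,
                                     noise_sd = 2.5, group_effect = NULL) {
  if (is.null(group_effect))
    group_effect <- stats::setNames(rep(0, length(n_per_group)),
                                    names(n_per_group))
  with_seed(seed, {
    rows <- list()
    for (g in names(n_per_group)) {
      for (a in seq_len(n_per_group[[g]])) {
        aid <- sprintf("%s_b%02d", g, a)
        ai <- stats::rnorm(1, 0, animal_sd)
        w <- seq_len(weeks)
        curve <- start + (asymptote - start) * (1 - exp(-(w - 1) / 1.1))
        pc <- curve + group_effect[[g]] + ai + stats::rnorm(weeks, 0, noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = aid, group = g, week = w,
          percent_correct = pmin(pmax(pc, 0), 100))
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a go/no-go session from a simple poking agent
#'
#' Generates a trial stream (targets interleaved with catch trials) and an
#' agent that pokes with probability `p_hit` within the window after a
#' target and at a background Poisson rate otherwise. Used to exercise the
#' session scorer end-to-end.
#'
#' @param n_targets,n_catch Trial counts.
#' @param p_hit Probability the agent pokes within the window of a target.
#' @param background_rate Background poke rate, Hz.
#' @param iti Intertrial interval, s (default 10).
#' @param hit_window Response window, s.
#' @param seed Integer seed.
#' @return List with `trials`, `pokes`, and the scored `session`.
#' @export
simulate_gonogo_session <- function(n_targets = 180, n_catch = 60,
                                    p_hit = 0.5, background_rate = 0.01,
                                    iti = 10, hit_window = 3, seed = 1) {
  with_seed(seed, {
    kinds <- sample(c(rep("target", n_targets), rep("silence", n_catch)))
    times <- seq_along(kinds) * iti
    trials <- data.frame(time = times, stimulus = kinds)
    dur <- max(times) + iti
    n_bg <- stats::rpois(1, background_rate * dur)
    pokes <- stats::runif(n_bg, 0, dur)
    hit_idx <- which(kinds == "target")[stats::runif(n_targets) < p_hit]
    pokes <- sort(c(pokes, times[hit_idx] + stats::runif(length(hit_idx), 0.2,
                                                         hit_window - 0.2)))
    list(trials = trials, pokes = pokes,
         session = score_go_nogo(trials, pokes, hit_window = hit_window))
  })
}
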