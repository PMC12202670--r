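# nested test data: y = group effect + animal effect + site noise, with
# `reps` observations per site
sim_nested <- function(delta = c(0, 0, 0), n_animals = 10, n_sites = 30,
                       reps = 1, animal_sd = 0.25, site_sd = 0.3,
                       resid_sd = 1, groups = c("SAL", "VPA", "VNS")) {
  rows <- list()
  for (g in seq_along(groups)) {
    for (a in seq_len(n_animals)) {
      aid <- paste0(groups[g], "_a", a)
      ae <- rnorm(1, 0, animal_sd)
      for (s in seq_len(n_sites)) {
        se <- rnorm(1, 0, site_sd)
        rows[[length(rows) + 1]] <- data.frame(
          group = groups[g], animal_id = aid, site_id = paste0(aid, "_s", s),
          rep = seq_len(reps),
          y = delta[g] + ae + se + rnorm(reps, 0, resid_sd))
      }
    }
  }
  do.call(rbind, rows)
}

test_that("normality test choice follows the kurtosis rule", {
  set.seed(31)
  heavy <- rt(500, df = 3)           # leptokurtic
  light <- runif(500)                # platykurtic
  expect_equal(choose_normality_test(heavy)$test, "shapiro-francia")
  expect_equal(choose_normality_test(light)$test, "shapiro-wilk")
  expect_gte(pearson_kurtosis(heavy), 3)
  expect_lt(pearson_kurtosis(light), 3)
  expect_error(choose_normality_test(rnorm(5)), "at least 8")
})

test_that("normality screen is calibrated under the null and powered", {
  set.seed(77)
  p_null <- replicate(400, choose_normality_test(rnorm(500))$p.value)
  expect_equal(mean(p_null < 0.05), 0.05, tolerance = 0.5)  # ~5% rejections
  p_lnorm <- replicate(100, choose_normality_test(rlnorm(500))$p.value)
  expect_gt(mean(p_lnorm < 0.05), 0.95)
})

test_that("the Gaussian LMM path matches an independent mixed-model fitter", {
  set.seed(55)
  for (k in 1:12) {
    d <- sim_nested(delta = rnorm(3, 0, 0.3), n_animals = 4, n_sites = 6,
                    reps = 3)
    f <- fit_nested_model(d, "y", family = "gaussian")
    # independent route: nlme with the same nesting, REML
    m2 <- nlme::lme(y ~ group, random = ~ 1 | animal_id / site_id, data = d)
    expect_equal(unname(lme4::fixef(f$model)), unname(nlme::fixef(m2)),
                 tolerance = 1e-4)
    # Wald chi-square for group from each fit's coefficient covariance
    w1 <- f$wald_table$chisq[f$wald_table$term == "group"]
    b2 <- nlme::fixef(m2)[2:3]; V2 <- as.matrix(m2$varFix)[2:3, 2:3]
    w2 <- drop(t(b2) %*% solve(V2) %*% b2)
    expect_equal(w1, w2, tolerance = 1e-3)
  }
})

test_that("identical groups give unit contrast p-values and equal EMMs", {
  set.seed(9)
  base <- sim_nested(n_animals = 4, n_sites = 8)
  base$y <- rep(rnorm(4 * 8), 3) + 5  # literally identical data per group
  f <- fit_nested_model(base, "y", family = "gaussian")
  expect_true(all(f$contrasts$p.value > 0.999))
  expect_lt(diff(range(f$emm_table$emmean)), 1e-8)
})

test_that("nesting guards: fewer than two animals per group is an error", {
  d <- sim_nested(n_animals = 1, n_sites = 5)
  expect_error(fit_nested_model(d, "y", family = "gaussian"), "2 animals")
  d2 <- sim_nested(n_animals = 3, n_sites = 5)
  expect_error(fit_nested_model(d2[0, ], "y"), "groups")
})

test_that("an injected group shift of one animal-level SD is detected", {
  set.seed(2024)
  # graded exposure/restoration pattern: adjacent groups differ by one SD
  # of the animal-level means (the variance scale the group test works on)
  sd_animal_mean <- sqrt(0.25^2 + (0.3^2 + 1) / 30)
  hits <- replicate(40, {
    d <- sim_nested(delta = c(0, -sd_animal_mean, -2 * sd_animal_mean),
                    animal_sd = 0.25, site_sd = 0.3)
    f <- fit_nested_model(d, "y", family = "gaussian")
    f$wald_table$p[f$wald_table$term == "group"] < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("log-link families back-transform EMMs onto the response scale", {
  set.seed(8)
  d <- sim_nested(delta = c(0, -0.4, -0.1), animal_sd = 0.1)
  d$y <- exp(d$y)  # lognormal positive response
  f <- fit_nested_model(d, "y", family = "gaussian-log")
  expect_true(all(f$emm_table$lower > 0))
  expect_true(all(f$emm_table$lower <= f$emm_table$emmean &
                  f$emm_table$emmean <= f$emm_table$upper))
  expect_equal(nrow(f$contrasts), choose(3, 2))
  # back-transformed group means track the lognormal medians
  med <- tapply(d$y, d$group, function(x) exp(mean(log(x))))
  expect_equal(as.numeric(f$emm_table$emmean[order(f$emm_table$group)]),
               as.numeric(med[order(names(med))]), tolerance = 0.15)
  # tweedie-approx runs on zero-inflated data and labels itself
  d$y2 <- pmax(d$y - 1, 0)
  f2 <- fit_nested_model(d, "y2", family = "tweedie-approx")
  expect_true(any(grepl("tweedie-approx", f2$notes)))
  expect_true(all(f2$emm_table$upper >= f2$emm_table$emmean))
})

test_that("emm back-transforms are exact inverse links", {
  # identity: unchanged
  bt <- emm_backtransform(3.2, 0.5, "identity")
  expect_equal(bt$mean, 3.2); expect_equal(bt$upper, 3.2 + 1.96 * 0.5)
  # log link at eta = log(14.4) with vanishing SE: mean 14.4, degenerate CI
  bt2 <- emm_backtransform(log(14.4), 1e-12, "log")
  expect_equal(bt2$mean, 14.4, tolerance = 1e-9)
  expect_equal(bt2$upper - bt2$lower, 0, tolerance = 1e-8)
  # log CIs always positive
  bt3 <- emm_backtransform(-4, 2, "log")
  expect_gt(bt3$lower, 0)
  # round trips: inverse then forward is identity to 1e-10
  for (lk in c("log", "sqrt", "logit", "probit")) {
    fwd <- switch(lk, log = log, sqrt = sqrt, logit = stats::qlogis,
                  probit = stats::qnorm)
    eta <- 0.37
    expect_equal(fwd(emm_backtransform(eta, 0, lk)$mean), eta,
                 tolerance = 1e-10)
  }
  expect_error(emm_backtransform(1, 1, "cloglog"), "unsupported")
})

test_that("Tukey adjustment keeps family-wise error near nominal", {
  set.seed(12)
  fw <- replicate(200, {
    d <- sim_nested(n_animals = 4, n_sites = 4, animal_sd = 0.01)
    f <- fit_nested_model(d, "y", family = "gaussian")
    any(f$contrasts$p.value < 0.05)
  })
  expect_lte(mean(fw), 0.1)
})

test_that("go/no-go scoring: perfect, oracle replay, and conservation", {
  # all targets poked in-window, no catch pokes: 100%
  trials <- data.frame(time = seq(10, 100, by = 10),
                       stimulus = rep(c("target", "silence"), 5))
  pokes <- trials$time[trials$stimulus == "target"] + 1
  s <- score_go_nogo(trials, pokes, hit_window = 3)
  expect_equal(s$percent_correct, 100)
  expect_equal(s$hits + s$misses + s$false_alarms + s$correct_rejections,
               s$n_trials)
  # random-poking agent scored identically by an event-by-event replay
  sim <- simulate_gonogo_session(n_targets = 30, n_catch = 20, p_hit = 0.6,
                                 background_rate = 0.05, seed = 41)
  replay <- local({
    tr <- sim$trials; pk <- sim$pokes
    out <- rep(NA_character_, nrow(tr)); t_end <- -Inf; n_to <- 0
    for (p in pk) {
      if (p < t_end) next
      i <- findInterval(p, tr$time)
      if (i == 0) next
      if (p <= tr$time[i] + 3) {
        if (tr$stimulus[i] == "target") {
          if (is.na(out[i])) out[i] <- "hit"
        } else {
          if (is.na(out[i])) out[i] <- "false_alarm"
          t_end <- p + 6; n_to <- n_to + 1
        }
      } else { t_end <- p + 6; n_to <- n_to + 1 }
    }
    out[is.na(out) & tr$stimulus == "target"] <- "miss"
    out[is.na(out) & tr$stimulus != "target"] <- "correct_rejection"
    list(pc = 100 * mean(out %in% c("hit", "correct_rejection")), out = out)
  })
  expect_equal(sim$session$percent_correct, replay$pc)
  expect_equal(sim$session$outcomes$outcome, replay$out)
  expect_equal(with(sim$session, hits + misses + false_alarms +
                      correct_rejections), sim$session$n_trials)
  # malformed sessions are rejected
  expect_error(score_go_nogo(data.frame(time = c(10, 11),
                                        stimulus = c("target", "silence")),
                             numeric(0)), "overlap")
  expect_error(score_go_nogo(trials, pokes, hit_window = 5), "hit_window")
})

test_that("proficiency requires four consecutive criterion sessions", {
  expect_true(proficiency_criterion(c(60, 70, 76, 80, 79, 90))$proficient)
  expect_equal(proficiency_criterion(c(60, 70, 76, 80, 79, 90))$session_reached, 6)
  expect_false(proficiency_criterion(c(80, 80, 74, 80, 80, 80))$proficient)
  expect_false(proficiency_criterion(c(80, 80, 80))$proficient)
})

test_that("success-paired stimulation counts equal rewarded hits", {
  trials <- data.frame(time = seq(10, 1000, by = 10),
                       stimulus = rep(c("target", "silence"), 50))
  pokes <- trials$time[trials$stimulus == "target"] + 0.5
  perfect <- score_go_nogo(trials, pokes, hit_window = 3)
  log1 <- success_paired_vns_log(list(perfect))
  expect_equal(log1$n_stimulations, 50)
  expect_equal(success_paired_vns_log(numeric(1) * 0)$n_stimulations, 0)
  # a ~50% performer on ~180 target trials lands near the reported regime
  sim <- simulate_gonogo_session(n_targets = 180, n_catch = 60, p_hit = 0.5,
                                 seed = 10)
  expect_equal(success_paired_vns_log(list(sim$session))$n_stimulations,
               90, tolerance = 0.3)
})

test_that("repeated measures ANOVA finds learning but no group effect", {
  d <- simulate_learning_curves(seed = 42)
  res <- rm_anova(d)
  tab <- res$anova_table
  expect_equal(tab$term, c("group", "week", "group:week"))
  expect_lt(tab$p[tab$term == "week"], 1e-6)
  expect_gt(tab$p[tab$term == "group"], 0.05)
  expect_equal(tab$df1[tab$term == "week"], 3)
  expect_equal(tab$df2[tab$term == "week"], 75)  # (28 animals - 1 - 2) * 3
  expect_true(all(res$posthoc$p_bonferroni >= 0 &
                  res$posthoc$p_bonferroni <= 1))
  # degenerate constant data: flagged, not an error
  dc <- d; dc$percent_correct <- 50
  expect_true(rm_anova(dc)$degenerate)
  # unbalanced weeks are rejected
  expect_error(rm_anova(d[-1, ]), "balanced")
})

test_that("RM-ANOVA type-I error is near nominal under the null", {
  set.seed(314)
  p <- replicate(200, {
    d <- simulate_learning_curves(
      n_per_group = c(A = 6, B = 6, C = 6), seed = sample.int(1e8, 1),
      start = 70, asymptote = 70)  # flat: no week or group effect
    rm_anova(d)$anova_table$p
  })
  rej <- rowMeans(p < 0.05)
  expect_equal(rej[1], 0.05, tolerance = 0.9)  # group
  expect_equal(rej[2], 0.05, tolerance = 0.9)  # week
  expect_equal(rej[3], 0.05, tolerance = 0.9)  # interaction
})
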