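# Nested group-comparison statistics: normality screening, nested mixed
# models with Type II Wald chi-square tests, and Tukey-adjusted estimated
# marginal means.

#' Pearson kurtosis
#'
#' Fourth standardized moment (normal distribution = 3).
#'
#' @param x Numeric sample.
#' @return Kurtosis.
#' @export
pearson_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2
}

#' Kurtosis-dependent normality test
#'
#' Tests the sample with the Shapiro-Francia test when it is leptokurtic
#' (Pearson kurtosis >= 3) and with the Shapiro-Wilk test otherwise.
#'
#' @param x Numeric sample, n >= 8 (and <= 5000, the tests' supported
#'   range).
#' @return List with `test` ("shapiro-francia" or "shapiro-wilk"),
#'   `kurtosis`, `statistic`, `p.value`.
#' @export
choose_normality_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8) stop("need at least 8 observations")
  if (length(x) > 5000) stop("normality tests support at most 5000 observations")
  k <- pearson_kurtosis(x)
  if (k >= 3) {
    ht <- nortest::sf.test(x)
    test <- "shapiro-francia"
  } else {
    ht <- stats::shapiro.test(x)
    test <- "shapiro-wilk"
  }
  list(test = test, kurtosis = k, statistic = unname(ht$statistic),
       p.value = ht$p.value)
}

#' Specify a nested group-comparison model
#'
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect terms (default "group").
#' @param family One of "gaussian", "gaussian-log", "tweedie",
#'   "tweedie-approx", "beta", "binomial". "gaussian-log" fits a Gaussian
#'   LMM on `log(y)`; "tweedie-approx" fits a Gaussian LMM on `log(y + c)`
#'   (a documented approximation to the Tweedie log-link GLMM, which is
#'   also available exactly as "tweedie" via glmmTMB).
#' @param offset_c Offset for "tweedie-approx"; default (`NULL`) uses half
#'   the minimum positive response value.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, fixed = "group",
                       family = c("gaussian", "gaussian-log", "tweedie",
                                  "tweedie-approx", "beta", "binomial"),
                       offset_c = NULL) {
  family <- match.arg(family)
  structure(list(response = response, fixed = fixed, family = family,
                 offset_c = offset_c, random = "(1 | animal_id/site_id)"),
            class = "model_spec")
}

# choose the random-effect structure: sites nested in animals when sites
# are replicated, animal-only intercepts otherwise (an unreplicated site
# term is confounded with the residual)
random_term <- function(data) {
  replicated <- any(duplicated(data$site_id))
  if (replicated) "(1 | animal_id/site_id)" else "(1 | animal_id)"
}

#' Fit a nested mixed model and summarize group effects
#'
#' Fits the response against the fixed effects with nested random
#' intercepts (site within animal; the site term is dropped automatically
#' when sites are unreplicated). Gaussian families use REML via
#' \pkg{lme4}; Tweedie, beta and binomial families use \pkg{glmmTMB}. Each
#' fixed term gets a Type II Wald chi-square test (\pkg{car}); group
#' estimated marginal means are back-transformed to the response scale with
#' Tukey-adjusted pairwise contrasts (\pkg{emmeans}).
#'
#' @param data Data.frame with columns `animal_id`, `site_id`, the response
#'   and the fixed-effect variables (`group` etc.).
#' @param spec A [model_spec()] (or a response name, with the remaining
#'   arguments taken from `...`).
#' @param ... Passed to [model_spec()] when `spec` is a name.
#' @return A `fit_result`: list with `model`, `family`, `formula`,
#'   `wald_table` (term, chisq, df, p), `emm_table` (group, emmean, lower,
#'   upper, SE on the response scale), `contrasts` (Tukey-adjusted),
#'   `converged`, `notes`.
#' @export
fit_nested_model <- function(data, spec, ...) {
  if (is.character(spec)) spec <- model_spec(spec, ...)
  if (length(unique(data$group)) < 2) stop("need >= 2 groups")
  n_an <- tapply(data$animal_id, data$group, function(a) length(unique(a)))
  if (any(n_an < 2))
    stop("singular nesting: every group needs >= 2 animals")
  data$group <- factor(data$group)
  data$animal_id <- factor(data$animal_id)
  data$site_id <- factor(data$site_id)
  rnd <- random_term(data)
  notes <- character(0)
  if (rnd == "(1 | animal_id)")
    notes <- c(notes, "site random intercept dropped (sites unreplicated)")

  y <- data[[spec$response]]
  fam <- spec$family
  offset_c <- spec$offset_c
  lhs <- spec$response
  if (fam == "gaussian-log") {
    if (any(y <= 0)) stop("gaussian-log requires strictly positive response")
    data$.y <- log(y); lhs <- ".y"
  } else if (fam == "tweedie-approx") {
    if (is.null(offset_c)) {
      pos <- y[y > 0]
      offset_c <- if (length(pos) > 0) min(pos) / 2 else 1e-3
    }
    if (any(y + offset_c <= 0))
      stop("tweedie-approx requires y + c > 0")
    data$.y <- log(y + offset_c); lhs <- ".y"
    notes <- c(notes, sprintf(
      "tweedie-approx: Gaussian LMM on log(y + %.6g), not an exact Tweedie GLMM",
      offset_c))
  }
  fml <- stats::as.formula(paste(lhs, "~", paste(spec$fixed, collapse = " + "),
                                 "+", rnd))
  converged <- TRUE
  if (fam %in% c("gaussian", "gaussian-log", "tweedie-approx")) {
    mod <- lme4::lmer(fml, data = data, REML = TRUE)
    conv <- mod@optinfo$conv$lme4
    if (!is.null(conv$messages)) {
      converged <- FALSE
      notes <- c(notes, paste("lme4:", conv$messages))
    }
  } else {
    tmb_family <- switch(fam,
      tweedie = glmmTMB::tweedie(link = "log"),
      beta = glmmTMB::beta_family(link = "logit"),
      binomial = stats::binomial())
    mod <- glmmTMB::glmmTMB(fml, data = data, family = tmb_family)
    converged <- isTRUE(mod$sdr$pdHess) && mod$fit$convergence == 0
    if (!converged) notes <- c(notes, "glmmTMB did not converge cleanly")
  }
  wald <- as.data.frame(car::Anova(mod, type = "II"))
  wald_table <- data.frame(term = rownames(wald),
                           chisq = wald[["Chisq"]],
                           df = wald[["Df"]],
                           p = wald[["Pr(>Chisq)"]])
  link <- switch(fam, gaussian = "identity",
                 `gaussian-log` = "log", `tweedie-approx` = "log-offset",
                 tweedie = "log", beta = "logit", binomial = "logit")
  emm <- emmeans::emmeans(mod, stats::as.formula("~ group"))
  es <- as.data.frame(emm)
  eta <- es$emmean; se <- es$SE
  bt <- emm_backtransform(eta, se, link, offset_c = offset_c)
  emm_table <- data.frame(group = es$group, emmean = bt$mean,
                          lower = bt$lower, upper = bt$upper,
                          SE = se, link_estimate = eta)
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  structure(list(model = mod, family = fam, formula = fml, link = link,
                 wald_table = wald_table, emm_table = emm_table,
                 contrasts = ctr, converged = converged, notes = notes),
            class = "fit_result")
}

#' Back-transform a linear-predictor mean and SE to the response scale
#'
#' `mean = inverse-link(eta)`; `CI = inverse-link(eta +/- 1.96 * SE)`.
#' Monotone links preserve the CI ordering.
#'
#' @param eta Linear-predictor estimate(s).
#' @param se Standard error(s) on the link scale.
#' @param link One of "identity", "log", "log-offset" (log(y + c)), "sqrt",
#'   "logit", "probit".
#' @param offset_c Offset c for "log-offset".
#' @param z CI multiplier (default 1.96).
#' @return List with `mean`, `lower`, `upper`.
#' @export
emm_backtransform <- function(eta, se, link = "identity", offset_c = NULL,
                              z = 1.96) {
  inv <- switch(link,
    identity = function(x) x,
    log = exp,
    `log-offset` = function(x) exp(x) - (if (is.null(offset_c)) 0 else offset_c),
    sqrt = function(x) x^2,
    logit = stats::plogis,
    probit = stats::pnorm,
    stop("unsupported link '", link, "'"))
  list(mean = inv(eta), lower = inv(eta - z * se), upper = inv(eta + z * se))
}

#' Model-fit comparison report
#'
#' AIC/BIC (and log-likelihood) for a set of fitted models, as a report to
#' inform model choice rather than an automatic selector.
#'
#' @param ... Named `fit_result` objects or fitted models.
#' @return Data.frame with `model`, `AIC`, `BIC`, `logLik`.
#' @export
model_fit_report <- function(...) {
  fits <- list(...)
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    m <- fits[[i]]
    if (inherits(m, "fit_result")) m <- m$model
    data.frame(model = nm[i], AIC = stats::AIC(m), BIC = stats::BIC(m),
               logLik = as.numeric(stats::logLik(m)))
  })
  do.call(rbind, rows)
}
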