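# Longitudinal mixed-effects models for the learning experiment. Days are
# coded on a natural-log scale (day 1 = 0) to capture the saturating
# learning curve; tDCS effects that accumulate over training appear as a
# group x log(day) interaction. Animals enter as a random intercept;
# missing days are handled by likelihood. t and F statistics use
# Satterthwaite denominator degrees of freedom. No multiple-comparison
# correction is applied; treat the p-values accordingly.

fit_lmm <- function(formula, data, response_label) {
  msgs <- character()
  fit <- withCallingHandlers(
    suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  singular <- lme4::isSingular(fit, tol = 1e-5)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- length(conv_msgs) == 0 &&
    !any(grepl("converge", msgs, ignore.case = TRUE))
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(term = rownames(sm),
                          estimate = unname(sm[, "Estimate"]),
                          std_error = unname(sm[, "Std. Error"]),
                          df = unname(sm[, "df"]),
                          statistic = unname(sm[, "t value"]),
                          p_value = unname(sm[, "Pr(>|t|)"]))
  an <- tryCatch(stats::anova(fit), error = function(e) NULL)
  anova_tbl <- if (!is.null(an) && nrow(an) > 0) {
    tibble::tibble(term = rownames(an),
                   f_statistic = an[, "F value"],
                   df_num = an[, "NumDF"], df_den = an[, "DenDF"],
                   p_value = an[, "Pr(>F)"])
  } else {
    tibble::tibble(term = character(), f_statistic = numeric(),
                   df_num = numeric(), df_den = numeric(),
                   p_value = numeric())
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = fit, coefficients = coefs, anova = anova_tbl,
                 formula = formula, response = response_label,
                 n_obs = stats::nobs(fit),
                 n_animals = lme4::ngrps(fit)[["animal_id"]],
                 random_sd = vc$sdcor[vc$grp == "animal_id" &
                                        is.na(vc$var2)][1],
                 sigma = stats::sigma(fit),
                 converged = converged, singular = singular,
                 messages = c(msgs, conv_msgs)),
            class = "reach_fit")
}

check_learning_table <- function(table) {
  assert_columns(table, c("animal_id", "day", "group", "successes"),
                 "learning table")
  if (any(table$day < 1)) abort("`day` must be >= 1 (log-day coding).")
  per_group <- table |>
    dplyr::distinct(.data$animal_id, .data$group) |>
    dplyr::count(.data$group)
  if (nrow(per_group) < 2 || any(per_group$n < 2)) {
    abort("need at least 2 animals in each of 2 groups.")
  }
  if (length(unique(table$day)) < 2) abort("need at least 2 days.")
  table$group <- factor(table$group, levels = c("control", "anodal"))
  table$log_day <- log(table$day)
  table
}

#' Fit the success learning-curve model
#'
#' `successes ~ log(day) * group + (1 | animal)`: fixed effects for the
#' learning slope on log-day, the tDCS group offset and their interaction
#' (the accumulating benefit of stimulation), with a per-animal random
#' intercept. Unbalanced or missing days are handled by likelihood.
#' Non-convergence is flagged on the returned object, never silently
#' worked around.
#'
#' @param table a learning tibble: `animal_id`, `day` (1-based), `group`
#'   (control/anodal), `successes` (and `attempts` for the rate model).
#' @param random_slope add a random log-day slope per animal
#'   (`(1 + log(day) | animal)`); default is the random intercept only.
#' @return A `reach_fit` object; see [tidy.reach_fit()] /
#'   [glance.reach_fit()].
#' @export
fit_success_model <- function(table, random_slope = FALSE) {
  data <- check_learning_table(table)
  re <- if (random_slope) "(1 + log_day | animal_id)" else "(1 | animal_id)"
  f <- stats::as.formula(paste("successes ~ log_day * group +", re))
  fit_lmm(f, data, "successes")
}

#' @rdname fit_success_model
#' @details `fit_rate_model()` uses the success rate
#'   (`successes / attempts`) as response, mirroring the same fixed and
#'   random structure; sessions with zero attempts are dropped with a
#'   message. The ratio is modelled as Gaussian, matching the analysis
#'   this pipeline reproduces, not as a binomial response.
#' @export
fit_rate_model <- function(table, random_slope = FALSE) {
  assert_columns(table, "attempts", "learning table")
  data <- check_learning_table(table)
  n0 <- sum(data$attempts == 0)
  if (n0 > 0) {
    inform(sprintf("dropping %d session(s) with zero attempts.", n0))
    data <- data[data$attempts > 0, ]
  }
  data$rate <- data$successes / data$attempts
  re <- if (random_slope) "(1 + log_day | animal_id)" else "(1 | animal_id)"
  f <- stats::as.formula(paste("rate ~ log_day * group +", re))
  fit_lmm(f, data, "success rate")
}

#' Fit the stereotypy model
#'
#' Per-trial stereotypy scores against log-day, tDCS group and their
#' interaction, with a per-animal random intercept. Because left- and
#' right-pawed animals behave differently around the reach, the analysis
#' is typically run on the right-pawed subset (`paw = "right"`), and can
#' be stratified by trial outcome.
#'
#' @param records stereotypy records (e.g. [score_trials()] output joined
#'   with animal metadata): columns `animal_id`, `day`, `group`, `score`,
#'   plus `paw` and `success` when subsetting.
#' @param paw `"all"`, `"right"` or `"left"` subset.
#' @param outcome `"all"`, `"success"` (successful trials only) or
#'   `"failure"`.
#' @inheritParams fit_success_model
#' @return A `reach_fit`.
#' @export
fit_stereotypy_model <- function(records, paw = c("all", "right", "left"),
                                 outcome = c("all", "success", "failure"),
                                 random_slope = FALSE) {
  paw <- match.arg(paw)
  outcome <- match.arg(outcome)
  assert_columns(records, c("animal_id", "day", "group", "score"),
                 "stereotypy records")
  data <- records
  if (paw != "all") {
    assert_columns(data, "paw", "stereotypy records")
    data <- data[data$paw == paw, ]
  }
  if (outcome != "all") {
    assert_columns(data, "success", "stereotypy records")
    data <- data[!is.na(data$success) &
                   data$success == (outcome == "success"), ]
  }
  n_na <- sum(is.na(data$score))
  if (n_na > 0) {
    inform(sprintf("excluding %d trial(s) with no detected grab.", n_na))
    data <- data[!is.na(data$score), ]
  }
  data <- check_learning_table(dplyr::rename(data, successes = "score"))
  re <- if (random_slope) "(1 + log_day | animal_id)" else "(1 | animal_id)"
  f <- stats::as.formula(paste("successes ~ log_day * group +", re))
  fit <- fit_lmm(f, data, sprintf("stereotypy (%s paw, %s trials)",
                                  paw, outcome))
  fit
}

#' Fit MEP amplitude models
#'
#' Three model shapes on log MEP amplitudes, all with a per-animal random
#' intercept:
#' \describe{
#'   \item{`"side"`}{`log_amplitude ~ hemisphere`: contralateral vs
#'     ipsilateral stimulation.}
#'   \item{`"logdiff"`}{contra-minus-ipsi log contrast (computed via
#'     [contra_ipsi_log_contrast()] when given raw amplitudes) against
#'     tDCS group, trained/untrained paw and their interaction — the
#'     contrast cancels per-animal EMG-strength differences.}
#'   \item{`"success"`}{`log_amplitude ~ successes + group`: does final
#'     performance (successful reaches, e.g. on the last training day)
#'     predict excitability?}
#' }
#'
#' @param amplitudes an amplitude table ([mep_amplitude()] output joined
#'   with a `group` column; for `"success"` also a `successes` column; for
#'   `"logdiff"` either raw amplitudes with both hemispheres or a
#'   precomputed `log_contrast` column).
#' @param model which model shape to fit.
#' @return A `reach_fit`.
#' @export
fit_mep_model <- function(amplitudes, model = c("side", "logdiff", "success")) {
  model <- match.arg(model)
  if (model == "side") {
    assert_columns(amplitudes, c("animal_id", "hemisphere", "log_amplitude"),
                   "amplitude table")
    data <- amplitudes
    data$hemisphere <- factor(data$hemisphere, levels = c("ipsi", "contra"))
    return(fit_lmm(log_amplitude ~ hemisphere + (1 | animal_id), data,
                   "log MEP amplitude"))
  }
  if (model == "logdiff") {
    if (!"log_contrast" %in% names(amplitudes)) {
      grp_map <- dplyr::distinct(
        amplitudes[, intersect(c("animal_id", "group"), names(amplitudes))])
      amplitudes <- contra_ipsi_log_contrast(amplitudes) |>
        dplyr::left_join(grp_map, by = "animal_id")
    }
    assert_columns(amplitudes, c("animal_id", "group", "paw", "log_contrast"),
                   "contrast table")
    data <- amplitudes
    data$group <- factor(data$group, levels = c("control", "anodal"))
    data$paw <- factor(data$paw, levels = c("untrained", "trained"))
    return(fit_lmm(log_contrast ~ group * paw + (1 | animal_id), data,
                   "contra-ipsi log MEP contrast"))
  }
  assert_columns(amplitudes, c("animal_id", "group", "successes",
                               "log_amplitude"), "amplitude table")
  data <- amplitudes
  data$group <- factor(data$group, levels = c("control", "anodal"))
  fit_lmm(log_amplitude ~ successes + group + (1 | animal_id), data,
          "log MEP amplitude")
}

#' Group-by-day summary of the learning table
#'
#' Mean and SEM of successes (and of the success rate when `attempts` is
#' present) across the animals present on each group x day cell;
#' SEM = SD / sqrt(n). Cells with a single animal get `NA` SEM and are
#' flagged.
#'
#' @param table a learning tibble.
#' @return Tibble: `group`, `day`, `n_animals`, `mean_successes`,
#'   `sem_successes` (and `mean_rate`, `sem_rate`), `single_animal`.
#' @export
success_summary <- function(table) {
  assert_columns(table, c("animal_id", "day", "group", "successes"),
                 "learning table")
  has_att <- "attempts" %in% names(table)
  out <- table |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      n_animals = dplyr::n_distinct(.data$animal_id),
      mean_successes = mean(.data$successes),
      sem_successes = if (dplyr::n() > 1) {
        sd(.data$successes) / sqrt(dplyr::n())
      } else NA_real_,
      mean_rate = if (has_att) mean(.data$successes / .data$attempts)
                  else NA_real_,
      sem_rate = if (has_att && dplyr::n() > 1) {
        sd(.data$successes / .data$attempts) / sqrt(dplyr::n())
      } else NA_real_,
      .groups = "drop")
  out$single_animal <- out$n_animals == 1
  out
}

#' @method print reach_fit
#' @export
print.reach_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model for %s (n = %d observations, %d animals)\n",
              x$response, x$n_obs, x$n_animals))
  cat(sprintf("  random intercept SD = %.4g, residual SD = %.4g%s%s\n",
              x$random_sd, x$sigma,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular fit]" else ""))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  cat("p-values are not corrected for multiple comparisons.\n")
  invisible(x)
}

#' Tidy a mixed-model fit
#'
#' @param x a `reach_fit`.
#' @param effects `"fixed"` for the coefficient table (estimate, SE,
#'   Satterthwaite df, t, p) or `"anova"` for the type-III F table.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.reach_fit <- function(x, effects = c("fixed", "anova"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$coefficients else x$anova
}

#' @rdname tidy.reach_fit
#' @export
glance.reach_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_animals = x$n_animals,
                 random_sd = x$random_sd, sigma = x$sigma,
                 logLik = as.numeric(logLik(x$model)),
                 AIC = AIC(x$model),
                 converged = x$converged, singular = x$singular)
}

#' Confidence intervals for the fixed effects
#'
#' Wald intervals using the Satterthwaite degrees of freedom of each
#' coefficient.
#'
#' @param fit a `reach_fit`.
#' @param level confidence level.
#' @return The coefficient tibble with `conf_low`, `conf_high`.
#' @export
fixed_effect_ci <- function(fit, level = 0.95) {
  co <- fit$coefficients
  crit <- qt(1 - (1 - level) / 2, df = co$df)
  co$conf_low <- co$estimate - crit * co$std_error
  co$conf_high <- co$estimate + crit * co$std_error
  co
}
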