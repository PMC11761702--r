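test_that("noiseless learning tables return the generating coefficients", {
  cfg <- learning_sim_config(n_animals = 8, beta0 = 3, beta_day = 4,
                             beta_tdcs = 1.5, beta_interaction = 2,
                             animal_sd = 0, resid_sd = 0, seed = 2)
  tab <- sim_learning_table(cfg, integer_counts = FALSE)
  fit <- fit_success_model(tab)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), 3, tolerance = 1e-8)
  expect_equal(unname(est["log_day"]), 4, tolerance = 1e-8)
  expect_equal(unname(est["groupanodal"]), 1.5, tolerance = 1e-8)
  expect_equal(unname(est["log_day:groupanodal"]), 2, tolerance = 1e-8)
})

test_that("fits are invariant to row permutation and animal relabeling", {
  tab <- sim_learning_table(learning_sim_config(n_animals = 8, seed = 3))
  fit1 <- fit_success_model(tab)
  set.seed(4)
  fit2 <- fit_success_model(tab[sample(nrow(tab)), ])
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-8)
  relabel <- tab
  relabel$animal_id <- paste0("z", relabel$animal_id)
  fit3 <- fit_success_model(relabel)
  expect_equal(fit3$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("missing days are handled by likelihood without dropping animals", {
  tab <- sim_learning_table(learning_sim_config(n_animals = 8, seed = 5))
  # three animals lose days 8-10, as happens when a headcap detaches
  drop <- tab$animal_id %in% c("a01", "a02", "a05") & tab$day >= 8
  fit <- fit_success_model(tab[!drop, ])
  expect_equal(fit$n_obs, nrow(tab) - sum(drop))
  expect_equal(fit$n_animals, 8)
  expect_true(fit$converged)
})

test_that("the rate model works on successes/attempts and drops empty sessions", {
  tab <- sim_learning_table(learning_sim_config(n_animals = 8, seed = 6))
  tab$attempts[1] <- 0
  expect_message(fit <- fit_rate_model(tab), "zero attempts")
  expect_equal(fit$n_obs, nrow(tab) - 1L)
  expect_equal(fit$response, "success rate")
})

test_that("stereotypy model bookkeeping: paw and outcome subsets", {
  set.seed(7)
  grid <- expand.grid(animal_id = sprintf("a%02d", 1:8), day = 1:5,
                      trial = 1:4, stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$animal_id <= "a04", "control", "anodal")
  grid$paw <- ifelse(grid$animal_id %in% c("a01", "a02", "a05", "a06"),
                     "right", "left")
  grid$success <- runif(nrow(grid)) < 0.5
  grid$score <- 0.5 + 0.05 * log(grid$day) + rnorm(nrow(grid), 0, 0.05)
  fit_r <- fit_stereotypy_model(grid, paw = "right")
  expect_equal(fit_r$n_obs, sum(grid$paw == "right"))
  fit_s <- fit_stereotypy_model(grid, paw = "right", outcome = "success")
  expect_equal(fit_s$n_obs, sum(grid$paw == "right" & grid$success))
  # constant scores -> zero day and interaction coefficients
  const <- grid
  const$score <- 0.7
  fit_c <- fit_stereotypy_model(const)
  est <- setNames(fit_c$coefficients$estimate, fit_c$coefficients$term)
  expect_equal(unname(est["log_day"]), 0, tolerance = 1e-10)
  expect_equal(unname(est["log_day:groupanodal"]), 0, tolerance = 1e-10)
  # NA scores (no detected grab) are excluded with a message
  withna <- grid
  withna$score[1:5] <- NA
  expect_message(fit_na <- fit_stereotypy_model(withna), "no detected grab")
  expect_equal(fit_na$n_obs, nrow(grid) - 5L)
})

test_that("stereotypy interaction sign is recovered when one group improves", {
  set.seed(8)
  hits <- 0
  for (rep in 1:20) {
    grid <- expand.grid(animal_id = sprintf("a%02d", 1:12), day = 1:10,
                        trial = 1:5, stringsAsFactors = FALSE)
    grid$group <- ifelse(grid$animal_id <= "a06", "control", "anodal")
    b_i <- setNames(rnorm(12, 0, 0.05), sprintf("a%02d", 1:12))
    eff <- ifelse(grid$group == "anodal", 0.08, 0)
    grid$score <- 0.4 + 0.02 * log(grid$day) + eff * log(grid$day) +
      b_i[grid$animal_id] + rnorm(nrow(grid), 0, 0.1)
    fit <- fit_stereotypy_model(grid)
    est <- fit$coefficients
    hits <- hits + (est$estimate[est$term == "log_day:groupanodal"] > 0)
  }
  expect_gte(hits, 19)
})

test_that("the side model recovers an exact log-ratio at zero noise", {
  amp <- tidyr::expand_grid(animal_id = sprintf("a%02d", 1:6),
                            paw = c("trained", "untrained"),
                            hemisphere = c("contra", "ipsi"))
  base <- setNames(runif(6, 0.1, 0.5), sprintf("a%02d", 1:6))
  amp$median_mv <- base[amp$animal_id] *
    ifelse(amp$hemisphere == "contra", exp(2), 1)
  amp$log_amplitude <- log(amp$median_mv)
  fit <- fit_mep_model(amp, model = "side")
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "hemispherecontra"], 2,
               tolerance = 1e-8)
})

test_that("the log-difference model consumes raw amplitudes and factors", {
  set.seed(9)
  amp <- tidyr::expand_grid(animal_id = sprintf("a%02d", 1:8),
                            paw = c("trained", "untrained"),
                            hemisphere = c("contra", "ipsi"))
  amp$group <- ifelse(amp$animal_id <= "a04", "control", "anodal")
  training_eff <- ifelse(amp$paw == "trained" & amp$hemisphere == "contra",
                         0.8, 0)
  amp$median_mv <- exp(log(0.3) + training_eff + rnorm(nrow(amp), 0, 0.05))
  amp$log_amplitude <- log(amp$median_mv)
  fit <- fit_mep_model(amp, model = "logdiff")
  expect_equal(fit$n_obs, 16L)  # one contrast per animal x paw
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "pawtrained"], 0.8, tolerance = 0.15)

  # success model: amplitudes regressed on final-day performance, with
  # both paws' contralateral measurements per animal
  succ <- amp[amp$hemisphere == "contra", ]
  final_day <- setNames(rpois(8, 20), sprintf("a%02d", 1:8))
  succ$successes <- final_day[succ$animal_id]
  fit_s <- fit_mep_model(succ, model = "success")
  expect_true(all(c("successes", "groupanodal") %in%
                    fit_s$coefficients$term))
})

test_that("group/day summaries match a brute-force mean/SEM oracle", {
  tab <- sim_learning_table(learning_sim_config(n_animals = 8, n_days = 4,
                                                seed = 10))
  sm <- success_summary(tab)
  for (i in seq_len(nrow(sm))) {
    sub <- tab[tab$group == sm$group[i] & tab$day == sm$day[i], ]
    expect_equal(sm$mean_successes[i], mean(sub$successes), tolerance = 1e-12)
    expect_equal(sm$sem_successes[i],
                 sd(sub$successes) / sqrt(nrow(sub)), tolerance = 1e-12)
    expect_equal(sm$mean_rate[i], mean(sub$successes / sub$attempts),
                 tolerance = 1e-12)
  }
  # identical animals -> SEM 0; single animal -> SEM flagged NA
  same <- tab
  same$successes <- 5
  expect_true(all(success_summary(same)$sem_successes == 0))
  one <- tab[tab$animal_id == "a01", ]
  one$group <- "control"
  sm1 <- success_summary(one)
  expect_true(all(is.na(sm1$sem_successes)))
  expect_true(all(sm1$single_animal))
})

test_that("tidy, glance and CI accessors expose the fit", {
  tab <- sim_learning_table(learning_sim_config(n_animals = 8, seed = 11))
  fit <- fit_success_model(tab)
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_true(all(c("estimate", "std_error", "df", "statistic", "p_value")
                  %in% names(td)))
  ta <- tidy(fit, effects = "anova")
  expect_true("f_statistic" %in% names(ta))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 80L)
  expect_equal(gl$n_animals, 8)
  ci <- fixed_effect_ci(fit)
  expect_true(all(ci$conf_low < ci$estimate & ci$estimate < ci$conf_high))
  expect_output(print(fit), "not corrected for multiple comparisons")
  # degrees of freedom are positive and finite
  expect_true(all(td$df > 0))
})

test_that("input validation guards degenerate designs", {
  tab <- sim_learning_table(learning_sim_config(n_animals = 8, seed = 12))
  expect_error(fit_success_model(tab[tab$group == "control", ]), "2 groups")
  expect_error(fit_success_model(tab[tab$day == 1, ]), "2 days")
  bad <- tab
  bad$day[1] <- 0
  expect_error(fit_success_model(bad), "log-day")
})
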