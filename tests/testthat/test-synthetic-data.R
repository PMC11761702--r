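# The generators are first-class code: their outputs must be
# deterministic under a fixed seed and statistically faithful to the
# configured ground truth.

test_that("config validation rejects out-of-range parameters", {
  expect_error(trajectory_sim_config(stereotypy_level = 1.2), "stereotypy")
  expect_error(trajectory_sim_config(trial_len = 40), "trial_len")
  expect_error(trajectory_sim_config(grab_jitter_sd = -1), "grab_jitter_sd")
  expect_error(learning_sim_config(n_animals = 7), "even")
  expect_error(mep_sim_config(sweep_len_s = 0.02), "sweep too short")
  expect_error(field_sim_config(currents = c(0, 10)), "currents")
  expect_error(field_sim_config(contact_spacing = 2), "1.0 mm")
})

test_that("every generator is byte-identical under a repeated seed", {
  cfg_t <- trajectory_sim_config(n_trials = 3, seed = 11)
  expect_identical(sim_pose_trials(cfg_t), sim_pose_trials(cfg_t))
  cfg_l <- learning_sim_config(n_animals = 6, seed = 11)
  expect_identical(sim_learning_table(cfg_l), sim_learning_table(cfg_l))
  cfg_m <- mep_sim_config(n_trials_per_intensity = 3, intensities = c(100, 140),
                          seed = 11)
  expect_identical(sim_mep_sweeps(cfg_m), sim_mep_sweeps(cfg_m))
  cfg_f <- field_sim_config(duration = 0.05, seed = 11)
  expect_identical(sim_field_recordings(cfg_f), sim_field_recordings(cfg_f))
})

test_that("adding trials leaves earlier trials untouched (sub-streams)", {
  small <- sim_pose_trials(trajectory_sim_config(n_trials = 2, seed = 7))
  big <- sim_pose_trials(trajectory_sim_config(n_trials = 4, seed = 7))
  expect_identical(small$tracks,
                   dplyr::filter(big$tracks, trial_id %in% c("t001", "t002")))
  expect_identical(small$grabs,
                   dplyr::filter(big$grabs, trial_id %in% c("t001", "t002")))
})

test_that("noiseless fully stereotyped trials embed the base waveform exactly", {
  cfg <- trajectory_sim_config(n_trials = 5, stereotypy_level = 1,
                               baseline_noise_sd = 0, time_warp_sd = 0,
                               grabs_per_trial = 1, seed = 3)
  sim <- sim_pose_trials(cfg)
  for (tid in unique(sim$grabs$trial_id)) {
    tr <- dplyr::filter(sim$tracks, trial_id == tid)
    f <- sim$grabs$frame[sim$grabs$trial_id == tid]
    expect_equal(extract_grab_window(tr, f),
                 unname(cfg$grab_waveform) * 1, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("ground-truth grab log has exactly grabs_per_trial events per trial", {
  cfg <- trajectory_sim_config(n_trials = 25, grabs_per_trial = 3, seed = 13)
  sim <- sim_pose_trials(cfg)
  expect_equal(nrow(sim$grabs), 75L)
  per_trial <- table(sim$grabs$trial_id)
  expect_true(all(per_trial == 3))
  # brute-force scan: embedded centers are where the track leaves the rest
  # posture (noiseless check on a dedicated config)
  cfg0 <- trajectory_sim_config(n_trials = 4, grabs_per_trial = 3,
                                stereotypy_level = 1, baseline_noise_sd = 0,
                                time_warp_sd = 0, seed = 13)
  sim0 <- sim_pose_trials(cfg0)
  rest <- cfg0$grab_waveform[1, ]
  for (tid in unique(sim0$grabs$trial_id)) {
    m <- coords_of(dplyr::filter(sim0$tracks, trial_id == tid))
    moving <- which(rowSums(abs(sweep(m, 2, rest))) > 1e-9)
    claimed <- sim0$grabs$frame[sim0$grabs$trial_id == tid]
    covered <- sort(unique(unlist(lapply(claimed + 1,
                                         function(c) (c - 24):(c + 25)))))
    expect_true(all(moving %in% covered))
  }
  expect_error(sim_pose_trials(trajectory_sim_config(trial_len = 100,
                                                     grabs_per_trial = 3)),
               "too short")
})

test_that("learning table follows the configured linear-in-log-day model", {
  # all betas zero, no noise -> all zeros
  z <- sim_learning_table(learning_sim_config(n_animals = 4, beta0 = 0,
                                              beta_day = 0, beta_tdcs = 0,
                                              beta_interaction = 0,
                                              animal_sd = 0, resid_sd = 0,
                                              seed = 1))
  expect_true(all(z$successes == 0))
  # pure intercept -> constant cells
  c5 <- sim_learning_table(learning_sim_config(n_animals = 4, beta0 = 5,
                                               beta_day = 0, beta_tdcs = 0,
                                               beta_interaction = 0,
                                               animal_sd = 0, resid_sd = 0,
                                               seed = 1))
  expect_true(all(c5$successes == 5))
  # group-mean trajectories converge to the linear-in-log-day form
  cfg <- learning_sim_config(n_animals = 10, beta0 = 3, beta_day = 4,
                             beta_tdcs = 1, beta_interaction = 2,
                             animal_sd = 0, resid_sd = 0, seed = 2)
  tab <- sim_learning_table(cfg, integer_counts = FALSE)
  mu <- with(tab, 3 + 4 * log(day) + (group == "anodal") * (1 + 2 * log(day)))
  expect_lt(max(abs(tab$successes - mu)), 1e-6)
  # OLS slope-difference oracle recovers beta_interaction at large n
  cfg2 <- learning_sim_config(n_animals = 200, beta_interaction = 2,
                              animal_sd = 1, resid_sd = 2, seed = 8)
  tab2 <- sim_learning_table(cfg2)
  ols <- function(df) unname(coef(lm(successes ~ log(day), df))[2])
  diff_slope <- ols(tab2[tab2$group == "anodal", ]) -
    ols(tab2[tab2$group == "control", ])
  expect_lt(abs(diff_slope - 2), 0.25)
})

test_that("learning table is balanced with valid attempts and paws", {
  tab <- sim_learning_table(learning_sim_config(n_animals = 12, seed = 5))
  expect_equal(nrow(tab), 120L)
  groups <- dplyr::distinct(tab, animal_id, group)
  expect_equal(sum(groups$group == "anodal"), 6L)
  expect_true(all(tab$attempts >= tab$successes))
  expect_true(all(tab$attempts >= 1))
  expect_true(all(tab$paw %in% c("left", "right")))
})

test_that("MEP sweeps obey the noise floor and recruitment monotonicity", {
  # max_amplitude = 0: window means stay near the rectified-noise mean
  cfg0 <- mep_sim_config(max_amplitude = 0, n_trials_per_intensity = 20,
                         intensities = c(100, 200), seed = 6)
  sw0 <- mep_window_mean(sim_mep_sweeps(cfg0)$sweeps)
  # mean |N(0,s)| = s*sqrt(2/pi); with 200 window samples the sample mean
  # concentrates tightly, 3*s is a generous Monte-Carlo bound
  expect_true(all(sw0$window_mean_mv <= 3 * cfg0$noise_floor_sd))
  # noiseless constant-burst amplitudes follow the sigmoid ordering
  cfgm <- mep_sim_config(noise_floor_sd = 0, amplitude_cv = 0, seed = 6)
  truth <- sim_mep_sweeps(cfgm)$truth
  med <- tapply(truth$burst_peak_mv, truth$intensity, median)
  expect_true(all(diff(med[order(as.numeric(names(med)))]) >= 0))
  sw <- mep_window_mean(sim_mep_sweeps(cfgm)$sweeps)
  m <- tapply(sw$window_mean_mv, sw$intensity, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) >= 0))
})

test_that("field recordings are linear in current with exact uniform structure", {
  # zero gain -> pure noise
  cfg0 <- field_sim_config(true_gain_x = 0, true_gain_y = 0, duration = 0.05,
                           noise_sd = 1e-6, seed = 9)
  rec0 <- sim_field_recordings(cfg0)
  expect_true(all(vapply(rec0$potentials, function(m) max(abs(m)) < 1e-5,
                         logical(1))))
  # noiseless: doubling current doubles every channel
  cfg <- field_sim_config(noise_sd = 0, currents = c(10, 20), duration = 0.05,
                          frequencies = 100, seed = 9)
  rec <- sim_field_recordings(cfg)
  p10 <- rec$potentials[[which(rec$current_ua == 10)]]
  p20 <- rec$potentials[[which(rec$current_ua == 20)]]
  expect_equal(p20, 2 * p10, tolerance = 1e-12)
  # uniform-field residual is exactly zero at zero noise
  est <- estimate_field(rec)
  expect_equal(est$magnitude, sqrt(0.02^2 + 0.015^2) * c(10, 20),
               tolerance = 1e-9)
})

test_that("YAML config files round-trip through read/write", {
  cfgs <- list(learning = learning_sim_config(n_animals = 8, seed = 3),
               mep = mep_sim_config(seed = 4),
               field = field_sim_config(seed = 5),
               trajectory = trajectory_sim_config(n_trials = 2, seed = 6))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfgs, path)
  back <- read_sim_config(path)
  for (nm in names(cfgs)) {
    expect_equal(back[[nm]], cfgs[[nm]], tolerance = 1e-9)
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(unknown_section = list(a = 1)), bad)
  expect_error(read_sim_config(bad), "unknown config section")
})
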