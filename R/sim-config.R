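#' Simulation configuration objects
#'
#' Constructors for the four synthetic-data generators. Each returns a
#' validated classed list; defaults reproduce the recording conditions the
#' pipeline is designed for (309 fps high-speed video, 10 kHz EMG sweeps with
#' 20 trials per intensity at 90/100/120/140/200 % of motor threshold,
#' sinusoidal transcranial stimulation at 10/100/1000 Hz and 10/20/40 uA on a
#' 1 mm four-contact lattice, and a 24-animal x 10-day training protocol).
#'
#' @param n_trials number of reaching trials to simulate.
#' @param frame_rate video frame rate, frames/s.
#' @param trial_len trial length in frames (must fit all requested grabs).
#' @param grab_waveform 50 x 10 matrix giving the canonical grab trajectory
#'   (absolute pixel coordinates, columns `digit1_x, digit1_y, ...,
#'   digit5_y`). Defaults to [default_grab_waveform()].
#' @param grabs_per_trial number of grab events embedded per trial.
#' @param grab_jitter_sd SD (pixels) of the smooth trajectory distortion
#'   applied to each embedded grab, scaled by `1 - stereotypy_level`.
#' @param time_warp_sd SD of the multiplicative time-warp factor applied to
#'   each embedded grab (fraction; 0 disables warping).
#' @param baseline_noise_sd SD (pixels) of white measurement noise added to
#'   every coordinate of every frame.
#' @param stereotypy_level trial-to-trial waveform fidelity in \[0, 1\];
#'   1 means every grab equals the base waveform exactly (before
#'   measurement noise).
#' @param seed integer seed; per-trial sub-streams are derived from it so
#'   that enlarging `n_trials` never alters earlier trials.
#' @return A classed list of validated simulation parameters.
#' @seealso [sim_pose_trials()], [sim_learning_table()], [sim_mep_sweeps()],
#'   [sim_field_recordings()], [read_sim_config()]
#' @export
trajectory_sim_config <- function(n_trials = 100, frame_rate = 309,
                                  trial_len = 400,
                                  grab_waveform = default_grab_waveform(),
                                  grabs_per_trial = 3, grab_jitter_sd = 6,
                                  time_warp_sd = 0.02, baseline_noise_sd = 1,
                                  stereotypy_level = 0.5, seed = 1) {
  n_trials <- assert_count(n_trials, "n_trials")
  assert_scalar_number(frame_rate, "frame_rate", min = 1e-9)
  trial_len <- assert_count(trial_len, "trial_len", min = 50)
  grabs_per_trial <- assert_count(grabs_per_trial, "grabs_per_trial")
  assert_scalar_number(grab_jitter_sd, "grab_jitter_sd", min = 0)
  assert_scalar_number(time_warp_sd, "time_warp_sd", min = 0)
  assert_scalar_number(baseline_noise_sd, "baseline_noise_sd", min = 0)
  assert_scalar_number(stereotypy_level, "stereotypy_level", min = 0, max = 1)
  seed <- assert_count(seed, "seed", min = 0)
  grab_waveform <- as.matrix(grab_waveform)
  if (!identical(dim(grab_waveform), c(50L, 10L)) ||
      !all(is.finite(grab_waveform))) {
    abort("`grab_waveform` must be a finite 50 x 10 matrix.")
  }
  colnames(grab_waveform) <- DIGIT_COORDS
  structure(list(n_trials = n_trials, frame_rate = frame_rate,
                 trial_len = trial_len, grab_waveform = grab_waveform,
                 grabs_per_trial = grabs_per_trial,
                 grab_jitter_sd = grab_jitter_sd,
                 time_warp_sd = time_warp_sd,
                 baseline_noise_sd = baseline_noise_sd,
                 stereotypy_level = stereotypy_level, seed = seed),
            class = "trajectory_sim_config")
}

#' @rdname trajectory_sim_config
#' @param n_animals number of animals (must be even; groups are balanced).
#' @param n_days training days, numbered from 1.
#' @param beta0,beta_day,beta_tdcs,beta_interaction fixed-effect coefficients
#'   of the generating model `successes = beta0 + beta_day*log(day) +
#'   beta_tdcs*G + beta_interaction*G*log(day)` with `G = 1` for the anodal
#'   group (natural log, day 1 = 0).
#' @param animal_sd SD of the per-animal random intercept (successes).
#' @param resid_sd residual SD (successes).
#' @param mean_extra_attempts mean number of unsuccessful attempts added per
#'   session (Poisson), so `attempts >= successes`.
#' @param p_right probability that an animal is right-pawed (default 13/24,
#'   the proportion observed in the cohort the defaults emulate).
#' @export
learning_sim_config <- function(n_animals = 24, n_days = 10, beta0 = 2,
                                beta_day = 4, beta_tdcs = 0,
                                beta_interaction = 2, animal_sd = 2,
                                resid_sd = 3, mean_extra_attempts = 25,
                                p_right = 13 / 24, seed = 1) {
  n_animals <- assert_count(n_animals, "n_animals", min = 2)
  if (n_animals %% 2L != 0L) abort("`n_animals` must be even (balanced groups).")
  n_days <- assert_count(n_days, "n_days", min = 1)
  for (nm in c("beta0", "beta_day", "beta_tdcs", "beta_interaction")) {
    assert_scalar_number(get(nm), nm)
  }
  assert_scalar_number(animal_sd, "animal_sd", min = 0)
  assert_scalar_number(resid_sd, "resid_sd", min = 0)
  assert_scalar_number(mean_extra_attempts, "mean_extra_attempts", min = 0)
  assert_scalar_number(p_right, "p_right", min = 0, max = 1)
  seed <- assert_count(seed, "seed", min = 0)
  structure(list(n_animals = n_animals, n_days = n_days, beta0 = beta0,
                 beta_day = beta_day, beta_tdcs = beta_tdcs,
                 beta_interaction = beta_interaction, animal_sd = animal_sd,
                 resid_sd = resid_sd,
                 mean_extra_attempts = mean_extra_attempts,
                 p_right = p_right, seed = seed),
            class = "learning_sim_config")
}

#' @rdname trajectory_sim_config
#' @param n_trials_per_intensity trials per stimulation intensity.
#' @param intensities stimulation intensities, % of motor threshold.
#' @param noise_floor_sd SD (mV) of baseline EMG noise.
#' @param recruitment_midpoint intensity (% threshold) at half-maximal
#'   response.
#' @param recruitment_slope logistic slope of the recruitment curve per 10 %
#'   of threshold intensity.
#' @param max_amplitude asymptotic burst peak amplitude, mV.
#' @param amplitude_cv trial-to-trial lognormal variability of burst size.
#' @param response_latency burst onset after the first stimulation pulse, ms.
#' @param response_duration burst duration, ms.
#' @param burst_freq_hz oscillation frequency of the simulated MEP burst.
#' @param sample_rate samples/s.
#' @param stim_onset_s time of the first stimulation pulse within the sweep.
#' @param sweep_len_s sweep length, s.
#' @export
mep_sim_config <- function(n_trials_per_intensity = 20,
                           intensities = c(90, 100, 120, 140, 200),
                           noise_floor_sd = 0.02, recruitment_midpoint = 110,
                           recruitment_slope = 1.5, max_amplitude = 1.5,
                           amplitude_cv = 0.25, response_latency = 12,
                           response_duration = 15, burst_freq_hz = 150,
                           sample_rate = 10000, stim_onset_s = 0.005,
                           sweep_len_s = 0.06, seed = 1) {
  n_trials_per_intensity <- assert_count(n_trials_per_intensity,
                                         "n_trials_per_intensity", min = 2)
  if (!is.numeric(intensities) || length(intensities) < 1 ||
      any(intensities <= 0)) {
    abort("`intensities` must be positive percentages of motor threshold.")
  }
  assert_scalar_number(noise_floor_sd, "noise_floor_sd", min = 0)
  assert_scalar_number(recruitment_midpoint, "recruitment_midpoint", min = 0)
  assert_scalar_number(recruitment_slope, "recruitment_slope", min = 0)
  assert_scalar_number(max_amplitude, "max_amplitude", min = 0)
  assert_scalar_number(amplitude_cv, "amplitude_cv", min = 0)
  assert_scalar_number(response_latency, "response_latency", min = 0)
  assert_scalar_number(response_duration, "response_duration", min = 0)
  assert_scalar_number(burst_freq_hz, "burst_freq_hz", min = 0)
  assert_scalar_number(sample_rate, "sample_rate", min = 1)
  assert_scalar_number(stim_onset_s, "stim_onset_s", min = 0)
  assert_scalar_number(sweep_len_s, "sweep_len_s", min = 1e-9)
  seed <- assert_count(seed, "seed", min = 0)
  if (response_latency < 10 || response_latency + response_duration > 30) {
    warn("simulated response window extends outside the default 10-30 ms analysis window")
  }
  if (stim_onset_s + 0.030 > sweep_len_s) {
    abort("sweep too short: the 10-30 ms post-stimulus window overruns the sweep.")
  }
  structure(list(n_trials_per_intensity = n_trials_per_intensity,
                 intensities = sort(intensities),
                 noise_floor_sd = noise_floor_sd,
                 recruitment_midpoint = recruitment_midpoint,
                 recruitment_slope = recruitment_slope,
                 max_amplitude = max_amplitude, amplitude_cv = amplitude_cv,
                 response_latency = response_latency,
                 response_duration = response_duration,
                 burst_freq_hz = burst_freq_hz, sample_rate = sample_rate,
                 stim_onset_s = stim_onset_s, sweep_len_s = sweep_len_s,
                 seed = seed),
            class = "mep_sim_config")
}

#' @rdname trajectory_sim_config
#' @param true_gain_x,true_gain_y ground-truth field gain along the two
#'   lattice axes, (V/m)/uA.
#' @param currents stimulation current amplitudes, uA (all > 0).
#' @param frequencies stimulation frequencies, Hz.
#' @param duration recording duration per condition, s.
#' @param noise_sd SD of additive recording noise, volts.
#' @param contact_spacing lattice side length, mm (fixed at 1.0).
#' @export
field_sim_config <- function(true_gain_x = 0.02, true_gain_y = 0.015,
                             currents = c(10, 20, 40),
                             frequencies = c(10, 100, 1000), duration = 0.5,
                             sample_rate = 20000, noise_sd = 5e-6,
                             contact_spacing = 1.0, seed = 1) {
  assert_scalar_number(true_gain_x, "true_gain_x")
  assert_scalar_number(true_gain_y, "true_gain_y")
  if (!is.numeric(currents) || any(currents <= 0)) {
    abort("`currents` must all be > 0 uA.")
  }
  if (!is.numeric(frequencies) || any(frequencies <= 0)) {
    abort("`frequencies` must all be > 0 Hz.")
  }
  assert_scalar_number(duration, "duration", min = 1e-9)
  assert_scalar_number(sample_rate, "sample_rate", min = 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  if (!isTRUE(all.equal(contact_spacing, 1.0))) {
    abort("`contact_spacing` is fixed at 1.0 mm (square planar lattice).")
  }
  seed <- assert_count(seed, "seed", min = 0)
  structure(list(true_gain_x = true_gain_x, true_gain_y = true_gain_y,
                 currents = currents, frequencies = frequencies,
                 duration = duration, sample_rate = sample_rate,
                 noise_sd = noise_sd, contact_spacing = 1.0, seed = seed),
            class = "field_sim_config")
}

#' Read or write simulation configurations as YAML
#'
#' A single YAML file holds up to four top-level sections (`trajectory`,
#' `learning`, `mep`, `field`), each a mapping of constructor arguments.
#' Unknown keys are rejected by the constructors. The trajectory section may
#' omit `grab_waveform` (the default is used) or give it as a list of 50
#' rows of 10 numbers.
#'
#' @param path file path.
#' @return `read_sim_config()` returns a named list of config objects, one
#'   per section present in the file.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  constructors <- list(trajectory = trajectory_sim_config,
                       learning = learning_sim_config,
                       mep = mep_sim_config,
                       field = field_sim_config)
  unknown <- setdiff(names(raw), names(constructors))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config section(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  purrr::imap(raw, function(args, section) {
    if (section == "trajectory" && !is.null(args$grab_waveform)) {
      args$grab_waveform <- do.call(rbind, args$grab_waveform)
    }
    do.call(constructors[[section]], args)
  })
}

#' @rdname read_sim_config
#' @param configs named list of config objects (names among `trajectory`,
#'   `learning`, `mep`, `field`).
#' @export
write_sim_config <- function(configs, path) {
  out <- purrr::map(configs, function(cfg) {
    x <- unclass(cfg)
    if (!is.null(x$grab_waveform)) {
      x$grab_waveform <- apply(unname(x$grab_waveform), 1, as.list,
                               simplify = FALSE)
      x$grab_waveform <- purrr::map(x$grab_waveform, unlist)
    }
    x
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
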