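#' Canonical synthetic grab waveform
#'
#' A smooth reach-advance-close-retract arc over 50 samples (150 ms at
#' 309 fps) for the five digit markers, in absolute pixel coordinates
#' (image convention: origin top-left, y increases downward). The paw
#' advances ~140 px toward the pellet while lifting, the digits close
#' toward the paw centroid at the moment of the grab (sample 25), and the
#' trajectory returns exactly to the resting posture, so embedded grabs
#' join the baseline continuously.
#'
#' @return A 50 x 10 matrix with columns `digit1_x, digit1_y, ...,
#'   digit5_y`.
#' @export
default_grab_waveform <- function() {
  t <- 0:(TEMPLATE_LEN - 1L)
  s <- sin(pi * t / (TEMPLATE_LEN - 1L))^2   # 0 -> 1 -> 0 advance profile
  f <- 1 - 0.5 * s                           # digit spread (closing at peak)
  w <- matrix(0, TEMPLATE_LEN, 10L, dimnames = list(NULL, DIGIT_COORDS))
  for (i in 1:5) {
    w[, 2L * i - 1L] <- 300 + (i - 3) * 12 * f + 140 * s
    w[, 2L * i] <- 620 + abs(i - 3) * 4 * f - 60 * s
  }
  w
}

# Smooth random 50 x 10 distortion: white noise at 6 knots (endpoints
# anchored at 0) interpolated to 50 samples, per coordinate.
smooth_distortion <- function(sd) {
  knots <- seq(1, TEMPLATE_LEN, length.out = 6)
  apply(matrix(0, TEMPLATE_LEN, 10L), 2, function(col) {
    k <- c(0, rnorm(4, 0, sd), 0)
    approx(knots, k, xout = seq_len(TEMPLATE_LEN))$y
  })
}

place_grab_centers <- function(n_grabs, trial_len, min_sep = 60L) {
  lo <- 25L
  hi <- trial_len - 26L
  if (lo + (n_grabs - 1L) * min_sep > hi) {
    abort(sprintf(
      "trial_len = %d is too short to place %d grabs (need >= %d frames).",
      trial_len, n_grabs, 51L + (n_grabs - 1L) * min_sep))
  }
  for (try in 1:200) {
    centers <- sort(sample(lo:hi, n_grabs))
    if (n_grabs == 1L || min(diff(centers)) >= min_sep) return(centers)
  }
  # fall back to evenly spaced centers with a small jitter
  base <- round(seq(lo, hi, length.out = n_grabs))
  base
}

#' Simulate pose-tracked reaching trials with known grab times
#'
#' Generates per-trial pose tables in the same shape [read_pose_csv()]
#' produces: one row per frame per tracked point (five digits, wrist,
#' pellet), with 0-based frame indices. Each trial embeds
#' `cfg$grabs_per_trial` grab events: a copy of the base waveform,
#' distorted by a smooth random perturbation with SD
#' `(1 - stereotypy_level) * grab_jitter_sd` pixels and a random time warp,
#' placed at recorded center frames (minimum separation 60 frames, 25-frame
#' margins). White measurement noise of SD `baseline_noise_sd` is added to
#' every coordinate. The wrist follows the digit centroid; the pellet is
#' stationary.
#'
#' Randomness is drawn from per-trial sub-streams derived from `cfg$seed`,
#' so outputs are reproducible and earlier trials are unchanged when
#' `n_trials` grows.
#'
#' @param cfg a [trajectory_sim_config()].
#' @param animal_id,day identifiers stamped on every row.
#' @return A list with `tracks`, a tibble of pose rows (`trial_id`,
#'   `animal_id`, `day`, `frame`, `point`, `x`, `y`, `likelihood`), and
#'   `grabs`, the ground truth (`trial_id`, `grab_index`, `frame` = center
#'   frame of each embedded grab, `is_final`).
#' @export
sim_pose_trials <- function(cfg, animal_id = "a01", day = 1L) {
  stopifnot(inherits(cfg, "trajectory_sim_config"))
  rest <- cfg$grab_waveform[1L, ]
  n <- cfg$trial_len
  trials <- purrr::map(seq_len(cfg$n_trials), function(k) {
    with_local_seed(substream_seed(cfg$seed, k, salt = 1), {
      centers <- place_grab_centers(cfg$grabs_per_trial, n)
      coords <- matrix(rest, n, 10L, byrow = TRUE,
                       dimnames = list(NULL, DIGIT_COORDS))
      for (ctr in centers) {
        w <- cfg$grab_waveform +
          (1 - cfg$stereotypy_level) * smooth_distortion(cfg$grab_jitter_sd)
        if (cfg$time_warp_sd > 0) {
          warp <- rnorm(1, 1, cfg$time_warp_sd)
          p <- pmin(pmax(25.5 + (seq_len(TEMPLATE_LEN) - 25.5) * warp, 1),
                    TEMPLATE_LEN)
          w <- apply(w, 2, function(col) {
            approx(seq_len(TEMPLATE_LEN), col, xout = p, rule = 2)$y
          })
        }
        rows <- (ctr - 24L):(ctr + 25L)  # 0-based frames ctr-25 .. ctr+24
        coords[rows, ] <- w
      }
      xs <- coords[, seq(1, 9, by = 2)]
      ys <- coords[, seq(2, 10, by = 2)]
      wrist_x <- rowMeans(xs) - 25
      wrist_y <- rowMeans(ys) + 20
      pellet_x <- rep(660, n)
      pellet_y <- rep(700, n)
      all_x <- cbind(xs, wrist_x, pellet_x)
      all_y <- cbind(ys, wrist_y, pellet_y)
      if (cfg$baseline_noise_sd > 0) {
        all_x <- all_x + matrix(rnorm(n * 7L, 0, cfg$baseline_noise_sd), n)
        all_y <- all_y + matrix(rnorm(n * 7L, 0, cfg$baseline_noise_sd), n)
      }
      lik <- matrix(runif(n * 7L, 0.95, 1), n)
      list(
        track = tibble::tibble(
          trial_id = sprintf("t%03d", k),
          animal_id = animal_id, day = as.integer(day),
          frame = rep(0:(n - 1L), times = 7L),
          point = rep(POSE_POINTS, each = n),
          x = as.vector(all_x), y = as.vector(all_y),
          likelihood = as.vector(lik)),
        grabs = tibble::tibble(
          trial_id = sprintf("t%03d", k),
          grab_index = seq_along(centers),
          frame = as.integer(centers),
          is_final = centers == max(centers)))
    })
  })
  list(tracks = dplyr::bind_rows(purrr::map(trials, "track")),
       grabs = dplyr::bind_rows(purrr::map(trials, "grabs")))
}

#' Simulate an animal-by-day learning table
#'
#' Draws success counts from the same model the learning-curve statistics
#' fit: `successes = beta0 + beta_day*log(day) + beta_tdcs*G +
#' beta_interaction*G*log(day) + b_animal + e`, with `G = 1` for anodal
#' animals (the second half of the cohort), a Gaussian random intercept
#' per animal and Gaussian residuals. By default the continuous draws are
#' rounded to integers and floored at 0, as befits counts; set
#' `integer_counts = FALSE` to keep the continuous response (useful for
#' exact parameter-recovery checks). Attempts are successes plus a Poisson
#' number of misses. Paw preference is drawn per animal with
#' `P(right) = cfg$p_right`.
#'
#' @param cfg a [learning_sim_config()].
#' @param integer_counts round and floor the response at 0 (default TRUE).
#' @return A tibble with columns `animal_id`, `day`, `group`
#'   (control/anodal), `paw` (left/right), `successes`, `attempts`.
#' @export
sim_learning_table <- function(cfg, integer_counts = TRUE) {
  stopifnot(inherits(cfg, "learning_sim_config"))
  half <- cfg$n_animals %/% 2L
  rows <- purrr::map(seq_len(cfg$n_animals), function(i) {
    with_local_seed(substream_seed(cfg$seed, i, salt = 2), {
      g <- as.integer(i > half)
      b_i <- rnorm(1, 0, cfg$animal_sd)
      paw <- if (runif(1) < cfg$p_right) "right" else "left"
      day <- seq_len(cfg$n_days)
      mu <- cfg$beta0 + cfg$beta_day * log(day) + cfg$beta_tdcs * g +
        cfg$beta_interaction * g * log(day) + b_i
      y <- mu + rnorm(cfg$n_days, 0, cfg$resid_sd)
      succ <- if (integer_counts) pmax(0, round(y)) else y
      extra <- rpois(cfg$n_days, cfg$mean_extra_attempts)
      att <- pmax(1, pmax(0, round(y)) + extra)
      tibble::tibble(animal_id = sprintf("a%02d", i), day = day,
                     group = if (g == 1L) "anodal" else "control",
                     paw = paw, successes = succ, attempts = att)
    })
  })
  out <- dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = c("control", "anodal"))
  out
}

# Deterministic part of the simulated MEP burst, in mV, over the sweep time
# grid (seconds). peak_mv scales a 150 ms-free-standing oscillation:
#   burst(t) = peak * sin(2*pi*f_b*(t - t0)) * sin(pi*(t - t0)/dur)^2
# for t0 <= t < t0 + dur, where t0 = stim_onset + latency and dur is the
# response duration.
mep_burst <- function(t, cfg, peak_mv) {
  t0 <- cfg$stim_onset_s + cfg$response_latency / 1000
  dur <- cfg$response_duration / 1000
  rel <- t - t0
  inside <- rel >= 0 & rel < dur
  out <- numeric(length(t))
  out[inside] <- peak_mv * sin(2 * pi * cfg$burst_freq_hz * rel[inside]) *
    sin(pi * rel[inside] / dur)^2
  out
}

# Noiseless burst peak for one intensity: logistic recruitment in % of
# motor threshold.
recruitment_peak <- function(cfg, intensity) {
  cfg$max_amplitude *
    plogis(cfg$recruitment_slope * (intensity - cfg$recruitment_midpoint) / 10)
}

#' Simulate motor-evoked-potential sweeps
#'
#' For every intensity in `cfg$intensities`, generates
#' `cfg$n_trials_per_intensity` EMG sweeps (mV, sampled at
#' `cfg$sample_rate`). Each sweep holds baseline Gaussian noise of SD
#' `noise_floor_sd` plus an oscillatory burst in the response window; the
#' burst peak follows a logistic recruitment curve of the stimulation
#' intensity, with lognormal trial-to-trial variability of coefficient
#' `amplitude_cv`.
#'
#' @param cfg a [mep_sim_config()].
#' @param animal_id,hemisphere,paw metadata stamped on every sweep.
#' @return A list with `sweeps`, a tibble of one row per sweep
#'   (`animal_id`, `paw`, `hemisphere`, `intensity`, `trial_index`,
#'   `stim_onset_s`, `sample_rate`, `samples` list-column of mV vectors),
#'   and `truth`, the noise-free burst peak per sweep
#'   (`intensity`, `trial_index`, `burst_peak_mv`).
#' @export
sim_mep_sweeps <- function(cfg, animal_id = "a01", hemisphere = "contra",
                           paw = "trained") {
  stopifnot(inherits(cfg, "mep_sim_config"))
  t <- seq(0, cfg$sweep_len_s - 1 / cfg$sample_rate, by = 1 / cfg$sample_rate)
  grid <- expand.grid(trial_index = seq_len(cfg$n_trials_per_intensity),
                      intensity = cfg$intensities)
  rows <- purrr::pmap(grid, function(trial_index, intensity) {
    ii <- match(intensity, cfg$intensities)
    with_local_seed(
      substream_seed(cfg$seed, ii * 1000L + trial_index, salt = 3), {
        jitter <- if (cfg$amplitude_cv > 0) {
          exp(rnorm(1, 0, cfg$amplitude_cv))
        } else 1
        peak <- recruitment_peak(cfg, intensity) * jitter
        samples <- mep_burst(t, cfg, peak) +
          rnorm(length(t), 0, cfg$noise_floor_sd)
        list(sweep = tibble::tibble(
               animal_id = animal_id, paw = paw, hemisphere = hemisphere,
               intensity = intensity, trial_index = trial_index,
               stim_onset_s = cfg$stim_onset_s,
               sample_rate = cfg$sample_rate, samples = list(samples)),
             truth = tibble::tibble(intensity = intensity,
                                    trial_index = trial_index,
                                    burst_peak_mv = peak))
      })
  })
  list(sweeps = dplyr::bind_rows(purrr::map(rows, "sweep")),
       truth = dplyr::bind_rows(purrr::map(rows, "truth")))
}

#' Simulate four-contact intracranial field recordings
#'
#' For every frequency x current condition, generates potentials at the
#' four contacts of the 1 mm square lattice under a uniform sinusoidal
#' field: `V_k(t) = -(Ex*x_k + Ey*y_k) * sin(2*pi*f*t) + noise`, with
#' contact positions in metres and `Ex = true_gain_x * current` (V/m),
#' likewise for y. The uniform-field assumption therefore holds exactly up
#' to the injected noise.
#'
#' @param cfg a [field_sim_config()].
#' @return A tibble with one row per recording: `recording_id`,
#'   `frequency_hz`, `current_ua`, `sample_rate`, `duration_s` and a
#'   `potentials` list-column of (samples x 4) matrices in volts with
#'   columns `ch1..ch4` ordered as [lattice_positions()].
#' @export
sim_field_recordings <- function(cfg) {
  stopifnot(inherits(cfg, "field_sim_config"))
  pos <- lattice_positions(cfg$contact_spacing)
  t <- seq(0, cfg$duration - 1 / cfg$sample_rate, by = 1 / cfg$sample_rate)
  grid <- expand.grid(current_ua = cfg$currents,
                      frequency_hz = cfg$frequencies)
  rows <- purrr::pmap(cbind(grid, idx = seq_len(nrow(grid))),
                      function(current_ua, frequency_hz, idx) {
    with_local_seed(substream_seed(cfg$seed, idx, salt = 4), {
      ex <- cfg$true_gain_x * current_ua
      ey <- cfg$true_gain_y * current_ua
      carrier <- sin(2 * pi * frequency_hz * t)
      pot <- vapply(seq_len(4), function(k) {
        v <- -(ex * pos$x_mm[k] + ey * pos$y_mm[k]) * 1e-3 * carrier
        v + rnorm(length(t), 0, cfg$noise_sd)
      }, numeric(length(t)))
      colnames(pot) <- pos$channel
      tibble::tibble(recording_id = sprintf("r%02d", idx),
                     frequency_hz = frequency_hz, current_ua = current_ua,
                     sample_rate = cfg$sample_rate,
                     duration_s = cfg$duration, potentials = list(pot))
    })
  })
  dplyr::bind_rows(rows)
}
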