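# Motor-evoked-potential quantification: rectified window means per trial,
# robust per-condition medians on a log scale, motor-threshold estimation,
# recruitment curves and the contra/ipsilateral log contrast.

# Mean of |samples| in [onset + w1, onset + w2) ms; half-open, inclusive
# start. Errors if the window overruns the sweep.
rectified_window_mean <- function(samples, stim_onset_s, sample_rate,
                                  window_ms = c(10, 30), blank_ms = NULL) {
  if (length(window_ms) != 2 || window_ms[2] <= window_ms[1]) {
    abort("`window_ms` must be (start, end) with end > start.")
  }
  n <- length(samples)
  t0 <- stim_onset_s + window_ms[1] / 1000
  t1 <- stim_onset_s + window_ms[2] / 1000
  # sample i sits at time (i-1)/fs; keep t0 <= time < t1
  i0 <- as.integer(ceiling(t0 * sample_rate + 1 - 1e-9))
  i1 <- as.integer(floor(t1 * sample_rate + 1 - 1e-9))
  if (i0 < 1L || i1 > n) {
    abort(sprintf("analysis window [%g, %g) ms overruns the %g ms sweep.",
                  window_ms[1], window_ms[2], 1000 * n / sample_rate))
  }
  idx <- i0:i1
  x <- samples
  if (!is.null(blank_ms)) {
    b0 <- floor((stim_onset_s + blank_ms[1] / 1000) * sample_rate) + 1L
    b1 <- ceiling((stim_onset_s + blank_ms[2] / 1000) * sample_rate)
    x[max(1L, b0):min(n, b1)] <- 0
  }
  mean(abs(x[idx]))
}

#' Per-trial rectified MEP window means
#'
#' For each sweep, computes the mean of the rectified (absolute-value)
#' EMG signal in a window after the first stimulation pulse (default
#' 10-30 ms, half-open with inclusive start). An optional blanking window
#' (e.g. `blank_ms = c(0, 8)`) zeroes any residual stimulation artifact
#' before averaging; it is off by default since sweeps are normally
#' artifact-truncated upstream.
#'
#' @param sweeps a sweep tibble (see [sim_mep_sweeps()] /
#'   [read_mep_sweeps_csv()]): needs list-column `samples` plus
#'   `stim_onset_s` and `sample_rate`.
#' @param window_ms analysis window in ms after the first pulse.
#' @param blank_ms optional (start, end) ms artifact-blanking window.
#' @return The sweep tibble with a `window_mean_mv` column added (the
#'   `samples` column is retained).
#' @export
mep_window_mean <- function(sweeps, window_ms = c(10, 30), blank_ms = NULL) {
  assert_columns(sweeps, c("samples", "stim_onset_s", "sample_rate"),
                 "sweep table")
  sweeps$window_mean_mv <- purrr::pmap_dbl(
    list(sweeps$samples, sweeps$stim_onset_s, sweeps$sample_rate),
    function(s, onset, fs) {
      rectified_window_mean(s, onset, fs, window_ms, blank_ms)
    })
  sweeps
}

#' Condition-level MEP amplitude (median across trials)
#'
#' The amplitude of a condition (animal x paw x hemisphere x intensity) is
#' the median of its per-trial rectified window means — robust to the
#' occasional contaminated trial — and analyses work on its natural
#' logarithm, so amplitude differences read as amplitude ratios. Even
#' trial counts take the mean of the middle two order statistics.
#'
#' @param sweeps a sweep tibble; `window_mean_mv` is computed first if
#'   absent.
#' @param window_ms,blank_ms passed to [mep_window_mean()] when needed.
#' @return A tibble with one row per condition: grouping columns,
#'   `n_trials`, `median_mv`, `log_amplitude` (`NA` with `zero_median =
#'   TRUE` when the median is not positive).
#' @export
mep_amplitude <- function(sweeps, window_ms = c(10, 30), blank_ms = NULL) {
  if (!"window_mean_mv" %in% names(sweeps)) {
    sweeps <- mep_window_mean(sweeps, window_ms, blank_ms)
  }
  grp <- intersect(c("animal_id", "paw", "hemisphere", "intensity"),
                   names(sweeps))
  out <- sweeps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     median_mv = median(.data$window_mean_mv),
                     .groups = "drop")
  if (any(out$n_trials < 2)) {
    abort("each condition needs at least 2 trials for a median amplitude.")
  }
  out$zero_median <- out$median_mv <= 0
  out$log_amplitude <- ifelse(out$zero_median, NA_real_, log(out$median_mv))
  if (any(out$zero_median)) {
    warn(sprintf("%d condition(s) have a non-positive median; log undefined.",
                 sum(out$zero_median)))
  }
  out
}

#' Estimate the motor threshold from a current ladder
#'
#' The motor threshold is the smallest tested current at which at least
#' 90 % of trials (ceiling rule: >= 18 of 20) produce a rectified window
#' mean above the noise floor (0.05 mV by default).
#'
#' @param trials tibble with one row per trial: a current column and a
#'   window-mean amplitude column.
#' @param current,amplitude column names (strings).
#' @param noise_floor amplitude floor in mV.
#' @param prop required proportion of supra-floor trials.
#' @return One-row tibble: `threshold_ma` (`NA` if no current qualifies)
#'   and `n_currents` tested.
#' @export
estimate_threshold <- function(trials, current = "current_ma",
                               amplitude = "window_mean_mv",
                               noise_floor = 0.05, prop = 0.9) {
  assert_columns(trials, c(current, amplitude), "threshold ladder")
  tab <- trials |>
    dplyr::group_by(current_val = .data[[current]]) |>
    dplyr::summarise(n = dplyr::n(),
                     n_above = sum(.data[[amplitude]] > noise_floor),
                     .groups = "drop") |>
    dplyr::arrange(.data$current_val)
  ok <- tab$n_above >= ceiling(prop * tab$n)
  tibble::tibble(
    threshold_ma = if (any(ok)) tab$current_val[which(ok)[1]] else NA_real_,
    n_currents = nrow(tab))
}

#' Recruitment curve across stimulation intensities
#'
#' Orders per-condition median amplitudes by intensity (typically 90, 100,
#' 120, 140, 200 % of motor threshold). Intensities in
#' `expected_intensities` that are absent from the data appear as rows
#' with `NA` amplitude and `present = FALSE`.
#'
#' @param amplitudes output of [mep_amplitude()] (or a sweep tibble, which
#'   is reduced first).
#' @param expected_intensities intensities that should be present.
#' @return A tibble sorted by intensity within condition: grouping
#'   columns, `intensity`, `median_mv`, `n_trials`, `present`.
#' @export
recruitment_curve <- function(amplitudes,
                              expected_intensities = c(90, 100, 120, 140, 200)) {
  if ("samples" %in% names(amplitudes)) amplitudes <- mep_amplitude(amplitudes)
  assert_columns(amplitudes, c("intensity", "median_mv"), "amplitude table")
  grp <- intersect(c("animal_id", "paw", "hemisphere"), names(amplitudes))
  amplitudes$present <- TRUE
  out <- amplitudes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    tidyr::complete(intensity = union(expected_intensities,
                                      unique(amplitudes$intensity)),
                    fill = list(present = FALSE)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "intensity"))))
  out[, c(grp, "intensity", "median_mv", "n_trials", "present",
          intersect(c("log_amplitude", "zero_median"), names(out)))]
}

#' Contra- vs ipsilateral log-amplitude contrast
#'
#' For each animal x paw x intensity present on both sides, the contrast
#' `log(median contra) - log(median ipsi)` — the log of the amplitude
#' ratio. Using the same recording electrode for both sides, this
#' controls for EMG-strength differences across animals.
#'
#' @param amplitudes output of [mep_amplitude()] containing a `hemisphere`
#'   column with values `"contra"` and `"ipsi"`.
#' @return A tibble with the grouping columns and `log_contrast`.
#' @export
contra_ipsi_log_contrast <- function(amplitudes) {
  assert_columns(amplitudes, c("hemisphere", "median_mv"), "amplitude table")
  grp <- intersect(c("animal_id", "paw", "intensity"), names(amplitudes))
  wide <- amplitudes |>
    dplyr::select(dplyr::all_of(c(grp, "hemisphere", "median_mv"))) |>
    tidyr::pivot_wider(names_from = "hemisphere", values_from = "median_mv")
  assert_columns(wide, c("contra", "ipsi"), "contrast table")
  wide <- wide[!is.na(wide$contra) & !is.na(wide$ipsi), ]
  if (any(wide$contra <= 0 | wide$ipsi <= 0)) {
    abort("log contrast needs positive median amplitudes on both sides.")
  }
  wide$log_contrast <- log(wide$contra) - log(wide$ipsi)
  wide
}
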