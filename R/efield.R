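# Intracranial electric-field dosimetry: recover the 2D field from
# potentials on a four-contact 1 mm lattice under sinusoidal stimulation,
# fit the current-to-field gain, and calibrate the stimulation current for
# a target field.

#' Contact positions of the recording lattice
#'
#' Channels `ch1..ch4` sit on a square planar lattice of 1 mm side:
#' ch1 = (0,0), ch2 = (1,0), ch3 = (0,1), ch4 = (1,1) mm.
#'
#' @param spacing_mm lattice side, mm.
#' @return Tibble with `channel`, `x_mm`, `y_mm`.
#' @export
lattice_positions <- function(spacing_mm = 1.0) {
  tibble::tibble(channel = paste0("ch", 1:4),
                 x_mm = c(0, spacing_mm, 0, spacing_mm),
                 y_mm = c(0, 0, spacing_mm, spacing_mm))
}

# Least-squares fit of offset + a*cos + b*sin at a known frequency over an
# integer number of cycles (trailing partial cycle discarded).
sinusoid_coeffs <- function(x, freq, sample_rate) {
  n <- length(x)
  samples_per_cycle <- sample_rate / freq
  n_cycles <- floor(n / samples_per_cycle)
  if (n_cycles < 1) {
    abort(sprintf(
      "record too short: %d samples hold no full cycle at %g Hz.", n, freq))
  }
  m <- floor(n_cycles * samples_per_cycle)
  t <- (0:(m - 1)) / sample_rate
  xc <- cos(2 * pi * freq * t)
  xs <- sin(2 * pi * freq * t)
  fit <- stats::lm.fit(cbind(1, xc, xs), x[1:m])
  c(offset = fit$coefficients[[1]], a = fit$coefficients[[2]],
    b = fit$coefficients[[3]])
}

#' Amplitude of a sinusoidal component
#'
#' Least-squares amplitude of the component at `freq` (fit of
#' sine + cosine + offset over an integer number of cycles; a trailing
#' partial cycle is discarded).
#'
#' @param x numeric series, volts.
#' @param freq component frequency, Hz.
#' @param sample_rate samples/s.
#' @return Amplitude in the units of `x` (>= 0).
#' @export
sinusoid_amplitude <- function(x, freq, sample_rate) {
  cf <- sinusoid_coeffs(x, freq, sample_rate)
  sqrt(cf[["a"]]^2 + cf[["b"]]^2)
}

#' 2D field from four lattice potentials
#'
#' Finite-difference estimate on the unit-square lattice: each component
#' is the mean of the two parallel pair differences divided by the 1 mm
#' spacing, with the physical sign convention E = -grad V (the field
#' points from high to low potential). Exact for any uniform (linear)
#' potential on the lattice.
#'
#' @param amplitudes signed potentials at `ch1..ch4`, volts (a named or
#'   positionally ordered length-4 vector; for sinusoidal stimulation use
#'   in-phase amplitudes, as [estimate_field()] does).
#' @param positions contact positions as from [lattice_positions()].
#' @return One-row tibble: `ex`, `ey`, `magnitude` (V/m).
#' @export
field_from_potentials <- function(amplitudes, positions = lattice_positions()) {
  if (length(amplitudes) != 4) abort("exactly 4 channel potentials required.")
  v <- as.numeric(amplitudes)
  d_m <- (positions$x_mm[2] - positions$x_mm[1]) * 1e-3
  ord <- order(positions$y_mm, positions$x_mm)
  v <- v[ord]   # v[1]=(0,0), v[2]=(1,0), v[3]=(0,1), v[4]=(1,1)
  ex <- -((v[2] - v[1]) + (v[4] - v[3])) / 2 / d_m
  ey <- -((v[3] - v[1]) + (v[4] - v[2])) / 2 / d_m
  tibble::tibble(ex = ex, ey = ey, magnitude = sqrt(ex^2 + ey^2))
}

#' Estimate the field for each recording
#'
#' For each recording, fits the sinusoidal component at the stimulation
#' frequency on every channel, forms the two pair-difference phasors along
#' each lattice axis, and reports the field components (signed along the
#' dominant stimulation phase) and the phase-insensitive magnitude.
#'
#' @param recordings a recording tibble (see [sim_field_recordings()] /
#'   [read_field_recordings_csv()]).
#' @param positions contact positions.
#' @return Tibble with one row per recording: `recording_id`,
#'   `frequency_hz`, `current_ua`, `ex`, `ey`, `magnitude` (V/m).
#' @export
estimate_field <- function(recordings, positions = lattice_positions()) {
  assert_columns(recordings,
                 c("frequency_hz", "current_ua", "sample_rate", "potentials"),
                 "recording table")
  d_m <- 1e-3
  rows <- purrr::pmap(
    list(recordings$potentials, recordings$frequency_hz,
         recordings$sample_rate),
    function(pot, freq, fs) {
      cf <- apply(pot, 2, sinusoid_coeffs, freq = freq, sample_rate = fs)
      ph <- cf[c("a", "b"), , drop = FALSE]   # 2 x 4 phasors
      ord <- order(positions$y_mm, positions$x_mm)
      ph <- ph[, ord, drop = FALSE]
      dx <- ((ph[, 2] - ph[, 1]) + (ph[, 4] - ph[, 3])) / 2
      dy <- ((ph[, 3] - ph[, 1]) + (ph[, 4] - ph[, 2])) / 2
      dom <- if (sum(dx^2) >= sum(dy^2)) dx else dy
      u <- dom / sqrt(sum(dom^2))
      if (!all(is.finite(u))) u <- c(1, 0)
      # the carrier phase is unobservable: orient it so the dominant
      # field component is positive
      if (-sum(dom * u) < 0) u <- -u
      tibble::tibble(ex = -sum(dx * u) / d_m, ey = -sum(dy * u) / d_m,
                     magnitude = sqrt(sum(dx^2) + sum(dy^2)) / d_m)
    })
  dplyr::bind_cols(
    recordings[, intersect(c("recording_id", "frequency_hz", "current_ua"),
                           names(recordings))],
    dplyr::bind_rows(rows))
}

#' Fit the current-to-field gain
#'
#' Per frequency, regresses field magnitude on stimulation current through
#' the origin (zero current produces zero field), the structure expected
#' when the field grows linearly with current. The slope is the gain in
#' (V/m)/uA; the RMS residual is reported as a linearity diagnostic.
#'
#' @param estimates output of [estimate_field()] (columns `frequency_hz`,
#'   `current_ua`, `magnitude`).
#' @return A `gain_fit` tibble: one row per frequency with `gain`,
#'   `fit_residual` (RMS, V/m), `n`, and an `estimates` list-column of the
#'   per-current points with their residuals.
#' @export
fit_gain <- function(estimates) {
  assert_columns(estimates, c("frequency_hz", "current_ua", "magnitude"),
                 "field estimates")
  out <- estimates |>
    dplyr::group_by(.data$frequency_hz) |>
    dplyr::group_modify(function(df, key) {
      gain <- sum(df$current_ua * df$magnitude) / sum(df$current_ua^2)
      df$residual <- df$magnitude - gain * df$current_ua
      tibble::tibble(gain = gain,
                     fit_residual = sqrt(mean(df$residual^2)),
                     n = nrow(df), estimates = list(df))
    }) |>
    dplyr::ungroup()
  class(out) <- c("gain_fit", class(out))
  out
}

#' Current needed to reach a target field
#'
#' Inverts the measured gain: `current = target_field / gain`. With the
#' montage gains in (V/m)/uA this yields the stimulation current in uA
#' for a target cortical field (e.g. 2 V/m).
#'
#' @param target_field target field magnitude, V/m (>= 0).
#' @param gain measured gain, (V/m)/uA (> 0).
#' @return Current in uA.
#' @export
calibrate_current <- function(target_field, gain) {
  assert_scalar_number(target_field, "target_field", min = 0)
  assert_scalar_number(gain, "gain")
  if (gain <= 0) abort("`gain` must be > 0 to calibrate a current.")
  target_field / gain
}

#' Flag outlier field measurements
#'
#' Marks points that sit off the per-frequency through-origin line.
#' Residuals are measured against a robust reference slope — the median of
#' the per-point magnitude/current ratios — so that a single gross outlier
#' cannot drag the line toward itself and mask the flag; a point is
#' flagged when its absolute residual exceeds `k` times the median
#' absolute residual (strict inequality, so a degenerate set with
#' identical residuals is never flagged). Optionally refits the
#' least-squares gain without the flagged points.
#'
#' @param estimates output of [estimate_field()].
#' @param k residual multiple (default 3).
#' @param refit if `TRUE`, also return the gain refit excluding flags.
#' @return `estimates` with `residual` and `outlier` columns; when
#'   `refit = TRUE`, a list with `estimates` and the refitted `gain_fit`.
#' @export
outlier_flag <- function(estimates, k = 3, refit = FALSE) {
  assert_columns(estimates, c("frequency_hz", "current_ua", "magnitude"),
                 "field estimates")
  flagged <- estimates |>
    dplyr::group_by(.data$frequency_hz) |>
    dplyr::mutate(residual = .data$magnitude -
                    median(.data$magnitude / .data$current_ua) *
                    .data$current_ua,
                  outlier = abs(.data$residual) >
                    k * median(abs(.data$residual))) |>
    dplyr::ungroup()
  if (!refit) return(flagged)
  clean <- flagged[!flagged$outlier, ]
  list(estimates = flagged, refit = fit_gain(clean))
}
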