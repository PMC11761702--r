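# Shared fixtures and independent oracles, built in code at test time.

# Build a single-trial pose tibble from an n x 10 digit-coordinate matrix
# (columns digit1_x..digit5_y). Wrist/pellet are filled with constants.
track_from_matrix <- function(m, trial_id = "t001", animal_id = "a01",
                              day = 1L, frame0 = 0L) {
  n <- nrow(m)
  frames <- frame0 + 0:(n - 1L)
  digit_rows <- purrr::map(1:5, function(i) {
    tibble::tibble(frame = frames, point = paste0("digit", i),
                   x = m[, 2 * i - 1], y = m[, 2 * i], likelihood = 1)
  })
  extra <- purrr::map(c("wrist", "pellet"), function(p) {
    tibble::tibble(frame = frames, point = p, x = 100, y = 100,
                   likelihood = 1)
  })
  dplyr::bind_cols(
    tibble::tibble(trial_id = trial_id, animal_id = animal_id,
                   day = day)[rep(1, n * 7L), ],
    dplyr::bind_rows(c(digit_rows, extra)))
}

# Embed a 50 x 10 waveform into constant padding at given 0-based center
# frames (centered alignment).
embed_waveform <- function(waveform, trial_len, centers, pad = NULL, ...) {
  if (is.null(pad)) pad <- waveform[1, ]
  m <- matrix(pad, trial_len, 10L, byrow = TRUE)
  colnames(m) <- colnames(waveform)
  for (ctr in centers) m[(ctr - 24L):(ctr + 25L), ] <- waveform
  track_from_matrix(m, ...)
}

# Brute-force sliding correlation oracle: stats::cor on every full
# window per coordinate, averaged, labelled by the window center frame.
brute_sliding_corr <- function(m, template_values) {
  n <- nrow(m)
  starts <- 1:(n - 49L)
  vals <- vapply(starts, function(s) {
    rs <- vapply(1:10, function(j) {
      w <- m[s:(s + 49L), j]
      tv <- template_values[, j]
      if (stats::sd(w) == 0 || stats::sd(tv) == 0) 0 else stats::cor(w, tv)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  tibble::tibble(frame = as.integer(starts - 1L + 25L), correlation = vals)
}

# n x 10 digit matrix of a single-trial pose tibble, for oracle use.
coords_of <- function(track) {
  pts <- paste0("digit", 1:5)
  frames <- sort(unique(track$frame))
  m <- do.call(cbind, lapply(pts, function(p) {
    sub <- track[track$point == p, ]
    sub <- sub[order(sub$frame), ]
    cbind(sub$x, sub$y)
  }))
  colnames(m) <- as.vector(t(outer(pts, c("x", "y"), paste, sep = "_")))
  m
}

# Deterministic MEP burst re-derived from the documented generator model,
# independent of the package internals.
oracle_burst <- function(t, cfg, peak_mv) {
  t0 <- cfg$stim_onset_s + cfg$response_latency / 1000
  dur <- cfg$response_duration / 1000
  ifelse(t >= t0 & t < t0 + dur,
         peak_mv * sin(2 * pi * cfg$burst_freq_hz * (t - t0)) *
           sin(pi * (t - t0) / dur)^2,
         0)
}

oracle_recruitment_peak <- function(cfg, intensity) {
  cfg$max_amplitude /
    (1 + exp(-cfg$recruitment_slope * (intensity - cfg$recruitment_midpoint) / 10))
}
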