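# Stereotypy scoring by normalized template matching: build a per-session
# 50-sample grab template from three grabs, slide a Pearson correlation
# along each trial (per digit coordinate, averaged over the 10
# coordinates), pick correlation peaks as grab events, and score the trial
# by the correlation at its final grab.

# 10-column matrix (digit1_x .. digit5_y) of one trial, rows ordered by
# frame. Frames must be contiguous per point.
digit_matrix <- function(track) {
  assert_columns(track, c("frame", "point", "x", "y"), "pose track")
  frames <- sort(unique(track$frame))
  cols <- purrr::map(DIGIT_POINTS, function(p) {
    sub <- track[track$point == p, ]
    if (nrow(sub) != length(frames)) {
      abort(sprintf("point '%s' missing from some frames.", p))
    }
    sub <- sub[order(sub$frame), ]
    cbind(sub$x, sub$y)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- DIGIT_COORDS
  attr(m, "frame0") <- frames[1]
  m
}

window_rows <- function(center_frame, frame0, n_frames, alignment) {
  start0 <- switch(alignment,
                   centered = center_frame - 25L,
                   start = center_frame)
  first <- start0 - frame0 + 1L
  if (first < 1L || first + TEMPLATE_LEN - 1L > n_frames) {
    abort(sprintf(
      "grab window [%d, %d) overruns the trial (frames %d..%d).",
      start0, start0 + TEMPLATE_LEN, frame0, frame0 + n_frames - 1L))
  }
  first:(first + TEMPLATE_LEN - 1L)
}

#' Extract a 50-sample grab window from a trial
#'
#' Returns the 10 digit-coordinate series over 50 samples (150 ms at
#' 309 fps) around `center_frame`. Under the default `"centered"`
#' alignment the center frame maps to sample 25 (0-based) of the window,
#' i.e. frames `[center-25, center+25)`; `"start"` places the window at
#' `[center, center+50)`.
#'
#' @param track a single-trial pose tibble.
#' @param center_frame 0-based frame index of the grab.
#' @param alignment `"centered"` (default) or `"start"`.
#' @return A 50 x 10 numeric matrix (columns `digit1_x .. digit5_y`).
#' @export
extract_grab_window <- function(track, center_frame,
                                alignment = c("centered", "start")) {
  alignment <- match.arg(alignment)
  m <- digit_matrix(track)
  rows <- window_rows(as.integer(center_frame), attr(m, "frame0"),
                      nrow(m), alignment)
  out <- m[rows, , drop = FALSE]
  attr(out, "frame0") <- NULL
  out
}

#' Build a grab template by averaging three grabs
#'
#' The canonical per-animal, per-session template is the element-wise mean
#' of three 50 x 10 grab windows, one from each of three trials.
#'
#' @param tracks list of three single-trial pose tibbles.
#' @param grab_frames integer vector of three grab center frames (same
#'   order as `tracks`).
#' @param animal_id,day identifiers stored on the template.
#' @param alignment window alignment, see [extract_grab_window()].
#' @return A `grab_template`: list with `values` (50 x 10 matrix),
#'   `animal_id`, `day`, `source_trials`.
#' @export
build_template <- function(tracks, grab_frames, animal_id = NA_character_,
                           day = NA_integer_,
                           alignment = c("centered", "start")) {
  alignment <- match.arg(alignment)
  if (length(tracks) < 3 || length(grab_frames) < 3) {
    abort("a template is the average of three grabs; supply 3 tracks and 3 frames.")
  }
  if (length(tracks) != length(grab_frames)) {
    abort("`tracks` and `grab_frames` must have equal length.")
  }
  windows <- purrr::map2(tracks, as.integer(grab_frames),
                         function(tr, f) extract_grab_window(tr, f, alignment))
  values <- Reduce(`+`, windows) / length(windows)
  if (!all(is.finite(values))) abort("template contains non-finite values.")
  src <- purrr::map_chr(tracks, function(tr) {
    if ("trial_id" %in% names(tr)) as.character(tr$trial_id[1]) else NA_character_
  })
  structure(list(values = values, animal_id = animal_id,
                 day = as.integer(day), source_trials = src),
            class = "grab_template")
}

#' @method print grab_template
#' @export
print.grab_template <- function(x, ...) {
  cat(sprintf("<grab_template> animal %s, day %s; 50 x 10; from trials: %s\n",
              x$animal_id, x$day,
              paste(x$source_trials, collapse = ", ")))
  invisible(x)
}

# Rolling Pearson correlation of each trial coordinate against the
# matching template column, via running sums; one value per valid window
# start. Zero-variance windows or template columns contribute 0.
rolling_pearson <- function(x, tpl) {
  n <- length(x)
  L <- TEMPLATE_LEN
  n_out <- n - L + 1L
  st <- sum(tpl)
  st2 <- sum(tpl^2)
  var_t <- st2 - st^2 / L
  cx <- c(0, cumsum(x))
  cx2 <- c(0, cumsum(x^2))
  s1 <- cx[(L + 1):(n + 1)] - cx[1:n_out]
  s2 <- cx2[(L + 1):(n + 1)] - cx2[1:n_out]
  # cross[i] = sum(x[i:(i+L-1)] * tpl) via one-sided convolution
  conv <- stats::filter(x, rev(tpl), method = "convolution", sides = 1)
  cross <- conv[L:n]
  var_x <- pmax(s2 - s1^2 / L, 0)
  denom <- sqrt(var_x * max(var_t, 0))
  num <- cross - s1 * st / L
  r <- ifelse(denom > 0, num / denom, 0)
  pmin(pmax(r, -1), 1)
}

#' Slide the template correlation along a trial
#'
#' At every alignment where the full 50-sample window fits, computes the
#' Pearson correlation between the trial window and the template for each
#' of the 10 digit coordinates and averages the 10 values. Alignments
#' whose window would overrun the trial edges are not emitted (no zero
#' padding), so a final peak can never be an edge artifact. A
#' zero-variance window or template coordinate contributes a correlation
#' of 0 for that alignment.
#'
#' @param track a single-trial pose tibble (>= 50 frames).
#' @param template a `grab_template` (or bare 50 x 10 matrix).
#' @param alignment frame labelling convention: `"centered"` (default)
#'   labels each window by its center frame (sample 25), `"start"` by its
#'   first frame.
#' @return A tibble with `frame` (0-based) and `correlation` in \[-1, 1\].
#' @export
sliding_correlation <- function(track, template,
                                alignment = c("centered", "start")) {
  alignment <- match.arg(alignment)
  values <- if (inherits(template, "grab_template")) template$values else template
  if (!identical(dim(values), c(50L, 10L))) {
    abort("template must be a 50 x 10 matrix.")
  }
  m <- digit_matrix(track)
  if (nrow(m) < TEMPLATE_LEN) {
    abort("trial shorter than the 50-sample template.")
  }
  per_coord <- vapply(seq_len(10L),
                      function(j) rolling_pearson(m[, j], values[, j]),
                      numeric(nrow(m) - TEMPLATE_LEN + 1L))
  avg <- rowMeans(per_coord)
  starts0 <- attr(m, "frame0") + 0:(nrow(m) - TEMPLATE_LEN)
  frame <- if (alignment == "centered") starts0 + 25L else starts0
  tibble::tibble(frame = as.integer(frame), correlation = avg)
}

#' Detect grab events from a correlation trace
#'
#' Grabs are local maxima of the averaged sliding correlation that exceed
#' `min_score`, kept greedily in descending score order subject to a
#' minimum separation (default one template length). The last surviving
#' peak in time is flagged as the final grab.
#'
#' @param corr tibble from [sliding_correlation()] (columns `frame`,
#'   `correlation`).
#' @param min_separation minimum frame distance between kept peaks.
#' @param min_score correlation threshold for a peak to count as a grab.
#' @return A tibble of events: `frame`, `score`, `is_final` (possibly
#'   empty).
#' @export
detect_grabs <- function(corr, min_separation = 50L, min_score = 0.3) {
  min_separation <- assert_count(min_separation, "min_separation", min = 1)
  assert_scalar_number(min_score, "min_score", min = -1, max = 1)
  empty <- tibble::tibble(frame = integer(), score = numeric(),
                          is_final = logical())
  if (is.null(corr) || nrow(corr) < 3) return(empty)
  v <- corr$correlation
  n <- length(v)
  i <- 2:(n - 1)
  is_peak <- v[i] >= v[i - 1] & v[i] > v[i + 1] & v[i] > min_score
  cand <- i[is_peak]
  if (length(cand) == 0) return(empty)
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer()
  for (idx in cand) {
    if (all(abs(corr$frame[idx] - corr$frame[kept]) >= min_separation)) {
      kept <- c(kept, idx)
    }
  }
  kept <- sort(kept)
  tibble::tibble(frame = corr$frame[kept], score = v[kept],
                 is_final = corr$frame[kept] == max(corr$frame[kept]))
}

#' Score the stereotypy of one trial
#'
#' The trial's stereotypy is the averaged correlation at its final
#' detected grab (the last correlation peak in the trial, which contains
#' the successful reach when there is one). Trials with no detected grab
#' get a missing score and are excluded from downstream statistics with a
#' logged count.
#'
#' @param track a single-trial pose tibble.
#' @param template a `grab_template`.
#' @param min_separation,min_score,alignment passed to
#'   [sliding_correlation()] and [detect_grabs()].
#' @param success optional logical trial outcome carried into the record.
#' @return A one-row tibble: `trial_id`, `animal_id`, `day`, `frame`,
#'   `score`, `success` (`frame`/`score` are `NA` when no grab was
#'   detected).
#' @export
stereotypy_score <- function(track, template, min_separation = 50L,
                             min_score = 0.3,
                             alignment = c("centered", "start"),
                             success = NA) {
  alignment <- match.arg(alignment)
  corr <- sliding_correlation(track, template, alignment)
  events <- detect_grabs(corr, min_separation, min_score)
  meta <- function(col, default) {
    if (col %in% names(track)) track[[col]][1] else default
  }
  final <- events[events$is_final, ]
  tibble::tibble(
    trial_id = as.character(meta("trial_id", NA_character_)),
    animal_id = as.character(meta("animal_id", NA_character_)),
    day = as.integer(meta("day", NA_integer_)),
    frame = if (nrow(final)) final$frame else NA_integer_,
    score = if (nrow(final)) final$score else NA_real_,
    success = as.logical(success))
}

#' Score every trial of a cohort against a template
#'
#' Convenience wrapper mapping [stereotypy_score()] over all trials in a
#' multi-trial pose tibble; reports how many trials had no detectable
#' grab.
#'
#' @param tracks a pose tibble with a `trial_id` column.
#' @param template a `grab_template`.
#' @param outcomes optional tibble (`trial_id`, `success`) joined onto the
#'   records.
#' @inheritParams stereotypy_score
#' @return A tibble of stereotypy records, one row per trial.
#' @export
score_trials <- function(tracks, template, min_separation = 50L,
                         min_score = 0.3,
                         alignment = c("centered", "start"),
                         outcomes = NULL) {
  alignment <- match.arg(alignment)
  assert_columns(tracks, "trial_id", "pose table")
  recs <- tracks |>
    dplyr::group_split(.data$trial_id) |>
    purrr::map(stereotypy_score, template = template,
               min_separation = min_separation, min_score = min_score,
               alignment = alignment) |>
    dplyr::bind_rows()
  if (!is.null(outcomes)) {
    recs$success <- NULL
    recs <- dplyr::left_join(recs, outcomes[, c("trial_id", "success")],
                             by = "trial_id")
  }
  n_missing <- sum(is.na(recs$score))
  if (n_missing > 0) {
    inform(sprintf("%d of %d trials had no detectable grab (score = NA).",
                   n_missing, nrow(recs)))
  }
  recs
}

#' Bootstrap a session template from the data
#'
#' When no grab frames are hand-picked, the session template is seeded
#' from a cross-trial average (the window at each trial's peak digit
#' speed), then refined: the seed is slid along the first trials and the
#' best-scoring grab from each of the first three trials with a detected
#' grab forms the final three-grab average. The selection is recorded in
#' the returned template's `source_trials`.
#'
#' @param tracks a multi-trial pose tibble.
#' @inheritParams score_trials
#' @return A `grab_template`.
#' @export
session_template <- function(tracks, min_separation = 50L, min_score = 0.3,
                             alignment = c("centered", "start")) {
  alignment <- match.arg(alignment)
  trials <- dplyr::group_split(tracks, .data$trial_id)
  # seed: average window at each trial's peak digit displacement
  seed_windows <- purrr::compact(purrr::map(trials, function(tr) {
    m <- digit_matrix(tr)
    speed <- rowSums(abs(diff(m)))
    ctr <- which.max(speed) + attr(m, "frame0") - 1L
    lo <- attr(m, "frame0") + 25L
    hi <- attr(m, "frame0") + nrow(m) - 26L
    ctr <- min(max(ctr, lo), hi)
    tryCatch(extract_grab_window(tr, ctr, alignment), error = function(e) NULL)
  }))
  if (length(seed_windows) == 0) abort("no usable trials for a seed template.")
  seed <- Reduce(`+`, seed_windows) / length(seed_windows)
  picks <- list()
  for (tr in trials) {
    ev <- detect_grabs(sliding_correlation(tr, seed, alignment),
                       min_separation, min_score)
    if (nrow(ev) > 0) {
      best <- ev[which.max(ev$score), ]
      picks[[length(picks) + 1L]] <- list(track = tr, frame = best$frame)
    }
    if (length(picks) == 3L) break
  }
  if (length(picks) < 3L) {
    abort("fewer than 3 trials with a detected grab; cannot build a session template.")
  }
  build_template(purrr::map(picks, "track"),
                 purrr::map_int(picks, "frame"),
                 animal_id = if ("animal_id" %in% names(tracks))
                   as.character(tracks$animal_id[1]) else NA_character_,
                 day = if ("day" %in% names(tracks))
                   as.integer(tracks$day[1]) else NA_integer_,
                 alignment = alignment)
}
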