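#' Read a markerless pose-tracking CSV
#'
#' Parses the three-header-row pose CSV dialect emitted by markerless
#' tracking software (row 1 `scorer`, row 2 `bodyparts`, row 3 `coords`,
#' then one row per frame with a leading frame index and an `x`, `y`,
#' `likelihood` triplet per body part). Body parts are mapped to the
#' canonical seven-point order (`digit1..digit5`, `wrist`, `pellet`); a
#' missing `likelihood` column is tolerated and filled with 1.0.
#'
#' @param path CSV file path.
#' @param trial_id,animal_id,day identifiers attached to the rows (the
#'   dialect itself carries none).
#' @return A pose tibble: one row per frame per point with columns
#'   `trial_id`, `animal_id`, `day`, `frame` (0-based), `point`, `x`, `y`,
#'   `likelihood`.
#' @export
read_pose_csv <- function(path, trial_id = NA_character_,
                          animal_id = NA_character_, day = NA_integer_) {
  if (!file.exists(path)) abort(sprintf("pose file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 4) abort("pose CSV needs 3 header rows plus data.")
  cells <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf("ragged pose CSV: line %d has %d fields, expected %d.",
                  bad, widths[bad], widths[1]))
  }
  header <- cells[1:3]
  if (tolower(header[[2]][1]) != "bodyparts" ||
      tolower(header[[3]][1]) != "coords") {
    abort("not a pose CSV: expected 'bodyparts' and 'coords' header rows.")
  }
  parts <- header[[2]][-1]
  coords <- tolower(header[[3]][-1])
  unknown <- setdiff(unique(parts), POSE_POINTS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown body-part label(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(POSE_POINTS, unique(parts))
  if (length(missing) > 0) {
    abort(sprintf("pose CSV missing body part(s): %s",
                  paste(missing, collapse = ", ")))
  }
  data <- do.call(rbind, lapply(cells[-(1:3)], as.numeric))
  frame <- as.integer(data[, 1])
  cols <- purrr::map(POSE_POINTS, function(p) {
    ix <- which(parts == p & coords == "x") + 1L
    iy <- which(parts == p & coords == "y") + 1L
    il <- which(parts == p & coords == "likelihood") + 1L
    if (length(ix) != 1L || length(iy) != 1L) {
      abort(sprintf("body part '%s' needs exactly one x and one y column.", p))
    }
    tibble::tibble(
      frame = frame, point = p,
      x = data[, ix], y = data[, iy],
      likelihood = if (length(il) == 1L) data[, il] else rep(1.0, length(frame)))
  })
  out <- dplyr::bind_rows(cols)
  if (any(out$likelihood < 0 | out$likelihood > 1, na.rm = TRUE)) {
    abort("likelihood values must lie in [0, 1].")
  }
  dplyr::bind_cols(
    tibble::tibble(trial_id = trial_id, animal_id = animal_id,
                   day = day)[rep(1, nrow(out)), ],
    out)
}

#' @rdname read_pose_csv
#' @param track a single-trial pose tibble (as from [read_pose_csv()] or
#'   [sim_pose_trials()]).
#' @param scorer label written in the first header row.
#' @export
write_pose_csv <- function(track, path, scorer = "reachmetrics") {
  assert_columns(track, c("frame", "point", "x", "y", "likelihood"),
                 "pose track")
  if ("trial_id" %in% names(track) &&
      length(unique(track$trial_id)) > 1L) {
    abort("write_pose_csv() writes a single trial; got several trial_id values.")
  }
  frames <- sort(unique(track$frame))
  blocks <- purrr::map(POSE_POINTS, function(p) {
    sub <- track[track$point == p, ]
    sub <- sub[order(sub$frame), ]
    if (!identical(as.integer(sub$frame), as.integer(frames))) {
      abort(sprintf("point '%s' does not cover every frame.", p))
    }
    cbind(sub$x, sub$y, sub$likelihood)
  })
  mat <- do.call(cbind, blocks)
  h1 <- c("scorer", rep(scorer, ncol(mat)))
  h2 <- c("bodyparts", rep(POSE_POINTS, each = 3))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), times = 7))
  body <- cbind(format(frames, scientific = FALSE, trim = TRUE),
                matrix(formatC(mat, format = "g", digits = 15), nrow(mat)))
  lines <- c(paste(h1, collapse = ","), paste(h2, collapse = ","),
             paste(h3, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Median-filter the coordinate traces of a pose track
#'
#' Replaces each point's `x` and `y` series by a running median (default
#' 5 samples, i.e. 15 ms at 309 fps), the standard despiking step for
#' markerless-tracking output. Edges are handled by shrinking the window;
#' series length and point count are preserved. Likelihood is untouched.
#'
#' @param track a pose tibble (one or more trials).
#' @param window odd window length in samples.
#' @return The filtered pose tibble.
#' @export
median_filter_track <- function(track, window = 5L) {
  window <- assert_count(window, "window", min = 1)
  if (window %% 2L == 0L) abort("`window` must be odd.")
  assert_columns(track, c("frame", "point", "x", "y"), "pose track")
  if (window == 1L) return(track)
  grp <- intersect(c("trial_id", "point"), names(track))
  track |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(x = running_median(.data$x, window),
                  y = running_median(.data$y, window)) |>
    dplyr::ungroup()
}

#' Mirror left-pawed trials horizontally
#'
#' Left-pawed animals' videos are flipped so one tracking model and one
#' grab template serve all animals. If `paw` is `"left"`, every x
#' coordinate becomes `image_width - 1 - x` (0-based pixel convention);
#' y is unchanged. Right-pawed tracks pass through untouched.
#'
#' @param track a pose tibble.
#' @param paw `"left"` or `"right"`.
#' @param image_width frame width in pixels (default 2032, the recording
#'   resolution the defaults emulate).
#' @return The (possibly mirrored) pose tibble.
#' @export
mirror_if_left <- function(track, paw, image_width = 2032) {
  paw <- match.arg(paw, c("left", "right"))
  assert_scalar_number(image_width, "image_width", min = 1)
  if (paw == "right") return(track)
  dplyr::mutate(track, x = image_width - 1 - .data$x)
}

#' Determine paw preference from shaping reaches
#'
#' Applies the shaping rule: over the first 10 observed reaches, the paw
#' used at least 6 times is the preferred paw. A 5-5 split returns
#' `"undetermined"`; shaping should then be extended.
#'
#' @param reach_sides character vector of `"left"`/`"right"`, at least 10
#'   entries (only the first 10 are used).
#' @return `"left"`, `"right"` or `"undetermined"`.
#' @export
paw_preference <- function(reach_sides) {
  if (length(reach_sides) < 10) {
    abort("need at least 10 shaping reaches to call paw preference.")
  }
  first10 <- reach_sides[1:10]
  bad <- setdiff(unique(first10), c("left", "right"))
  if (length(bad) > 0) {
    abort(sprintf("unknown side value(s): %s", paste(bad, collapse = ", ")))
  }
  n_right <- sum(first10 == "right")
  if (n_right >= 6) "right" else if (n_right <= 4) "left" else "undetermined"
}

#' Read or write a flat learning/outcome table
#'
#' Flat CSV with columns `animal_id`, `day`, `group`, `paw`, `successes`,
#' `attempts` (extra columns are preserved).
#'
#' @param table a learning tibble.
#' @param path CSV file path.
#' @export
write_learning_csv <- function(table, path) {
  assert_columns(table, c("animal_id", "day", "successes", "attempts"),
                 "learning table")
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_learning_csv
#' @export
read_learning_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_columns(out, c("animal_id", "day", "successes", "attempts"),
                 "learning table")
  if ("group" %in% names(out)) {
    out$group <- factor(out$group, levels = c("control", "anodal"))
  }
  out$day <- as.integer(out$day)
  out
}
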