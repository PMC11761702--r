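# Plain-text containers for sweeps, field recordings, templates and
# stereotypy records: long-format CSV with metadata columns, written at
# full double precision so read(write(x)) is value-exact to formatting
# precision.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_long_csv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write MEP sweeps as long CSV
#'
#' One row per sample with sweep metadata repeated: `animal_id`, `paw`,
#' `hemisphere`, `intensity`, `trial_index`, `stim_onset_s`,
#' `sample_rate`, `sample` (1-based index), `value_mv`. The reader nests
#' samples back into the list-column layout of [sim_mep_sweeps()].
#'
#' @param sweeps a sweep tibble with a `samples` list-column.
#' @param path CSV file path.
#' @export
write_mep_sweeps_csv <- function(sweeps, path) {
  assert_columns(sweeps, c("animal_id", "paw", "hemisphere", "intensity",
                           "trial_index", "stim_onset_s", "sample_rate",
                           "samples"), "sweep table")
  long <- sweeps |>
    dplyr::mutate(sample = purrr::map(.data$samples, seq_along)) |>
    tidyr::unnest(c("samples", "sample")) |>
    dplyr::rename(value_mv = "samples")
  write_long_csv(long, path)
}

#' @rdname write_mep_sweeps_csv
#' @export
read_mep_sweeps_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  long <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_columns(long, c("animal_id", "paw", "hemisphere", "intensity",
                         "trial_index", "stim_onset_s", "sample_rate",
                         "sample", "value_mv"), "sweep CSV")
  long |>
    dplyr::arrange(.data$animal_id, .data$paw, .data$hemisphere,
                   .data$intensity, .data$trial_index, .data$sample) |>
    dplyr::group_by(.data$animal_id, .data$paw, .data$hemisphere,
                    .data$intensity, .data$trial_index,
                    .data$stim_onset_s, .data$sample_rate) |>
    dplyr::summarise(samples = list(.data$value_mv), .groups = "drop")
}

#' Read or write field recordings as long CSV
#'
#' One row per sample per channel: `recording_id`, `frequency_hz`,
#' `current_ua`, `sample_rate`, `duration_s`, `channel` (`ch1..ch4`),
#' `sample`, `value_v`. The reader rebuilds the (samples x 4) potential
#' matrices of [sim_field_recordings()].
#'
#' @param recordings a recording tibble with a `potentials` list-column.
#' @param path CSV file path.
#' @export
write_field_recordings_csv <- function(recordings, path) {
  assert_columns(recordings, c("recording_id", "frequency_hz", "current_ua",
                               "sample_rate", "duration_s", "potentials"),
                 "recording table")
  long <- recordings |>
    dplyr::mutate(long = purrr::map(.data$potentials, function(m) {
      tibble::tibble(channel = rep(colnames(m), each = nrow(m)),
                     sample = rep(seq_len(nrow(m)), times = ncol(m)),
                     value_v = as.vector(m))
    })) |>
    dplyr::select(-"potentials") |>
    tidyr::unnest("long")
  write_long_csv(long, path)
}

#' @rdname write_field_recordings_csv
#' @export
read_field_recordings_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  long <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_columns(long, c("recording_id", "frequency_hz", "current_ua",
                         "sample_rate", "duration_s", "channel", "sample",
                         "value_v"), "recording CSV")
  long |>
    dplyr::group_by(.data$recording_id, .data$frequency_hz,
                    .data$current_ua, .data$sample_rate, .data$duration_s) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df, names_from = "channel",
                                 values_from = "value_v")
      wide <- wide[order(wide$sample), ]
      m <- as.matrix(wide[, paste0("ch", 1:4)])
      tibble::tibble(potentials = list(m))
    }) |>
    dplyr::ungroup()
}

#' Read or write a grab-template archive as CSV
#'
#' Long CSV holding one or more templates: `animal_id`, `day`,
#' `source_trials` (`;`-separated), `sample` (1..50), `coord`
#' (`digit1_x..digit5_y`), `value`.
#'
#' @param templates a `grab_template` or list of them.
#' @param path CSV file path.
#' @export
write_templates_csv <- function(templates, path) {
  if (inherits(templates, "grab_template")) templates <- list(templates)
  long <- purrr::map(templates, function(tp) {
    tibble::tibble(animal_id = tp$animal_id, day = tp$day,
                   source_trials = paste(tp$source_trials, collapse = ";"),
                   sample = rep(seq_len(TEMPLATE_LEN), times = 10L),
                   coord = rep(DIGIT_COORDS, each = TEMPLATE_LEN),
                   value = as.vector(tp$values))
  }) |>
    dplyr::bind_rows()
  write_long_csv(long, path)
}

#' @rdname write_templates_csv
#' @export
read_templates_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  long <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_columns(long, c("animal_id", "day", "source_trials", "sample",
                         "coord", "value"), "template CSV")
  long |>
    dplyr::group_split(.data$animal_id, .data$day) |>
    purrr::map(function(df) {
      m <- matrix(NA_real_, TEMPLATE_LEN, 10L,
                  dimnames = list(NULL, DIGIT_COORDS))
      m[cbind(df$sample, match(df$coord, DIGIT_COORDS))] <- df$value
      structure(list(values = m, animal_id = df$animal_id[1],
                     day = as.integer(df$day[1]),
                     source_trials = strsplit(df$source_trials[1], ";",
                                              fixed = TRUE)[[1]]),
                class = "grab_template")
    })
}

#' Write per-trial stereotypy records as CSV
#'
#' Flat CSV with `trial_id`, `animal_id`, `day`, `frame`, `score`,
#' `success`.
#'
#' @param records output of [score_trials()].
#' @param path CSV file path.
#' @export
write_stereotypy_csv <- function(records, path) {
  assert_columns(records, c("trial_id", "animal_id", "day", "frame",
                            "score", "success"), "stereotypy records")
  write_long_csv(records, path)
}

#' @rdname write_stereotypy_csv
#' @export
read_stereotypy_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_columns(out, c("trial_id", "animal_id", "day", "frame", "score",
                        "success"), "stereotypy CSV")
  out
}
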