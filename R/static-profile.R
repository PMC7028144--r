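# Static segmentation of ordered cortical cell-length profiles into
# meristem / rapid-elongation / mature zones, and the derived anatomy
# statistics (meristem cell number and length, mature cell length).

#' Locate the onset of rapid elongation in a cell-length profile
#'
#' Applies the cell-length doubling rule: the first cell of the rapid
#' elongation zone is the first cell at least twice as long as its
#' predecessor *and* followed by a longer cell (the second condition skips
#' recently divided cells).
#'
#' @param lengths Ordered cell lengths in um, cell 1 being the first cell
#'   after the cortex/endodermis initial.
#' @param id Optional profile label used in error messages.
#' @return The 1-based index of the first rapid-elongation-zone cell.
#' @export
detect_elongation_onset <- function(lengths, id = NULL) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 3L) {
    stop_rootkin("at least 3 cells are required to detect the elongation onset",
                 "rootkin_error_insufficient_data")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop_rootkin("cell lengths must be positive and finite", "rootkin_error_domain")
  }
  n <- length(lengths)
  for (i in 2:(n - 1L)) {
    if (lengths[i] >= 2 * lengths[i - 1L] && lengths[i + 1L] > lengths[i]) {
      return(i)
    }
  }
  stop_rootkin(
    paste0("no elongation onset found", if (!is.null(id)) paste0(" in profile ", id),
           ": no cell doubles its predecessor with a longer successor"),
    "rootkin_error_segmentation"
  )
}

#' Locate the onset of the mature zone
#'
#' The first mature cell is the first cell past the elongation onset whose
#' successor is at most `(1 + tol)` times its own length, i.e. where
#' elongation has effectively ceased. At least five cells must remain at and
#' after the onset so that the mature cell length can be averaged.
#'
#' @inheritParams detect_elongation_onset
#' @param onset Elongation onset index from [detect_elongation_onset()].
#' @param tol Ratio tolerance defining "approximately the same length"
#'   (default 0.05).
#' @return The 1-based index of the first mature-zone cell.
#' @export
detect_maturation_onset <- function(lengths, onset, tol = 0.05, id = NULL) {
  lengths <- as.numeric(lengths)
  n <- length(lengths)
  if (!is.numeric(onset) || onset < 2 || onset >= n) {
    stop_rootkin("`onset` must be a valid elongation-onset index", "rootkin_error_parameter")
  }
  last_candidate <- n - 4L # 5 cells must remain at and after the onset
  if (last_candidate > onset) {
    for (i in (onset + 1L):last_candidate) {
      if (lengths[i + 1L] <= (1 + tol) * lengths[i]) {
        return(i)
      }
    }
  }
  stop_rootkin(
    paste0("no maturation onset found", if (!is.null(id)) paste0(" in profile ", id),
           ": no cell matches its successor within ", tol * 100,
           "% with 5 cells remaining"),
    "rootkin_error_segmentation"
  )
}

#' Mature cell length of a profile
#'
#' The arithmetic mean of the first five cells of the mature zone.
#'
#' @inheritParams detect_maturation_onset
#' @param maturation_onset Index of the first mature cell.
#' @return Mean mature cell length, um.
#' @export
mature_cell_length <- function(lengths, maturation_onset) {
  lengths <- as.numeric(lengths)
  if (maturation_onset + 4L > length(lengths)) {
    stop_rootkin("fewer than 5 cells at and after the maturation onset",
                 "rootkin_error_insufficient_data")
  }
  mean(lengths[maturation_onset:(maturation_onset + 4L)])
}

#' Segment cortical cell files into root zones
#'
#' Applies [detect_elongation_onset()] and [detect_maturation_onset()] to each
#' cell file of a tidy cell-length table and extracts the static anatomy
#' statistics. Segmentation failures are recorded per file, not raised, so a
#' batch never aborts on a single difficult profile.
#'
#' @param cell_files A data frame with columns `root_id`, `file_side`,
#'   `cell_index`, `length_um` and optionally `qc_offset_um` (as written by
#'   [simulate_cohort()] or read from `cellfile.csv`).
#' @param tol Ratio tolerance for the maturation rule.
#' @param qc_offset Default distance (um) from the QC to the first cell, used
#'   when the table has no `qc_offset_um` column. The meristem length includes
#'   this offset.
#' @param median_filter If `TRUE`, run the *detection* rules on a 3-cell
#'   running-median of the profile (statistics are always computed from raw
#'   lengths). Off by default, matching manual practice.
#' @return A tibble with one row per (root, file): onset indices, meristem
#'   cell count and length, mature cell length, `segmented` flag and
#'   `failure` message for files the rules could not segment.
#' @export
segment_cell_file <- function(cell_files, tol = 0.05, qc_offset = 0,
                              median_filter = FALSE) {
  req <- c("root_id", "file_side", "cell_index", "length_um")
  missing_cols <- setdiff(req, names(cell_files))
  if (length(missing_cols) > 0) {
    stop_rootkin(paste0("`cell_files` is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "rootkin_error_schema")
  }
  cell_files %>%
    dplyr::group_by(.data$root_id, .data$file_side) %>%
    dplyr::arrange(.data$cell_index, .by_group = TRUE) %>%
    dplyr::group_modify(function(df, key) {
      offset <- if ("qc_offset_um" %in% names(df)) df$qc_offset_um[1] else qc_offset
      segment_one_file(df$length_um, tol, offset, median_filter,
                       id = paste(key$root_id, key$file_side))
    }) %>%
    dplyr::ungroup()
}

segment_one_file <- function(lengths, tol, qc_offset, median_filter, id = NULL) {
  fail <- function(msg) {
    tibble::tibble(
      n_cells = length(lengths),
      elongation_onset_index = NA_integer_,
      maturation_onset_index = NA_integer_,
      meristem_cell_count = NA_integer_,
      meristem_length_um = NA_real_,
      mature_cell_length_um = NA_real_,
      segmented = FALSE,
      failure = msg
    )
  }
  if (length(lengths) < 8L) {
    return(fail("fewer than 8 cells; segmentation not attempted"))
  }
  detect <- if (median_filter) stats::runmed(lengths, 3L) else lengths
  onset <- tryCatch(detect_elongation_onset(detect, id = id), error = identity)
  if (inherits(onset, "error")) return(fail(conditionMessage(onset)))
  mat <- tryCatch(detect_maturation_onset(detect, onset, tol = tol, id = id),
                  error = identity)
  if (inherits(mat, "error")) return(fail(conditionMessage(mat)))
  tibble::tibble(
    n_cells = length(lengths),
    elongation_onset_index = as.integer(onset),
    maturation_onset_index = as.integer(mat),
    meristem_cell_count = as.integer(onset - 1L),
    meristem_length_um = qc_offset + sum(lengths[seq_len(onset - 1L)]),
    mature_cell_length_um = mature_cell_length(lengths, mat),
    segmented = TRUE,
    failure = NA_character_
  )
}

#' Average left and right cell files per seedling
#'
#' Each scalar statistic is the arithmetic mean of the values from the
#' seedling's segmented files (normally the left and right cortical files).
#' If only one file of a pair segmented successfully its values are used
#' alone and the row is flagged as partial.
#'
#' @param file_summaries Output of [segment_cell_file()].
#' @return A tibble with one row per `root_id`: `meristem_cells`,
#'   `meristem_length_um`, `elongation_onset_index`, `maturation_onset_index`,
#'   `mature_cell_length_um`, `n_files_used`, `partial`.
#' @export
summarize_seedling <- function(file_summaries) {
  file_summaries %>%
    dplyr::group_by(.data$root_id) %>%
    dplyr::summarise(
      meristem_cells = mean(.data$meristem_cell_count[.data$segmented]),
      meristem_length_um = mean(.data$meristem_length_um[.data$segmented]),
      elongation_onset_index = mean(.data$elongation_onset_index[.data$segmented]),
      maturation_onset_index = mean(.data$maturation_onset_index[.data$segmented]),
      mature_cell_length_um = mean(.data$mature_cell_length_um[.data$segmented]),
      n_files_used = sum(.data$segmented),
      partial = sum(.data$segmented) < dplyr::n(),
      .groups = "drop"
    )
}
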