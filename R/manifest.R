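manifest_cols <- c("subject_id", "visit_index", "story_index", "topic",
                   "label", "audio_path", "transcript_path")

#' Read a story manifest
#'
#' A manifest is a CSV with one row per story and columns `subject_id`,
#' `visit_index`, `story_index`, `topic`, `label`, `audio_path`,
#' `transcript_path`. Audio and transcript paths are interpreted relative to
#' the manifest location (or `root`). Labels are parsed case-insensitively
#' ("HC" vs "MCI"/"AD"/"IMPAIRED") into integer 0/1.
#'
#' @param path Path to the manifest CSV.
#' @param root Directory that relative paths are resolved against; defaults
#'   to the manifest's directory.
#' @param load_transcripts If `TRUE` (default), each transcript JSON is read
#'   into a `transcript` list-column of tibbles (see
#'   [read_timed_transcript()]).
#' @return A tibble of stories, one row per story, with parsed integer
#'   `label` and resolved paths; label consistency within each
#'   (subject, visit) is enforced.
#' @export
read_story_manifest <- function(path, root = dirname(path), load_transcripts = TRUE) {
  if (!file.exists(path)) abort(paste0("Manifest not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    visit_index = readr::col_integer(),
    story_index = readr::col_integer(),
    topic = readr::col_character(),
    label = readr::col_character(),
    audio_path = readr::col_character(),
    transcript_path = readr::col_character()
  ), progress = FALSE)
  assert_cols(df, manifest_cols, "Manifest")
  df$label <- parse_label(df$label)

  bad <- df |>
    dplyr::summarise(n_labels = dplyr::n_distinct(.data$label),
                     .by = c("subject_id", "visit_index")) |>
    dplyr::filter(.data$n_labels > 1)
  if (nrow(bad) > 0) {
    abort(paste0("Inconsistent labels within (subject, visit): ",
                 paste(paste0(bad$subject_id, "/v", bad$visit_index), collapse = ", ")))
  }
  if (any(df$visit_index < 1) || any(df$story_index < 1)) {
    abort("visit_index and story_index must be 1-based positive integers")
  }

  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p), p, file.path(root, p))
  df$audio_path <- resolve(df$audio_path)
  df$transcript_path <- resolve(df$transcript_path)
  df <- df[order(df$subject_id, df$visit_index, df$story_index), ]

  if (load_transcripts) {
    df$transcript <- lapply(df$transcript_path, function(p) {
      if (is.na(p) || p == "") NULL else read_timed_transcript(p)
    })
  }
  tibble::as_tibble(df)
}

#' Write a story manifest
#'
#' Writes the canonical manifest CSV (fixed column order, labels as strings,
#' stable formatting): a write/read/write cycle is byte-identical.
#'
#' @param stories Story tibble (as returned by [read_story_manifest()] or
#'   [simulate_cohort()]); extra columns are dropped.
#' @param path Output CSV path.
#' @param rel_to Directory to relativize audio/transcript paths against
#'   (default: the manifest's directory); pass `NULL` to keep paths as-is.
#' @return `path`, invisibly.
#' @export
write_story_manifest <- function(stories, path, rel_to = dirname(path)) {
  assert_cols(stories, setdiff(manifest_cols, "label"), "Story table")
  if (!("label" %in% names(stories))) abort("Story table is missing required column(s): label")
  out <- stories[, manifest_cols[manifest_cols %in% names(stories)]]
  out <- out[order(out$subject_id, out$visit_index, out$story_index), ]
  if (is.numeric(out$label)) out$label <- format_label(out$label)
  if (!is.null(rel_to)) {
    strip <- function(p) {
      pref <- paste0(sub("/*$", "", rel_to), "/")
      ifelse(startsWith(p, pref), substring(p, nchar(pref) + 1L), p)
    }
    out$audio_path <- strip(out$audio_path)
    out$transcript_path <- strip(out$transcript_path)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate longitudinal completeness of a story table
#'
#' Longitudinal modeling requires every subject to have at least one story at
#' every visit `1..visits` and a single label per (subject, visit). This
#' reports violations rather than raising, so incomplete cohorts can be
#' inspected and filtered.
#'
#' @param stories Story tibble.
#' @param visits Number of visits required per subject (default: the maximum
#'   visit index present).
#' @return A tibble of violations with columns `subject_id`, `visit_index`,
#'   `issue`; zero rows when the dataset is longitudinal-complete.
#' @export
validate_longitudinal <- function(stories, visits = max(stories$visit_index)) {
  assert_cols(stories, c("subject_id", "visit_index", "label"), "Story table")
  subjects <- unique(stories$subject_id)
  grid <- tidyr::expand_grid(subject_id = subjects, visit_index = seq_len(visits))
  present <- dplyr::distinct(stories, .data$subject_id, .data$visit_index)
  missing <- dplyr::anti_join(grid, present, by = c("subject_id", "visit_index"))
  viol <- tibble::tibble(
    subject_id = missing$subject_id,
    visit_index = as.integer(missing$visit_index),
    issue = "missing visit"
  )
  incons <- stories |>
    dplyr::summarise(n_labels = dplyr::n_distinct(.data$label),
                     .by = c("subject_id", "visit_index")) |>
    dplyr::filter(.data$n_labels > 1)
  if (nrow(incons) > 0) {
    viol <- dplyr::bind_rows(viol, tibble::tibble(
      subject_id = incons$subject_id,
      visit_index = as.integer(incons$visit_index),
      issue = "inconsistent labels"
    ))
  }
  dplyr::arrange(viol, .data$subject_id, .data$visit_index)
}
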