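#' Read a timed transcript
#'
#' Reads the JSON dialect emitted by timestamped ASR tools: a top-level
#' `"segments"` array of objects with `"start"`, `"end"` and `"text"` fields
#' (seconds and character text). Segments are returned sorted by start time;
#' each ASR segment is treated as one utterance downstream.
#'
#' @param path Path to a transcript JSON file.
#' @return A tibble with columns `start`, `end` (seconds) and `text`,
#'   sorted by `start`. May have zero rows (downstream feature extractors
#'   reject empty transcripts).
#' @export
read_timed_transcript <- function(path) {
  if (!file.exists(path)) abort(paste0("Transcript file not found: ", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!("segments" %in% names(obj))) {
    abort(paste0("Transcript JSON has no top-level \"segments\" key: ", path))
  }
  seg <- obj$segments
  if (is.null(seg) || (is.data.frame(seg) && nrow(seg) == 0) || length(seg) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(), text = character()))
  }
  if (!is.data.frame(seg)) seg <- as.data.frame(seg, stringsAsFactors = FALSE)
  assert_cols(seg, c("start", "end", "text"), "Transcript \"segments\"")
  tr <- tibble::tibble(
    start = as.numeric(seg$start),
    end = as.numeric(seg$end),
    text = as.character(seg$text)
  )
  validate_transcript(tr, path)
  tr[order(tr$start), ]
}

validate_transcript <- function(tr, context = "transcript") {
  if (any(!is.finite(tr$start)) || any(!is.finite(tr$end))) {
    abort(paste0("Non-numeric timestamps in ", context))
  }
  if (any(tr$start < 0)) abort(paste0("Negative start time in ", context))
  if (any(tr$end < tr$start)) {
    abort(paste0("Segment with end < start in ", context))
  }
  invisible(tr)
}

#' Write a timed transcript
#'
#' Inverse of [read_timed_transcript()]; a read/write cycle is idempotent.
#'
#' @param tr Tibble with columns `start`, `end`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timed_transcript <- function(tr, path) {
  assert_cols(tr, c("start", "end", "text"), "Transcript")
  jsonlite::write_json(
    list(segments = data.frame(start = tr$start, end = tr$end, text = tr$text)),
    path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
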