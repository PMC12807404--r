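#' Parse cognitive labels
#'
#' Labels are stored as strings in manifests and as integers internally:
#' 0 = healthy control (HC), 1 = impaired (MCI in longitudinal memory-test
#' cohorts, AD in picture-description cohorts). Parsing is case-insensitive.
#'
#' @param x Character vector of labels ("HC", "MCI", "AD", "IMPAIRED").
#' @return Integer vector of 0/1.
#' @export
#' @examples
#' parse_label(c("HC", "mci", "AD"))
parse_label <- function(x) {
  lx <- toupper(trimws(as.character(x)))
  out <- ifelse(lx == "HC", 0L, ifelse(lx %in% c("MCI", "AD", "IMPAIRED"), 1L, NA_integer_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(paste0("Unknown cognitive label(s): ", paste(bad, collapse = ", "),
                 " (expected HC, MCI, AD or IMPAIRED)"))
  }
  out
}

#' Format integer labels back to manifest strings
#'
#' @param x Integer vector of 0/1.
#' @param impaired String used for the impaired class (default "MCI").
#' @return Character vector.
#' @export
format_label <- function(x, impaired = "MCI") {
  stopifnot(all(x %in% c(0L, 1L)))
  ifelse(x == 0L, "HC", impaired)
}

# Deterministic 31-bit hash of a string (polynomial rolling hash).
hash_string <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Combine a user seed with stream identifiers into a reproducible sub-seed.
# Stays below 2^31 so it is a valid R integer seed. The multiplier is small
# enough that h * 69069 stays below 2^53, keeping the arithmetic exact in
# doubles (a larger multiplier would silently drop low-order bits and
# collapse nearby streams onto one seed).
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) hash_string(p) else as.integer(p)
  })))
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (as.double(p) %% 2147483647) + 12345) %% 2147483647
    h <- (h * 69069 + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_cols <- function(df, cols, what = "data frame") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
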