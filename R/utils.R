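#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties always rounded away from zero
#' (the convention used for reported survey percentages), unlike [round()],
#' which rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(2.45, 1)  # 2.5, where round() gives 2.4
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage rounded half-up to one decimal
#'
#' @param num numerator count.
#' @param den denominator count.
#' @return `100 * num / den` rounded half-up to one decimal; `NA` when the
#'   denominator is zero.
#' @export
pct <- function(num, den) {
  r <- suppressWarnings(100 * num / den)
  out <- round_half_up(r, 1)
  out[rep_len(den == 0, length(out))] <- NA_real_
  out
}

#' Normalize free text for comparison
#'
#' Case-folds, collapses internal whitespace, and strips leading/trailing
#' punctuation and whitespace. No stemming is applied: downstream duplicate
#' detection is exact-match on the normalized form.
#'
#' @param x character vector.
#' @return normalized character vector; `NA` and empty input become `""`.
#' @export
normalize_text <- function(x) {
  x <- ifelse(is.na(x), "", as.character(x))
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  x <- gsub("^[[:punct:]\\s]+|[[:punct:]\\s]+$", "", x, perl = TRUE)
  x
}

#' Tokenize normalized text
#' @param x a single normalized string.
#' @return character vector of whitespace-delimited tokens (length 0 for "").
#' @export
tokenize <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

#' Count tokens in normalized text
#' @param x character vector of normalized strings.
#' @return integer vector of token counts.
#' @export
n_tokens <- function(x) {
  vapply(x, function(s) length(tokenize(s)), integer(1), USE.NAMES = FALSE)
}

# Token trigrams of a normalized string (character vector, possibly empty).
token_trigrams <- function(x) {
  toks <- tokenize(x)
  n <- length(toks)
  if (n < 3) return(character(0))
  vapply(seq_len(n - 2), function(i) paste(toks[i:(i + 2)], collapse = " "),
         character(1))
}

#' Token-trigram Jaccard similarity
#'
#' Similarity between two normalized strings, computed as the Jaccard index
#' of their sets of consecutive token triples. Strings shorter than three
#' tokens have an empty trigram set and similarity 0.
#'
#' @param a,b normalized strings.
#' @return similarity in `[0, 1]`.
#' @export
trigram_jaccard <- function(a, b) {
  ta <- unique(token_trigrams(a))
  tb <- unique(token_trigrams(b))
  u <- length(union(ta, tb))
  if (u == 0) return(0)
  length(intersect(ta, tb)) / u
}

#' Normalized string similarity
#'
#' Levenshtein-based similarity `1 - dist / max(nchar)` between normalized
#' forms, used for fuzzy matching of facility and referral names.
#'
#' @param x a single string.
#' @param table character vector of candidate names.
#' @return numeric vector of similarities in `[0, 1]`, one per candidate.
#' @export
string_similarity <- function(x, table) {
  x <- normalize_text(x)
  tbl <- normalize_text(table)
  if (!nzchar(x) || length(tbl) == 0) return(numeric(0))
  d <- as.integer(utils::adist(x, tbl))
  len <- pmax(nchar(x), nchar(tbl))
  ifelse(len == 0, 1, 1 - d / len)
}

# --- timestamps ------------------------------------------------------------

#' Parse ISO-8601 timestamps with explicit UTC offset
#'
#' Accepts strings of the form `"2020-06-02T03:15:00-04:00"` (a `T` or space
#' separator; offset `±HH:MM` or `±HHMM`). The local clock time is taken
#' verbatim from the string; the instant is obtained by subtracting the
#' offset. Anything else (including missing offsets) parses as invalid:
#' invalidity is a value, not an error, so that cases with unusable
#' timestamps can still be screened on every time-independent indicator.
#'
#' @param x character vector of timestamp strings.
#' @return a tibble with one row per input: `valid` (logical), `clock`
#'   (POSIXct, the local wall-clock time carried in UTC), `offset_min`
#'   (integer minutes east of UTC), `instant` (POSIXct, UTC),
#'   `local_hour` (integer 0-23, `NA` when invalid).
#' @export
parse_timestamps <- function(x) {
  x <- ifelse(is.na(x), "", as.character(x))
  pat <- "^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}:\\d{2}:\\d{2})([+-])(\\d{2}):?(\\d{2})$"
  ok <- grepl(pat, x)
  clock <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  offset <- rep(NA_integer_, length(x))
  if (any(ok)) {
    d <- regmatches(x[ok], regexec(pat, x[ok]))
    dd <- do.call(rbind, d)
    clock[ok] <- as.POSIXct(paste(dd[, 2], dd[, 3]), tz = "UTC")
    offset[ok] <- ifelse(dd[, 4] == "-", -1L, 1L) *
      (as.integer(dd[, 5]) * 60L + as.integer(dd[, 6]))
  }
  bad_clock <- ok & is.na(clock)  # e.g. impossible dates
  ok[bad_clock] <- FALSE
  offset[!ok] <- NA_integer_
  instant <- clock - offset * 60
  tibble(
    valid = ok,
    clock = clock,
    offset_min = offset,
    instant = instant,
    local_hour = ifelse(ok, as.integer(format(clock, "%H", tz = "UTC")), NA_integer_)
  )
}

#' Format an instant as an ISO-8601 string at a given UTC offset
#'
#' @param instant POSIXct instant (UTC).
#' @param offset_min integer minutes east of UTC.
#' @return character vector like `"2020-06-02T03:15:00-04:00"`.
#' @export
format_timestamp <- function(instant, offset_min) {
  clock <- instant + offset_min * 60
  sgn <- ifelse(offset_min < 0, "-", "+")
  a <- abs(offset_min)
  sprintf("%s%s%02d:%02d", format(clock, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
          sgn, a %/% 60, a %% 60)
}

# Local seed helper: runs code under a fixed seed, restoring RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
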