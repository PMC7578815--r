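read_csv_chr <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  as_tibble(utils::read.csv(path, colClasses = "character", check.names = FALSE,
                            na.strings = NULL))
}

#' Read a survey response export
#'
#' Reads an RFC-4180 CSV export (one row per completed case) and checks it
#' against the schema. All cells are kept as character; timestamps are
#' validated but left raw, so that a record with an unparseable timestamp is
#' retained and simply excluded from time-dependent indicators downstream.
#' Rows are never silently dropped.
#'
#' @param path path to the CSV export.
#' @param schema a [survey_schema()] describing the expected columns.
#' @return a tibble with one row per case, in file order. Data-quality
#'   annotations discovered at load time (invalid timestamps, end before
#'   start) are attached as the `"data_errors"` attribute, a tibble with
#'   columns `case_id`, `field`, `problem`.
#' @export
load_responses <- function(path, schema) {
  df <- read_csv_chr(path)
  missing_cols <- setdiff(schema_columns(schema), names(df))
  if (length(missing_cols)) {
    abort(paste0("Export is missing schema columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$case_id)) {
    dup <- unique(df$case_id[duplicated(df$case_id)])
    abort(paste0("Duplicate case_id in export: ", paste(dup, collapse = ", ")))
  }
  zip_col <- schema$identity_fields[["zip"]]
  bad_zip <- nzchar(df[[zip_col]]) & !grepl("^\\d{3}$", df[[zip_col]])
  st <- parse_timestamps(df[[schema$time_fields[1]]])
  en <- parse_timestamps(df[[schema$time_fields[2]]])
  err <- dplyr::bind_rows(
    tibble(case_id = df$case_id[!st$valid], field = schema$time_fields[1],
           problem = "invalid timestamp"),
    tibble(case_id = df$case_id[!en$valid], field = schema$time_fields[2],
           problem = "invalid timestamp"),
    tibble(case_id = df$case_id[st$valid & en$valid & en$instant < st$instant],
           field = schema$time_fields[2], problem = "end before start"),
    tibble(case_id = df$case_id[bad_zip], field = zip_col,
           problem = "zip prefix not 3 digits")
  )
  attr(df, "data_errors") <- err
  df
}

#' Write a survey response export
#' @param responses tibble of responses.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an eligibility-screening export
#'
#' @param path CSV with columns `screening_id`, `submitted_ts`, `passed`
#'   (`"TRUE"`/`"FALSE"`).
#' @return tibble with `screening_id` (chr), `submitted_ts` (chr, ISO-8601
#'   with offset), `passed` (logical).
#' @export
load_screening <- function(path) {
  df <- read_csv_chr(path)
  need <- c("screening_id", "submitted_ts", "passed")
  if (!all(need %in% names(df))) {
    abort(paste0("Screening export must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$screening_id)) abort("Duplicate screening_id in export.")
  df$passed <- toupper(df$passed) %in% c("TRUE", "T", "1", "YES")
  df
}

#' @rdname load_screening
#' @param screening tibble of screening records.
#' @export
write_screening <- function(screening, path) {
  utils::write.csv(screening, path, row.names = FALSE, na = "")
  invisible(path)
}

# --- geographic mappings ---------------------------------------------------

#' Construct a zip-region map
#'
#' Bundles the two lookup tables used by the verifiable-item checks: the
#' 3-digit zip (sectional-center) prefix to state assignment, and the set of
#' IANA time zones plausibly observed in each state. The set of US zones is
#' their union.
#'
#' @param zip3 data frame with columns `zip3`, `state`.
#' @param zones data frame with columns `state`, `zone` (long format, one row
#'   per state-zone pair).
#' @return an object of class `zip_region_map` with elements `zip3_to_state`
#'   (named character), `state_to_zones` (named list), `us_zones` (character).
#' @export
zip_region_map <- function(zip3, zones) {
  zip3 <- as_tibble(zip3)
  zones <- as_tibble(zones)
  stopifnot(all(c("zip3", "state") %in% names(zip3)),
            all(c("state", "zone") %in% names(zones)))
  state_to_zones <- split(zones$zone, zones$state)
  missing_state <- setdiff(unique(zip3$state), names(state_to_zones))
  if (length(missing_state)) {
    abort(paste0("State(s) in zip3 table with no time-zone entry: ",
                 paste(missing_state, collapse = ", ")))
  }
  structure(
    list(
      zip3_to_state = stats::setNames(zip3$state, zip3$zip3),
      state_to_zones = state_to_zones,
      us_zones = sort(unique(zones$zone))
    ),
    class = "zip_region_map"
  )
}

#' @export
print.zip_region_map <- function(x, ...) {
  cat(sprintf("<zip_region_map> %d zip3 prefixes, %d states, %d US zones\n",
              length(x$zip3_to_state), length(x$state_to_zones),
              length(x$us_zones)))
  invisible(x)
}

#' Read a zip-region map from CSV tables
#'
#' @param zip3_path CSV with columns `zip3`, `state`.
#' @param zones_path CSV with columns `state`, `zone`. Defaults to the file
#'   `state_zones.csv` next to `zip3_path` when omitted.
#' @return a [zip_region_map()].
#' @export
load_zip_map <- function(zip3_path, zones_path = NULL) {
  zones_path <- zones_path %||% file.path(dirname(zip3_path), "state_zones.csv")
  zip_region_map(read_csv_chr(zip3_path), read_csv_chr(zones_path))
}

#' Packaged reference fixtures
#'
#' Small editable lookup tables shipped with the package: a zip3-to-state /
#' state-to-zone map covering the states used by the simulators, a registry
#' of cancer-care facility names, and the recruitment-channel list. Users
#' screening real cohorts should supply their own, more complete tables.
#'
#' @return `fraudsieve_zip_map()`: a [zip_region_map()];
#'   `fraudsieve_facilities()`, `fraudsieve_channels()`: character vectors.
#' @export
fraudsieve_zip_map <- function() {
  load_zip_map(system.file("extdata", "zip3_state.csv", package = "fraudsieve"),
               system.file("extdata", "state_zones.csv", package = "fraudsieve"))
}

#' @rdname fraudsieve_zip_map
#' @export
fraudsieve_facilities <- function() {
  readLines(system.file("extdata", "facilities.txt", package = "fraudsieve"),
            encoding = "UTF-8")
}

#' @rdname fraudsieve_zip_map
#' @export
fraudsieve_channels <- function() {
  readLines(system.file("extdata", "channels.txt", package = "fraudsieve"),
            encoding = "UTF-8")
}

#' Read a reference text corpus
#'
#' Reads every plain-text file in a directory as one document each, for use
#' with the plagiarized-text detector.
#'
#' @param dir directory of `.txt` files.
#' @return character vector, one document per file (empty if none).
#' @export
load_corpus <- function(dir) {
  if (is.null(dir) || !dir.exists(dir)) return(character(0))
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  vapply(files, function(f) paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                                  collapse = " "), character(1), USE.NAMES = FALSE)
}

#' Read a nonsense-response annotation file
#'
#' Human review of nonsensical or irrelevant open-text answers is recorded in
#' a two-column CSV (`case_id`, `item_id`); the pipeline flags exactly the
#' annotated pairs and applies no automated semantic judgment.
#'
#' @param path CSV path.
#' @return tibble with columns `case_id`, `item_id` (zero rows if the file is
#'   empty).
#' @export
load_annotations <- function(path) {
  df <- read_csv_chr(path)
  if (!all(c("case_id", "item_id") %in% names(df))) {
    abort("Annotation file must have columns case_id, item_id.")
  }
  df[c("case_id", "item_id")]
}
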