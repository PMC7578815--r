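log_line <- function(con, ...) {
  msg <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 paste0(...))
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

#' Assemble a screening run configuration
#'
#' @param responses path to the survey response CSV (required).
#' @param schema path to the schema JSON (required).
#' @param zip_map path to the zip3/state CSV (with `state_zones.csv`
#'   alongside), or `NULL` to leave geographic checks unverifiable.
#' @param screening optional path to the screening CSV.
#' @param facilities,channels optional paths to one-name-per-line lists;
#'   default to the packaged fixtures.
#' @param corpus optional directory of reference `.txt` documents.
#' @param annotations optional path to a nonsense-annotation CSV.
#' @param out output directory (created if needed).
#' @param params detector parameters, see [detector_params()].
#' @return a `run_config` list.
#' @export
run_config <- function(responses, schema, zip_map = NULL, screening = NULL,
                       facilities = NULL, channels = NULL, corpus = NULL,
                       annotations = NULL, out = ".",
                       params = detector_params()) {
  structure(
    list(responses = responses, schema = schema, zip_map = zip_map,
         screening = screening, facilities = facilities, channels = channels,
         corpus = corpus, annotations = annotations, out = out,
         params = params),
    class = "run_config"
  )
}

#' Run the screening pipeline end to end and write its artifacts
#'
#' Loads all inputs named by the configuration, runs detection,
#' classification and summary, and writes three artifacts to the output
#' directory: `per_case.csv` (one row per case with verdict, counts and
#' triggering codes), `summary.json` (the versioned cohort summary) and
#' `screen.log` (parameter values and stage counts). Reference inputs that
#' are missing degrade to "unverifiable" with a warning; a malformed
#' required input is an error.
#'
#' @param config a [run_config()].
#' @return the `fraud_screen` object, invisibly.
#' @export
run_screen <- function(config) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out, "screen.log"), open = "wt")
  on.exit(close(logf))
  log_line(logf, "screen: start")
  log_line(logf, "params: ", paste(names(config$params), unlist(config$params),
                                   sep = "=", collapse = " "))

  schema <- load_schema(config$schema)
  responses <- load_responses(config$responses, schema)
  log_line(logf, sprintf("loaded %d response rows", nrow(responses)))

  zip_map <- NULL
  if (!is.null(config$zip_map) && file.exists(config$zip_map)) {
    zip_map <- load_zip_map(config$zip_map)
  } else {
    warn("No zip-region map: geographic checks are unverifiable.")
    log_line(logf, "no zip map; geo checks unverifiable")
  }
  facilities <- if (!is.null(config$facilities)) {
    readLines(config$facilities, encoding = "UTF-8")
  } else fraudsieve_facilities()
  channels <- if (!is.null(config$channels)) {
    readLines(config$channels, encoding = "UTF-8")
  } else fraudsieve_channels()
  corpus <- if (!is.null(config$corpus)) load_corpus(config$corpus)
  annotations <- if (!is.null(config$annotations)) load_annotations(config$annotations)
  screening <- if (!is.null(config$screening)) load_screening(config$screening)
  if (!is.null(screening)) {
    log_line(logf, sprintf("loaded %d screening rows", nrow(screening)))
  }

  scr <- screen_cohort(responses, schema, zip_map, facilities, channels,
                       corpus, annotations, screening, config$params)
  log_line(logf, sprintf("%d indicator flags over %d cases",
                         nrow(scr$indicators), nrow(scr$cases)))
  v <- scr$summary$verdicts
  log_line(logf, sprintf("verdicts: fraudulent=%d suspicious=%d legitimate=%d",
                         v$n[1], v$n[2], v$n[3]))

  utils::write.csv(
    tidy(scr), file.path(config$out, "per_case.csv"), row.names = FALSE, na = ""
  )
  write_summary_json(scr$summary, file.path(config$out, "summary.json"))
  log_line(logf, "screen: done")
  invisible(scr)
}

#' Write a named replication fixture to disk
#'
#' @param profile_name a profile listed by [fixture_profiles()].
#' @param seed integer seed.
#' @param out output directory.
#' @return the fixture list (see [generate_fixture()]), invisibly. Writes
#'   `responses.csv`, `screening.csv`, `schema.json`, `truth_cases.csv`,
#'   `truth_screening.csv`.
#' @export
run_fixture <- function(profile_name = "pozzar2020", seed = 1, out = ".") {
  profiles <- fixture_profiles()
  if (!profile_name %in% names(profiles)) {
    abort(paste0("Unknown profile \"", profile_name, "\". Available: ",
                 paste(names(profiles), collapse = ", ")))
  }
  fx <- generate_fixture(profiles[[profile_name]], seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_responses(fx$responses, file.path(out, "responses.csv"))
  write_screening(fx$screening, file.path(out, "screening.csv"))
  write_schema(fx$schema, file.path(out, "schema.json"))
  utils::write.csv(fx$truth, file.path(out, "truth_cases.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(fx$truth_screening, file.path(out, "truth_screening.csv"),
                   row.names = FALSE, na = "")
  invisible(fx)
}

#' Simulate a cohort and write it to disk
#'
#' @inheritParams simulate_cohort
#' @param out output directory.
#' @return the simulation list, invisibly. Writes `responses.csv`,
#'   `schema.json`, `truth_personas.csv` and `simulate.log` (which records
#'   the seed used).
#' @export
run_simulate <- function(n, mix, seed = NULL, out = ".",
                         params = default_persona_params()) {
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  sim <- simulate_cohort(n, mix, params, seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_responses(sim$responses, file.path(out, "responses.csv"))
  write_schema(sim$schema, file.path(out, "schema.json"))
  utils::write.csv(sim$personas, file.path(out, "truth_personas.csv"),
                   row.names = FALSE, na = "")
  logf <- file(file.path(out, "simulate.log"), open = "wt")
  on.exit(close(logf))
  log_line(logf, sprintf("simulate: n=%d seed=%d mix=%s", n, seed,
                         paste(names(mix), mix, sep = "=", collapse = ",")))
  message(sprintf("seed used: %d", seed))
  invisible(sim)
}

#' Re-render a cohort summary from a per-case CSV
#'
#' Recomputes the verdict marginals from a previously written `per_case.csv`
#' (full summaries need the raw export; this re-rendering covers the verdict
#' and count fields only).
#'
#' @param per_case_path path to a `per_case.csv` written by [run_screen()].
#' @param out optional path for a JSON rendering.
#' @return a tibble of verdict counts and percentages.
#' @export
run_report <- function(per_case_path, out = NULL) {
  d <- read_csv_chr(per_case_path)
  if (!"verdict" %in% names(d)) abort("per-case file has no verdict column")
  n <- nrow(d)
  cnt <- table(factor(d$verdict, levels = c("fraudulent", "suspicious", "legitimate")))
  rep <- tibble(verdict = names(cnt), n = as.integer(cnt),
                pct = pct(as.integer(cnt), n))
  if (!is.null(out)) {
    jsonlite::write_json(list(schema_version = "1.0", n_cases = n,
                              verdicts = rep),
                         out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}
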