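#' The indicator codebook
#'
#' The thirteen case-level indicators of low-quality or fraudulent survey
#' data, with their fixed designations and categories. Designations encode
#' how strongly an indicator suggests misrepresentation: `fraudulent`
#' indicators (completion under 5 minutes, an exact duplicate open-text
#' answer, a non-US timestamp zone, a response to a hidden honeypot item)
#' strongly suggest automation or misrepresentation; `suspicious` indicators
#' could plausibly arise from respondent error or carelessness. Categories
#' group the indicators into evidence of inattention, duplicate/unusual
#' open-text responses, inconsistent verifiable items, and bot automation.
#'
#' @return a tibble with columns `code`, `designation`, `category`, `label`.
#' @export
indicator_codes <- function() {
  tibble(
    code = c("TIME_LT5", "TIME_5TO10", "STRAIGHTLINE",
             "DUP_TEXT", "NONSENSE_TEXT", "PATTERN_TEXT", "CORPUS_TEXT",
             "ZIP_STATE_MISMATCH", "STATE_TZ_MISMATCH", "FACILITY_UNKNOWN",
             "NONUS_TZ", "REFERRAL_UNKNOWN",
             "HIDDEN_RESPONSE"),
    designation = c("fraudulent", "suspicious", "suspicious",
                    "fraudulent", "suspicious", "suspicious", "suspicious",
                    "suspicious", "suspicious", "suspicious",
                    "fraudulent", "suspicious",
                    "fraudulent"),
    category = c(rep("inattention", 3), rep("open_text", 4),
                 rep("verifiable", 5), "automation"),
    label = c(
      "Survey completion time <5 minutes",
      "Survey completion time <10 minutes",
      "Same response to every closed item on a page (straight-lining)",
      "Exact open-text response shared by more than one respondent",
      "Open-text response nonsensical or irrelevant to item",
      "Several open-text responses follow the same pattern",
      "Open-text response duplicates a reference corpus document",
      "Reported location and zip code prefix do not match",
      "Reported location and timestamp time zone do not match",
      "Reported treatment facility is not a known cancer care facility",
      "Timestamp time zone outside the United States",
      "Referral source names an organization not involved in recruitment",
      "Response provided to one or more hidden items"
    )
  )
}

#' Default detector parameters
#'
#' @param min_tokens minimum token count for an open-text answer to count as
#'   a shareable duplicate (the "more than 2-3 words" rule).
#' @param similarity_threshold token-trigram Jaccard threshold for the
#'   patterned-phrasing clusterer.
#' @param min_cluster minimum number of distinct cases in a phrasing cluster
#'   before its members are flagged.
#' @param corpus_min_tokens minimum token count for a corpus-plagiarism match.
#' @param fuzzy_threshold normalized string-similarity threshold for facility
#'   and referral matching.
#' @param min_straightline_items minimum number of answered closed items for
#'   a page to be eligible for the straight-lining check.
#' @return a named list of parameters.
#' @export
detector_params <- function(min_tokens = 3,
                            similarity_threshold = 0.6,
                            min_cluster = 3,
                            corpus_min_tokens = 5,
                            fuzzy_threshold = 0.85,
                            min_straightline_items = 3) {
  stopifnot(min_tokens >= 1, similarity_threshold > 0, similarity_threshold <= 1,
            min_cluster >= 2, corpus_min_tokens >= 1,
            fuzzy_threshold > 0, fuzzy_threshold <= 1, min_straightline_items >= 1)
  list(
    min_tokens = min_tokens,
    similarity_threshold = similarity_threshold,
    min_cluster = min_cluster,
    corpus_min_tokens = corpus_min_tokens,
    fuzzy_threshold = fuzzy_threshold,
    min_straightline_items = min_straightline_items
  )
}

flag_tbl <- function(case_id = character(0), code = character(0),
                     evidence = character(0)) {
  tibble(case_id = as.character(case_id), code = as.character(code),
         evidence = as.character(evidence))
}

#' Survey completion time per case
#'
#' Computes end minus start in minutes. A case whose timestamps do not both
#' parse (or whose end precedes its start) gets `NA` with `ts_valid = FALSE`:
#' invalidity is a value, and such cases are excluded only from
#' time-dependent indicators, never from screening.
#'
#' @param responses response tibble (see [load_responses()]).
#' @param schema a [survey_schema()].
#' @return tibble with `case_id`, `completion_minutes` (dbl, `NA` when
#'   invalid), `ts_valid` (lgl), `end_local_hour` (int, hour 0-23 of the end
#'   timestamp on the case's own clock, `NA` when invalid).
#' @export
completion_minutes <- function(responses, schema) {
  st <- parse_timestamps(responses[[schema$time_fields[1]]])
  en <- parse_timestamps(responses[[schema$time_fields[2]]])
  mins <- as.numeric(difftime(en$instant, st$instant, units = "mins"))
  ok <- st$valid & en$valid & !is.na(mins) & mins >= 0
  tibble(
    case_id = responses$case_id,
    completion_minutes = ifelse(ok, mins, NA_real_),
    ts_valid = ok,
    end_local_hour = ifelse(en$valid, en$local_hour, NA_integer_)
  )
}

#' Detect evidence of inattention
#'
#' Emits `TIME_LT5` (fraudulent) for completion times in `[0, 5)` minutes and
#' `TIME_5TO10` (suspicious) for `[5, 10)`; the bands are disjoint, so a case
#' carries at most one. Emits `STRAIGHTLINE` (suspicious) when some page with
#' at least `min_straightline_items` answered closed items has the identical
#' response to every answered closed item.
#'
#' @inheritParams completion_minutes
#' @param params see [detector_params()].
#' @return tibble of flags: `case_id`, `code`, `evidence`.
#' @export
detect_inattention <- function(responses, schema, params = detector_params()) {
  cm <- completion_minutes(responses, schema)
  lt5 <- cm$ts_valid & cm$completion_minutes < 5
  b510 <- cm$ts_valid & cm$completion_minutes >= 5 & cm$completion_minutes < 10
  out <- dplyr::bind_rows(
    flag_tbl(cm$case_id[lt5], "TIME_LT5",
             sprintf("completed in %.2f min", cm$completion_minutes[lt5])),
    flag_tbl(cm$case_id[b510], "TIME_5TO10",
             sprintf("completed in %.2f min", cm$completion_minutes[b510]))
  )
  closed <- schema$items[schema$items$kind == "closed", , drop = FALSE]
  if (nrow(closed) > 0) {
    for (pg in unique(closed$page_id)) {
      cols <- closed$item_id[closed$page_id == pg]
      if (length(cols) < params$min_straightline_items) next
      vals <- as.matrix(responses[cols])
      vals[is.na(vals) | vals == ""] <- NA_character_
      n_ans <- rowSums(!is.na(vals))
      n_distinct_ans <- apply(vals, 1, function(r) length(unique(r[!is.na(r)])))
      hit <- n_ans >= params$min_straightline_items & n_distinct_ans == 1
      if (any(hit)) {
        out <- dplyr::bind_rows(out, flag_tbl(
          responses$case_id[hit], "STRAIGHTLINE",
          sprintf("page %s: identical response to %d closed items", pg, n_ans[hit])
        ))
      }
    }
    # one STRAIGHTLINE flag per case even if several pages straight-line
    out <- dplyr::distinct(out, .data$case_id, .data$code, .keep_all = TRUE)
  }
  out
}

#' Detect exact duplicate open-text responses across the cohort
#'
#' Normalizes each open-text answer (case-fold, collapse whitespace, strip
#' terminal punctuation) and flags every case that shares a normalized answer
#' of at least `min_tokens` tokens with at least one other case on the same
#' item. The flag is symmetric: all members of a duplicate group are flagged.
#'
#' @inheritParams detect_inattention
#' @return tibble of `DUP_TEXT` flags.
#' @export
detect_duplicate_texts <- function(responses, schema, params = detector_params()) {
  open_items <- schema_items(schema, "open")
  out <- flag_tbl()
  for (it in open_items) {
    txt <- normalize_text(responses[[it]])
    keep <- nzchar(txt) & n_tokens(txt) >= params$min_tokens
    if (!any(keep)) next
    d <- tibble(case_id = responses$case_id[keep], text = txt[keep]) |>
      dplyr::distinct(.data$case_id, .data$text) |>
      dplyr::add_count(.data$text, name = "n_cases") |>
      dplyr::filter(.data$n_cases >= 2)
    if (nrow(d) > 0) {
      out <- dplyr::bind_rows(out, flag_tbl(
        d$case_id, "DUP_TEXT",
        sprintf("item %s: \"%s\" shared by %d cases", it,
                substr(d$text, 1, 60), d$n_cases)
      ))
    }
  }
  dplyr::distinct(out, .data$case_id, .data$code, .keep_all = TRUE)
}

# Single-linkage components of texts whose trigram Jaccard meets `thr`.
similarity_components <- function(texts, thr) {
  n <- length(texts)
  comp <- seq_len(n)
  if (n < 2) return(comp)
  grams <- lapply(texts, function(t) unique(token_trigrams(t)))
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (i in seq_len(n - 1)) {
    gi <- grams[[i]]
    if (length(gi) == 0) next
    for (j in (i + 1):n) {
      gj <- grams[[j]]
      if (length(gj) == 0) next
      inter <- sum(gi %in% gj)
      if (inter == 0) next
      if (inter / (length(gi) + length(gj) - inter) >= thr) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Detect open-text responses that follow a shared phrasing pattern
#'
#' Per open item, clusters the distinct normalized answers (answers occurring
#' verbatim in more than one case are exact duplicates and are excluded; they
#' are [detect_duplicate_texts()]'s job) by single-linkage on token-trigram
#' Jaccard similarity at `similarity_threshold`. Clusters spanning at least
#' `min_cluster` distinct cases flag all their members with `PATTERN_TEXT`.
#'
#' @inheritParams detect_inattention
#' @return tibble of `PATTERN_TEXT` flags.
#' @export
detect_pattern_texts <- function(responses, schema, params = detector_params()) {
  open_items <- schema_items(schema, "open")
  out <- flag_tbl()
  for (it in open_items) {
    txt <- normalize_text(responses[[it]])
    keep <- nzchar(txt)
    d <- tibble(case_id = responses$case_id[keep], text = txt[keep]) |>
      dplyr::add_count(.data$text, name = "n_shared") |>
      dplyr::filter(.data$n_shared == 1)  # exclude exact duplicates
    if (nrow(d) < params$min_cluster) next
    comp <- similarity_components(d$text, params$similarity_threshold)
    sizes <- table(comp)
    big <- as.integer(names(sizes)[sizes >= params$min_cluster])
    hit <- comp %in% big
    if (any(hit)) {
      out <- dplyr::bind_rows(out, flag_tbl(
        d$case_id[hit], "PATTERN_TEXT",
        sprintf("item %s: phrasing cluster of %d cases", it,
                as.integer(sizes[as.character(comp[hit])]))
      ))
    }
  }
  dplyr::distinct(out, .data$case_id, .data$code, .keep_all = TRUE)
}

#' Detect open-text responses copied from a reference corpus
#'
#' Flags `CORPUS_TEXT` when a normalized open-text answer of at least
#' `corpus_min_tokens` tokens occurs verbatim as a substring of any document
#' in the user-supplied reference corpus (documents are normalized with the
#' same rules as responses). With an empty corpus nothing is flagged; no live
#' web search is performed.
#'
#' @inheritParams detect_inattention
#' @param corpus character vector of reference documents (see [load_corpus()]).
#' @return tibble of `CORPUS_TEXT` flags.
#' @export
detect_corpus_matches <- function(responses, schema, corpus,
                                  params = detector_params()) {
  out <- flag_tbl()
  if (is.null(corpus) || length(corpus) == 0) return(out)
  corpus <- normalize_text(corpus)
  for (it in schema_items(schema, "open")) {
    txt <- normalize_text(responses[[it]])
    keep <- which(nzchar(txt) & n_tokens(txt) >= params$corpus_min_tokens)
    for (i in keep) {
      if (any(vapply(corpus, function(doc) grepl(txt[i], doc, fixed = TRUE),
                     logical(1)))) {
        out <- dplyr::bind_rows(out, flag_tbl(
          responses$case_id[i], "CORPUS_TEXT",
          sprintf("item %s matches reference corpus", it)
        ))
      }
    }
  }
  dplyr::distinct(out, .data$case_id, .data$code, .keep_all = TRUE)
}

#' Apply human nonsense/irrelevance annotations
#'
#' Judging an answer nonsensical or irrelevant is a human call; this detector
#' only translates a reviewer's annotation file into `NONSENSE_TEXT` flags
#' and validates that it references real cases and open items.
#'
#' @inheritParams detect_inattention
#' @param annotations tibble with columns `case_id`, `item_id`
#'   (see [load_annotations()]); may have zero rows.
#' @return tibble of `NONSENSE_TEXT` flags.
#' @export
flag_nonsense <- function(responses, schema, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) return(flag_tbl())
  unknown_case <- setdiff(annotations$case_id, responses$case_id)
  if (length(unknown_case)) {
    abort(paste0("Annotation references unknown case_id: ",
                 paste(unknown_case, collapse = ", ")))
  }
  unknown_item <- setdiff(annotations$item_id, schema_items(schema, "open"))
  if (length(unknown_item)) {
    abort(paste0("Annotation references unknown open item: ",
                 paste(unknown_item, collapse = ", ")))
  }
  dplyr::distinct(
    flag_tbl(annotations$case_id, "NONSENSE_TEXT",
             sprintf("item %s annotated by reviewer", annotations$item_id)),
    .data$case_id, .data$code, .keep_all = TRUE
  )
}

#' Check verifiable item pairs for consistency
#'
#' Cross-checks each case's reported state against its zip prefix, its
#' timestamp time zone against the reported state and against the set of US
#' zones, its treatment facility against a registry of cancer-care
#' facilities, and its referral source against the configured recruitment
#' channels. A time zone outside the US set emits the fraudulent `NONUS_TZ`
#' flag (and subsumes the state/zone comparison, which is only meaningful for
#' US zones). Unmappable inputs (unknown zip prefix, missing state or zone,
#' missing registry) are *unverifiable* and never generate flags: they are
#' recorded in the `"unverifiable"` attribute of the result instead.
#'
#' @inheritParams detect_inattention
#' @param zip_map a [zip_region_map()], or `NULL` (geo checks unverifiable).
#' @param facilities character vector of known facility names, or `NULL`.
#' @param channels character vector of recruitment-channel names, or `NULL`.
#' @return tibble of flags with attribute `"unverifiable"` (tibble:
#'   `case_id`, `field`, `reason`).
#' @export
check_verifiable <- function(responses, schema, zip_map = NULL,
                             facilities = NULL, channels = NULL,
                             params = detector_params()) {
  n <- nrow(responses)
  idf <- schema$identity_fields
  state <- toupper(trimws(responses[[idf[["state"]]]]))
  zip <- trimws(responses[[idf[["zip"]]]])
  zone <- trimws(responses[[schema$tz_field]])
  fac <- responses[[idf[["facility"]]]]
  ref <- responses[[idf[["referral"]]]]
  out <- flag_tbl()
  unver <- tibble(case_id = character(0), field = character(0),
                  reason = character(0))
  note <- function(ids, field, reason) {
    if (length(ids)) unver <<- dplyr::bind_rows(
      unver, tibble(case_id = ids, field = field, reason = reason))
  }

  if (is.null(zip_map)) {
    note(responses$case_id, "geo", "no zip-region map supplied")
  } else {
    zip_known <- nzchar(zip) & zip %in% names(zip_map$zip3_to_state)
    state_known <- nzchar(state) & state %in% names(zip_map$state_to_zones)
    mapped <- ifelse(zip_known, zip_map$zip3_to_state[zip], NA_character_)
    hit <- zip_known & state_known & mapped != state
    out <- dplyr::bind_rows(out, flag_tbl(
      responses$case_id[hit], "ZIP_STATE_MISMATCH",
      sprintf("zip prefix %s maps to %s, reported state %s",
              zip[hit], mapped[hit], state[hit])
    ))
    note(responses$case_id[!zip_known | !state_known], "zip/state",
         "zip prefix or state not mappable")

    zone_known <- nzchar(zone) & length(zip_map$us_zones) > 0
    nonus <- zone_known & !(zone %in% zip_map$us_zones)
    out <- dplyr::bind_rows(out, flag_tbl(
      responses$case_id[nonus], "NONUS_TZ",
      sprintf("time zone %s is outside the United States", zone[nonus])
    ))
    cand <- which(zone_known & !nonus & state_known)
    tz_bad <- cand[!vapply(cand, function(i) {
      zone[i] %in% zip_map$state_to_zones[[state[i]]]
    }, logical(1))]
    out <- dplyr::bind_rows(out, flag_tbl(
      responses$case_id[tz_bad], "STATE_TZ_MISMATCH",
      sprintf("time zone %s not observed in state %s", zone[tz_bad], state[tz_bad])
    ))
    note(responses$case_id[!zone_known], "time zone", "no parseable zone")
  }

  if (is.null(facilities) || length(facilities) == 0) {
    note(responses$case_id, "facility", "no facility registry supplied")
  } else {
    for (i in seq_len(n)) {
      if (is.na(fac[i]) || !nzchar(trimws(fac[i]))) {
        note(responses$case_id[i], "facility", "no facility reported")
      } else if (max(string_similarity(fac[i], facilities)) < params$fuzzy_threshold) {
        out <- dplyr::bind_rows(out, flag_tbl(
          responses$case_id[i], "FACILITY_UNKNOWN",
          sprintf("\"%s\" matches no registered cancer care facility", fac[i])
        ))
      }
    }
  }

  if (is.null(channels) || length(channels) == 0) {
    note(responses$case_id, "referral", "no channel list supplied")
  } else {
    for (i in seq_len(n)) {
      if (is.na(ref[i]) || !nzchar(trimws(ref[i]))) {
        note(responses$case_id[i], "referral", "no referral source reported")
      } else if (max(string_similarity(ref[i], channels)) < params$fuzzy_threshold) {
        out <- dplyr::bind_rows(out, flag_tbl(
          responses$case_id[i], "REFERRAL_UNKNOWN",
          sprintf("\"%s\" matches no recruitment channel", ref[i])
        ))
      }
    }
  }

  out <- dplyr::distinct(out, .data$case_id, .data$code, .keep_all = TRUE)
  attr(out, "unverifiable") <- unver
  out
}

#' Detect responses to hidden honeypot items
#'
#' Hidden items are present in the survey document structure but invisible to
#' human respondents; any non-empty text in one implies automation and emits
#' the fraudulent `HIDDEN_RESPONSE` flag. Missing values and empty strings
#' are non-responses.
#'
#' @inheritParams detect_inattention
#' @return tibble of `HIDDEN_RESPONSE` flags.
#' @export
detect_hidden_responses <- function(responses, schema) {
  hidden <- schema_items(schema, "hidden")
  out <- flag_tbl()
  for (it in hidden) {
    v <- responses[[it]]
    hit <- !is.na(v) & nzchar(trimws(v))
    out <- dplyr::bind_rows(out, flag_tbl(
      responses$case_id[hit], "HIDDEN_RESPONSE",
      sprintf("hidden item %s answered \"%s\"", it, trimws(v[hit]))
    ))
  }
  dplyr::distinct(out, .data$case_id, .data$code, .keep_all = TRUE)
}

#' Run the full indicator battery
#'
#' Runs every detector and returns the combined flag table, joined to the
#' codebook designations and categories. Detectors whose reference inputs
#' are absent (`zip_map`, `facilities`, `channels`, `corpus`, `annotations`)
#' degrade to "unverifiable"/vacuous rather than failing.
#'
#' @inheritParams check_verifiable
#' @param corpus character vector of reference documents, or `NULL`.
#' @param annotations nonsense annotation tibble, or `NULL`.
#' @return tibble with columns `case_id`, `code`, `designation`, `category`,
#'   `evidence`; at most one row per (case, code).
#' @export
detect_indicators <- function(responses, schema, zip_map = NULL,
                              facilities = NULL, channels = NULL,
                              corpus = NULL, annotations = NULL,
                              params = detector_params()) {
  flags <- dplyr::bind_rows(
    detect_inattention(responses, schema, params),
    detect_duplicate_texts(responses, schema, params),
    detect_pattern_texts(responses, schema, params),
    detect_corpus_matches(responses, schema, corpus, params),
    flag_nonsense(responses, schema, annotations),
    check_verifiable(responses, schema, zip_map, facilities, channels, params),
    detect_hidden_responses(responses, schema)
  )
  flags |>
    dplyr::distinct(.data$case_id, .data$code, .keep_all = TRUE) |>
    dplyr::left_join(indicator_codes()[c("code", "designation", "category")],
                     by = "code") |>
    dplyr::arrange(.data$case_id, .data$code)
}

#' Build per-case indicator profiles
#'
#' Collapses the flag table to one row per case (each indicator code counts
#' at most once per case, however many items triggered it) with fraudulent
#' and suspicious counts and the completion time. Cases with no flags are
#' retained with zero counts.
#'
#' @param flags output of [detect_indicators()].
#' @inheritParams completion_minutes
#' @return tibble with `case_id`, `codes` (list of chr), `n_fraudulent`,
#'   `n_suspicious` (int), `completion_minutes` (dbl, `NA` when invalid),
#'   `ts_valid` (lgl), `end_local_hour` (int).
#' @export
build_profiles <- function(flags, responses, schema) {
  cm <- completion_minutes(responses, schema)
  counts <- flags |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      codes = list(sort(unique(.data$code))),
      n_fraudulent = sum(.data$designation == "fraudulent"),
      n_suspicious = sum(.data$designation == "suspicious"),
      .groups = "drop"
    )
  cm |>
    dplyr::left_join(counts, by = "case_id") |>
    dplyr::mutate(
      codes = lapply(.data$codes, function(z) if (is.null(z)) character(0) else z),
      n_fraudulent = as.integer(dplyr::coalesce(.data$n_fraudulent, 0L)),
      n_suspicious = as.integer(dplyr::coalesce(.data$n_suspicious, 0L))
    ) |>
    dplyr::select("case_id", "codes", "n_fraudulent", "n_suspicious",
                  "completion_minutes", "ts_valid", "end_local_hour")
}
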