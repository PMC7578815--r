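#' Construct a survey schema
#'
#' A schema declares the survey's structure: ordered pages, the items on each
#' page with their kinds, and the fixed metadata columns every conforming
#' export carries. Item kinds are `"closed"` (fixed response domain),
#' `"open"` (free text) and `"hidden"` (honeypot items invisible to human
#' respondents; any non-empty response implies automation).
#'
#' @param pages named list: page ID -> character vector of item IDs, in
#'   display order.
#' @param kinds named character vector: item ID -> one of
#'   `"closed"`, `"open"`, `"hidden"`.
#' @param domains optional named list: closed item ID -> vector of admissible
#'   response values.
#' @param time_fields character(2): names of the start and end timestamp
#'   columns.
#' @param tz_field name of the IANA time-zone column.
#' @param identity_fields named character vector with entries `state`, `zip`,
#'   `facility`, `referral`, `email` giving the corresponding column names.
#' @return an object of class `survey_schema`.
#' @examples
#' sch <- survey_schema(
#'   pages = list(p1 = c("q1", "q2", "hp1"), p2 = "cmt"),
#'   kinds = c(q1 = "closed", q2 = "closed", hp1 = "hidden", cmt = "open")
#' )
#' @export
survey_schema <- function(pages,
                          kinds,
                          domains = NULL,
                          time_fields = c("start_ts", "end_ts"),
                          tz_field = "tz",
                          identity_fields = c(
                            state = "reported_state", zip = "zip_prefix",
                            facility = "facility", referral = "referral_source",
                            email = "email_hash"
                          )) {
  if (length(pages) > 0 && is.null(names(pages))) {
    abort("`pages` must be a named list of page ID -> item IDs.")
  }
  item_ids <- unlist(unname(pages), use.names = FALSE) %||% character(0)
  if (anyDuplicated(item_ids)) {
    dup <- unique(item_ids[duplicated(item_ids)])
    abort(paste0("Duplicate item IDs across pages: ", paste(dup, collapse = ", ")))
  }
  missing_kind <- setdiff(item_ids, names(kinds))
  if (length(missing_kind)) {
    abort(paste0("Items without a declared kind: ", paste(missing_kind, collapse = ", ")))
  }
  orphan <- setdiff(names(kinds), item_ids)
  if (length(orphan)) {
    abort(paste0("Items not placed on any page: ", paste(orphan, collapse = ", ")))
  }
  bad <- setdiff(unique(unname(kinds)), c("closed", "open", "hidden"))
  if (length(bad)) {
    abort(paste0("Unknown item kind(s): ", paste(bad, collapse = ", ")))
  }
  stopifnot(length(time_fields) == 2, is.character(time_fields))
  need <- c("state", "zip", "facility", "referral", "email")
  if (!all(need %in% names(identity_fields))) {
    abort("`identity_fields` must name state, zip, facility, referral and email columns.")
  }
  items <- tibble(
    item_id = item_ids,
    page_id = rep(names(pages), lengths(pages)),
    kind = unname(kinds[item_ids])
  )
  structure(
    list(
      pages = pages, items = items, domains = domains,
      time_fields = unname(time_fields), tz_field = tz_field,
      identity_fields = identity_fields[need]
    ),
    class = "survey_schema"
  )
}

#' @export
print.survey_schema <- function(x, ...) {
  k <- table(factor(x$items$kind, levels = c("closed", "open", "hidden")))
  cat(sprintf(
    "<survey_schema> %d pages, %d items (%d closed, %d open, %d hidden)\n",
    length(x$pages), nrow(x$items), k[["closed"]], k[["open"]], k[["hidden"]]
  ))
  invisible(x)
}

#' Items of a given kind
#' @param schema a `survey_schema`.
#' @param kind one of `"closed"`, `"open"`, `"hidden"`.
#' @return character vector of item IDs.
#' @export
schema_items <- function(schema, kind) {
  schema$items$item_id[schema$items$kind == kind]
}

# All column names a conforming export must carry.
schema_columns <- function(schema) {
  c("case_id", schema$time_fields, schema$tz_field,
    unname(schema$identity_fields), schema$items$item_id)
}

#' Read a survey schema from JSON
#'
#' The JSON layout mirrors the constructor arguments: an object with
#' `pages` (object: page ID -> array of item IDs), `kinds` (object:
#' item ID -> kind), and optional `domains`, `time_fields`, `tz_field`,
#' `identity_fields`.
#'
#' @param path path to a schema JSON file.
#' @return a `survey_schema`.
#' @seealso [write_schema()]
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) abort(paste0("Schema file not found: ", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pages <- lapply(j$pages, as.character)
  survey_schema(
    pages = pages,
    kinds = unlist(j$kinds),
    domains = j$domains,
    time_fields = j$time_fields %||% c("start_ts", "end_ts"),
    tz_field = j$tz_field %||% "tz",
    identity_fields = if (!is.null(j$identity_fields)) unlist(j$identity_fields) else
      c(state = "reported_state", zip = "zip_prefix", facility = "facility",
        referral = "referral_source", email = "email_hash")
  )
}

#' Write a survey schema to JSON
#' @param schema a `survey_schema`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(
    list(
      pages = schema$pages,
      kinds = as.list(stats::setNames(schema$items$kind, schema$items$item_id)),
      domains = schema$domains,
      time_fields = schema$time_fields,
      tz_field = schema$tz_field,
      identity_fields = as.list(schema$identity_fields)
    ),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  invisible(path)
}
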