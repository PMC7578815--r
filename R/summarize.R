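category_membership <- function(classified) {
  code_cat <- stats::setNames(indicator_codes()$category, indicator_codes()$code)
  cats <- c("inattention", "open_text", "verifiable", "automation")
  m <- vapply(cats, function(cat) {
    vapply(classified$codes,
           function(cs) any(code_cat[cs] == cat), logical(1))
  }, logical(nrow(classified)))
  if (nrow(classified) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, cats))
  m
}

eastern_hour <- function(ts) {
  p <- parse_timestamps(ts)
  ifelse(p$valid,
         as.integer(format(p$instant, "%H", tz = "America/New_York")),
         NA_integer_)
}

#' Summarize a screened cohort
#'
#' Computes the cohort-level summary: verdict counts and percentages,
#' per-category indicator prevalence (cohort-wide and among
#' fraudulent-verdict cases), the share of cases exhibiting more than one
#' indicator category, the share submitted between 01:00 and 04:59 on the
#' case's own clock, completion-time statistics, the overlap of hidden-item
#' responses with valid timestamps, and (when screening records are
#' supplied) the eligibility funnel and the share of screenings submitted
#' between 00:00 and 03:59 Eastern time. Hour bands are half-open; all
#' percentages are rounded half-up to one decimal.
#'
#' @param classified output of [classify_cases()].
#' @param screening optional screening tibble (see [load_screening()]).
#' @return an object of class `fraud_summary`.
#' @export
summarize_cohort <- function(classified, screening = NULL) {
  n <- nrow(classified)
  vcount <- table(factor(classified$verdict,
                         levels = c("fraudulent", "suspicious", "legitimate")))
  verdicts <- tibble(
    verdict = names(vcount),
    n = as.integer(vcount),
    pct = pct(as.integer(vcount), !!n)
  )

  memb <- category_membership(classified)
  is_fraud <- classified$verdict == "fraudulent"
  n_fraud <- sum(is_fraud)
  categories <- tibble(
    category = colnames(memb),
    n = as.integer(colSums(memb)),
    pct = unname(pct(colSums(memb), !!n)),
    n_among_fraudulent = as.integer(colSums(memb[is_fraud, , drop = FALSE])),
    pct_among_fraudulent = unname(pct(colSums(memb[is_fraud, , drop = FALSE]),
                                      n_fraud))
  )

  n_multi <- sum(rowSums(memb) > 1)
  in_band <- !is.na(classified$end_local_hour) &
    classified$end_local_hour >= 1 & classified$end_local_hour < 5

  cm <- classified$completion_minutes
  lt5_fraud <- sum(is_fraud & !is.na(cm) & cm < 5)
  b510_fraud <- sum(is_fraud & !is.na(cm) & cm >= 5 & cm < 10)

  hidden <- vapply(classified$codes, function(cs) "HIDDEN_RESPONSE" %in% cs,
                   logical(1))
  hv <- hidden & classified$ts_valid

  scr <- NULL
  if (!is.null(screening) && nrow(screening) > 0) {
    eh <- eastern_hour(screening$submitted_ts)
    scr <- list(
      n_screened = nrow(screening),
      n_passed = sum(screening$passed),
      pct_passed = pct(sum(screening$passed), nrow(screening)),
      n_band_eastern = sum(!is.na(eh) & eh >= 0 & eh < 4),
      pct_band_eastern = pct(sum(!is.na(eh) & eh >= 0 & eh < 4), nrow(screening))
    )
  }

  structure(
    list(
      n_cases = n,
      verdicts = verdicts,
      categories = categories,
      n_multi_category = n_multi,
      pct_multi_category = pct(n_multi, n),
      n_local_band = sum(in_band),
      pct_local_band = pct(sum(in_band), n),
      completion = list(
        n_valid = sum(classified$ts_valid),
        mean = if (any(classified$ts_valid)) mean(cm, na.rm = TRUE) else NA_real_,
        sd = if (sum(classified$ts_valid) > 1) stats::sd(cm, na.rm = TRUE) else NA_real_,
        n_fraud_lt5 = lt5_fraud,
        pct_fraud_lt5 = pct(lt5_fraud, n_fraud),
        n_fraud_5to10 = b510_fraud,
        pct_fraud_5to10 = pct(b510_fraud, n_fraud)
      ),
      hidden_valid_ts = list(
        n = sum(hv),
        pct = pct(sum(hv), n),
        max_completion = if (any(hv)) max(cm[hv]) else NA_real_
      ),
      screening = scr,
      conventions = list(
        local_band = "[01:00, 05:00) on the case's own clock, survey end timestamp",
        screening_band = "[00:00, 04:00) America/New_York",
        rounding = "percentages rounded half-up to 1 decimal"
      )
    ),
    class = "fraud_summary"
  )
}

#' @export
print.fraud_summary <- function(x, ...) {
  cat(sprintf("<fraud_summary> %d cases screened\n", x$n_cases))
  v <- x$verdicts
  for (i in seq_len(nrow(v))) {
    cat(sprintf("  %-11s %4d (%s%%)\n", v$verdict[i], v$n[i],
                formatC(v$pct[i], format = "f", digits = 1)))
  }
  cat(sprintf("  >1 indicator category: %d (%s%%)\n", x$n_multi_category,
              formatC(x$pct_multi_category, format = "f", digits = 1)))
  cat(sprintf("  submitted 01:00-04:59 local: %d (%s%%)\n", x$n_local_band,
              formatC(x$pct_local_band, format = "f", digits = 1)))
  if (!is.null(x$screening)) {
    cat(sprintf("  screening: %d records, %d passed (%s%%), %d (%s%%) in 00:00-03:59 Eastern\n",
                x$screening$n_screened, x$screening$n_passed,
                formatC(x$screening$pct_passed, format = "f", digits = 1),
                x$screening$n_band_eastern,
                formatC(x$screening$pct_band_eastern, format = "f", digits = 1)))
  }
  invisible(x)
}

#' Convert a cohort summary to JSON
#'
#' @param summary a `fraud_summary`.
#' @param path output path.
#' @return `path`, invisibly. The JSON object is versioned via its
#'   `schema_version` field.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(
    c(list(schema_version = "1.0"), unclass(summary)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

# --- end-to-end pipeline object -------------------------------------------

#' Screen a survey cohort end to end
#'
#' Runs the full pipeline: indicator detection, profile construction, case
#' classification, and cohort summary.
#'
#' @inheritParams detect_indicators
#' @param screening optional screening tibble (see [load_screening()]).
#' @return an object of class `fraud_screen` with elements `indicators`
#'   (flag table), `cases` (per-case classified tibble), `summary`
#'   (a `fraud_summary`), `params`, and `unverifiable` (fields that could
#'   not be checked).
#' @examples
#' fx <- generate_fixture(seed = 1)
#' scr <- screen_cohort(fx$responses, fx$schema,
#'                      zip_map = fraudsieve_zip_map(),
#'                      facilities = fraudsieve_facilities(),
#'                      channels = fraudsieve_channels(),
#'                      screening = fx$screening)
#' scr$summary
#' @export
screen_cohort <- function(responses, schema, zip_map = NULL, facilities = NULL,
                          channels = NULL, corpus = NULL, annotations = NULL,
                          screening = NULL, params = detector_params()) {
  flags <- detect_indicators(responses, schema, zip_map, facilities, channels,
                             corpus, annotations, params)
  classified <- classify_cases(build_profiles(flags, responses, schema))
  verif <- check_verifiable(responses, schema, zip_map, facilities, channels,
                            params)
  structure(
    list(
      indicators = flags,
      cases = classified,
      summary = summarize_cohort(classified, screening),
      params = params,
      unverifiable = attr(verif, "unverifiable")
    ),
    class = "fraud_screen"
  )
}

#' @export
print.fraud_screen <- function(x, ...) {
  cat(sprintf("<fraud_screen> %d cases, %d indicator flags\n",
              nrow(x$cases), nrow(x$indicators)))
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a screened cohort
#'
#' @param x a `fraud_screen`.
#' @param ... unused.
#' @return one row per case: `case_id`, `verdict`, `n_fraudulent`,
#'   `n_suspicious`, `completion_minutes`, `codes` (`;`-separated).
#' @method tidy fraud_screen
#' @export
tidy.fraud_screen <- function(x, ...) {
  x$cases |>
    dplyr::select("case_id", "verdict", "n_fraudulent", "n_suspicious",
                  "completion_minutes", codes = "codes_collapsed")
}

#' Glance at a screened cohort
#'
#' @param x a `fraud_screen`.
#' @param ... unused.
#' @return a one-row tibble of headline cohort statistics.
#' @method glance fraud_screen
#' @export
glance.fraud_screen <- function(x, ...) {
  s <- x$summary
  v <- stats::setNames(s$verdicts$pct, s$verdicts$verdict)
  tibble(
    n_cases = s$n_cases,
    pct_fraudulent = v[["fraudulent"]],
    pct_suspicious = v[["suspicious"]],
    pct_legitimate = v[["legitimate"]],
    pct_multi_category = s$pct_multi_category,
    pct_local_band = s$pct_local_band,
    mean_completion = s$completion$mean,
    sd_completion = s$completion$sd
  )
}

#' @method tidy fraud_summary
#' @export
tidy.fraud_summary <- function(x, ...) {
  dplyr::bind_rows(
    x$verdicts |>
      dplyr::transmute(metric = paste0("verdict_", .data$verdict),
                       n = .data$n, pct = .data$pct),
    x$categories |>
      dplyr::transmute(metric = paste0("category_", .data$category),
                       n = .data$n, pct = .data$pct),
    tibble(metric = "multi_category", n = x$n_multi_category,
           pct = x$pct_multi_category),
    tibble(metric = "local_band_01_05", n = x$n_local_band,
           pct = x$pct_local_band),
    tibble(metric = "hidden_and_valid_ts", n = x$hidden_valid_ts$n,
           pct = x$hidden_valid_ts$pct),
    if (!is.null(x$screening)) dplyr::bind_rows(
      tibble(metric = "screening_band_00_04", n = x$screening$n_band_eastern,
             pct = x$screening$pct_band_eastern),
      tibble(metric = "screening_passed", n = x$screening$n_passed,
             pct = x$screening$pct_passed)
    )
  )
}

#' Plot indicator prevalence for a screened cohort
#'
#' Bar chart of the share of cases carrying each indicator, coloured by
#' designation.
#'
#' @param object a `fraud_screen`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fraud_screen
#' @export
autoplot.fraud_screen <- function(object, ...) {
  prev <- object$indicators |>
    dplyr::count(.data$code, .data$designation) |>
    dplyr::mutate(pct = 100 * .data$n / nrow(object$cases))
  ggplot2::ggplot(prev, ggplot2::aes(
    x = stats::reorder(.data$code, .data$pct), y = .data$pct,
    fill = .data$designation
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of cases", fill = "Designation",
                  title = "Indicator prevalence") +
    ggplot2::theme_minimal()
}

#' Plot the completion-time distribution by verdict
#'
#' @param x a `fraud_screen`.
#' @param binwidth histogram bin width in minutes.
#' @return a ggplot object.
#' @export
plot_completion_times <- function(x, binwidth = 2) {
  d <- dplyr::filter(x$cases, .data$ts_valid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$completion_minutes,
                                  fill = .data$verdict)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(5, 10), linetype = "dashed") +
    ggplot2::labs(x = "Completion time (min)", y = "Cases", fill = "Verdict",
                  title = "Survey completion times") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
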