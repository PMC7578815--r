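#' Case verdict from indicator counts
#'
#' The classification rule is a pure function of the per-case indicator
#' counts: a case with at least one fraudulent indicator or at least three
#' suspicious indicators is *fraudulent*; a case with no fraudulent
#' indicators and one or two suspicious indicators is *suspicious*; a case
#' with neither is *legitimate*. The rule is monotone: adding an indicator
#' can only move a case toward the fraudulent verdict.
#'
#' @param n_fraudulent,n_suspicious non-negative integer vectors of equal
#'   length.
#' @return character vector of verdicts (`"fraudulent"`, `"suspicious"`,
#'   `"legitimate"`).
#' @examples
#' verdict_from_counts(1, 0)  # "fraudulent"
#' verdict_from_counts(0, 2)  # "suspicious"
#' verdict_from_counts(0, 0)  # "legitimate"
#' @export
verdict_from_counts <- function(n_fraudulent, n_suspicious) {
  stopifnot(length(n_fraudulent) == length(n_suspicious),
            all(n_fraudulent >= 0), all(n_suspicious >= 0))
  dplyr::case_when(
    n_fraudulent >= 1 | n_suspicious >= 3 ~ "fraudulent",
    n_suspicious >= 1 ~ "suspicious",
    .default = "legitimate"
  )
}

#' Classify cases from their indicator profiles
#'
#' @param profiles output of [build_profiles()].
#' @return the profiles tibble with `verdict` and `codes_collapsed` (the
#'   triggering codes as a `;`-separated string) columns added.
#' @export
classify_cases <- function(profiles) {
  profiles |>
    dplyr::mutate(
      verdict = verdict_from_counts(.data$n_fraudulent, .data$n_suspicious),
      codes_collapsed = vapply(.data$codes, paste, character(1), collapse = ";")
    )
}
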