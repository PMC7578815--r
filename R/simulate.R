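#' Default persona parameters
#'
#' Reads the packaged persona parameter constants. Four respondent personas
#' are modelled. *legitimate*: an attentive eligible respondent — completion
#' time log-normal around 15 minutes truncated below at 10 (so the persona
#' emits no time-band indicator by construction), consistent location fields,
#' daytime submission. *satisficer*: an eligible but careless respondent —
#' fast (around 7 minutes), prone to straight-lining, otherwise consistent.
#' *bot*: automated form completion — answers hidden items with probability
#' one, completes in about a minute, frequently masks a non-US origin.
#' *farm*: a coordinated human fraud operation — reuses answer templates from
#' a small shared pool, submits at night, and is often inconsistent on
#' verifiable fields.
#'
#' @return named list (one element per persona) of parameter lists with
#'   entries `completion_meanlog`, `completion_sdlog`, `completion_min`
#'   (log-normal location/scale and lower truncation, minutes),
#'   `night_prob` (submission in the 01:00-04:59 local band), `hidden_prob`,
#'   `template_reuse_prob`, `n_templates`, `zip_mismatch_prob`, `nonus_prob`,
#'   `facility_unknown_prob`, `referral_unknown_prob`, `straightline_prob`.
#' @export
default_persona_params <- function() {
  jsonlite::read_json(
    system.file("extdata", "persona_params.json", package = "fraudsieve"),
    simplifyVector = TRUE
  )
}

#' Simulate a survey cohort from a persona mixture
#'
#' Draws a persona for each case from the mixture, then draws the case's raw
#' record content (timestamps, closed/open/hidden answers, location fields)
#' from that persona's distributions. The persona assignment is emitted as a
#' ground-truth sidecar. Output is reproducible for a fixed seed.
#'
#' @param n number of cases (`>= 0`).
#' @param mix named numeric vector of persona proportions over
#'   `legitimate`, `satisficer`, `bot`, `farm` (must sum to 1 within 1e-9).
#' @param params persona parameters, see [default_persona_params()].
#' @param seed integer seed.
#' @return list with `responses` (raw export tibble), `personas` (sidecar
#'   tibble: `case_id`, `persona`), `schema`, `mix`, `seed`.
#' @examples
#' sim <- simulate_cohort(20, c(bot = 0.5, legitimate = 0.5), seed = 7)
#' table(sim$personas$persona)
#' @export
simulate_cohort <- function(n, mix, params = default_persona_params(), seed = 1) {
  stopifnot(n >= 0)
  if (is.null(names(mix)) || any(!nzchar(names(mix)))) {
    abort("`mix` must be a named vector of persona proportions.")
  }
  unknown <- setdiff(names(mix), names(params))
  if (length(unknown)) {
    abort(paste0("Unknown persona(s) in mix: ", paste(unknown, collapse = ", ")))
  }
  if (abs(sum(mix) - 1) > 1e-9) {
    abort(sprintf("Mixture proportions must sum to 1 (got %.12f).", sum(mix)))
  }
  schema <- fixture_schema()
  with_seed(seed, {
    persona <- if (n > 0) {
      sample(names(mix), n, replace = TRUE, prob = unname(mix))
    } else character(0)
    responses <- simulate_records(persona, params, schema)
    list(
      responses = responses,
      personas = tibble(case_id = responses$case_id, persona = persona),
      schema = schema, mix = mix, seed = seed
    )
  })
}

simulate_records <- function(persona, params, schema) {
  n <- length(persona)
  homes <- fixture_homes()
  facilities <- fraudsieve_facilities()
  day <- "2020-06-02"
  prm <- function(field) {
    vapply(persona, function(p) as.numeric(params[[p]][[field]]), numeric(1),
           USE.NAMES = FALSE)
  }
  draw <- function(prob) if (n > 0) stats::runif(n) < prob else logical(0)

  hm <- homes[sample(seq_len(nrow(homes)), n, replace = TRUE), , drop = FALSE]
  state <- hm$state
  zip <- hm$zip3
  zone <- hm$zone
  offset <- hm$offset

  zmis <- draw(prm("zip_mismatch_prob"))
  if (any(zmis)) {
    other <- (match(hm$state, homes$state)[zmis] %% nrow(homes)) + 1
    zip[zmis] <- homes$zip3[other]
  }
  nonus <- draw(prm("nonus_prob"))
  zone[nonus] <- "Asia/Shanghai"
  offset[nonus] <- 480L

  facility <- if (n > 0) sample(facilities, n, replace = TRUE) else character(0)
  facility[draw(prm("facility_unknown_prob"))] <- "Lakeside Vitality Wellness Collective"
  referral <- rep(c("Facebook", "Twitter"), length.out = n)
  referral[draw(prm("referral_unknown_prob"))] <- "Global Survey Rewards Network"

  dur <- pmax(prm("completion_min"),
              stats::rlnorm(n, prm("completion_meanlog"), prm("completion_sdlog")))
  night <- draw(prm("night_prob"))
  hour <- ifelse(night, sample(1:4, max(n, 1), replace = TRUE)[seq_len(n)],
                 sample(9:22, max(n, 1), replace = TRUE)[seq_len(n)])
  end_clock <- as.POSIXct(sprintf("%s %02d:%02d:%02d", day, hour,
                                  sample(0:59, max(n, 1), replace = TRUE)[seq_len(n)],
                                  sample(0:59, max(n, 1), replace = TRUE)[seq_len(n)]),
                          tz = "UTC")
  end_instant <- end_clock - offset * 60
  start_instant <- end_instant - round(dur * 60)

  closed_items <- schema_items(schema, "closed")
  closed <- matrix(sample(as.character(1:5), max(n, 1) * length(closed_items),
                          replace = TRUE)[seq_len(n * length(closed_items))],
                   nrow = n, ncol = length(closed_items),
                   dimnames = list(NULL, closed_items))
  closed_pages <- unique(schema$items$page_id[schema$items$kind == "closed"])
  for (pg in closed_pages) {
    cols <- intersect(schema$pages[[pg]], closed_items)
    if (length(cols) < 2 || n == 0) next
    same <- apply(closed[, cols, drop = FALSE], 1, function(r) length(unique(r)) == 1)
    if (any(same)) {
      v <- as.integer(closed[same, cols[2]])
      closed[same, cols[2]] <- as.character(v %% 5 + 1)
    }
  }
  straight <- draw(prm("straightline_prob"))
  for (i in which(straight)) {
    pg <- sample(closed_pages, 1)
    cols <- intersect(schema$pages[[pg]], closed_items)
    closed[i, cols] <- sample(as.character(1:5), 1)
  }

  open_items <- schema_items(schema, "open")
  open <- matrix("", nrow = n, ncol = length(open_items),
                 dimnames = list(NULL, open_items))
  reuse <- draw(prm("template_reuse_prob"))
  n_templates <- prm("n_templates")
  k <- 0
  for (i in seq_len(n)) {
    for (jj in seq_along(open_items)) {
      if (jj == 1 && reuse[i] && n_templates[i] >= 1) {
        open[i, jj] <- dup_template(sample.int(n_templates[i], 1))
      } else {
        k <- k + 1
        open[i, jj] <- filler_sentence(k)
      }
    }
  }

  hidden_items <- schema_items(schema, "hidden")
  hidden <- matrix("", nrow = n, ncol = length(hidden_items),
                   dimnames = list(NULL, hidden_items))
  hid <- draw(prm("hidden_prob"))
  if (length(hidden_items) > 0 && any(hid)) hidden[hid, 1] <- "N/A"

  responses <- dplyr::bind_cols(
    tibble(
      case_id = sprintf("sim%05d", seq_len(n)),
      start_ts = format_timestamp(start_instant, offset),
      end_ts = format_timestamp(end_instant, offset),
      tz = zone,
      reported_state = state, zip_prefix = zip, facility = facility,
      referral_source = referral,
      email_hash = sprintf("%08x", sample.int(.Machine$integer.max,
                                              max(n, 1))[seq_len(n)])
    ),
    as_tibble(closed), as_tibble(open), as_tibble(hidden)
  )
  responses[schema_columns(schema)]
}
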