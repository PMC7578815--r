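#' Composition profile for a replication fixture
#'
#' A composition profile specifies the joint indicator composition of a
#' synthetic cohort: how many cases exist, how many carry each indicator
#' marginal, and the screening funnel. [generate_fixture()] derives a
#' feasible case-by-case assignment from these marginals (the marginals
#' under-determine the joint assignment; the derived one is emitted as a
#' ground-truth sidecar) and refuses infeasible profiles with an error
#' naming the violated constraint.
#'
#' @param n_cases number of completed survey cases.
#' @param n_fraudulent,n_suspicious target verdict counts (the remainder of
#'   `n_cases` is legitimate).
#' @param n_verifiable cases carrying at least one verifiable-item
#'   inconsistency indicator.
#' @param n_hidden cases answering at least one hidden item.
#' @param n_hidden_valid_ts the subset of `n_hidden` with valid timestamps;
#'   these are given completion times under 2 minutes, the rest get
#'   unusable timestamps.
#' @param n_dup_text cases sharing an exact open-text duplicate (the only
#'   open-text indicator the fixture plants).
#' @param n_time_lt5,n_time_5to10 cases in the `[0,5)` and `[5,10)` minute
#'   completion bands.
#' @param n_local_band cases whose survey end falls in `[01:00, 05:00)` on
#'   the case's own clock.
#' @param n_multi_category cases exhibiting more than one indicator
#'   category.
#' @param n_screened,n_screen_band screening records in total and in the
#'   `[00:00, 04:00)` Eastern band; exactly `n_cases` screenings pass and
#'   are linked to survey cases.
#' @return an object of class `composition_profile`.
#' @export
composition_profile <- function(n_cases,
                                n_fraudulent = 0,
                                n_suspicious = 0,
                                n_verifiable = 0,
                                n_hidden = 0,
                                n_hidden_valid_ts = 0,
                                n_dup_text = 0,
                                n_time_lt5 = 0,
                                n_time_5to10 = 0,
                                n_local_band = 0,
                                n_multi_category = 0,
                                n_screened = n_cases,
                                n_screen_band = 0) {
  p <- list(
    n_cases = n_cases, n_fraudulent = n_fraudulent,
    n_suspicious = n_suspicious, n_verifiable = n_verifiable,
    n_hidden = n_hidden, n_hidden_valid_ts = n_hidden_valid_ts,
    n_dup_text = n_dup_text, n_time_lt5 = n_time_lt5,
    n_time_5to10 = n_time_5to10, n_local_band = n_local_band,
    n_multi_category = n_multi_category, n_screened = n_screened,
    n_screen_band = n_screen_band
  )
  if (any(unlist(p) < 0)) abort("Profile counts must be non-negative.")
  structure(p, class = "composition_profile")
}

#' The packaged pozzar2020 replication profile
#'
#' Encodes a 576-screening, 271-case cohort whose indicator composition
#' reproduces a published social-media recruitment fraud episode: 256
#' fraudulent and 15 suspicious cases; 235 with a verifiable-item
#' inconsistency; 44 hidden-item responders of whom 25 have valid timestamps
#' (all under 2 minutes); 138 exact-duplicate open-text cases; 63 and 70
#' cases in the under-5 and 5-to-10 minute bands; 128 submissions between
#' 01:00 and 05:00 local; 241 multi-category cases; and 475 of 576
#' screenings submitted between midnight and 04:00 Eastern.
#'
#' @return a [composition_profile()].
#' @export
pozzar2020_profile <- function() {
  composition_profile(
    n_cases = 271, n_fraudulent = 256, n_suspicious = 15,
    n_verifiable = 235, n_hidden = 44, n_hidden_valid_ts = 25,
    n_dup_text = 138, n_time_lt5 = 63, n_time_5to10 = 70,
    n_local_band = 128, n_multi_category = 241,
    n_screened = 576, n_screen_band = 475
  )
}

#' Named fixture profiles
#' @return named list of available [composition_profile()]s.
#' @export
fixture_profiles <- function() {
  list(pozzar2020 = pozzar2020_profile())
}

#' The fixture survey schema
#'
#' A scaled-down instrument in the style of a patient-provider communication
#' survey: five pages of six closed items each (responses 1-5), one page of
#' four open-ended items, and two hidden honeypot items.
#'
#' @return a [survey_schema()].
#' @export
fixture_schema <- function() {
  closed <- sprintf("c%02d", 1:30)
  pages <- list(
    p1 = c(closed[1:6], "h1"), p2 = closed[7:12], p3 = closed[13:18],
    p4 = c(closed[19:24], "h2"), p5 = closed[25:30],
    p6 = c("o1", "o2", "o3", "o4")
  )
  kinds <- c(stats::setNames(rep("closed", 30), closed),
             h1 = "hidden", h2 = "hidden",
             o1 = "open", o2 = "open", o3 = "open", o4 = "open")
  survey_schema(pages, kinds,
                domains = stats::setNames(rep(list(as.character(1:5)), 30), closed))
}

infeasible <- function(msg) abort(paste0("Infeasible composition profile: ", msg))

# Consistent (state, zip3, zone, offset-minutes) home locations; offsets are
# for the fixture date (2020-06-02, US daylight saving in effect).
fixture_homes <- function() {
  tibble(
    state = c("MA", "NY", "GA", "FL", "IL", "TX", "MN", "CO", "AZ", "CA", "WA", "OR"),
    zip3 = c("021", "100", "303", "331", "606", "770", "553", "802", "850", "900", "980", "972"),
    zone = c(rep("America/New_York", 4), rep("America/Chicago", 3),
             "America/Denver", "America/Phoenix", rep("America/Los_Angeles", 3)),
    offset = c(rep(-240L, 4), rep(-300L, 3), -360L, -420L, -420L, -420L, -420L),
    # a US zone NOT plausible for the state, for state/zone mismatch plants,
    # with its offset on the fixture date
    mismatch_zone = c(rep("America/Chicago", 4), rep("America/New_York", 3),
                      "America/Phoenix", "America/Denver",
                      rep("America/Denver", 3)),
    mismatch_offset = c(rep(-300L, 4), rep(-240L, 3), -420L, -360L,
                        rep(-360L, 3)),
    single_zone = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
                    TRUE, TRUE, TRUE)
  )
}

# Derive the per-case plan (group, planted codes, timing class) from a
# profile's marginals. Returns a tibble with one row per case.
derive_assignment <- function(p) {
  A <- p$n_hidden_valid_ts                       # hidden + valid ts, <2 min
  if (A > p$n_hidden) infeasible("n_hidden_valid_ts exceeds n_hidden")
  if (A > p$n_time_lt5) {
    infeasible("hidden cases with valid timestamps complete in under 2 minutes and must fit within n_time_lt5")
  }
  D <- p$n_hidden - A                            # hidden, invalid ts
  B <- p$n_time_lt5 - A                          # <5 min only
  C <- p$n_time_5to10
  L <- p$n_cases - p$n_fraudulent - p$n_suspicious
  if (L < 0) infeasible("n_fraudulent + n_suspicious exceeds n_cases")
  E <- p$n_fraudulent - p$n_time_lt5 - C - D
  if (E < 0) infeasible("time-band and hidden cases exceed n_fraudulent")
  if (p$n_dup_text > p$n_fraudulent) {
    infeasible("n_dup_text exceeds n_fraudulent (exact duplicates are a fraudulent indicator)")
  }
  if (p$n_dup_text == 1) infeasible("a duplicate group needs at least 2 cases")

  e_dup <- min(E, p$n_dup_text)
  c_dup <- min(C, p$n_dup_text - e_dup)
  rest_dup <- p$n_dup_text - e_dup - c_dup       # placed on A/B/D if any
  a_dup <- min(A, rest_dup)
  b_dup <- min(B, rest_dup - a_dup)
  d_dup <- rest_dup - a_dup - b_dup
  if (d_dup > D) infeasible("n_dup_text cases cannot all be placed")
  E_nonus <- E - e_dup                           # fraud route: non-US zone
  C_nonus <- C - c_dup

  if (p$n_verifiable < p$n_suspicious) {
    infeasible("suspicious cases carry one verifiable indicator each; n_verifiable < n_suspicious")
  }
  verif_fraud <- p$n_verifiable - p$n_suspicious
  if (verif_fraud > p$n_fraudulent) infeasible("n_verifiable exceeds the case budget")
  slots <- verif_fraud - (E_nonus + C_nonus)
  if (slots < 0) {
    infeasible("cases needing a non-US-zone fraud route exceed n_verifiable")
  }

  singles <- p$n_cases - p$n_multi_category
  f_singles <- singles - p$n_suspicious - L
  if (f_singles < 0) {
    infeasible("n_multi_category too large: suspicious and legitimate cases are single- or zero-category")
  }
  if (f_singles < E_nonus) {
    infeasible("n_multi_category too large: non-US-zone-only cases are single-category")
  }
  bare <- f_singles - E_nonus                    # cases left without a verifiable code
  bare_e <- min(bare, e_dup)
  bare_b <- min(bare - bare_e, B - b_dup)
  bare_d <- bare - bare_e - bare_b
  if (bare_d > D - d_dup) infeasible("n_multi_category too small for the case mix")
  covered <- (B - bare_b) + (D - bare_d) + (e_dup - bare_e) + b_dup + d_dup
  slots_rest <- slots - covered
  if (slots_rest < 0) {
    infeasible("n_verifiable too small to keep n_multi_category cases multi-category")
  }
  a_v <- min(slots_rest, A)
  c_v <- slots_rest - a_v
  if (c_v > c_dup + C_nonus) infeasible("n_verifiable too large for the case mix")

  grp <- function(group, n) {
    if (n <= 0) return(NULL)
    tibble(group = group, idx = seq_len(n))
  }
  plan <- dplyr::bind_rows(
    grp("A", A), grp("B", B), grp("C_dup", c_dup), grp("C_nonus", C_nonus),
    grp("D", D), grp("E_dup", e_dup), grp("E_nonus", E_nonus),
    grp("S", p$n_suspicious), grp("L", L)
  )
  if (is.null(plan) || nrow(plan) == 0) {
    plan <- tibble(group = character(0), idx = integer(0))
  }

  plan$hidden <- plan$group %in% c("A", "D")
  plan$valid_ts <- plan$group != "D"
  plan$time_band <- dplyr::case_when(
    plan$group %in% c("A", "B") ~ "lt5",
    plan$group %in% c("C_dup", "C_nonus") ~ "5to10",
    .default = "ge10"
  )
  plan$time_band[plan$group == "D"] <- "invalid"
  plan$dup <- plan$group %in% c("C_dup", "E_dup") |
    (plan$group == "A" & plan$idx <= a_dup) |
    (plan$group == "B" & plan$idx <= b_dup) |
    (plan$group == "D" & plan$idx <= d_dup)
  plan$nonus <- plan$group %in% c("C_nonus", "E_nonus")

  # suspicious-verifiable plants: S always; B/D/E_dup except their "bare"
  # tail; then A and C_dup to absorb remaining verifiable budget
  plan$verif_susp <- FALSE
  plan$verif_susp[plan$group == "S"] <- TRUE
  plan$verif_susp[plan$group == "B"] <- plan$idx[plan$group == "B"] <= B - bare_b
  plan$verif_susp[plan$group == "D"] <- plan$idx[plan$group == "D"] <= D - bare_d
  plan$verif_susp[plan$group == "E_dup"] <- plan$idx[plan$group == "E_dup"] <= e_dup - bare_e
  plan$verif_susp[plan$group == "A"] <- plan$idx[plan$group == "A"] <= a_v
  plan$verif_susp[plan$group == "C_dup"] <- plan$idx[plan$group == "C_dup"] <= c_v

  # which suspicious-verifiable code: cycle for variety; no state/zone plant
  # for invalid-timestamp or non-US-zone cases, zip-only for suspicious cases
  cyc <- c("ZIP_STATE_MISMATCH", "FACILITY_UNKNOWN", "REFERRAL_UNKNOWN",
           "STATE_TZ_MISMATCH")
  cyc_nots <- cyc[1:3]
  k <- which(plan$verif_susp)
  plan$verif_code <- NA_character_
  plan$verif_code[k] <- cyc[(seq_along(k) - 1) %% 4 + 1]
  no_ts <- plan$verif_susp & (!plan$valid_ts | plan$nonus)
  plan$verif_code[no_ts] <- cyc_nots[(seq_len(sum(no_ts)) - 1) %% 3 + 1]
  plan$verif_code[plan$group == "S"] <- "ZIP_STATE_MISMATCH"

  # local-hour band membership: fill in fixed group order among valid-ts cases
  if (p$n_local_band > sum(plan$valid_ts)) {
    infeasible("n_local_band exceeds the number of cases with valid timestamps")
  }
  ord <- order(match(plan$group, c("A", "B", "C_dup", "C_nonus", "E_dup",
                                   "E_nonus", "S", "L", "D")))
  eligible <- ord[plan$valid_ts[ord]]
  plan$in_band <- FALSE
  plan$in_band[eligible[seq_len(p$n_local_band)]] <- TRUE

  # planted indicator codes per case
  plan$codes <- lapply(seq_len(nrow(plan)), function(i) {
    codes <- character(0)
    if (plan$time_band[i] == "lt5") codes <- c(codes, "TIME_LT5")
    if (plan$time_band[i] == "5to10") codes <- c(codes, "TIME_5TO10")
    if (plan$dup[i]) codes <- c(codes, "DUP_TEXT")
    if (plan$nonus[i]) codes <- c(codes, "NONUS_TZ")
    if (plan$hidden[i]) codes <- c(codes, "HIDDEN_RESPONSE")
    if (plan$verif_susp[i]) codes <- c(codes, plan$verif_code[i])
    sort(codes)
  })
  plan
}

#' Generate a deterministic replication fixture
#'
#' Emits raw screening and survey records (timestamps, open texts with
#' planted duplicate templates, zip/state/zone values, hidden-item answers)
#' such that running the indicator battery recovers exactly the planted
#' indicator codes of the given [composition_profile()]. The two verbatim
#' duplicate sentences documented in the episode the pozzar2020 profile
#' replicates are planted literally (one shared by 2 cases, one by 6) when
#' the duplicate budget allows. Output is deterministic for a fixed seed.
#'
#' @param profile a [composition_profile()]; defaults to [pozzar2020_profile()].
#' @param seed integer seed; all randomness (times within bands, filler
#'   text, row order) derives from it.
#' @return a list with elements `responses` (raw survey export tibble),
#'   `screening` (screening export tibble), `schema` (the fixture
#'   [survey_schema()]), `truth` (ground-truth sidecar: `case_id`, `group`,
#'   `codes` `;`-separated, `valid_ts`, `in_band`), `truth_screening`
#'   (`screening_id`, `passed`, `in_band_eastern`, `case_id`), `profile`,
#'   and `seed`.
#' @export
generate_fixture <- function(profile = pozzar2020_profile(), seed = 1) {
  stopifnot(inherits(profile, "composition_profile"))
  if (profile$n_cases > profile$n_screened) {
    infeasible("n_cases passing screening exceeds n_screened")
  }
  if (profile$n_screen_band > profile$n_screened) {
    infeasible("n_screen_band exceeds n_screened")
  }
  plan <- derive_assignment(profile)
  schema <- fixture_schema()
  with_seed(seed, build_fixture_records(profile, plan, schema, seed))
}

# word pools for filler sentences and generated duplicate templates
.fill_adj <- c("honest", "patient", "gentle", "rushed", "careful", "kind",
               "thorough", "quiet", "direct", "warm", "calm", "frank",
               "helpful", "clear", "brisk", "attentive", "guarded", "open",
               "steady", "candid", "measured", "gracious", "precise", "blunt")
.fill_noun <- c("surgeon", "oncologist", "nurse", "resident", "pharmacist",
                "counselor", "team", "specialist", "physician", "assistant",
                "navigator", "clinician", "therapist", "dietitian", "fellow",
                "practitioner", "aide", "coordinator", "social worker",
                "technician", "intern", "doctor", "provider", "consultant")
.fill_words <- c("explained", "listened", "answered", "discussed", "reviewed",
                 "options", "questions", "results", "treatment", "schedule",
                 "appointment", "diagnosis", "recovery", "symptoms", "visits",
                 "clearly", "slowly", "twice", "together", "beforehand",
                 "afterwards", "honestly", "directly", "patiently", "openly",
                 "about", "during", "without", "between", "through",
                 "scans", "labs", "dosage", "referral", "paperwork", "billing",
                 "family", "support", "choices", "concerns")

filler_sentence <- function(k) {
  i1 <- (k - 1) %% 24 + 1
  i2 <- ((k - 1) %/% 24) %% 24 + 1
  i3 <- ((k - 1) %/% 576) %% 40 + 1
  paste(c(.fill_adj[i1], .fill_noun[i2], .fill_words[i3],
          sample(.fill_words, 5)), collapse = " ")
}

.tmpl_verb <- c("repeated", "summarized", "documented", "confirmed",
                "arranged", "described", "scheduled", "outlined", "recorded",
                "finalized", "updated", "restated", "clarified", "itemized",
                "collected", "prepared", "verified", "catalogued")
.tmpl_obj <- c("standard treatment information", "routine clinic materials",
               "general appointment details", "basic care instructions",
               "official discharge papers", "common therapy guidelines",
               "typical consent paperwork", "usual referral documents",
               "generic insurance forms", "plain medication lists",
               "simple visit summaries", "formal test protocols",
               "regular follow up notes", "initial intake records",
               "final billing statements", "complete pathology reports",
               "printed education handouts", "entire scheduling packets")

dup_template <- function(g) {
  i1 <- (g - 1) %% 18 + 1
  i2 <- ((g - 1) %/% 18) %% 18 + 1
  paste("the office", .tmpl_verb[i1], .tmpl_obj[i2], "for every patient")
}

episode_dup_sentences <- function() {
  c("professional and technical personnel carry out film packaging management",
    "the first choice surgery excision treatment, surgery pathology")
}

build_fixture_records <- function(profile, plan, schema, seed) {
  n <- nrow(plan)
  homes <- fixture_homes()
  facilities <- fraudsieve_facilities()
  day <- "2020-06-02"

  # home location: cases planted with a state/zone mismatch need a
  # single-zone home state so the mismatched zone is unambiguous
  needs_single <- !is.na(plan$verif_code) & plan$verif_code == "STATE_TZ_MISMATCH"
  single_rows <- which(homes$single_zone)
  home_idx <- sample(seq_len(nrow(homes)), n, replace = TRUE)
  home_idx[needs_single] <- single_rows[(seq_len(sum(needs_single)) - 1) %%
                                          length(single_rows) + 1]
  hm <- homes[home_idx, ]

  state <- hm$state
  zip <- hm$zip3
  zone <- hm$zone
  offset <- hm$offset
  facility <- sample(facilities, n, replace = TRUE)
  referral <- rep(c("Facebook", "Twitter"), length.out = n)

  # verifiable-item plants
  vc <- ifelse(is.na(plan$verif_code), "", plan$verif_code)
  zmis <- vc == "ZIP_STATE_MISMATCH"
  if (any(zmis)) {
    other <- (home_idx[zmis] %% nrow(homes)) + 1
    zip[zmis] <- homes$zip3[other]
  }
  tmis <- vc == "STATE_TZ_MISMATCH"
  zone[tmis] <- hm$mismatch_zone[tmis]
  offset[tmis] <- hm$mismatch_offset[tmis]
  facility[vc == "FACILITY_UNKNOWN"] <- "Lakeside Vitality Wellness Collective"
  referral[vc == "REFERRAL_UNKNOWN"] <- "Global Survey Rewards Network"
  zone[plan$nonus] <- "Asia/Shanghai"
  offset[plan$nonus] <- 480L

  # completion durations (minutes) by time band
  dur <- numeric(n)
  dur[plan$time_band == "lt5" & plan$hidden] <-
    stats::runif(sum(plan$time_band == "lt5" & plan$hidden), 0.7, 1.9)
  dur[plan$time_band == "lt5" & !plan$hidden] <-
    stats::runif(sum(plan$time_band == "lt5" & !plan$hidden), 2.2, 4.8)
  dur[plan$time_band == "5to10"] <-
    stats::runif(sum(plan$time_band == "5to10"), 5.3, 9.7)
  dur[plan$time_band == "ge10"] <-
    10.5 + stats::rlnorm(sum(plan$time_band == "ge10"), log(4), 0.6)

  # end timestamps: in-band cases end 01:00-04:59 local, others 09:00-22:59
  hour <- ifelse(plan$in_band, sample(1:4, n, replace = TRUE),
                 sample(9:22, n, replace = TRUE))
  end_clock <- as.POSIXct(sprintf("%s %02d:%02d:%02d", day, hour,
                                  sample(0:59, n, replace = TRUE),
                                  sample(0:59, n, replace = TRUE)),
                          tz = "UTC")
  end_instant <- end_clock - offset * 60
  start_instant <- end_instant - round(dur * 60)
  start_ts <- format_timestamp(start_instant, offset)
  end_ts <- format_timestamp(end_instant, offset)
  tz_col <- zone

  # invalid-timestamp cases: alternately blank both stamps or truncate the end
  bad <- which(!plan$valid_ts)
  blank <- bad[seq_along(bad) %% 2 == 1]
  trunc <- setdiff(bad, blank)
  start_ts[blank] <- ""
  end_ts[blank] <- ""
  tz_col[blank] <- ""
  end_ts[trunc] <- substr(end_ts[trunc], 1, 16)  # drop seconds and offset

  # closed items: varied answers, never straight-lining
  closed_items <- schema_items(schema, "closed")
  closed <- matrix(sample(as.character(1:5), n * length(closed_items),
                          replace = TRUE),
                   nrow = n, dimnames = list(NULL, closed_items))
  for (pg in unique(schema$items$page_id)) {
    cols <- intersect(schema$pages[[pg]], closed_items)
    if (length(cols) < 2) next
    same <- apply(closed[, cols, drop = FALSE], 1, function(r) length(unique(r)) == 1)
    if (any(same)) {
      v <- as.integer(closed[same, cols[2]])
      closed[same, cols[2]] <- as.character(v %% 5 + 1)
    }
  }

  # open items: planted duplicate templates + unique filler sentences
  open_items <- schema_items(schema, "open")
  open <- matrix("", nrow = n, ncol = length(open_items),
                 dimnames = list(NULL, open_items))
  dup_rows <- which(plan$dup)
  n_dup <- length(dup_rows)
  dup_item <- integer(0)
  dup_text <- character(0)
  if (n_dup > 0) {
    lit <- episode_dup_sentences()
    sizes <- integer(0)
    texts <- character(0)
    items <- integer(0)
    remaining <- n_dup
    if (remaining >= 8) {
      sizes <- c(6, 2); texts <- c(lit[2], lit[1]); items <- c(2, 4)
      remaining <- remaining - 8
    }
    if (remaining == 1 && length(sizes) > 0) {
      # a singleton can never be a duplicate: absorb it into the last group
      sizes[length(sizes)] <- sizes[length(sizes)] + 1
      remaining <- 0
    }
    g <- 0
    while (remaining > 0) {
      g <- g + 1
      sz <- if (remaining %% 2 == 1 && remaining >= 3) 3 else min(2, remaining)
      sizes <- c(sizes, sz)
      texts <- c(texts, dup_template(g))
      items <- c(items, (g - 1) %% length(open_items) + 1)
      remaining <- remaining - sz
    }
    dup_item <- rep(items, sizes)
    dup_text <- rep(texts, sizes)
    for (j in seq_along(dup_rows)) {
      open[dup_rows[j], dup_item[j]] <- dup_text[j]
    }
  }
  k <- 0
  for (i in seq_len(n)) {
    for (jj in seq_along(open_items)) {
      if (open[i, jj] == "") {
        k <- k + 1
        open[i, jj] <- filler_sentence(k)
      }
    }
  }

  # hidden items
  hidden_items <- schema_items(schema, "hidden")
  hidden <- matrix("", nrow = n, ncol = length(hidden_items),
                   dimnames = list(NULL, hidden_items))
  hrows <- which(plan$hidden)
  if (length(hrows) > 0 && length(hidden_items) > 0) {
    hidden[hrows, 1] <- rep(c("N/A", "none", "ok"), length.out = length(hrows))
    both <- hrows[plan$valid_ts[hrows]]
    if (length(hidden_items) > 1 && length(both) > 0) {
      hidden[both, 2] <- "N/A"
    }
  }

  case_id <- sprintf("case%04d", seq_len(n))
  responses <- dplyr::bind_cols(
    tibble(
      case_id = case_id, start_ts = start_ts, end_ts = end_ts, tz = tz_col,
      reported_state = state, zip_prefix = zip, facility = facility,
      referral_source = referral,
      email_hash = sprintf("%08x", sample.int(.Machine$integer.max, n))
    ),
    as_tibble(closed), as_tibble(open), as_tibble(hidden)
  )
  responses <- responses[schema_columns(schema)]
  responses <- responses[sample.int(n), , drop = FALSE]

  truth <- tibble(
    case_id = case_id,
    group = plan$group,
    codes = vapply(plan$codes, paste, character(1), collapse = ";"),
    valid_ts = plan$valid_ts,
    in_band = plan$in_band
  )

  # screening cohort
  ns <- profile$n_screened
  screening_id <- sprintf("scr%04d", seq_len(ns))
  passed <- rep(FALSE, ns)
  passed[sample.int(ns, profile$n_cases)] <- TRUE
  in_band_s <- rep(FALSE, ns)
  in_band_s[sample.int(ns, profile$n_screen_band)] <- TRUE
  sh <- ifelse(in_band_s, sample(0:3, ns, replace = TRUE),
               sample(6:23, ns, replace = TRUE))
  s_clock <- as.POSIXct(sprintf("%s %02d:%02d:%02d", day, sh,
                                sample(0:59, ns, replace = TRUE),
                                sample(0:59, ns, replace = TRUE)),
                        tz = "UTC")
  submitted_ts <- format_timestamp(s_clock + 240 * 60, -240L)
  screening <- tibble(screening_id = screening_id,
                      submitted_ts = submitted_ts,
                      passed = passed)
  truth_screening <- tibble(
    screening_id = screening_id, passed = passed, in_band_eastern = in_band_s,
    case_id = {
      cid <- rep(NA_character_, ns)
      cid[passed] <- case_id
      cid
    }
  )

  list(responses = responses, screening = screening, schema = schema,
       truth = truth, truth_screening = truth_screening,
       profile = profile, seed = seed)
}
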