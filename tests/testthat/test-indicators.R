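test_that("completion time bands are disjoint and half-open", {
  sch <- test_schema()
  mins <- c(4.0, 5.0, 7.5, 9.99, 10.0, 12.8, 0)
  cohort <- dplyr::bind_rows(lapply(seq_along(mins), function(i) {
    end <- as.POSIXct("2020-06-02 10:30:00", tz = "UTC")
    make_case(paste0("t", i),
              start_ts = format_timestamp(end - round(mins[i] * 60), -240L),
              end_ts = format_timestamp(end, -240L))
  }))
  flags <- detect_inattention(cohort, sch)
  got <- function(id) flags$code[flags$case_id == id]
  expect_equal(got("t1"), "TIME_LT5")    # 4.0 min
  expect_equal(got("t2"), "TIME_5TO10")  # exactly 5 -> suspicious band
  expect_equal(got("t3"), "TIME_5TO10")  # 7.5
  expect_equal(got("t4"), "TIME_5TO10")  # 9.99
  expect_length(got("t5"), 0)            # exactly 10 -> no band
  expect_length(got("t6"), 0)            # 12.8
  expect_equal(got("t7"), "TIME_LT5")    # 0 min

  # never both bands on one case, for random durations
  set.seed(71)
  rnd <- dplyr::bind_rows(lapply(1:200, function(i) {
    end <- as.POSIXct("2020-06-02 10:30:00", tz = "UTC")
    make_case(paste0("r", i),
              start_ts = format_timestamp(end - round(stats::runif(1, 0, 15) * 60), -240L),
              end_ts = format_timestamp(end, -240L))
  }))
  f <- detect_inattention(rnd, sch)
  both <- table(f$case_id[f$code %in% c("TIME_LT5", "TIME_5TO10")])
  expect_true(all(both <= 1))
})

test_that("invalid timestamps yield no time-band flags", {
  sch <- test_schema()
  cohort <- dplyr::bind_rows(
    make_case("inv1", end_ts = ""),
    make_case("inv2", start_ts = "garbled"),
    make_case("rev", start_ts = "2020-06-02T10:12:00-04:00",
              end_ts = "2020-06-02T10:00:00-04:00")
  )
  flags <- detect_inattention(cohort, sch)
  expect_equal(nrow(flags[flags$code %in% c("TIME_LT5", "TIME_5TO10"), ]), 0)
  cm <- completion_minutes(cohort, sch)
  expect_true(all(is.na(cm$completion_minutes)))
  expect_false(any(cm$ts_valid))
})

test_that("straight-lining needs >= 3 identical answered closed items on a page", {
  sch <- test_schema()
  flags <- detect_inattention(dplyr::bind_rows(
    make_case("flat", q = c("3", "3", "3", "3")),
    make_case("varied", q = c("3", "3", "2", "3")),
    make_case("two_answered", q = c("3", "3", "", ""))
  ), sch)
  sl <- flags$case_id[flags$code == "STRAIGHTLINE"]
  expect_equal(sl, "flat")
})

test_that("duplicate detection flags all sharers of a long-enough exact text", {
  sch <- test_schema()
  s1 <- "professional and technical personnel carry out film packaging management"
  cohort <- dplyr::bind_rows(
    make_case("a1", txt1 = s1),
    make_case("a2", txt1 = paste0("  ", toupper(substr(s1, 1, 1)), substr(s1, 2, nchar(s1)), ". ")),
    make_case("b1"), make_case("b2")
  )
  flags <- detect_duplicate_texts(cohort, sch)
  expect_setequal(flags$case_id, c("a1", "a2"))  # normalization unifies variants
  expect_true(all(flags$code == "DUP_TEXT"))

  # short shared token sequences are below the threshold
  short <- dplyr::bind_rows(lapply(1:40, function(i) {
    make_case(paste0("s", i), txt1 = "none")
  }))
  expect_equal(nrow(detect_duplicate_texts(short, sch)), 0)
  # ... but the threshold is configurable
  expect_equal(nrow(detect_duplicate_texts(short, sch,
                                           detector_params(min_tokens = 1))), 40)
})

test_that("duplicate detection is symmetric and permutation-invariant", {
  sch <- test_schema()
  cohort <- dplyr::bind_rows(
    make_case("x1", txt2 = "the first choice surgery excision treatment"),
    make_case("x2", txt2 = "the first choice surgery excision treatment"),
    make_case("x3"), make_case("x4"), make_case("x5")
  )
  base <- detect_duplicate_texts(cohort, sch)
  set.seed(9)
  for (i in 1:5) {
    shuffled <- cohort[sample.int(nrow(cohort)), ]
    f <- detect_duplicate_texts(shuffled, sch)
    expect_setequal(f$case_id, base$case_id)
  }
})

test_that("pattern clustering flags templated phrasing but not exact duplicates", {
  sch <- test_schema()
  tpl <- function(w) paste("the doctor recommended that i consider", w)
  cohort <- dplyr::bind_rows(
    make_case("p1", txt1 = tpl("surgery")),
    make_case("p2", txt1 = tpl("chemotherapy")),
    make_case("p3", txt1 = tpl("radiation")),
    make_case("u1", txt1 = "billing took forever to sort out"),
    make_case("u2", txt1 = "parking near the clinic was easy")
  )
  flags <- detect_pattern_texts(cohort, sch, detector_params(similarity_threshold = 0.3))
  expect_setequal(flags$case_id, c("p1", "p2", "p3"))
  # same at the shipped default threshold: pairwise similarity is 4/6
  flags6 <- detect_pattern_texts(cohort, sch)
  expect_setequal(flags6$case_id, c("p1", "p2", "p3"))

  # a cluster smaller than min_cluster is not flagged
  small <- dplyr::bind_rows(
    make_case("q1", txt1 = tpl("surgery")),
    make_case("q2", txt1 = tpl("chemotherapy")),
    make_case("q3", txt1 = "nothing else to add about my care")
  )
  expect_equal(nrow(detect_pattern_texts(small, sch)), 0)

  # exact duplicates are DUP_TEXT's job, not a pattern cluster
  dups <- dplyr::bind_rows(
    make_case("d1", txt1 = tpl("surgery")),
    make_case("d2", txt1 = tpl("surgery")),
    make_case("d3", txt1 = tpl("surgery"))
  )
  expect_equal(nrow(detect_pattern_texts(dups, sch)), 0)

  # fully dissimilar texts never cluster
  expect_equal(nrow(detect_pattern_texts(dplyr::bind_rows(
    make_case("z1"), make_case("z2"), make_case("z3")
  ), sch)), 0)
})

test_that("corpus matching requires a verbatim long-enough substring", {
  sch <- test_schema()
  doc <- "Ovarian cancer care involves many specialists. The first choice is surgical excision followed by pathology review."
  cohort <- dplyr::bind_rows(
    make_case("m1", txt1 = "The first choice is surgical excision followed by pathology review"),
    make_case("m2", txt1 = "some entirely original thought here today"),
    make_case("m3", txt1 = "cancer care involves")  # 3 tokens < 5
  )
  flags <- detect_corpus_matches(cohort, sch, corpus = doc)
  expect_equal(flags$case_id, "m1")
  expect_equal(nrow(detect_corpus_matches(cohort, sch, corpus = character(0))), 0)
})

test_that("nonsense flags are a validated passthrough of reviewer annotations", {
  sch <- test_schema()
  cohort <- make_cohort(3)
  ann <- tibble::tibble(case_id = "c2", item_id = "txt1")
  flags <- flag_nonsense(cohort, sch, ann)
  expect_equal(flags$case_id, "c2")
  expect_equal(flags$code, "NONSENSE_TEXT")
  expect_equal(nrow(flag_nonsense(cohort, sch, ann[0, ])), 0)
  expect_error(flag_nonsense(cohort, sch,
                             tibble::tibble(case_id = "ghost", item_id = "txt1")),
               "unknown case_id")
  expect_error(flag_nonsense(cohort, sch,
                             tibble::tibble(case_id = "c1", item_id = "q1")),
               "unknown open item")
})

test_that("verifiable-item checks match the documented contracts", {
  sch <- test_schema()
  zm <- fraudsieve_zip_map()
  fac <- fraudsieve_facilities()
  ch <- fraudsieve_channels()
  codes_for <- function(case) {
    f <- check_verifiable(case, sch, zm, fac, ch)
    sort(f$code)
  }
  # zip 900 maps to CA, state says MA
  expect_equal(codes_for(make_case("z", zip_prefix = "900")), "ZIP_STATE_MISMATCH")
  # non-US zone is fraudulent and subsumes the state/zone comparison
  expect_equal(codes_for(make_case("n", tz = "Asia/Shanghai",
                                   start_ts = "2020-06-02T22:00:00+08:00",
                                   end_ts = "2020-06-02T22:12:00+08:00")),
               "NONUS_TZ")
  # a US zone implausible for the state
  expect_equal(codes_for(make_case("t", tz = "America/Chicago")), "STATE_TZ_MISMATCH")
  # unknown facility and unknown referral organization
  expect_equal(codes_for(make_case("f", facility = "Lakeside Vitality Wellness Collective")),
               "FACILITY_UNKNOWN")
  expect_equal(codes_for(make_case("r", referral_source = "Global Survey Rewards Network")),
               "REFERRAL_UNKNOWN")
  # fully consistent case: no flags
  expect_length(codes_for(make_case("okc")), 0)
  # unmappable inputs are unverifiable, not flagged
  f <- check_verifiable(make_case("u", zip_prefix = "999", reported_state = ""),
                        sch, zm, fac, ch)
  expect_equal(nrow(f), 0)
  expect_true(any(attr(f, "unverifiable")$field == "zip/state"))
})

test_that("hidden-item responses are flagged only when non-empty", {
  sch <- test_schema()
  flags <- detect_hidden_responses(dplyr::bind_rows(
    make_case("h_na", h1 = "N/A"),
    make_case("h_sp", h1 = "   "),
    make_case("h_empty", h1 = "")
  ), sch)
  expect_equal(flags$case_id, "h_na")

  # a schema without hidden items never flags
  no_hidden <- survey_schema(pages = list(p1 = c("q1", "txt1")),
                             kinds = c(q1 = "closed", txt1 = "open"))
  expect_equal(nrow(detect_hidden_responses(
    make_case("x")[c("case_id", "q1", "txt1")], no_hidden)), 0)
})

test_that("adding hidden text only ever adds the automation flag", {
  sch <- test_schema()
  base <- dplyr::bind_rows(make_case("a", zip_prefix = "900"), make_case("b"))
  with_hidden <- base
  with_hidden$h1 <- c("bot text", "x")
  f0 <- detect_indicators(base, sch, fraudsieve_zip_map(),
                          fraudsieve_facilities(), fraudsieve_channels())
  f1 <- detect_indicators(with_hidden, sch, fraudsieve_zip_map(),
                          fraudsieve_facilities(), fraudsieve_channels())
  for (id in c("a", "b")) {
    before <- f0$code[f0$case_id == id]
    after <- f1$code[f1$case_id == id]
    expect_true(all(before %in% after))
    expect_setequal(setdiff(after, before), "HIDDEN_RESPONSE")
  }
})

test_that("profiles count each code once per case", {
  sch <- test_schema()
  # same duplicated text in both open items: one DUP_TEXT code
  cohort <- dplyr::bind_rows(
    make_case("d1", txt1 = "one two three four five", txt2 = "one two three four five"),
    make_case("d2", txt1 = "one two three four five", txt2 = "one two three four five"),
    make_case("clean")
  )
  flags <- detect_indicators(cohort, sch)
  prof <- build_profiles(flags, cohort, sch)
  d1 <- prof[prof$case_id == "d1", ]
  expect_equal(d1$codes[[1]], "DUP_TEXT")
  expect_equal(d1$n_fraudulent, 1L)
  clean <- prof[prof$case_id == "clean", ]
  expect_equal(clean$n_fraudulent + clean$n_suspicious, 0L)
  expect_equal(clean$codes[[1]], character(0))
  # counts recomputable from the designation table
  des <- indicator_codes()
  for (i in seq_len(nrow(prof))) {
    cs <- prof$codes[[i]]
    expect_equal(prof$n_fraudulent[i],
                 sum(des$designation[match(cs, des$code)] == "fraudulent"))
  }
})
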