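classify_all <- function(cohort, sch = test_schema()) {
  flags <- detect_indicators(cohort, sch, fraudsieve_zip_map(),
                             fraudsieve_facilities(), fraudsieve_channels())
  classify_cases(build_profiles(flags, cohort, sch))
}

test_that("a two-case cohort splits 50/50 and percents sum to 100", {
  cohort <- dplyr::bind_rows(
    make_case("f1", h1 = "bot"),
    make_case("s1", zip_prefix = "900")
  )
  s <- summarize_cohort(classify_all(cohort))
  expect_equal(s$verdicts$pct, c(50.0, 50.0, 0.0))
  expect_equal(sum(s$verdicts$pct), 100, tolerance = 0.1)
})

test_that("the local-hour band is [01:00, 05:00) on the case's own clock", {
  cohort <- dplyr::bind_rows(
    case_ending_at("h00", 0), case_ending_at("h01", 1),
    case_ending_at("h04", 4), case_ending_at("h05", 5),
    # 04:30 in Shanghai: in band on its own clock even though UTC differs
    case_ending_at("cn", 4, offset = "+08:00", tz = "Asia/Shanghai"),
    make_case("inv", end_ts = "")
  )
  s <- summarize_cohort(classify_all(cohort))
  expect_equal(s$n_local_band, 3)  # h01, h04, cn; h00 and h05 excluded
  expect_equal(s$pct_local_band, pct(3, 6))
})

test_that("the screening band is [00:00, 04:00) Eastern with funnel percents", {
  scr <- tibble::tibble(
    screening_id = sprintf("s%d", 1:5),
    submitted_ts = c(
      "2020-06-02T00:00:00-04:00",  # boundary: in
      "2020-06-02T03:59:59-04:00",  # in
      "2020-06-02T04:00:00-04:00",  # boundary: out
      "2020-06-02T01:30:00+08:00",  # 13:30 Eastern previous day: out
      "2020-06-01T23:30:00-05:00"   # 00:30 Eastern: in, zone-converted
    ),
    passed = c(TRUE, TRUE, FALSE, FALSE, TRUE)
  )
  s <- summarize_cohort(classify_all(make_cohort(2)), screening = scr)
  expect_equal(s$screening$n_band_eastern, 3)
  expect_equal(s$screening$pct_band_eastern, pct(3, 5))
  expect_equal(s$screening$n_passed, 3)
  expect_equal(s$screening$pct_passed, pct(3, 5))
})

test_that("summaries are invariant to case order", {
  set.seed(31)
  cohort <- dplyr::bind_rows(
    make_cohort(6),
    make_case("f1", h1 = "a"), make_case("f2", h1 = "b"),
    make_case("s1", zip_prefix = "900"),
    case_ending_at("n1", 2), case_ending_at("n2", 3)
  )
  ref <- summarize_cohort(classify_all(cohort))
  for (i in 1:3) {
    shuf <- cohort[sample.int(nrow(cohort)), ]
    s <- summarize_cohort(classify_all(shuf))
    expect_equal(s$verdicts, ref$verdicts)
    expect_equal(s$categories, ref$categories)
    expect_equal(s$n_local_band, ref$n_local_band)
    expect_equal(s$n_multi_category, ref$n_multi_category)
  }
})

test_that("an empty cohort yields zero counts and missing percents", {
  s <- summarize_cohort(classify_all(make_cohort(0)))
  expect_equal(s$n_cases, 0)
  expect_true(all(is.na(s$verdicts$pct)))
  expect_true(is.na(s$completion$mean))
})

test_that("verdict counts always partition the cohort", {
  set.seed(59)
  for (rep in 1:3) {
    n <- sample(5:25, 1)
    cohort <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      id <- sprintf("r%d_%d", rep, i)
      kind <- sample(c("clean", "zip", "hidden", "fast"), 1)
      switch(kind,
        clean = make_case(id),
        zip = make_case(id, zip_prefix = "900"),
        hidden = make_case(id, h1 = "x"),
        fast = make_case(id, start_ts = "2020-06-02T10:09:00-04:00",
                         end_ts = "2020-06-02T10:12:00-04:00")
      )
    }))
    s <- summarize_cohort(classify_all(cohort))
    expect_equal(sum(s$verdicts$n), n)
    expect_equal(sum(s$verdicts$pct), 100, tolerance = 0.1)
  }
})

test_that("tidy and glance expose the summary as tibbles", {
  cohort <- dplyr::bind_rows(make_case("f1", h1 = "x"), make_case("l1"))
  scr <- screen_with_defaults(cohort)
  td <- tidy(scr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_true(all(c("case_id", "verdict", "codes") %in% names(td)))
  g <- glance(scr)
  expect_equal(nrow(g), 1)
  expect_equal(g$pct_fraudulent, 50.0)
  expect_s3_class(autoplot(scr), "ggplot")
})
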