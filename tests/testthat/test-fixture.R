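test_that("the packaged replication profile is feasible and fully structured", {
  fx <- generate_fixture(seed = 1)
  p <- pozzar2020_profile()
  expect_equal(nrow(fx$responses), p$n_cases)
  expect_equal(nrow(fx$screening), p$n_screened)
  expect_equal(sum(fx$screening$passed), p$n_cases)
  expect_equal(nrow(fx$truth), p$n_cases)
  expect_setequal(fx$responses$case_id, fx$truth$case_id)
  # ground-truth marginals equal the profile's
  codes <- strsplit(fx$truth$codes, ";", fixed = TRUE)
  has <- function(code) sum(vapply(codes, function(z) code %in% z, logical(1)))
  expect_equal(has("HIDDEN_RESPONSE"), p$n_hidden)
  expect_equal(has("DUP_TEXT"), p$n_dup_text)
  expect_equal(has("TIME_LT5"), p$n_time_lt5)
  expect_equal(has("TIME_5TO10"), p$n_time_5to10)
  expect_equal(sum(fx$truth$in_band), p$n_local_band)
  expect_equal(sum(!fx$truth$valid_ts), p$n_hidden - p$n_hidden_valid_ts)
})

test_that("fixture generation is deterministic for a fixed seed", {
  expect_identical(generate_fixture(seed = 7), generate_fixture(seed = 7))
  a <- generate_fixture(seed = 7)
  b <- generate_fixture(seed = 8)
  expect_false(identical(a$responses, b$responses))
})

test_that("the verbatim duplicate sentences are planted with their group sizes", {
  fx <- generate_fixture(seed = 1)
  open_cols <- schema_items(fx$schema, "open")
  all_text <- normalize_text(unlist(fx$responses[open_cols]))
  expect_equal(sum(all_text == normalize_text(
    "professional and technical personnel carry out film packaging management")), 2)
  expect_equal(sum(all_text == normalize_text(
    "the first choice surgery excision treatment, surgery pathology")), 6)
})

test_that("a degenerate one-case profile yields a single legitimate record", {
  prof <- composition_profile(n_cases = 1, n_screened = 1)
  fx <- generate_fixture(prof, seed = 3)
  expect_equal(nrow(fx$responses), 1)
  expect_equal(fx$truth$codes, "")
  scr <- screen_with_defaults(fx$responses, fx$schema)
  expect_equal(scr$cases$verdict, "legitimate")
})

test_that("infeasible profiles are refused with the violated constraint named", {
  # 5 duplicate-text cases among 4 records
  expect_error(
    generate_fixture(composition_profile(n_cases = 4, n_fraudulent = 4,
                                         n_dup_text = 5), seed = 1),
    "n_dup_text"
  )
  # a single duplicate case can never be a duplicate
  expect_error(
    generate_fixture(composition_profile(n_cases = 4, n_fraudulent = 4,
                                         n_dup_text = 1), seed = 1),
    "at least 2"
  )
  # more hidden-with-valid-timestamps than hidden
  expect_error(
    generate_fixture(composition_profile(n_cases = 10, n_fraudulent = 5,
                                         n_hidden = 2, n_hidden_valid_ts = 3,
                                         n_time_lt5 = 3), seed = 1),
    "n_hidden"
  )
  # more passing screenings than screening records
  expect_error(
    generate_fixture(composition_profile(n_cases = 10, n_screened = 5), seed = 1),
    "n_screened"
  )
  expect_error(composition_profile(n_cases = -1), "non-negative")
})

test_that("fixture raw records carry no stray indicators for clean groups", {
  fx <- generate_fixture(seed = 2)
  scr <- screen_with_defaults(fx$responses, fx$schema)
  cases <- dplyr::left_join(
    fx$truth,
    dplyr::select(scr$cases, "case_id", "verdict", "n_fraudulent"),
    by = "case_id"
  )
  legit_planted <- cases[cases$codes == "", ]
  if (nrow(legit_planted) > 0) {
    expect_true(all(legit_planted$verdict == "legitimate"))
  }
  # suspicious group: exactly one suspicious code, never fraudulent
  susp <- cases[cases$group == "S", ]
  expect_true(all(susp$verdict == "suspicious"))
  expect_true(all(susp$n_fraudulent == 0))
})
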