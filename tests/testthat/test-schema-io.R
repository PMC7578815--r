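test_that("schema construction validates structure", {
  sch <- test_schema()
  expect_s3_class(sch, "survey_schema")
  expect_equal(nrow(sch$items), 7)
  expect_equal(schema_items(sch, "hidden"), "h1")
  expect_equal(schema_items(sch, "open"), c("txt1", "txt2"))

  # item with a kind but on no page
  expect_error(
    survey_schema(pages = list(p1 = "q1"), kinds = c(q1 = "closed", q9 = "open")),
    "not placed on any page"
  )
  expect_error(
    survey_schema(pages = list(p1 = c("q1", "q1")), kinds = c(q1 = "closed")),
    "Duplicate item"
  )
  # degenerate: zero pages, zero items
  empty <- survey_schema(pages = list(), kinds = character(0))
  expect_equal(nrow(empty$items), 0)
})

test_that("schema JSON round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  sch <- test_schema()
  write_schema(sch, path)
  back <- load_schema(path)
  expect_equal(back$pages, sch$pages)
  expect_equal(back$items, sch$items)
  expect_equal(back$identity_fields, sch$identity_fields)
  expect_error(load_schema("no/such/file.json"), "not found")
})

test_that("response export round-trips field-identically", {
  sch <- test_schema()
  cohort <- make_cohort(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(cohort, path)
  back <- load_responses(path, sch)
  expect_equal(nrow(attr(back, "data_errors")), 0)
  attr(back, "data_errors") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})

test_that("loading surfaces data errors without dropping rows", {
  sch <- test_schema()
  cohort <- dplyr::bind_rows(
    make_case("ok1"),
    make_case("rev", start_ts = "2020-06-02T10:12:00-04:00",
              end_ts = "2020-06-02T10:00:00-04:00"),   # end before start
    make_case("bad_ts", end_ts = "not a time"),
    make_case("bad_zip", zip_prefix = "02139")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(cohort, path)
  back <- load_responses(path, sch)
  expect_equal(nrow(back), 4)  # nothing dropped
  err <- attr(back, "data_errors")
  expect_setequal(err$case_id, c("rev", "bad_ts", "bad_zip"))
  expect_true(any(err$case_id == "rev" & err$problem == "end before start"))
})

test_that("duplicate case ids and missing columns are load errors", {
  sch <- test_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(dplyr::bind_rows(make_case("dup"), make_case("dup")), path)
  expect_error(load_responses(path, sch), "Duplicate case_id")

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(dplyr::select(make_case("c1"), -"txt2"), path2)
  expect_error(load_responses(path2, sch), "missing schema columns")
})

test_that("zip-region map enforces state coverage and resolves known prefixes", {
  zm <- fraudsieve_zip_map()
  expect_equal(unname(zm$zip3_to_state[["021"]]), "MA")
  expect_true("America/New_York" %in% zm$state_to_zones[["MA"]])
  expect_setequal(zm$us_zones, unique(unlist(zm$state_to_zones)))

  expect_error(
    zip_region_map(data.frame(zip3 = "021", state = "MA"),
                   data.frame(state = "CA", zone = "America/Los_Angeles")),
    "no time-zone entry"
  )
})

test_that("an empty map is valid and makes geographic checks unverifiable", {
  empty <- zip_region_map(data.frame(zip3 = character(0), state = character(0)),
                          data.frame(state = character(0), zone = character(0)))
  flags <- check_verifiable(make_case("c1"), test_schema(), zip_map = empty)
  expect_equal(nrow(flags[flags$code %in%
    c("ZIP_STATE_MISMATCH", "STATE_TZ_MISMATCH", "NONUS_TZ"), ]), 0)
  unv <- attr(flags, "unverifiable")
  expect_true(any(unv$field == "zip/state"))
  expect_true(any(unv$field == "time zone"))
})

test_that("screening export round-trips with logical passed column", {
  path <- withr::local_tempfile(fileext = ".csv")
  scr <- tibble::tibble(
    screening_id = c("s1", "s2"),
    submitted_ts = c("2020-06-02T01:10:00-04:00", "2020-06-02T13:00:00-04:00"),
    passed = c(TRUE, FALSE)
  )
  write_screening(scr, path)
  back <- load_screening(path)
  expect_equal(back$passed, c(TRUE, FALSE))
  expect_equal(back$screening_id, scr$screening_id)
})
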