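# In-code fixtures: a compact two-page schema and a builder for raw cases.

test_schema <- function() {
  survey_schema(
    pages = list(p1 = c("q1", "q2", "q3", "q4", "h1"), p2 = c("txt1", "txt2")),
    kinds = c(q1 = "closed", q2 = "closed", q3 = "closed", q4 = "closed",
              h1 = "hidden", txt1 = "open", txt2 = "open")
  )
}

# one fully consistent, unremarkable case; override fields to plant indicators
make_case <- function(case_id,
                      start_ts = "2020-06-02T10:00:00-04:00",
                      end_ts = "2020-06-02T10:12:00-04:00",
                      tz = "America/New_York",
                      reported_state = "MA", zip_prefix = "021",
                      facility = "Dana-Farber Cancer Institute",
                      referral_source = "Facebook",
                      q = c("1", "3", "2", "5"),
                      # ids woven in so no two cases share a token trigram
                      txt1 = sprintf("notes %s from %s visit", case_id, case_id),
                      txt2 = sprintf("extra %s comment %s here", case_id, case_id),
                      h1 = "") {
  tibble::tibble(
    case_id = case_id, start_ts = start_ts, end_ts = end_ts, tz = tz,
    reported_state = reported_state, zip_prefix = zip_prefix,
    facility = facility, referral_source = referral_source,
    email_hash = paste0("hash", case_id),
    q1 = q[1], q2 = q[2], q3 = q[3], q4 = q[4],
    h1 = h1, txt1 = txt1, txt2 = txt2
  )
}

make_cohort <- function(n, prefix = "c") {
  if (n == 0) return(make_case("template")[0, ])
  dplyr::bind_rows(lapply(seq_len(n), function(i) make_case(paste0(prefix, i))))
}

# end timestamp at a given local clock hour, with matching start
case_ending_at <- function(case_id, hour, minutes = 12, offset = "-04:00", ...) {
  end <- sprintf("2020-06-02T%02d:30:00%s", hour, offset)
  start <- sprintf("2020-06-02T%02d:%02d:00%s", hour, 30 - minutes %% 30, offset)
  make_case(case_id, start_ts = start, end_ts = end, ...)
}

screen_with_defaults <- function(responses, schema = test_schema(), ...) {
  screen_cohort(responses, schema,
                zip_map = fraudsieve_zip_map(),
                facilities = fraudsieve_facilities(),
                channels = fraudsieve_channels(), ...)
}
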