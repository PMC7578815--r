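# fraudsieve

Screening of online-survey cohorts for fraudulent and low-quality
responses.

Health researchers who recruit survey participants through social media
routinely receive large bursts of fraudulent submissions — from bots that
auto-complete forms, from coordinated "survey farms" chasing remuneration,
and from careless (satisficing) respondents. Because such studies often
collect no IP addresses, screening has to work from the survey content
itself: timestamps, free-text answers, honeypot items, and fields that can
be cross-checked against each other. `fraudsieve` implements that
content-based screening as a reusable, testable pipeline for data managers
and research-integrity reviewers.

## The method

Each completed case is checked against a battery of thirteen indicators in
four categories, each with a fixed *designation*:

| Category | Indicator | Designation |
|---|---|---|
| Inattention | completion time < 5 min | fraudulent |
| | completion time in \[5, 10) min | suspicious |
| | straight-lining (identical answer to every closed item on a page) | suspicious |
| Open text | exact response (≥ 3 tokens) shared by > 1 respondent | fraudulent |
| | nonsensical / irrelevant response (human-annotated) | suspicious |
| | several responses with the same phrasing pattern | suspicious |
| | verbatim match to a reference corpus | suspicious |
| Verifiable items | reported state vs. zip-code prefix mismatch | suspicious |
| | reported state vs. timestamp time zone mismatch | suspicious |
| | treatment facility not a known cancer-care facility | suspicious |
| | timestamp time zone outside the US | fraudulent |
| | referral source not a recruitment channel | suspicious |
| Automation | response to a hidden (honeypot) item | fraudulent |

With `n_F` the number of fraudulent-designated and `n_S` the number of
suspicious-designated indicators present in a case (each indicator counted
at most once per case), the verdict is

    fraudulent  iff  n_F ≥ 1  or  n_S ≥ 3
    suspicious  iff  n_F = 0  and 1 ≤ n_S ≤ 2
    legitimate  iff  n_F = n_S = 0

Cohort reports add hour-of-submission summaries (the 01:00–04:59 band on
the respondent's own clock; the 00:00–03:59 Eastern band for eligibility
screenings); submission hour is reported but deliberately never used as an
indicator, since legitimate night-owl respondents exist. All percentages
round half-up to one decimal. Duplicate detection is exact match on
normalized text (case-fold, whitespace collapse, terminal punctuation
stripped); pattern detection is single-linkage clustering of token-trigram
Jaccard similarity; facility/referral matching is normalized Levenshtein
similarity with a 0.85 threshold.

The package also ships two generators: a persona-mixture simulator
(`simulate_cohort()`: legitimate / satisficer / bot / farm personas with
documented parameter constants) and a deterministic replication fixture
(`generate_fixture()`) whose indicator composition matches a published
fraud episode, with a ground-truth sidecar for round-trip testing.

## Worked example

```r
library(fraudsieve)

fx  <- generate_fixture(seed = 1)          # 576 screenings, 271 surveys
scr <- screen_cohort(fx$responses, fx$schema,
                     zip_map    = fraudsieve_zip_map(),
                     facilities = fraudsieve_facilities(),
                     channels   = fraudsieve_channels(),
                     screening  = fx$screening)
scr
#> <fraud_screen> 271 cases, 550 indicator flags
#> <fraud_summary> 271 cases screened
#>   fraudulent   256 (94.5%)
#>   suspicious    15 (5.5%)
#>   legitimate     0 (0.0%)
#>   >1 indicator category: 241 (88.9%)
#>   submitted 01:00-04:59 local: 128 (47.2%)
#>   screening: 576 records, 271 passed (47.0%), 475 (82.5%) in 00:00-03:59 Eastern
```

94.5% of cases are classified fraudulent and 5.5% suspicious; none are
legitimate. 88.9% of cases show more than one indicator category, and 47.2%
were submitted between 1 and 5 am on the respondent's own clock — the
night-hour signature of coordinated fraud. Per-case detail is a tibble away:

```r
head(tidy(scr), 4)
#> # A tibble: 4 × 6
#>   case_id  verdict    n_fraudulent n_suspicious completion_minutes codes
#>   <chr>    <chr>             <int>        <int>              <dbl> <chr>
#> 1 case0147 fraudulent            1            1               NA   FACILITY_UNKNOWN;HIDDEN_RESPONSE
#> 2 case0002 fraudulent            2            1                1.6 FACILITY_UNKNOWN;HIDDEN_RESPONSE;TIME_LT5
#> 3 case0252 fraudulent            1            0               13.6 DUP_TEXT
#> 4 case0166 fraudulent            1            1               15.6 DUP_TEXT;ZIP_STATE_MISMATCH
```

`glance(scr)` gives the one-row cohort summary, `autoplot(scr)` an
indicator-prevalence chart, and `plot_completion_times(scr)` the
completion-time histogram with the 5/10-minute band boundaries.

A command-line front end (`inst/cli/fraudsieve.R`) exposes the same
pipeline as `screen`, `fixture`, `simulate` and `report` subcommands for
use outside R.

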