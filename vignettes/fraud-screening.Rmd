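---
title: "Screening online survey cohorts for fraudulent and low-quality responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening online survey cohorts for fraudulent and low-quality responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraudsieve)
```

## The screening problem

Online surveys recruited through social media attract three kinds of
problematic respondents alongside genuine participants: bots that fill
forms automatically, coordinated human "survey farms" that complete
incentivized surveys at scale, and eligible but careless respondents
(satisficers). When no IP addresses are collected — common in health
research, where an IP address is treated as an identifier — screening must
rely entirely on the content of the submission. `fraudsieve` operationalizes
a content-based screening protocol: a battery of per-case indicator
detectors, a fixed classification rule, and a cohort-level report.

The method assumes a survey instrument designed for screenability:
start and end timestamps, at least one hidden honeypot item, open-ended
items, and pairs of fields that can be cross-checked (reported state
against zip-code prefix, reported state against the timestamp's time
zone, treatment facility against a registry, referral source against the
recruitment channels actually used).

## Indicators and the classification rule

Thirteen indicators are organized in four categories (inattention, open
text, verifiable items, automation); each carries a fixed designation.
*Fraudulent* indicators — completion under 5 minutes, an exact duplicate
open-text answer shared across respondents, a non-US timestamp zone, any
response to a hidden item — strongly suggest automation or
misrepresentation. *Suspicious* indicators could arise from honest error
or carelessness. A case is **fraudulent** with at least one fraudulent
indicator or at least three suspicious ones, **suspicious** with one or
two suspicious indicators and no fraudulent one, and **legitimate**
otherwise. Each indicator counts at most once per case however many items
trigger it: the battery is a case-level checklist, and the rule's
thresholds are calibrated to case-level counts.

The rule is monotone — adding an indicator can only move a case toward
the fraudulent verdict — and `verdict_from_counts()` is a pure function
of the two counts, which the test suite checks against an exhaustively
enumerated truth table.

Hour of submission is deliberately **not** an indicator. Cohort reports
summarize the 01:00–04:59 band on the respondent's own clock (and the
00:00–03:59 Eastern band for screening questionnaires) because night-hour
bursts are the signature of coordinated fraud, but legitimate respondents
do complete surveys at night, so the hour never affects a verdict.

## Tunable parameters

| Parameter | Default | Role |
|---|---|---|
| `min_tokens` | 3 | minimum token count for a shared open-text answer to count as a duplicate; implements "more than 2–3 words" as ≥ 3 tokens after normalization |
| `similarity_threshold` | 0.6 | token-trigram Jaccard threshold for phrasing-pattern clusters |
| `min_cluster` | 3 | minimum distinct cases in a phrasing cluster before members are flagged |
| `corpus_min_tokens` | 5 | minimum token count for a verbatim corpus match |
| `fuzzy_threshold` | 0.85 | normalized Levenshtein similarity for facility/referral matching; tolerates spelling variants while rejecting unrelated names |
| `min_straightline_items` | 3 | answered closed items a page needs before straight-lining is meaningful (a one-item page trivially "straight-lines") |

Text normalization (case-fold, whitespace collapse, strip terminal
punctuation, no stemming) is shared by the duplicate, pattern and corpus
detectors: exactness is the criterion, so stemming would over-trigger.
Judging an answer *nonsensical or irrelevant* is left to a human reviewer
via an annotation file that the pipeline validates and applies verbatim —
automating that judgment would invent a method rather than implement one.

## Numerical and convention choices

- **Completion-time bands are disjoint and half-open**: `[0, 5)` minutes
  is fraudulent, `[5, 10)` suspicious, and a case is never in both. The
  two bands partition the fast cases, which keeps inattention counts
  additive.
- **Hour bands are half-open** (`[01:00, 05:00)` local, `[00:00, 04:00)`
  Eastern): "between 1 and 5 am" is ambiguous at the boundary, and the
  half-open convention is the reproducible choice. It is recorded in the
  report's `conventions` field.
- **Percentages round half-up to one decimal** (`round_half_up()`), the
  convention used in published survey reports, rather than R's
  round-to-even.
- **Invalid timestamps are values, not errors.** A case whose stamps do
  not parse (or whose end precedes its start) is retained, annotated, and
  excluded only from time-dependent indicators, mirroring protocols that
  restrict completion-time analyses to cases with valid timestamp data.
- **A non-US zone subsumes the state/zone comparison**: such a case gets
  the fraudulent non-US flag only, not an additional state/zone mismatch —
  the state comparison is only meaningful within the US zone set.
- **Unverifiable is not inconsistent.** Unknown zip prefixes, missing
  states, empty registries or an empty zip-region map produce no flags;
  the affected fields are reported as unverifiable. Benefit of the doubt
  is deliberate: a screening pipeline should not punish missing reference
  data.
- **Zip prefix is the 3-digit sectional-center prefix**, the standard
  granularity at which a prefix maps to a state.

## What the generators emulate

`simulate_cohort()` draws cases from four personas whose parameters are
packaged constants (`default_persona_params()`), not hidden defaults:

- *legitimate*: log-normal completion around 15 minutes **truncated below
  at 10**, so the persona emits no time-band indicator by construction;
  consistent location fields; daytime submission.
- *satisficer*: fast (≈ 7 minutes), straight-lining with probability 0.6,
  otherwise consistent — the profile of a careless but genuine respondent.
- *bot*: answers hidden items with probability 1, completes in about a
  minute, submits at night, often with a non-US zone.
- *farm*: reuses open-text templates from a small shared pool (probability
  0.65 over 8 templates, so collisions — and hence duplicate flags — are
  near-certain in cohorts of tens of farm cases), submits at night, and is
  frequently inconsistent on verifiable fields.

With these defaults the personas separate on mean completion time
(bot < farm < legitimate), all-bot cohorts classify 100% fraudulent,
all-legitimate cohorts 0%, and the fraudulent fraction of a mixed cohort
tracks the planted fraud-persona share.

`generate_fixture()` serves a different purpose: a *deterministic
replication cohort* whose indicator composition equals a set of published
marginal counts (the packaged `pozzar2020` profile: 271 cases, 256
fraudulent, 15 suspicious, 235 with verifiable inconsistencies, 44
hidden-item responders of whom 25 have valid timestamps, 138 duplicate-text
cases, 63 + 70 in the two time bands, 128 night-band submissions, 241
multi-category cases, and a 576-record screening funnel with 475 in the
Eastern night band). Marginals under-determine the joint assignment of
codes to cases; the generator derives one feasible assignment
deterministically and emits it as a ground-truth sidecar. Notable choices
in that derivation:

- All open-text flags are planted as exact duplicates. The published
  open-text count conflates "duplicate or unusual" responses, and the
  exact-duplicate route is the only fraudulent-designated one consistent
  with the fraud-count arithmetic.
- The published 63 + 70 = 133 inattention split is only consistent with
  disjoint time bands, so the fixture plants no straight-lining-only
  inattention case.
- The 19 hidden-item cases beyond the 25 with valid timestamps receive
  deliberately unusable timestamps (blank or truncated stamps), so the
  hidden-and-valid overlap is exactly 25, all under 2 minutes.
- Cases in the 5–10-minute band need a fraudulent code to reach the
  fraudulent verdict; they receive duplicates where the duplicate budget
  allows and a non-US zone otherwise.
- Completion times for cases outside the fast bands are drawn above 10
  minutes; the published cohort mean is *not* imposed, because per-case
  times were never published and forcing moments would fabricate data.
- The two verbatim duplicate sentences documented in the replicated
  episode are planted literally (shared by 2 and 6 cases), so the
  published worked examples are live test inputs.

The profile constructor checks feasibility and names the violated
constraint (for example, five duplicate cases among four records).

What passing tests on these cohorts does **not** show: real cohorts
contain paraphrased rather than exact duplicates, plausible-but-fake
facilities that fuzzy-match real ones, satisficers indistinguishable from
farms on content alone, and legitimate night-shift respondents. The
simulator's personas are stylized; detector performance on the fixture is
a correctness check of the pipeline, not an estimate of real-world
sensitivity or specificity.

## Problem sizes and runtime

The shipped test suite screens the full 271-case replication cohort
(plus its 576 screenings) at three seeds, simulates persona cohorts of
50–300 cases, and runs property checks over a 220-case randomized cohort —
sizes chosen so the whole suite completes in well under a minute on a
single core while still exercising every detector at cohort scale. The
pattern clusterer is the only quadratic step (pairwise trigram Jaccard
within each open item's distinct texts); at a few hundred texts per item
this is a second or two, and larger cohorts would warrant an inverted
trigram index.

## Limitations

- Exact-duplicate detection misses paraphrase; the pattern clusterer
  catches shared templates but depends on the trigram threshold.
- The zip3/state and state/zone tables ship as small editable fixtures
  covering common states; production use should supply complete tables
  (users can pass their own paths).
- Facility and referral checks are only as good as the supplied registry
  and channel lists.
- No IP-based checks: the pipeline is designed for studies that collect
  no IP addresses; where IPs exist, VPS-detection tools complement it.
- Corpus matching searches only user-supplied documents; there is no live
  web search.
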