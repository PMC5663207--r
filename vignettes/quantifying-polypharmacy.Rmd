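---
title: "Quantifying polypharmacy from prescription claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polypharmacy from prescription claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrx)
library(data.table)
```

## The problem

Concomitant use of multiple prescription drugs — polypharmacy — is a major
driver of drug-related morbidity, yet real-world co-prescription patterns
are hard to characterize directly: pharmacy claims record individual
dispensing events, not periods of joint exposure. polyrx implements a
complete pipeline that turns a claims table (patient identifier, drug code,
age at fill in days, days of supply, payment) into incidence tables of
multi-drug combination exposure at the drug-ingredient and ATC level-2
class level, together with overrepresentation statistics, publication-format
record files, and profiling/sensitivity tools. Because real claims
warehouses are proprietary, the package also ships a synthetic cohort
generator with planted, known co-prescription structure, so every stage can
be validated against ground truth.

## Exposure model

Patient time is divided into discrete, non-overlapping windows of
`window_days` (default 30 — the single most common days-of-supply, hence the
natural prescription timescale), anchored at age 0 by integer division of
age-in-days. A prescription filled at age $a$ with $d$ days of supply
exposes the patient over the closed day interval $[a, a+d-1]$, and the
patient is considered exposed in every window that interval touches:

$$ \text{windows}(a, d) = \left\{ \left\lfloor a/w \right\rfloor, \dots,
   \left\lfloor (a+d-1)/w \right\rfloor \right\}. $$

With this closed-interval convention a 30-day supply filled exactly on a
window boundary occupies exactly one 30-day window. Duplicate exposures
(overlapping refills of the same ingredient in one window) collapse to a
single event. The scanner is pure integer arithmetic;
`day_level_exposures()` provides a brute-force one-row-per-exposed-day
reference implementation, and the test suite requires the two to agree
exactly on random inputs.

Fixed anchoring creates *partial windows* at the ends of each patient's
enrollment. With enrollment start offsets uniform modulo the window length,
partial windows cover on average about half a window (15 days at the
default): `window_universe()` counts them and reports their mean covered
duration, so the size of this censoring effect is always measurable.

Known model limitations, accepted deliberately: exposure equals dispensed
supply (no adherence adjustment, no stockpiling), and two prescriptions a
few days apart may fall in different windows while two separated by most of
a month may share one. These are the costs of a counting scheme that scales
linearly and ranks common combinations robustly.

```{r windowing}
prescription_windows(100, 30, 30)   # days 100-129 touch windows 3 and 4
prescription_windows(29, 2, 30)     # a 2-day script straddling a boundary
```

## Exact and "at-least" combination counts

Each exposed `(patient, window)` carries a set of distinct ingredients. The
*exact* count of a combination is the number of windows whose set equals it
(no additional drugs); the sum of exact counts therefore equals the number
of exposed windows, an invariant asserted on every run. The *at-least*
count of a combination is the number of windows whose set contains it. A
window with $k$ drugs contributes to exactly $2^k - 1$ at-least keys, so
at-least counting operates on the summarized exact table — orders of
magnitude smaller than the raw windows — via a per-drug inverted index and
set intersection (`atleast_count()`), with a naive superset-sum
(`atleast_count_naive()`) kept as an independent cross-check.

Enumerating all combinations is infeasible and pointless (most never
occur), so candidate N-drug combinations for $N = 2..5$ are generated from
the $(N-1)$-drug combinations meeting a support threshold (default 1000
windows; scale it down with cohort size). The gate is the Apriori rule —
*every* $(N-1)$-subset must qualify — which, by anti-monotonicity of
at-least counts, can never miss a combination whose own count reaches the
threshold. We read the looser phrase "constructing N-drug combinations from
N-minus-1 subset combinations" as this all-subsets rule precisely because
it is the only interpretation with that no-false-negative guarantee.

Class-level counting replaces each ingredient by the level-2 prefix
(letter-digit-digit) of its single *primary* ATC code and deduplicates, so
a class is counted once per window no matter how many of its members the
patient takes. Selecting the primary code among multiple ATC assignments is
an input contract of the vocabulary tables, not something the package
guesses. Ingredients without a well-formed code are dropped with a tally.

## Overrepresentation statistics

For a combination $S$ with at-least count $a(S)$:

* `fraction_exact` $= \text{exact}(S) / a(S)$ — how often the combination
  occurs with no additional drugs;
* `fraction_all_windows` $= a(S) / W_{\text{exposed}}$ — its incidence
  among windows with any prescription;
* `observe_per_expect_1s` $= a(S) \big/ \left[ W \prod_{d \in S} a(\{d\})/W
  \right]$ — observed over expected under independence of the single
  drugs ($N > 1$);
* `observe_per_expect_N1` $= \min_{d \in S} a(S) \big/ \left[ a(S \setminus
  d)\, a(\{d\}) / W \right]$ — the smallest of the $N$ partitions of $S$
  into an $(N-1)$-subset plus one drug ($N > 2$), measuring enrichment
  beyond the combination's own subsets. For $N = 2$ the two definitions
  coincide, so only the first is reported.

**Choice of the expectation universe $W$.** `fraction_all_windows` uses
$W_{\text{exposed}}$, the count of windows with at least one prescription,
exactly as the published column is defined. For the *expected-incidence*
denominator, however, the package uses the full count of eligibility
windows (exposed or not, from `window_universe()`): conditioning marginal
frequencies and the expectation on exposed windows makes the ratio of two
independently prescribed drugs converge to the exposed-window fraction
(about 0.5–0.6 in realistic cohorts) rather than 1, destroying the
interpretation of 1.0 as "no enrichment". With the full universe, the
independence null is exactly 1, which the test suite verifies on simulated
cohorts — and which makes the planted-enrichment oracle a meaningful
recovery target. `combo_stats()` exposes this as `W_expected`, defaulting
to `W_exposed` for self-contained use.

A further caveat computed faithfully rather than enforced: the claim that
the subset-based ratio always exceeds the single-drug ratio holds
algebraically only when every proper subset has ratio at most 1 — the
identity
$\texttt{N1}(S) = \texttt{1s}(S) / \max_d \texttt{1s}(S \setminus d)$
holds on every record (and is tested), so strongly enriched subsets push
`observe_per_expect_N1` *below* `observe_per_expect_1s`.

Ratios with a zero (or censored) marginal are undefined and emitted as
empty fields — never 0 or infinity.

Combination daily cost is the sum of the per-ingredient medians of payment
per day of supply (midpoint interpolation for even counts). Additivity is
the minimal assumption, and the column is labelled an estimate; for
combination products the full claim payment is attached to each
constituent ingredient's cost sample, a documented upward bias. Cost is
undefined at the class level.

## Record files

`write_drug_records()` / `write_class_records()` emit one tab-delimited
file per combination size (`db_drugs_1s.tsv` … `db_atc_classes_5s.tsv`)
with the exact published column set and order. Inclusion and privacy follow
`emission_policy()`: all singles and pairs; combinations of 3–5 drugs only
with at least 10,000 at-least windows; any exposure count below 100
patient-windows rendered as `"<100"`. Because the source text does not
settle whether masking covers both count columns or only the exact count,
`mask_columns` is configurable, defaulting to both (the conservative
reading). Rows sort by descending at-least count, ties by canonical key.
`read_records()` parses masked cells into a censored representation (flag
plus upper bound), never a number, and a write–read–write cycle is
byte-identical; rows whose at-least count is censored keep their incoming
order at the tail of the file, since their true ranks are destroyed by
masking. Undefined statistics round-trip as empty fields.

## The synthetic cohort generator

`simulate_cohort()` draws, per patient, one contiguous enrollment period:
length in months from a discretized log-normal (median ≈ 29–30 months,
10th–90th percentile ≈ 8–84 months) and a uniform random start age, so
window offsets are uniform. Correlated multi-drug refills come from latent
chronic conditions (`condition_spec()`): a patient has each condition
independently with its prevalence; while a per-cycle Bernoulli persistence
draw succeeds, *all* of the condition's drugs are refilled back-to-back
(next fill at previous fill + days of supply) starting at enrollment
start, truncated so every fill's supply fits inside eligibility. Acute
prescriptions arrive as a Poisson process (default 5 per patient-year)
with a short-duration-dominated days-of-supply mix, drawn uniformly over
the acute drug list; combination products expand to multiple ingredients
downstream. Payments are rate × days-of-supply × log-normal noise with
median multiplier 1, so the per-ingredient median payment-per-day recovers
the configured rate.

The default parameterization was chosen to match the claims profile the
source cohort reports — about one claim per patient-month, roughly half of
claims as 30-day supplies and about a fifth at 10 days or fewer — which the
defaults reproduce (≈ 0.98 claims/patient-month, 57% 30-day, 21% ≤ 10-day
at seed 1; the duration-mix test checks the acute mix against its
configured distribution at n > 10,000 claims). Claim intensity matters
beyond realism: in claim-sparse cohorts the window-length sensitivity can
reverse direction, because chronic windows (constant drug count) thin out
faster than acute singleton windows merge.

What the generator deliberately does **not** emulate: demographic
composition (age/sex strata, Medicare fraction), calendar-time trends and
non-stationary prescribing, imperfect adherence, and between-drug payment
structure beyond a per-drug daily rate. Passing tests therefore demonstrate
the *counting machinery* is correct and that planted statistical structure
is recovered — not that any simulated incidence matches a real cohort's.

All generator parameters are free configuration, documented as such, not
estimates of any proprietary database. Fixing the seed fixes the output
exactly; `planted_enrichment()` estimates a pair's true observed/expected
ratio by replicate simulation pushed through the *day-level reference*
scanner (never the production path), giving an independent oracle with a
Monte-Carlo standard error.

## Numerical and degenerate-input choices

* Claims with missing or non-positive days of supply, or negative fill age,
  are rejected with a tally — never silently coerced.
* Unmapped drug codes and unclassifiable ingredients are dropped with
  tallies reported alongside the results and in the pipeline manifest.
* Quantiles of the drugs-per-window distribution use the inverse-ECDF
  definition (`type = 1`), so reported percentiles are observed integers.
* Combination keys are canonically sorted, `"|"`-joined strings; ties in
  record ordering break lexicographically on the key.
* The outcome relative-risk screen isolates each patient's first event and
  uses a day-level 30-day lookback ending the day before the event (the
  literal reading of "30 days prior"); the discrete-window alternative is
  available via `method = "window"`. The pre-event fraction is computed
  over exposed lookbacks, matching the exposed-window universe of
  `fraction_all_windows`, so independently scheduled events give RR ≈ 1.
* Record-file numbers are written with 17 significant digits so doubles
  round-trip exactly.

## Scale of the bundled validation

The package validates at desk scale, chosen to finish in minutes on one
core: oracle-equivalence on thousands of random claims; exhaustive
subset-query checks on cohorts of up to 12 distinct drugs; independence
null and planted-pair recovery on ten replicate cohorts of 2,000 patients
against a Monte-Carlo oracle of dozens of replicates; partial-window
behavior on 10,000 patients. No claim is made that the artifact reaches
the hundreds of millions of combinations of a full claims warehouse; the
design (summarized exact table, inverted index, threshold-gated candidate
generation, columnar intermediates) is the one that scales there, but the
properties verified here are property-based, not scale benchmarks.

## A worked run

```{r pipeline}
cfg <- cohort_config(n_patients = 500, seed = 7)
cohort <- simulate_cohort(cfg)
vocab <- demo_vocabulary()

out <- file.path(tempdir(), "records")
manifest <- run_pipeline(cohort, mapping = vocab$mapping, out_dir = out,
                         support_threshold = 20,
                         class_names = vocab$classes)
manifest$W_exposed
manifest$exact_combos

pairs <- read_records(file.path(out, "db_drugs_2s.tsv"))
singles <- read_records(file.path(out, "db_drugs_1s.tsv"))
head(codrug_profile("metformin", pairs, singles), 3)
```

The planted metabolic-syndrome cluster (metformin + lisinopril +
simvastatin) surfaces immediately: its members co-occur with metformin in
nearly every metformin window and far above chance.
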