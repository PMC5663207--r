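library(data.table)

## Build an exposure table from a list of per-window drug sets.
## Each element of `windows` is a character vector of items; windows are
## assigned consecutive indices for a single patient unless patient ids are
## supplied.
exposures_from_windows <- function(windows, patient = "P1") {
  rbindlist(lapply(seq_along(windows), function(i) {
    data.table(patient_id = patient,
               window_index = i - 1L,
               ingredient = sort(unique(windows[[i]])))
  }))
}

## Toy 3-drug vocabulary: drugs A and B share ATC level-2 class Q01,
## drug C is in class R01.
toy_mapping <- function() {
  drug_mapping(
    list(A = "A", B = "B", C = "C"),
    data.frame(ingredient = c("A", "B", "C"),
               rxcui = c("1", "2", "3"),
               umls_cui = c("C1", "C2", "C3"),
               drugbank_id = c("DB1", "DB2", "DB3"),
               atc_code = c("Q01AA01", "Q01AB01", "R01AA01"),
               atc_name = c("CLASS Q", "CLASS Q", "CLASS R"))
  )
}

## Random ingredient-level claims for oracle comparisons.
random_claims <- function(n, n_drugs = 6L, n_patients = 20L,
                          max_age = 3000L, max_supply = 120L, seed = 1L) {
  set.seed(seed)
  data.table(
    patient_id = sprintf("P%03d", sample.int(n_patients, n, replace = TRUE)),
    ingredient = sprintf("drug%02d", sample.int(n_drugs, n, replace = TRUE)),
    fill_age_days = sample.int(max_age, n, replace = TRUE) - 1L,
    days_supply = sample.int(max_supply, n, replace = TRUE),
    payment = round(stats::runif(n, 1, 200), 2)
  )
}

## Enrollment distribution concentrated on a single length, in months.
fixed_enrollment <- function(months) {
  data.frame(months = as.integer(months), prob = 1)
}

## Small cohort with one coupled pair planted on top of acute noise.
planted_pair_config <- function(n_patients, seed,
                                prevalence = 0.2, persistence = 0.95) {
  cohort_config(
    n_patients, seed = seed,
    conditions = list(condition_spec("planted", prevalence, c("A", "B"),
                                     persistence)),
    acute_rate = 1.0,
    acute_drugs = c("x1", "x2", "x3", "x4"),
    combination_products = list()
  )
}

## Acute-only cohort: every drug assigned independently.
independent_config <- function(n_patients, seed, acute_rate = 2.0,
                               drugs = c("x1", "x2", "x3", "x4")) {
  cohort_config(
    n_patients, seed = seed, conditions = list(),
    acute_rate = acute_rate, acute_drugs = drugs,
    combination_products = list()
  )
}

## All non-empty subsets (as keys) of an item vector, up to max_size.
all_subsets <- function(items, max_size = length(items)) {
  items <- sort(unique(items))
  unlist(lapply(seq_len(min(max_size, length(items))), function(k) {
    utils::combn(items, k, paste, collapse = "|")
  }))
}
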