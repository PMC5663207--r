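#' Specify a chronic condition driving correlated refills
#'
#' A condition is a latent patient attribute that, when present, causes the
#' patient to fill all of the condition's drugs together on a monthly refill
#' schedule for as long as a per-cycle persistence draw succeeds. Conditions
#' are the mechanism by which the simulator plants co-prescription structure
#' (and hence overrepresented drug combinations) into a cohort.
#'
#' @param name Condition label, used in the ground-truth assignment table.
#' @param prevalence Probability in `[0, 1]` that a patient has the condition.
#' @param drugs Character vector of drug codes co-prescribed while the
#'   condition's refills persist. Must be non-empty.
#' @param refill_persistence Probability in `[0, 1]` that each refill cycle is
#'   followed by another; `1` means the patient refills until eligibility ends.
#' @param days_supply Days of supply per fill (default 30, the canonical
#'   chronic-prescription duration).
#' @return A `polyrx_condition` list.
#' @export
#' @examples
#' condition_spec("metabolic", 0.15,
#'                c("metformin", "lisinopril", "simvastatin"), 0.97)
condition_spec <- function(name, prevalence, drugs, refill_persistence,
                           days_supply = 30L) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_prob(prevalence, "prevalence")
  .check_prob(refill_persistence, "refill_persistence")
  if (length(drugs) == 0L)
    stop("condition '", name, "': drugs must be non-empty", call. = FALSE)
  if (anyDuplicated(drugs))
    stop("condition '", name, "': duplicated drugs", call. = FALSE)
  days_supply <- as.integer(days_supply)
  if (is.na(days_supply) || days_supply < 1L)
    stop("condition '", name, "': days_supply must be >= 1", call. = FALSE)
  structure(list(name = name, prevalence = prevalence,
                 drugs = as.character(drugs),
                 refill_persistence = refill_persistence,
                 days_supply = days_supply),
            class = "polyrx_condition")
}

.check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("invalid configuration: '", field, "' must be a probability in [0, 1]",
         call. = FALSE)
  invisible(x)
}

.check_distribution <- function(d, field, value_col) {
  if (!is.data.frame(d) || !all(c(value_col, "prob") %in% names(d)))
    stop("invalid configuration: '", field, "' must be a data.frame with ",
         "columns '", value_col, "' and 'prob'", call. = FALSE)
  if (nrow(d) == 0L || any(d$prob < 0) || sum(d$prob) <= 0)
    stop("invalid configuration: '", field, "' probabilities must be ",
         "non-negative and sum to a positive value", call. = FALSE)
  v <- d[[value_col]]
  if (any(v != as.integer(v)) || any(v < 1L))
    stop("invalid configuration: '", field, "' values must be positive integers",
         call. = FALSE)
  invisible(d)
}

#' Default chronic conditions for the bundled demonstration vocabulary
#'
#' Five condition clusters loosely patterned on the major chronic therapy
#' areas that dominate outpatient co-prescription (metabolic syndrome,
#' hypertension, cardiac disease, hypothyroidism, depression). Prevalences
#' and persistence values are illustrative simulator settings, not estimates
#' of any real cohort.
#'
#' @return List of [condition_spec()] objects.
#' @export
default_conditions <- function() {
  list(
    condition_spec("metabolic", 0.15,
                   c("metformin", "lisinopril", "simvastatin"), 0.97),
    condition_spec("hypertension", 0.20,
                   c("hydrochlorothiazide", "amlodipine"), 0.96),
    condition_spec("cardiac", 0.05, c("metoprolol", "warfarin"), 0.97),
    ## stable single-drug maintenance therapy is commonly dispensed as
    ## 90-day supplies
    condition_spec("hypothyroid", 0.08, "levothyroxine", 0.98,
                   days_supply = 90L),
    condition_spec("depression", 0.10, "sertraline", 0.95,
                   days_supply = 90L)
  )
}

#' Default enrollment-length distribution (months)
#'
#' Discretized log-normal over 6--96 months with median close to 30 months
#' and a long right tail, emulating the eligibility-duration profile typical
#' of commercial claims cohorts (median observation around two and a half
#' years, 10th--90th percentile spanning roughly 8 to 84 months).
#'
#' @return data.frame with columns `months` and `prob`.
#' @export
default_enrollment_months <- function() {
  ## meanlog slightly above log(30) compensates for the right truncation at
  ## 96 months, putting the realized median at 29-30 months
  months <- 6:96
  w <- stats::dlnorm(months, meanlog = log(32.5), sdlog = 0.92)
  data.frame(months = months, prob = w / sum(w))
}

#' Default duration mix for acute prescriptions
#'
#' Half the mass at 10 days or fewer, the rest spread over 14- to 90-day
#' scripts. Together with the default chronic conditions and acute rate
#' this yields a cohort-wide days-of-supply mix of roughly half 30-day
#' supplies with about a fifth of claims at 10 days or fewer, the profile
#' typical of outpatient claims.
#'
#' @return data.frame with columns `days` and `prob`.
#' @export
default_acute_durations <- function() {
  data.frame(days = c(5L, 7L, 10L, 14L, 21L, 30L, 60L, 90L),
             prob = c(0.15, 0.20, 0.15, 0.18, 0.12, 0.10, 0.06, 0.04))
}

#' Configure a synthetic claims cohort
#'
#' Full parameterization of the generative model: enrollment lengths,
#' latent chronic-condition clusters that induce correlated multi-drug
#' refills, independent acute prescriptions with a short-duration mix,
#' combination products, and per-claim payments. Fixing `seed` fixes the
#' emitted claims table exactly.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer RNG seed.
#' @param enrollment_months_distribution data.frame (`months`, `prob`)
#'   giving the discrete distribution of enrollment length in months; one
#'   contiguous eligibility period per patient.
#' @param conditions List of [condition_spec()] objects.
#' @param acute_rate Expected acute prescriptions per patient-year (>= 0).
#'   The default of 5, combined with the default chronic conditions, gives
#'   an overall claim intensity of about one claim per patient-month.
#' @param acute_drugs Drug codes drawn uniformly for acute prescriptions.
#' @param acute_duration_distribution data.frame (`days`, `prob`) for acute
#'   days of supply.
#' @param payment_per_day Named numeric vector, ingredient -> payment per
#'   day of supply (currency/day). Ingredients absent from the vector
#'   default to 1 currency unit per day.
#' @param combination_products Named list, drug code -> character vector of
#'   constituent ingredients. Codes not listed are single-ingredient drugs
#'   whose ingredient is the code itself.
#' @param payment_noise_sd Standard deviation of the log-normal
#'   multiplicative payment noise (median multiplier 1, so per-ingredient
#'   median payment-per-day is recoverable).
#' @return A `polyrx_config` list, validated.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 100, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' head(cohort$claims)
cohort_config <- function(n_patients,
                          seed = 1L,
                          enrollment_months_distribution = default_enrollment_months(),
                          conditions = default_conditions(),
                          acute_rate = 5,
                          acute_drugs = c("amoxicillin", "azithromycin",
                                          "ciprofloxacin", "ibuprofen",
                                          "acetaminophen", "prednisone",
                                          "oxycodone", "apap-hydrocodone"),
                          acute_duration_distribution = default_acute_durations(),
                          payment_per_day = numeric(),
                          combination_products = list(
                            "apap-hydrocodone" = c("acetaminophen", "hydrocodone")
                          ),
                          payment_noise_sd = 0.2) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L)
    stop("invalid configuration: 'n_patients' must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed))
    stop("invalid configuration: 'seed' must be an integer", call. = FALSE)
  .check_distribution(enrollment_months_distribution,
                      "enrollment_months_distribution", "months")
  if (!is.list(conditions) ||
      !all(vapply(conditions, inherits, logical(1), "polyrx_condition")))
    stop("invalid configuration: 'conditions' must be a list of condition_spec()",
         call. = FALSE)
  if (!is.numeric(acute_rate) || length(acute_rate) != 1L ||
      is.na(acute_rate) || acute_rate < 0)
    stop("invalid configuration: 'acute_rate' must be a non-negative real",
         call. = FALSE)
  if (acute_rate > 0 && length(acute_drugs) == 0L)
    stop("invalid configuration: 'acute_drugs' is empty but 'acute_rate' > 0",
         call. = FALSE)
  .check_distribution(acute_duration_distribution,
                      "acute_duration_distribution", "days")
  if (length(payment_per_day) &&
      (is.null(names(payment_per_day)) || any(payment_per_day < 0) ||
       any(!is.finite(payment_per_day))))
    stop("invalid configuration: 'payment_per_day' must be a named ",
         "non-negative finite vector", call. = FALSE)
  if (length(combination_products) && is.null(names(combination_products)))
    stop("invalid configuration: 'combination_products' must be a named list",
         call. = FALSE)
  structure(list(
    n_patients = n_patients, seed = seed,
    enrollment_months_distribution = enrollment_months_distribution,
    conditions = conditions,
    acute_rate = acute_rate, acute_drugs = as.character(acute_drugs),
    acute_duration_distribution = acute_duration_distribution,
    payment_per_day = payment_per_day,
    combination_products = combination_products,
    payment_noise_sd = payment_noise_sd
  ), class = "polyrx_config")
}

## per-day payment rate of a drug *code*: sum of its constituent ingredients'
## rates (default 1/day per ingredient)
.code_rates <- function(codes, config) {
  vapply(codes, function(code) {
    ings <- config$combination_products[[code]]
    if (is.null(ings)) ings <- code
    sum(vapply(ings, function(i) {
      r <- config$payment_per_day[i]
      if (is.na(r)) 1.0 else unname(r)
    }, numeric(1)))
  }, numeric(1))
}

#' Simulate a prescription-claims cohort with known structure
#'
#' Draws one contiguous eligibility period per patient (uniform random start
#' age, so eligibility offsets relative to window boundaries are uniform),
#' assigns chronic conditions by independent Bernoulli draws, and emits:
#' chronic drugs as back-to-back refills (next fill at previous fill +
#' days of supply) for as long as a per-cycle persistence draw succeeds,
#' and acute drugs as independent Poisson-count events at uniform fill ages.
#' Claims never extend past eligibility: refill chains stop at eligibility
#' end and acute days of supply are clipped to it.
#'
#' @param config A [cohort_config()] object.
#' @return List of class `polyrx_cohort`:
#' \describe{
#'   \item{claims}{data.table (`patient_id`, `drug_code`, `fill_age_days`,
#'     `days_supply`, `payment`), sorted for determinism.}
#'   \item{eligibility}{data.table (`patient_id`, `start_age_days`,
#'     `end_age_days`).}
#'   \item{ground_truth}{list with `condition_assignments` (data.table
#'     `patient_id`, `condition`) and `config` (the echoed configuration).}
#' }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "polyrx_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_patients
  pid <- sprintf("P%06d", seq_len(n))

  ## eligibility: uniform start age (18-65y), length from the months mix
  emd <- config$enrollment_months_distribution
  months <- emd$months[sample.int(nrow(emd), n, replace = TRUE,
                                  prob = emd$prob)]
  start <- sample.int(65L * 365L - 18L * 365L, n, replace = TRUE) + 18L * 365L - 1L
  elig <- data.table(patient_id = pid,
                     start_age_days = start,
                     end_age_days = start + months * 30L - 1L)

  claims_parts <- list()
  assign_parts <- list()

  ## chronic conditions
  for (cond in config$conditions) {
    has <- stats::rbinom(n, 1L, cond$prevalence) == 1L
    idx <- which(has)
    if (length(idx)) {
      assign_parts[[cond$name]] <-
        data.table(patient_id = pid[idx], condition = cond$name)
      ds <- cond$days_supply
      s <- elig$start_age_days[idx]; e <- elig$end_age_days[idx]
      ## refill chain runs from enrollment start while the persistence draw
      ## holds, truncated so every fill's full supply fits inside eligibility
      onset <- s
      k_max <- pmax(0L, as.integer((e - onset + 1L) %/% ds))
      k_draw <- if (cond$refill_persistence >= 1) {
        rep(.Machine$integer.max, length(idx))
      } else {
        1L + stats::rgeom(length(idx), 1 - cond$refill_persistence)
      }
      k <- pmin(k_max, k_draw)
      keep <- k > 0L
      if (any(keep)) {
        fills <- data.table(
          patient_id = rep(pid[idx][keep], k[keep]),
          fill_age_days = rep(onset[keep], k[keep]) +
            (sequence(k[keep]) - 1L) * ds,
          days_supply = ds
        )
        ## every condition drug filled at every refill
        per_drug <- lapply(cond$drugs, function(d) {
          out <- copy(fills); out[, drug_code := d]; out
        })
        claims_parts[[paste0("cond_", cond$name)]] <- rbindlist(per_drug)
      }
    }
  }

  ## acute prescriptions: Poisson count per patient-year, uniform timing
  if (config$acute_rate > 0) {
    years <- (elig$end_age_days - elig$start_age_days + 1L) / 365.25
    n_ac <- stats::rpois(n, config$acute_rate * years)
    idx <- which(n_ac > 0L)
    if (length(idx)) {
      tot <- sum(n_ac[idx])
      s <- rep(elig$start_age_days[idx], n_ac[idx])
      e <- rep(elig$end_age_days[idx], n_ac[idx])
      fill <- s + as.integer(floor(stats::runif(tot) * (e - s + 1L)))
      add <- config$acute_duration_distribution
      ds <- add$days[sample.int(nrow(add), tot, replace = TRUE,
                                prob = add$prob)]
      ds <- pmin(as.integer(ds), e - fill + 1L)  # stay within eligibility
      drug <- config$acute_drugs[sample.int(length(config$acute_drugs),
                                            tot, replace = TRUE)]
      claims_parts[["acute"]] <- data.table(
        patient_id = rep(pid[idx], n_ac[idx]),
        fill_age_days = fill, days_supply = ds, drug_code = drug)
    }
  }

  claims <- if (length(claims_parts)) rbindlist(claims_parts, use.names = TRUE)
            else data.table(patient_id = character(), fill_age_days = integer(),
                            days_supply = integer(), drug_code = character())

  if (nrow(claims)) {
    rate <- .code_rates(unique(claims$drug_code), config)
    claims[, payment := rate[drug_code] * days_supply *
             exp(stats::rnorm(.N, 0, config$payment_noise_sd))]
  } else {
    claims[, payment := numeric()]
  }
  setcolorder(claims, c("patient_id", "drug_code", "fill_age_days",
                        "days_supply", "payment"))
  setorder(claims, patient_id, fill_age_days, drug_code, days_supply)

  assignments <- if (length(assign_parts)) {
    a <- rbindlist(assign_parts); setorder(a, patient_id, condition); a
  } else data.table(patient_id = character(), condition = character())

  structure(list(claims = claims, eligibility = elig,
                 ground_truth = list(condition_assignments = assignments,
                                     config = config)),
            class = "polyrx_cohort")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Monte-Carlo oracle for a planted pair's overrepresentation
#'
#' Estimates the expected observed/expected co-exposure ratio of an
#' ingredient pair under a cohort configuration by simulating replicate
#' cohorts and pushing each through the brute-force day-level reference
#' pipeline ([day_level_exposures()]), *not* the production integer-division
#' scanner. Expected incidence is evaluated against the full universe of
#' eligibility windows, so independently assigned drugs give a ratio of 1.
#' The replicate mean and its standard error give an independent target
#' that the main pipeline's `observe_per_expect_1s` must recover.
#'
#' @param config A [cohort_config()]; replicate seeds are derived from
#'   `config$seed`.
#' @param pair Character vector of two ingredient identifiers; both must be
#'   reachable from the config (condition drugs, acute drugs, or combination
#'   product constituents).
#' @param n_reps Number of replicate cohorts (>= 2; 50 by default).
#' @param window_days Window length in days (default 30).
#' @param mapping Optional [drug_mapping()] used to expand drug codes; by
#'   default an identity mapping over the config's codes is built with
#'   [mapping_from_config()].
#' @return List with `ratio` (replicate mean of observed/expected), `se`
#'   (standard error over replicates), and `replicates` (per-replicate
#'   ratios; replicates where either drug has zero marginal exposure are NA
#'   and excluded from the mean).
#' @export
planted_enrichment <- function(config, pair, n_reps = 50L, window_days = 30L,
                               mapping = mapping_from_config(config)) {
  stopifnot(inherits(config, "polyrx_config"), length(pair) == 2L)
  known <- .config_ingredients(config)
  missing <- setdiff(pair, known)
  if (length(missing))
    stop("unknown ingredient(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ratios <- vapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * r) %% .Machine$integer.max
    cohort <- simulate_cohort(cfg)
    ing <- expand_to_ingredients(cohort$claims, mapping)
    expo <- day_level_exposures(ing$claims, window_days)
    el <- cohort$eligibility
    W <- sum(el$end_age_days %/% as.integer(window_days) -
               el$start_age_days %/% as.integer(window_days) + 1L)
    if (W == 0L || nrow(expo) == 0L) return(NA_real_)
    wA <- nrow(unique(expo[ingredient == pair[1L],
                           .(patient_id, window_index)]))
    wB <- nrow(unique(expo[ingredient == pair[2L],
                           .(patient_id, window_index)]))
    if (wA == 0L || wB == 0L) return(NA_real_)
    both <- merge(unique(expo[ingredient == pair[1L],
                              .(patient_id, window_index)]),
                  unique(expo[ingredient == pair[2L],
                              .(patient_id, window_index)]),
                  by = c("patient_id", "window_index"))
    nrow(both) / (W * (wA / W) * (wB / W))
  }, numeric(1))
  ok <- ratios[!is.na(ratios)]
  if (!length(ok))
    stop("pair has zero marginal exposure in every replicate; ",
         "enrichment undefined", call. = FALSE)
  list(ratio = mean(ok),
       se = if (length(ok) > 1L) stats::sd(ok) / sqrt(length(ok)) else NA_real_,
       replicates = ratios)
}

.config_ingredients <- function(config) {
  codes <- unique(c(unlist(lapply(config$conditions, `[[`, "drugs")),
                    config$acute_drugs))
  unique(unlist(lapply(codes, function(code) {
    ings <- config$combination_products[[code]]
    if (is.null(ings)) code else ings
  })))
}

#' Identity drug mapping derived from a cohort configuration
#'
#' Builds a [drug_mapping()] whose codes are exactly the drug codes a
#' configuration can emit: combination products expand to their configured
#' ingredient sets, all other codes map to themselves. Ingredients get
#' placeholder vocabulary identifiers and no ATC code (flagged
#' unclassified), which is sufficient for ingredient-level analyses of
#' simulated cohorts; supply a real vocabulary for class-level work.
#'
#' @param config A [cohort_config()].
#' @return A [drug_mapping()] object.
#' @export
mapping_from_config <- function(config) {
  codes <- unique(c(unlist(lapply(config$conditions, `[[`, "drugs")),
                    config$acute_drugs, names(config$combination_products)))
  code_to_ingredients <- lapply(codes, function(code) {
    ings <- config$combination_products[[code]]
    if (is.null(ings)) code else ings
  })
  names(code_to_ingredients) <- codes
  ings <- unique(unlist(code_to_ingredients))
  info <- data.table(ingredient = ings, rxcui = NA_character_,
                     umls_cui = NA_character_, drugbank_id = NA_character_,
                     atc_code = NA_character_, atc_name = NA_character_)
  drug_mapping(code_to_ingredients, info)
}
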