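#' Read and write claims and eligibility tables
#'
#' Claims are headered TSVs with columns `patient_id`, `drug_code`,
#' `fill_age_days`, `days_supply`, `payment`; eligibility tables have
#' `patient_id`, `start_age_days`, `end_age_days`.
#'
#' @param path File path.
#' @return data.table.
#' @export
read_claims <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("patient_id", "drug_code", "fill_age_days", "days_supply")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("claims file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt
}

#' @rdname read_claims
#' @export
read_eligibility <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("patient_id", "start_age_days", "end_age_days")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("eligibility file is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  dt
}

#' Write a simulated cohort to TSV files
#'
#' Serializes the claims, eligibility, and ground-truth condition
#' assignment tables of a [simulate_cohort()] result as headered TSVs.
#'
#' @param cohort A `polyrx_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "polyrx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("claims.tsv", "eligibility.tsv",
                            "condition_assignments.tsv"))
  fwrite(cohort$claims, paths[1L], sep = "\t", quote = FALSE)
  fwrite(cohort$eligibility, paths[2L], sep = "\t", quote = FALSE)
  fwrite(cohort$ground_truth$condition_assignments, paths[3L], sep = "\t",
         quote = FALSE)
  invisible(paths)
}

#' Run the full polypharmacy counting pipeline
#'
#' Executes the analysis stages in order — ingredient expansion, window
#' scan, exact combination counting, threshold-gated at-least counting for
#' N = 1..`max_n`, per-combination statistics, and record emission — at
#' both the drug ingredient and ATC class level, and writes the record
#' files plus a JSON run manifest of per-stage row counts so conservation
#' invariants are auditable after the fact. The manifest asserts that the
#' exact counts sum to the number of exposed windows and aborts otherwise.
#'
#' @param claims Claims table (see [read_claims()]) or a `polyrx_cohort`.
#' @param eligibility Eligibility table; taken from the cohort when
#'   `claims` is a `polyrx_cohort`.
#' @param mapping A [drug_mapping()].
#' @param out_dir Output directory for records and manifest.
#' @param window_days Window length in days (default 30).
#' @param max_n Largest combination size (default 5).
#' @param support_threshold Candidate support threshold (default 1000).
#' @param policy Record [emission_policy()].
#' @param class_names data.table (`atc_class`, `atc_class_name`) for the
#'   class record name columns (optional).
#' @param costs Optional precomputed cost table; estimated from the claims
#'   with [estimate_cost_per_day()] when omitted.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(claims, eligibility = NULL, mapping,
                         out_dir, window_days = 30L, max_n = 5L,
                         support_threshold = 1000L,
                         policy = emission_policy(), class_names = NULL,
                         costs = NULL) {
  if (inherits(claims, "polyrx_cohort")) {
    eligibility <- claims$eligibility
    claims <- claims$claims
  }
  if (is.null(eligibility))
    stop("stage 'windowing' requires an eligibility table", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(window_days = as.integer(window_days),
                   max_n = as.integer(max_n),
                   support_threshold = as.integer(support_threshold),
                   claims_in = nrow(claims))

  expanded <- expand_to_ingredients(claims, mapping)
  manifest$claims_dropped_unmapped <- expanded$n_dropped
  manifest$ingredient_claims <- nrow(expanded$claims)
  if (is.null(costs) && nrow(expanded$claims) &&
      "payment" %in% names(expanded$claims))
    costs <- estimate_cost_per_day(expanded$claims)

  scan <- build_exposure_table(expanded$claims, window_days)
  manifest$claims_rejected_windowing <- scan$n_rejected
  manifest$exposures <- nrow(scan$exposures)
  uni <- window_universe(eligibility, scan$exposures, window_days)
  manifest$W_all <- uni$W_all
  manifest$W_exposed <- uni$W_exposed
  manifest$n_partial_windows <- uni$n_partial

  run_level <- function(exposures, level) {
    exact <- exact_combo_counts(exposures)
    W <- attr(exact, "W_exposed")
    if (sum(exact$count) != W)
      stop("stage 'counting' (", level, "): exact counts do not sum to ",
           "the number of exposed windows", call. = FALSE)
    atl <- count_combos(exact, max_n = max_n,
                        support_threshold = support_threshold)
    stats <- combo_stats(atl, exact, W_exposed = W,
                         W_expected = uni$W_all,
                         costs = if (level == "ingredient") costs,
                         level = level)
    list(exact = exact, atleast = atl, stats = stats, W_exposed = W)
  }

  ing <- run_level(scan$exposures, "ingredient")
  manifest$exact_combos <- nrow(ing$exact)
  manifest$combos_per_n <- lapply(ing$atleast, nrow)
  drug_paths <- write_drug_records(ing$stats, policy, out_dir)

  cls <- class_exposures(scan$exposures, mapping)
  manifest$class_exposures <- nrow(cls$exposures)
  manifest$class_exposures_dropped_unclassified <- cls$n_dropped
  clv <- run_level(cls$exposures, "class")
  manifest$exact_class_combos <- nrow(clv$exact)
  manifest$class_combos_per_n <- lapply(clv$atleast, nrow)
  class_paths <- write_class_records(clv$stats, policy, out_dir,
                                     class_names = class_names)
  write_records_readme(out_dir, policy, max_n)

  manifest$records_emitted <- lapply(
    stats::setNames(c(drug_paths, class_paths),
                    basename(c(drug_paths, class_paths))),
    function(p) length(readLines(p)) - 1L)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
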