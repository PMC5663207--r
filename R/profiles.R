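#' Co-drug exposure profile for a target drug or class
#'
#' For every partner observed together with the target in the pairwise
#' table, reports the conditional co-exposure probability
#' `P(co-exposure | exposure) = atleast({target, d}) / atleast({target})`
#' and the pair's observed/expected incidence ratio. Partners never
#' co-observed with the target have no pair record and are absent from the
#' profile (not zero rows). Sort by either column to get the most common
#' or the most overrepresented co-exposures.
#'
#' @param target Ingredient or class identifier; must appear in the N=1
#'   table.
#' @param stats_n2 Pairwise (N = 2) statistics table from [combo_stats()]
#'   or [read_records()].
#' @param stats_n1 Single-drug (N = 1) table supplying the target's
#'   at-least count.
#' @return data.table (`codrug`, `p_coexposure`, `observed_expected`),
#'   sorted by descending `p_coexposure`.
#' @export
codrug_profile <- function(target, stats_n2, stats_n1) {
  n1 <- as.data.table(stats_n1)
  hit <- n1[key == target]
  if (nrow(hit) != 1L)
    stop("target '", target, "' not found in the single-drug table",
         call. = FALSE)
  denom <- hit$atleast_exposure_count
  n2 <- as.data.table(stats_n2)
  items <- combo_items(n2$key)
  has <- vapply(items, function(s) target %in% s, logical(1))
  n2 <- n2[has]
  partners <- vapply(items[has], function(s) setdiff(s, target)[1L],
                     character(1))
  out <- data.table(codrug = partners,
                    p_coexposure = n2$atleast_exposure_count / denom,
                    observed_expected = n2$observe_per_expect_1s)
  setorder(out, -p_coexposure, codrug, na.last = TRUE)
  out[]
}

#' Distribution of distinct drugs per exposed window
#'
#' Histogram of the number of distinct items (ingredients or classes) per
#' exposed window, with the median and 95th percentile computed over
#' exposed windows only (windows with no prescriptions are not part of the
#' distribution).
#'
#' @param exposures Deduplicated exposure table.
#' @return List: `histogram` (data.table `n_drugs`, `n_windows`), `median`,
#'   `p95` (both `NA` when there are no exposed windows).
#' @export
exposure_count_distribution <- function(exposures) {
  expo <- as.data.table(exposures)
  if (nrow(expo) == 0L)
    return(list(histogram = data.table(n_drugs = integer(),
                                       n_windows = integer()),
                median = NA_real_, p95 = NA_real_))
  sizes <- unique(expo)[, .N, by = .(patient_id, window_index)]$N
  hist <- data.table(n_drugs = as.integer(names(table(sizes))),
                     n_windows = as.integer(table(sizes)))
  setorder(hist, n_drugs)
  list(histogram = hist,
       median = as.numeric(stats::median(sizes)),
       p95 = as.numeric(stats::quantile(sizes, 0.95, type = 1L,
                                        names = FALSE)))
}

#' Relative risk of an outcome following combination exposure
#'
#' Screens combinations for overrepresentation in the lookback period
#' before an outcome event (e.g. an emergency-department visit): for each
#' qualifying combination, the fraction of *exposed* lookbacks (those with
#' at least one drug exposure, matching the exposed-window universe of
#' `fraction_all_windows`) containing it, where the lookback ends the day
#' before the patient's *first* event, is divided by the combination's
#' overall per-window incidence (`fraction_all_windows`). This is an
#' association screen only — it says nothing about causation.
#'
#' The default lookback is day-level: the 30 days ending the day before the
#' event, regardless of window boundaries. `method = "window"` instead uses
#' the discrete window immediately preceding the event's window.
#'
#' @param stats_n Statistics table for the combination size of interest
#'   (typically N = 3), with `fraction_all_windows` populated.
#' @param ingredient_claims Ingredient-level claims table.
#' @param events data.table (`patient_id`, `event_age_days`); only each
#'   patient's first event is used.
#' @param min_occurrences Combinations with fewer at-least exposures are
#'   excluded (default 5000; lower it at desk scale).
#' @param lookback_days Lookback length in days (default 30).
#' @param method `"day"` (default) or `"window"`.
#' @param window_days Window length for `method = "window"`.
#' @return data.table (`key`, `n_events`, `n_exposed_lookbacks`,
#'   `n_pre_exposed`, `pre_event_fraction`, `overall_fraction`,
#'   `relative_risk`), sorted by descending relative risk. Empty when there
#'   are no events.
#' @export
outcome_relative_risk <- function(stats_n, ingredient_claims, events,
                                  min_occurrences = 5000L,
                                  lookback_days = 30L,
                                  method = c("day", "window"),
                                  window_days = 30L) {
  method <- match.arg(method)
  tab <- as.data.table(stats_n)
  tab <- tab[atleast_exposure_count >= min_occurrences]
  ev <- as.data.table(events)
  empty <- as.data.table(list(key = character(), n_events = integer(),
                      n_exposed_lookbacks = integer(),
                      n_pre_exposed = integer(),
                      pre_event_fraction = numeric(),
                      overall_fraction = numeric(),
                      relative_risk = numeric()))
  if (nrow(ev) == 0L || nrow(tab) == 0L) return(empty)
  ev <- ev[, .(event_age_days = min(event_age_days)), by = patient_id]
  n_events <- nrow(ev)

  cl <- as.data.table(ingredient_claims)
  cl <- cl[!is.na(days_supply) & days_supply >= 1L]
  if (method == "day") {
    ## drug sets exposed in [event - lookback, event - 1], day-level
    j <- cl[ev, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    j <- j[fill_age_days <= event_age_days - 1L &
             fill_age_days + days_supply - 1L >=
               pmax(0L, event_age_days - lookback_days)]
    pre_sets <- j[, .(drugs = list(unique(ingredient))), by = patient_id]
  } else {
    expo <- build_exposure_table(cl, window_days)$exposures
    ev[, window_index := pmax(0L, event_age_days %/%
                                as.integer(window_days) - 1L)]
    j <- expo[ev, on = c("patient_id", "window_index"), nomatch = NULL]
    pre_sets <- j[, .(drugs = list(unique(ingredient))), by = patient_id]
  }
  n_exposed <- nrow(pre_sets)
  out <- copy(tab[, .(key, atleast_exposure_count, fraction_all_windows)])
  combo_sets <- combo_items(out$key)
  out[, n_pre_exposed := vapply(combo_sets, function(s)
    sum(vapply(pre_sets$drugs, function(d) all(s %in% d), logical(1))),
    integer(1))]
  out[, n_events := n_events]
  out[, n_exposed_lookbacks := n_exposed]
  out[, pre_event_fraction :=
        if (n_exposed > 0) n_pre_exposed / n_exposed else NA_real_]
  out[, overall_fraction := fraction_all_windows]
  out[, relative_risk := pre_event_fraction / overall_fraction]
  out <- out[, .(key, n_events, n_exposed_lookbacks, n_pre_exposed,
                 pre_event_fraction, overall_fraction, relative_risk)]
  setorder(out, -relative_risk, key)
  out[]
}

#' Sensitivity of exposure counts to window duration
#'
#' Re-runs the window scan and exact counting for each candidate window
#' length on a fixed claims table, reporting the mean number of distinct
#' drugs per exposed window and the top-K exact combinations. Because every
#' prescription counts as exposure for the whole of each window it touches,
#' longer windows can only add concomitance: the mean is non-decreasing in
#' window length, and short-duration prescriptions gain rank.
#'
#' @param ingredient_claims Ingredient-level claims table.
#' @param durations Window lengths in days (default 10, 20, 30, 40, 50,
#'   60, 90).
#' @param top_k Length of the reported ranking (default 20).
#' @return List: `summary` (data.table `window_days`, `W_exposed`,
#'   `mean_drugs_per_window`) and `rankings` (named list of top-K exact
#'   keys per duration).
#' @export
window_duration_sensitivity <- function(ingredient_claims,
                                        durations = c(10L, 20L, 30L, 40L,
                                                      50L, 60L, 90L),
                                        top_k = 20L) {
  res <- lapply(durations, function(wd) {
    expo <- build_exposure_table(ingredient_claims, wd)$exposures
    exact <- exact_combo_counts(expo)
    W <- attr(exact, "W_exposed")
    list(summary = data.table(
           window_days = as.integer(wd), W_exposed = W,
           mean_drugs_per_window = if (W > 0) nrow(expo) / W else NA_real_),
         ranking = utils::head(exact$key, top_k))
  })
  list(summary = rbindlist(lapply(res, `[[`, "summary")),
       rankings = stats::setNames(lapply(res, `[[`, "ranking"),
                                  as.character(durations)))
}

#' Sensitivity of combination incidence to cohort size
#'
#' Subsamples patients without replacement at each requested size (seeded,
#' so runs are reproducible), reruns windowing and exact counting, and
#' reports: the fraction of exposed windows carrying a combination observed
#' exactly once in that run (smaller cohorts overestimate uniqueness), the
#' overlap of the top-K at-least combinations with the full-cohort run, and
#' the Spearman rank correlation of the full run's top-K at-least counts
#' against their counts in the subsample.
#'
#' @param ingredient_claims Ingredient-level claims table.
#' @param sample_sizes Patient counts to subsample; each must not exceed
#'   the cohort size.
#' @param seed Integer seed for the subsampling.
#' @param top_k Ranking depth (default 100).
#' @param window_days Window length (default 30).
#' @param max_n Largest combination size ranked (default 2).
#' @param support_threshold Candidate support threshold for the at-least
#'   ranking (default 1).
#' @return data.table (`sample_size`, `n_patients`, `W_exposed`,
#'   `fraction_unique_windows`, `topk_overlap`, `rank_correlation`); the
#'   full-cohort row is included first with `sample_size = NA`.
#' @export
cohort_size_sensitivity <- function(ingredient_claims, sample_sizes, seed,
                                    top_k = 100L, window_days = 30L,
                                    max_n = 2L, support_threshold = 1L) {
  cl <- as.data.table(ingredient_claims)
  patients <- unique(cl$patient_id)
  if (any(sample_sizes > length(patients)))
    stop("sample size exceeds cohort size (", length(patients), " patients)",
         call. = FALSE)
  run <- function(claims) {
    expo <- build_exposure_table(claims, window_days)$exposures
    exact <- exact_combo_counts(expo)
    atl <- count_combos(exact, max_n = max_n,
                        support_threshold = support_threshold)
    pooled <- rbindlist(atl)
    setorder(pooled, -atleast_exposure_count, key)
    list(exact = exact, pooled = pooled)
  }
  full <- run(cl)
  full_top <- utils::head(full$pooled$key, top_k)
  full_counts <- stats::setNames(full$pooled$atleast_exposure_count,
                                 full$pooled$key)

  one_row <- function(size, res, n_pat) {
    W <- attr(res$exact, "W_exposed")
    uniq <- if (W > 0) sum(res$exact$count == 1L) / W else NA_real_
    samp_top <- utils::head(res$pooled$key, top_k)
    overlap <- if (length(full_top))
      length(intersect(full_top, samp_top)) / length(full_top) else NA_real_
    samp_counts <- stats::setNames(res$pooled$atleast_exposure_count,
                                   res$pooled$key)
    sc <- samp_counts[full_top]
    sc[is.na(sc)] <- 0
    rc <- if (length(full_top) >= 2L)
      suppressWarnings(stats::cor(full_counts[full_top], sc,
                                  method = "spearman")) else NA_real_
    data.table(sample_size = size, n_patients = n_pat, W_exposed = W,
               fraction_unique_windows = uniq, topk_overlap = overlap,
               rank_correlation = rc)
  }
  out <- list(one_row(NA_integer_, full, length(patients)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (i in seq_along(sample_sizes)) {
    set.seed((as.integer(seed) + 104729L * i) %% .Machine$integer.max)
    keep <- sample(patients, sample_sizes[i])
    res <- run(cl[patient_id %chin% keep])
    out[[i + 1L]] <- one_row(as.integer(sample_sizes[i]), res,
                             sample_sizes[i])
  }
  rbindlist(out)
}
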