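#' Windows touched by one prescription
#'
#' Exposure covers the closed day interval
#' `[fill_age_days, fill_age_days + days_supply - 1]`; a patient is exposed
#' in every window any of those days overlaps. Windows are anchored at age
#' zero by integer division of age-in-days by `window_days`, so the result
#' is the contiguous inclusive range
#' `floor(fill/window_days) .. floor((fill + supply - 1)/window_days)`.
#' With this convention a 30-day supply filled exactly on a window boundary
#' occupies exactly one 30-day window.
#'
#' @param fill_age_days Patient age in days at fill (>= 0).
#' @param days_supply Days of supply (>= 1).
#' @param window_days Window length in days (default 30).
#' @return Integer vector of window indices, contiguous and increasing.
#' @export
#' @examples
#' prescription_windows(100, 30, 30)  # days 100-129 -> windows 3 and 4
#' prescription_windows(29, 2, 30)    # days 29-30 straddle -> windows 0 and 1
prescription_windows <- function(fill_age_days, days_supply, window_days = 30L) {
  stopifnot(length(fill_age_days) == 1L, length(days_supply) == 1L,
            window_days >= 1L)
  if (is.na(days_supply) || days_supply < 1L)
    stop("days_supply must be >= 1", call. = FALSE)
  if (is.na(fill_age_days) || fill_age_days < 0L)
    stop("fill_age_days must be >= 0", call. = FALSE)
  w0 <- fill_age_days %/% window_days
  w1 <- (fill_age_days + days_supply - 1L) %/% window_days
  as.integer(seq.int(w0, w1))
}

#' Scan ingredient claims into deduplicated window exposures
#'
#' Converts ingredient-level claims into `(patient, window, ingredient)`
#' exposure events: the union over claims of [prescription_windows()],
#' deduplicated so overlapping refills of the same ingredient in one window
#' contribute a single event. Claims with missing or non-positive days of
#' supply (or negative fill age) are rejected and tallied, never coerced.
#'
#' @param ingredient_claims Claims with columns `patient_id`, `ingredient`,
#'   `fill_age_days`, `days_supply`.
#' @param window_days Window length in days (default 30).
#' @return List: `exposures` (data.table `patient_id`, `window_index`,
#'   `ingredient`, keyed and sorted) and `n_rejected` (rejected-claim
#'   tally).
#' @export
build_exposure_table <- function(ingredient_claims, window_days = 30L) {
  stopifnot(window_days >= 1L)
  dt <- as.data.table(ingredient_claims)
  bad <- is.na(dt$days_supply) | dt$days_supply < 1L |
    is.na(dt$fill_age_days) | dt$fill_age_days < 0L
  n_rejected <- sum(bad)
  dt <- dt[!bad]
  if (nrow(dt) == 0L) {
    return(list(exposures = data.table(patient_id = character(),
                                       window_index = integer(),
                                       ingredient = character()),
                n_rejected = n_rejected))
  }
  w0 <- dt$fill_age_days %/% as.integer(window_days)
  w1 <- (dt$fill_age_days + dt$days_supply - 1L) %/% as.integer(window_days)
  nw <- w1 - w0 + 1L
  expo <- data.table(
    patient_id = rep(dt$patient_id, nw),
    window_index = rep(w0, nw) + sequence(nw) - 1L,
    ingredient = rep(dt$ingredient, nw)
  )
  expo <- unique(expo)
  setorder(expo, patient_id, window_index, ingredient)
  list(exposures = expo, n_rejected = n_rejected)
}

#' Count observed, exposed, and partial windows
#'
#' Enumerates, per patient, the windows intersecting the eligibility period.
#' `W_all` counts every such patient-window; `W_exposed` counts those with
#' at least one exposure event; partial windows are those only partly
#' covered by eligibility — the inevitable consequence of anchoring windows
#' at age zero rather than re-anchoring per patient. With uniformly random
#' eligibility offsets the mean covered duration of a partial window is
#' about half the window length.
#'
#' @param eligibility data.table (`patient_id`, `start_age_days`,
#'   `end_age_days`), `start <= end`.
#' @param exposures Exposure table from [build_exposure_table()]. Every
#'   exposure must fall in a window its patient's eligibility intersects;
#'   a violation is an integrity error (the upstream generator or loader
#'   broke the eligibility contract).
#' @param window_days Window length in days (default 30).
#' @return List: `W_all`, `W_exposed`, `n_partial`, and
#'   `mean_partial_days` (mean eligibility coverage, in days, of partial
#'   windows; `NaN` when there are none).
#' @export
window_universe <- function(eligibility, exposures, window_days = 30L) {
  elig <- as.data.table(eligibility)
  if (any(elig$start_age_days > elig$end_age_days))
    stop("malformed eligibility period: start > end", call. = FALSE)
  wd <- as.integer(window_days)
  w0 <- elig$start_age_days %/% wd
  w1 <- elig$end_age_days %/% wd
  W_all <- sum(w1 - w0 + 1L)

  ## coverage of the first and last window of each period; interior windows
  ## are fully covered by construction
  first_cov <- pmin(elig$end_age_days, (w0 + 1L) * wd - 1L) -
    elig$start_age_days + 1L
  last_cov <- elig$end_age_days - pmax(elig$start_age_days, w1 * wd) + 1L
  one_window <- w0 == w1
  cov <- c(first_cov[!one_window], last_cov[!one_window],
           first_cov[one_window])
  partial <- cov < wd
  n_partial <- sum(partial)
  mean_partial_days <- mean(cov[partial])

  expo <- as.data.table(exposures)
  W_exposed <- if (nrow(expo) == 0L) 0L else
    nrow(unique(expo[, .(patient_id, window_index)]))
  if (nrow(expo)) {
    rng <- data.table(patient_id = elig$patient_id, w0 = w0, w1 = w1)
    chk <- rng[unique(expo[, .(patient_id, window_index)]),
               on = "patient_id"]
    if (anyNA(chk$w0) || chk[, any(window_index < w0 | window_index > w1)])
      stop("integrity error: exposure outside any eligibility window",
           call. = FALSE)
  }
  list(W_all = W_all, W_exposed = W_exposed, n_partial = n_partial,
       mean_partial_days = mean_partial_days)
}

#' Brute-force day-level exposure reference
#'
#' Reference implementation of the window scan used as an independent
#' oracle: materializes one row per exposed day per claim, assigns each day
#' to `floor(day / window_days)`, and deduplicates. Quadratically more
#' memory-hungry than [build_exposure_table()] but trivially correct; the
#' two must agree exactly on any input.
#'
#' @inheritParams build_exposure_table
#' @return data.table (`patient_id`, `window_index`, `ingredient`),
#'   deduplicated and sorted.
#' @export
day_level_exposures <- function(ingredient_claims, window_days = 30L) {
  dt <- as.data.table(ingredient_claims)
  dt <- dt[!is.na(days_supply) & days_supply >= 1L &
             !is.na(fill_age_days) & fill_age_days >= 0L]
  if (nrow(dt) == 0L)
    return(data.table(patient_id = character(), window_index = integer(),
                      ingredient = character()))
  nd <- dt$days_supply
  days <- rep(dt$fill_age_days, nd) + sequence(nd) - 1L
  expo <- data.table(patient_id = rep(dt$patient_id, nd),
                     window_index = days %/% as.integer(window_days),
                     ingredient = rep(dt$ingredient, nd))
  expo <- unique(expo)
  setorder(expo, patient_id, window_index, ingredient)
  expo
}
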