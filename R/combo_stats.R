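## Build an at-least lookup: named-vector counts, with optional fall-back
## to on-demand evaluation on the exact table's inverted index.
.atleast_lookup <- function(counts = NULL, exact = NULL, index = NULL) {
  if (!is.null(exact) && is.null(index)) index <- combo_index(exact)
  cache <- new.env(parent = emptyenv())
  if (!is.null(counts) && length(counts))
    for (i in seq_along(counts))
      assign(names(counts)[i], as.numeric(counts[[i]]), envir = cache)
  function(items) {
    k <- combo_key(items)
    if (exists(k, envir = cache, inherits = FALSE))
      return(get(k, envir = cache, inherits = FALSE))
    if (is.null(exact)) return(NA_real_)
    v <- as.numeric(atleast_count(k, exact, index))
    assign(k, v, envir = cache)
    v
  }
}

#' Overrepresentation based on single-drug marginal frequencies
#'
#' The ratio of a combination's observed at-least incidence to the
#' incidence expected under independence of its single drugs:
#' `atleast(S) / (W * prod_d atleast({d}) / W)` over all drugs `d` in `S`,
#' where `W` is the number of windows with any prescription. Defined for
#' combinations of two or more drugs; a zero (or unknown) marginal makes
#' the expectation undefined and yields `NA`, never 0 or infinity.
#'
#' @param query Items of the combination (vector or `"a|b"` key), size >= 2.
#' @param counts At-least counts: a named numeric vector keyed by
#'   combination key (must cover the query and its singles), or a
#'   [exact_combo_counts()] table from which counts are evaluated on
#'   demand.
#' @param W Number of exposed windows (> 0).
#' @param index Optional prebuilt [combo_index()] when `counts` is an
#'   exact table.
#' @return Non-negative real, or `NA` when undefined.
#' @export
#' @examples
#' overrep_singles(c("A", "B"), c(A = 50, B = 40, "A|B" = 30), W = 100) # 1.5
overrep_singles <- function(query, counts, W, index = NULL) {
  items <- if (length(query) == 1L && grepl("|", query, fixed = TRUE))
    combo_items(query)[[1L]] else unique(as.character(query))
  if (length(items) < 2L)
    stop("overrepresentation requires a combination of >= 2 drugs",
         call. = FALSE)
  stopifnot(W > 0)
  f <- if (inherits(counts, "polyrx_exact"))
    .atleast_lookup(exact = counts, index = index)
  else .atleast_lookup(counts = counts)
  aS <- f(items)
  singles <- vapply(items, function(d) f(d), numeric(1))
  if (anyNA(singles) || any(singles == 0) || is.na(aS)) return(NA_real_)
  aS / (W * prod(singles / W))
}

#' Overrepresentation based on (N-1)+1 subset frequencies
#'
#' For a combination `S` of N > 2 drugs, compares its at-least incidence to
#' the incidence expected from each of the N partitions of `S` into an
#' (N-1)-drug subset plus the remaining single drug, and reports the
#' smallest such ratio:
#' `min_d atleast(S) / (atleast(S \ d) * atleast({d}) / W)`.
#' This measures the combination's overrepresentation beyond its own
#' subsets. Missing subset counts are evaluated on demand when an exact
#' table is supplied; a zero subset count yields `NA`.
#'
#' @inheritParams overrep_singles
#' @return Non-negative real, or `NA` when undefined.
#' @export
overrep_subsets <- function(query, counts, W, index = NULL) {
  items <- if (length(query) == 1L && grepl("|", query, fixed = TRUE))
    combo_items(query)[[1L]] else unique(as.character(query))
  if (length(items) <= 2L)
    stop("subset-based overrepresentation requires > 2 drugs", call. = FALSE)
  stopifnot(W > 0)
  f <- if (inherits(counts, "polyrx_exact"))
    .atleast_lookup(exact = counts, index = index)
  else .atleast_lookup(counts = counts)
  aS <- f(items)
  if (is.na(aS)) return(NA_real_)
  terms <- vapply(seq_along(items), function(i) {
    asub <- f(items[-i])
    ad <- f(items[i])
    if (is.na(asub) || is.na(ad) || asub == 0 || ad == 0) return(NA_real_)
    aS / (asub * ad / W)
  }, numeric(1))
  if (anyNA(terms)) return(NA_real_)
  min(terms)
}

#' Daily cost of a drug combination
#'
#' Sum of the per-ingredient median daily costs. Only defined at the
#' ingredient level (daily cost cannot be calculated for drug classes). An
#' ingredient missing from the cost table makes the whole combination's
#' cost missing (`NA`), never zero.
#'
#' @param query Items of the combination (vector or key string).
#' @param costs Cost table from [estimate_cost_per_day()] (`ingredient`,
#'   `cost_per_day`) or a named numeric vector.
#' @return Non-negative real, or `NA`.
#' @export
combo_cost <- function(query, costs) {
  items <- if (length(query) == 1L && grepl("|", query, fixed = TRUE))
    combo_items(query)[[1L]] else unique(as.character(query))
  v <- if (is.data.frame(costs)) {
    costs <- as.data.table(costs)
    costs$cost_per_day[match(items, costs$ingredient)]
  } else {
    unname(costs[items])
  }
  if (anyNA(v)) NA_real_ else sum(v)
}

#' Per-combination statistics tables for N = 1..max_n
#'
#' Joins the at-least and exact counts and derives, per combination: the
#' fraction of its at-least exposures occurring with no additional drugs
#' (`fraction_exact` = exact / at-least), its incidence among all exposed
#' windows (`fraction_all_windows` = at-least / `W_exposed`), the
#' single-drug overrepresentation (N > 1), the (N-1)+1 subset
#' overrepresentation (N > 2; for N = 2 the two definitions coincide and
#' only the single-drug column is carried), and — at the ingredient level —
#' the estimated daily cost of the combination. Undefined ratios are `NA`.
#'
#' @param atleast_by_n List from [count_combos()].
#' @param exact Table from [exact_combo_counts()].
#' @param W_exposed Number of exposed windows; defaults to the exact
#'   table's `W_exposed` attribute. Denominator of `fraction_all_windows`.
#' @param W_expected Window universe used when computing expected incidence
#'   for the overrepresentation ratios. Defaults to `W_exposed`; pass the
#'   total count of eligibility windows (exposed or not, from
#'   [window_universe()]) so that independently prescribed drugs have an
#'   expected ratio of 1 — restricting the expectation universe to exposed
#'   windows deflates the null toward the exposed-window fraction.
#' @param costs Optional cost table ([estimate_cost_per_day()]); ignored
#'   for `level = "class"`.
#' @param level `"ingredient"` or `"class"`.
#' @return Named list of data.tables, one per N, with columns `key`,
#'   `size`, `atleast_exposure_count`, `exact_exposure_count`,
#'   `fraction_exact`, `fraction_all_windows`, `observe_per_expect_1s`
#'   (N > 1), `observe_per_expect_N1` (N > 2), and
#'   `estimate_drug_combo_cost_per_day` (ingredient level).
#' @export
combo_stats <- function(atleast_by_n, exact,
                        W_exposed = attr(exact, "W_exposed"),
                        W_expected = W_exposed,
                        costs = NULL, level = c("ingredient", "class")) {
  level <- match.arg(level)
  stopifnot(inherits(exact, "polyrx_exact"), W_exposed >= 0)
  idx <- combo_index(exact)
  all_counts <- unlist(lapply(atleast_by_n, function(t)
    stats::setNames(as.numeric(t$atleast_exposure_count), t$key)),
    use.names = TRUE)
  names(all_counts) <- unlist(lapply(atleast_by_n, `[[`, "key"))
  f <- .atleast_lookup(counts = all_counts, exact = exact, index = idx)

  lapply(stats::setNames(names(atleast_by_n), names(atleast_by_n)),
         function(nm) {
    n <- as.integer(nm)
    tab <- copy(atleast_by_n[[nm]])
    if (nrow(tab) == 0L) {
      tab[, `:=`(exact_exposure_count = integer(),
                 fraction_exact = numeric(),
                 fraction_all_windows = numeric())]
      if (n > 1L) tab[, observe_per_expect_1s := numeric()]
      if (n > 2L) tab[, observe_per_expect_N1 := numeric()]
      if (level == "ingredient")
        tab[, estimate_drug_combo_cost_per_day := numeric()]
      return(tab[])
    }
    ex <- exact$count[match(tab$key, exact$key)]
    tab[, exact_exposure_count := fifelse(is.na(ex), 0L, as.integer(ex))]
    tab[, fraction_exact := exact_exposure_count / atleast_exposure_count]
    tab[, fraction_all_windows :=
          if (W_exposed > 0) atleast_exposure_count / W_exposed
          else NA_real_]
    if (n > 1L)
      tab[, observe_per_expect_1s :=
            vapply(key, overrep_singles, numeric(1),
                   counts = exact, W = W_expected, index = idx)]
    if (n > 2L)
      tab[, observe_per_expect_N1 :=
            vapply(key, overrep_subsets, numeric(1),
                   counts = exact, W = W_expected, index = idx)]
    if (level == "ingredient")
      tab[, estimate_drug_combo_cost_per_day :=
            if (is.null(costs)) NA_real_
            else vapply(key, combo_cost, numeric(1), costs = costs)]
    tab[]
  })
}
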