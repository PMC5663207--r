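#' Canonical combination key
#'
#' Combinations are identified by their canonically sorted, duplicate-free
#' item sequence joined with `"|"` — lexicographic order makes equal sets
#' compare equal and output files stable and joinable.
#'
#' @param items Character vector of ingredient (or ATC class) identifiers.
#' @return Single key string.
#' @export
#' @examples
#' combo_key(c("b", "a", "a"))  # "a|b"
combo_key <- function(items) {
  paste(sort(unique(as.character(items))), collapse = "|")
}

#' Split combination keys back into item vectors
#' @param keys Character vector of keys.
#' @return List of character vectors.
#' @export
combo_items <- function(keys) {
  strsplit(keys, "|", fixed = TRUE)
}

#' Exact combination counts per exposure window
#'
#' Summarizes a deduplicated exposure table so that each `(patient,
#' window)` contributes one count to exactly one key: the canonical set of
#' its distinct items. The sum of all exact counts therefore equals the
#' number of exposed windows — an invariant asserted downstream on every
#' run. This summarized table, not the raw windows, is the substrate for
#' all "at-least" counting.
#'
#' @param exposures Exposure table (`patient_id`, `window_index`,
#'   `ingredient`), deduplicated.
#' @return `polyrx_exact` data.table (`key`, `size`, `count`) with
#'   attribute `W_exposed` (total exposed windows), sorted by descending
#'   count then key.
#' @export
exact_combo_counts <- function(exposures) {
  expo <- as.data.table(exposures)
  if (nrow(expo) == 0L) {
    out <- as.data.table(list(key = character(), size = integer(),
                              count = integer()))
  } else {
    expo <- unique(expo[, .(patient_id, window_index, ingredient)])
    setorder(expo, patient_id, window_index, ingredient)
    win <- expo[, .(key = paste(ingredient, collapse = "|"), size = .N),
                by = .(patient_id, window_index)]
    out <- win[, .(count = .N), by = .(key, size)]
    setorder(out, -count, key)
  }
  setattr(out, "W_exposed", sum(out$count))
  setattr(out, "class", c("polyrx_exact", class(out)))
  out[]
}

#' Inverted per-item index over an exact combination table
#'
#' Maps each item to the integer row indices of the exact keys containing
#' it; intersecting the per-item row sets and summing counts answers any
#' "at-least" query without touching the raw windows.
#'
#' @param exact Table from [exact_combo_counts()].
#' @return Named list, item -> integer vector of row indices.
#' @export
combo_index <- function(exact) {
  items <- combo_items(exact$key)
  split(rep(seq_along(items), lengths(items)),
        unlist(items, use.names = FALSE))
}

#' "At-least" exposure count of a combination
#'
#' Number of windows whose drug set contains the queried combination,
#' possibly with additional drugs: the sum of exact counts over all
#' superset keys, evaluated by set intersection on the inverted index.
#' Items never observed yield zero.
#'
#' @param query Character vector of items, or a single `"a|b"` key string.
#' @param exact Table from [exact_combo_counts()].
#' @param index Optional prebuilt [combo_index()] (rebuilt if omitted;
#'   prebuild it when issuing many queries).
#' @return Integer count.
#' @export
#' @examples
#' \dontrun{atleast_count(c("A", "B"), exact)}
atleast_count <- function(query, exact, index = combo_index(exact)) {
  items <- if (length(query) == 1L && grepl("|", query, fixed = TRUE))
    combo_items(query)[[1L]] else unique(as.character(query))
  if (length(items) == 0L) stop("query must be non-empty", call. = FALSE)
  rows <- index[[items[1L]]]
  if (is.null(rows)) return(0L)
  for (it in items[-1L]) {
    nxt <- index[[it]]
    if (is.null(nxt)) return(0L)
    rows <- intersect(rows, nxt)
    if (length(rows) == 0L) return(0L)
  }
  sum(exact$count[rows])
}

#' Naive superset-sum reference for at-least counts
#'
#' Independent of the inverted index: scans every exact key and sums the
#' counts of those containing the query. Used to cross-check
#' [atleast_count()]; the two must agree on any input.
#'
#' @inheritParams atleast_count
#' @return Integer count.
#' @export
atleast_count_naive <- function(query, exact) {
  items <- if (length(query) == 1L && grepl("|", query, fixed = TRUE))
    combo_items(query)[[1L]] else unique(as.character(query))
  keysets <- combo_items(exact$key)
  hit <- vapply(keysets, function(s) all(items %in% s), logical(1))
  sum(exact$count[hit])
}

#' Apriori candidate generation for N-drug combinations
#'
#' Enumerating all N-drug combinations is infeasible and unnecessary since
#' most are never observed; instead, N-combos are constructed greedily from
#' the (N-1)-combos whose at-least counts meet a support threshold. A
#' candidate is emitted iff *every* one of its (N-1)-subsets meets the
#' threshold; because at-least counts are anti-monotone (a superset can
#' never be more frequent than its subsets), this can never miss an N-combo
#' whose own at-least count reaches the threshold.
#'
#' @param n Combination size to generate, 2..`max_n`.
#' @param previous At-least counts at level `n - 1`: a data.table with
#'   columns `key` and `atleast_exposure_count` (or `count`), or a named
#'   integer vector keyed by combination key. Must contain every
#'   (n-1)-combo meeting the threshold.
#' @param support_threshold Minimum at-least count for a subset to support
#'   a candidate (default 1000, the production setting; use small values at
#'   desk scale).
#' @param max_n Largest permitted `n` (default 5).
#' @return Character vector of candidate keys (possibly empty), sorted.
#' @export
generate_candidates <- function(n, previous, support_threshold = 1000L,
                                max_n = 5L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L || n > max_n)
    stop("n must be in 2..", max_n, call. = FALSE)
  if (is.data.frame(previous)) {
    cnt_col <- intersect(c("atleast_exposure_count", "count"),
                         names(previous))[1L]
    if (is.na(cnt_col))
      stop("previous must carry an at-least count column", call. = FALSE)
    counts <- previous[[cnt_col]]
    names(counts) <- previous[["key"]]
  } else {
    counts <- previous
  }
  qual <- sort(names(counts)[counts >= support_threshold])
  if (length(qual) < n) return(character())
  sets <- combo_items(qual)
  if (any(lengths(sets) != n - 1L))
    stop("previous keys are not all of size ", n - 1L, call. = FALSE)

  if (n == 2L) {
    cand <- utils::combn(qual, 2L, paste, collapse = "|")
    return(sort(cand))
  }
  ## F(k-1) x F(k-1) join on the shared (n-2)-prefix, then full-subset prune
  prefix <- vapply(sets, function(s) paste(s[-(n - 1L)], collapse = "|"),
                   character(1))
  last <- vapply(sets, function(s) s[n - 1L], character(1))
  qual_set <- new.env(parent = emptyenv())
  for (k in qual) assign(k, TRUE, envir = qual_set)
  out <- character()
  groups <- split(seq_along(sets), prefix)
  for (g in groups) {
    if (length(g) < 2L) next
    lasts <- sort(last[g])
    pre_items <- sets[[g[1L]]][-(n - 1L)]
    pairs <- utils::combn(lasts, 2L)
    for (j in seq_len(ncol(pairs))) {
      cand_items <- sort(c(pre_items, pairs[1L, j], pairs[2L, j]))
      subs <- vapply(seq_len(n), function(i)
        paste(cand_items[-i], collapse = "|"), character(1))
      if (all(vapply(subs, exists, logical(1), envir = qual_set,
                     inherits = FALSE)))
        out <- c(out, paste(cand_items, collapse = "|"))
    }
  }
  sort(unique(out))
}

#' Count at-least exposures for combinations of size 1..max_n
#'
#' Driver for the full counting stage: level 1 counts every observed item's
#' at-least exposures; each subsequent level generates candidates with
#' [generate_candidates()] from the previous level's qualifying combos and
#' evaluates them on the inverted index. Candidates never observed
#' (at-least count zero) are dropped from the output tables.
#'
#' @param exact Table from [exact_combo_counts()].
#' @param max_n Largest combination size (default 5).
#' @param support_threshold Candidate-generation support threshold
#'   (default 1000).
#' @return Named list `"1"`..`"<max_n>"` of data.tables (`key`, `size`,
#'   `atleast_exposure_count`), each sorted by descending count then key.
#' @export
count_combos <- function(exact, max_n = 5L, support_threshold = 1000L) {
  stopifnot(inherits(exact, "polyrx_exact"))
  out <- vector("list", max_n)
  names(out) <- as.character(seq_len(max_n))
  if (nrow(exact) == 0L) {
    for (n in seq_len(max_n))
      out[[n]] <- as.data.table(list(key = character(), size = integer(),
                                     atleast_exposure_count = integer()))
    return(out)
  }
  idx <- combo_index(exact)
  singles <- as.data.table(list(
    key = names(idx),
    size = 1L,
    atleast_exposure_count = unname(vapply(idx, function(r)
      sum(exact$count[r]), integer(1)))
  ))
  setorder(singles, -atleast_exposure_count, key)
  out[["1"]] <- singles
  prev <- singles
  for (n in 2:max_n) {
    if (max_n < 2L) break
    cand <- generate_candidates(n, prev, support_threshold, max_n = max_n)
    if (length(cand) == 0L) {
      out[[as.character(n)]] <- as.data.table(list(
        key = character(), size = integer(),
        atleast_exposure_count = integer()))
      prev <- out[[as.character(n)]]
      next
    }
    cnt <- vapply(cand, function(k) atleast_count(k, exact, idx), integer(1))
    tab <- as.data.table(list(key = cand, size = n,
                              atleast_exposure_count = as.integer(cnt)))
    tab <- tab[atleast_exposure_count > 0L]
    setorder(tab, -atleast_exposure_count, key)
    out[[as.character(n)]] <- tab
    prev <- tab
  }
  out
}

#' Translate ingredient exposures to ATC level-2 class exposures
#'
#' Replaces each ingredient by its primary ATC level-2 class and
#' deduplicates per `(patient, window, class)`, so a class is counted only
#' once per window even when a patient takes several drugs from it.
#' Ingredients without a well-formed primary ATC code are dropped with a
#' tally.
#'
#' @param exposures Ingredient-level exposure table.
#' @param mapping A [drug_mapping()] resolving every exposed ingredient.
#' @return List: `exposures` (class-level table; class codes occupy the
#'   `ingredient` column) and `n_dropped` (unclassified exposure events
#'   dropped).
#' @export
class_exposures <- function(exposures, mapping) {
  expo <- as.data.table(exposures)
  if (nrow(expo) == 0L)
    return(list(exposures = copy(expo), n_dropped = 0L))
  ings <- unique(expo$ingredient)
  cls <- primary_class(ings, mapping)
  names(cls) <- ings
  out <- copy(expo)
  out[, ingredient := cls[ingredient]]
  n_dropped <- sum(out$ingredient == .sentinel_unclassified)
  out <- unique(out[ingredient != .sentinel_unclassified])
  setorder(out, patient_id, window_index, ingredient)
  list(exposures = out, n_dropped = n_dropped)
}
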