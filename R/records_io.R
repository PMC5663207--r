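#' Record emission policy: inclusion thresholds and privacy masking
#'
#' Controls which combinations appear in the published tables and how small
#' counts are censored. Defaults follow the publication convention: all
#' single drugs and pairs are included; for N = 3..5 only combinations with
#' at least 10,000 at-least exposures; and any exposure count below 100
#' patient-windows is rendered as the mask token `"<100"` to protect
#' patient privacy. Whether masking applies to both count columns or only
#' the exact count is configurable (both by default, the conservative
#' reading).
#'
#' @param include_all_up_to_n Combination sizes always fully included
#'   (default 2).
#' @param min_atleast_for_large_n Minimum at-least count for inclusion at
#'   larger N (default 10000).
#' @param privacy_mask_threshold Counts strictly below this are masked
#'   (default 100).
#' @param mask_token Replacement text (default `"<100"`).
#' @param mask_columns Count columns subject to masking.
#' @return A `polyrx_policy` list.
#' @export
emission_policy <- function(include_all_up_to_n = 2L,
                            min_atleast_for_large_n = 10000L,
                            privacy_mask_threshold = 100L,
                            mask_token = "<100",
                            mask_columns = c("atleast_exposure_count",
                                             "exact_exposure_count")) {
  stopifnot(include_all_up_to_n >= 0L, min_atleast_for_large_n >= 0L,
            privacy_mask_threshold >= 0L,
            is.character(mask_token), nzchar(mask_token))
  structure(list(include_all_up_to_n = as.integer(include_all_up_to_n),
                 min_atleast_for_large_n = as.integer(min_atleast_for_large_n),
                 privacy_mask_threshold = as.integer(privacy_mask_threshold),
                 mask_token = mask_token,
                 mask_columns = mask_columns),
            class = "polyrx_policy")
}

.fmt_real <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

.fmt_count <- function(x, censored, colname, policy) {
  masked <- (colname %in% policy$mask_columns) &
    ((!is.na(x) & x < policy$privacy_mask_threshold) |
       (is.na(x) & censored))
  out <- ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE))
  out[masked] <- policy$mask_token
  out
}

.apply_inclusion <- function(tab, n, policy) {
  if (n <= policy$include_all_up_to_n) return(tab)
  keep <- !is.na(tab$atleast_exposure_count) &
    tab$atleast_exposure_count >= policy$min_atleast_for_large_n
  tab[keep]
}

.sort_records <- function(tab) {
  ## rows whose at-least count is censored (NA after a read-back) cannot be
  ## re-ranked — their true counts are destroyed by masking — so they keep
  ## their incoming order at the tail
  a <- tab$atleast_exposure_count
  idx_ok <- which(!is.na(a))
  ord <- c(idx_ok[order(-xtfrm(a[idx_ok]), tab$key[idx_ok],
                        method = "radix")],
           which(is.na(a)))
  tab[ord]
}

.emit_record_file <- function(tab, n, path, policy, level,
                              class_names = NULL) {
  tab <- as.data.table(tab)
  if (!"atleast_censored" %in% names(tab))
    tab[, c("atleast_censored", "exact_censored") := FALSE]
  tab <- .apply_inclusion(tab, n, policy)
  tab <- .sort_records(tab)
  items <- combo_items(tab$key)
  if (nrow(tab) && any(lengths(items) != n))
    stop("record table for N=", n, " contains keys of the wrong size",
         call. = FALSE)
  cols <- list()
  if (level == "ingredient") {
    for (i in seq_len(n))
      cols[[paste0("drug_name_", LETTERS[i])]] <-
        vapply(items, `[`, character(1), i)
  } else {
    lookup <- if (!is.null(class_names))
      stats::setNames(class_names$atc_class_name, class_names$atc_class)
    for (i in seq_len(n)) {
      code <- vapply(items, `[`, character(1), i)
      cols[[paste0("atc_code_", LETTERS[i])]] <- code
      nm <- if (!is.null(class_names)) unname(lookup[code])
            else rep(NA_character_, length(code))
      cols[[paste0("atc_name_", LETTERS[i])]] <-
        ifelse(is.na(nm), "", nm)
    }
  }
  if (nrow(tab) == 0L) cols <- lapply(cols, function(x) character())
  cols[["atleast_exposure_count"]] <-
    .fmt_count(tab$atleast_exposure_count, tab$atleast_censored,
               "atleast_exposure_count", policy)
  cols[["exact_exposure_count"]] <-
    .fmt_count(tab$exact_exposure_count, tab$exact_censored,
               "exact_exposure_count", policy)
  if (level == "ingredient")
    cols[["estimate_drug_cost_per_day"]] <-
      .fmt_real(tab$estimate_drug_combo_cost_per_day)
  cols[["fraction_exact"]] <- .fmt_real(tab$fraction_exact)
  cols[["fraction_all_windows"]] <- .fmt_real(tab$fraction_all_windows)
  if (n > 1L)
    cols[["observe_per_expect_1s"]] <- .fmt_real(tab$observe_per_expect_1s)
  if (n > 2L)
    cols[["observe_per_expect_N1"]] <- .fmt_real(tab$observe_per_expect_N1)
  lines <- c(paste(names(cols), collapse = "\t"),
             if (nrow(tab)) do.call(paste, c(unname(cols), sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  path
}

#' Write drug-ingredient combination records
#'
#' Emits one tab-delimited file per combination size N
#' (`db_drugs_1s.tsv` .. `db_drugs_5s.tsv`), one row per combination with
#' N drug-name columns followed by the statistic columns
#' (`atleast_exposure_count`, `exact_exposure_count`,
#' `estimate_drug_cost_per_day`, `fraction_exact`, `fraction_all_windows`,
#' then `observe_per_expect_1s` for N > 1 and `observe_per_expect_N1` for
#' N > 2). Rows are sorted by descending at-least count with ties broken by
#' canonical key; inclusion thresholds and privacy masking follow the
#' [emission_policy()]. Undefined statistics are written as empty fields.
#'
#' @param stats_by_n List of statistics tables from [combo_stats()]
#'   (ingredient level), named by N.
#' @param policy An [emission_policy()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_drug_records <- function(stats_by_n, policy = emission_policy(),
                               out_dir = ".") {
  stopifnot(inherits(policy, "polyrx_policy"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(stats_by_n), function(nm) {
    n <- as.integer(nm)
    .emit_record_file(stats_by_n[[nm]], n,
                      file.path(out_dir, sprintf("db_drugs_%ds.tsv", n)),
                      policy, level = "ingredient")
  }, character(1))
  invisible(paths)
}

#' Write ATC drug-class combination records
#'
#' As [write_drug_records()] but for ATC level-2 class combinations: files
#' `db_atc_classes_1s.tsv` .. `db_atc_classes_5s.tsv` with interleaved
#' `atc_code_X`/`atc_name_X` column pairs and no cost column (daily cost
#' cannot be calculated at the drug class level).
#'
#' @inheritParams write_drug_records
#' @param class_names data.table (`atc_class`, `atc_class_name`) used to
#'   fill the name columns.
#' @return Invisibly, the named vector of file paths.
#' @export
write_class_records <- function(stats_by_n, policy = emission_policy(),
                                out_dir = ".", class_names = NULL) {
  stopifnot(inherits(policy, "polyrx_policy"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(stats_by_n), function(nm) {
    n <- as.integer(nm)
    .emit_record_file(stats_by_n[[nm]], n,
                      file.path(out_dir,
                                sprintf("db_atc_classes_%ds.tsv", n)),
                      policy, level = "class", class_names = class_names)
  }, character(1))
  invisible(paths)
}

.known_stat_cols <- c("atleast_exposure_count", "exact_exposure_count",
                      "estimate_drug_cost_per_day", "fraction_exact",
                      "fraction_all_windows", "observe_per_expect_1s",
                      "observe_per_expect_N1")

#' Read a published combination-record file
#'
#' Parses a file written by [write_drug_records()] or
#' [write_class_records()] back into a statistics table. Masked cells
#' (e.g. `"<100"`) are never turned into numbers: the count is `NA` and a
#' censoring flag plus the mask's upper bound are carried instead, so a
#' write-read-write cycle reproduces the file byte-identically.
#'
#' @param path Path to a record TSV.
#' @param mask_token Mask token to recognize (default any `"<k"` cell).
#' @return data.table with `key`, `size`, the numeric statistic columns,
#'   censoring flags `atleast_censored` / `exact_censored`, and — for
#'   censored cells — `censor_bound`. Attribute `level` is `"ingredient"`
#'   or `"class"`; class tables also carry an `atc_names` attribute.
#' @export
read_records <- function(path, mask_token = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  name_cols <- grepl("^drug_name_[A-Z]$", header)
  code_cols <- grepl("^atc_code_[A-Z]$", header)
  cname_cols <- grepl("^atc_name_[A-Z]$", header)
  unknown <- header[!(name_cols | code_cols | cname_cols |
                        header %in% .known_stat_cols)]
  if (length(unknown))
    stop("unknown columns: ", paste(unknown, collapse = ", "), call. = FALSE)
  level <- if (any(name_cols)) "ingredient" else "class"
  n <- if (level == "ingredient") sum(name_cols) else sum(code_cols)
  if (n == 0L) stop("no combination name columns in ", path, call. = FALSE)

  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(parts)
  ## trailing empty fields are dropped by strsplit; pad, but flag overlong rows
  bad <- which(widths > length(header))
  if (length(bad))
    stop("malformed row width at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  mat <- matrix("", nrow = length(parts), ncol = length(header),
                dimnames = list(NULL, header))
  for (i in seq_along(parts)) mat[i, seq_len(widths[i])] <- parts[[i]]

  item_cols <- if (level == "ingredient")
    paste0("drug_name_", LETTERS[seq_len(n)])
  else paste0("atc_code_", LETTERS[seq_len(n)])
  keys <- if (length(parts))
    apply(mat[, item_cols, drop = FALSE], 1L,
          function(r) paste(sort(r), collapse = "|"))
  else character()

  is_masked <- function(x) {
    if (!is.null(mask_token)) x == mask_token
    else grepl("^<[0-9]+$", x)
  }
  parse_count <- function(col) {
    x <- mat[, col]
    m <- is_masked(x)
    val <- suppressWarnings(as.numeric(x))
    val[m | x == ""] <- NA_real_
    bound <- rep(NA_real_, length(x))
    bound[m] <- as.numeric(sub("^<", "", x[m]))
    list(value = val, censored = m, bound = bound)
  }
  out <- as.data.table(list(key = keys, size = rep(n, length(keys))))
  al <- parse_count("atleast_exposure_count")
  ex <- parse_count("exact_exposure_count")
  out[, atleast_exposure_count := al$value]
  out[, exact_exposure_count := ex$value]
  out[, atleast_censored := al$censored]
  out[, exact_censored := ex$censored]
  out[, censor_bound := fifelse(is.na(al$bound), ex$bound, al$bound)]
  for (col in c("fraction_exact", "fraction_all_windows",
                "observe_per_expect_1s", "observe_per_expect_N1")) {
    if (col %in% header) {
      v <- suppressWarnings(as.numeric(mat[, col]))
      out[, (col) := v]
    }
  }
  if ("estimate_drug_cost_per_day" %in% header)
    out[, estimate_drug_combo_cost_per_day :=
          suppressWarnings(as.numeric(mat[, "estimate_drug_cost_per_day"]))]
  setattr(out, "level", level)
  if (level == "class" && any(cname_cols) && length(parts)) {
    codes <- as.vector(mat[, item_cols, drop = FALSE])
    nms <- as.vector(mat[, paste0("atc_name_", LETTERS[seq_len(n)]),
                         drop = FALSE])
    uc <- !duplicated(codes)
    setattr(out, "atc_names",
            data.table(atc_class = codes[uc], atc_class_name = nms[uc]))
  }
  out[]
}

#' Write a README.txt describing the record files
#'
#' Emits a plain-text manifest of the record files in a directory, with one
#' line per file and a short description of the layout and masking policy.
#'
#' @param out_dir Directory holding the record files.
#' @param policy The [emission_policy()] used when writing.
#' @param max_n Largest combination size emitted.
#' @return Invisibly, the README path.
#' @export
write_records_readme <- function(out_dir, policy = emission_policy(),
                                 max_n = 5L) {
  lines <- c(
    "Drug combination exposure counts",
    "",
    "Files:",
    sprintf("  db_drugs_%ds.tsv - exposure counts for combinations of %d drug ingredient(s)",
            seq_len(max_n), seq_len(max_n)),
    sprintf("  db_atc_classes_%ds.tsv - exposure counts for combinations of %d ATC level-2 drug class(es)",
            seq_len(max_n), seq_len(max_n)),
    "",
    sprintf("All combinations of N <= %d are included; for larger N only combinations with at least %d at-least exposure windows appear.",
            policy$include_all_up_to_n, policy$min_atleast_for_large_n),
    sprintf("Exposure counts below %d patient-windows are reported as '%s' to protect patient privacy.",
            policy$privacy_mask_threshold, policy$mask_token),
    "Files are tab-delimited with a header row, UTF-8, no quoting."
  )
  path <- file.path(out_dir, "README.txt")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
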