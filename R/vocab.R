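#' Construct a drug-code-to-ingredient vocabulary mapping
#'
#' @param code_to_ingredients Named list: drug code -> non-empty character
#'   vector of ingredient identifiers (combination products have more than
#'   one entry).
#' @param ingredient_info data.frame with columns `ingredient`, `rxcui`,
#'   `umls_cui`, `drugbank_id`, `atc_code`, `atc_name`. Every ingredient
#'   referenced by `code_to_ingredients` must have a row. `atc_code` holds
#'   the ingredient's single *primary* ATC code (the input vocabulary is
#'   expected to have pre-resolved primacy when RxNorm offers several); a
#'   missing or empty code is permitted and the ingredient is flagged
#'   unclassified.
#' @return A `polyrx_mapping` list.
#' @export
drug_mapping <- function(code_to_ingredients, ingredient_info) {
  if (!is.list(code_to_ingredients) || is.null(names(code_to_ingredients)))
    stop("code_to_ingredients must be a named list", call. = FALSE)
  if (any(lengths(code_to_ingredients) == 0L))
    stop("every drug code must map to a non-empty ingredient set",
         call. = FALSE)
  info <- as.data.table(ingredient_info)
  need <- c("ingredient", "rxcui", "umls_cui", "drugbank_id",
            "atc_code", "atc_name")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stop("ingredient_info is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(info$ingredient))
    stop("duplicated ingredient rows in ingredient_info", call. = FALSE)
  referenced <- unique(unlist(code_to_ingredients))
  unknown <- setdiff(referenced, info$ingredient)
  if (length(unknown))
    stop("ingredients referenced by code_to_ingredients but absent from ",
         "ingredient_info: ", paste(unknown, collapse = ", "), call. = FALSE)
  setkey(info, ingredient)
  structure(list(code_to_ingredients = code_to_ingredients,
                 ingredient_info = info),
            class = "polyrx_mapping")
}

#' Expand drug-code claims to ingredient-level claims
#'
#' Each claim row is replicated once per constituent ingredient of its drug
#' code, so a combination product counts as exposure to every ingredient it
#' contains. Patient, fill age, days of supply, and the full claim payment
#' are carried unchanged on every replicate (payment attribution for
#' combination products is deliberately whole-claim-per-ingredient, a known
#' upward bias for combination-product ingredients). Claims whose code is
#' not in the mapping are dropped and tallied, never silently ignored.
#'
#' @param claims data.frame of claims (`patient_id`, `drug_code`,
#'   `fill_age_days`, `days_supply`, `payment`; `payment` optional).
#' @param mapping A [drug_mapping()].
#' @return List: `claims` (data.table with `ingredient` replacing
#'   `drug_code`) and `n_dropped` (count of unmapped claims dropped).
#' @export
expand_to_ingredients <- function(claims, mapping) {
  stopifnot(inherits(mapping, "polyrx_mapping"))
  dt <- as.data.table(claims)
  mapped <- dt$drug_code %chin% names(mapping$code_to_ingredients)
  n_dropped <- sum(!mapped)
  dt <- dt[mapped]
  if (nrow(dt) == 0L) {
    out <- copy(dt)
    out[, ingredient := character()]
    out[, drug_code := NULL]
  } else {
    ings <- mapping$code_to_ingredients[dt$drug_code]
    k <- lengths(ings)
    out <- dt[rep(seq_len(.N), k)]
    out[, ingredient := unlist(ings, use.names = FALSE)]
    out[, drug_code := NULL]
  }
  front <- c("patient_id", "ingredient", "fill_age_days", "days_supply")
  setcolorder(out, c(front, setdiff(names(out), front)))
  list(claims = out[], n_dropped = n_dropped)
}

#' Estimate per-ingredient daily cost
#'
#' The approximate cost per day of an ingredient is the median over all of
#' its claims of payment divided by days of supply; the median of an even
#' number of claims is the midpoint of the two central values. Ingredients
#' with no claims are absent from the output.
#'
#' @param ingredient_claims Ingredient-level claims (from
#'   [expand_to_ingredients()]) with columns `ingredient`, `payment`,
#'   `days_supply` (> 0 on all rows).
#' @return data.table (`ingredient`, `cost_per_day`), one row per
#'   ingredient, sorted by ingredient.
#' @export
estimate_cost_per_day <- function(ingredient_claims) {
  dt <- as.data.table(ingredient_claims)
  if (any(dt$days_supply <= 0L))
    stop("days_supply must be > 0 on all rows", call. = FALSE)
  out <- dt[, .(cost_per_day = stats::median(payment / days_supply)),
            by = ingredient]
  setorder(out, ingredient)
  out[]
}

#' Primary ATC level-2 class of an ingredient
#'
#' Returns the level-2 ("therapeutic main group") prefix — the first three
#' characters, letter-digit-digit — of the ingredient's primary ATC code.
#' One ingredient can map to multiple ATC classes; only the single primary
#' code carried by the vocabulary is used. A missing or ill-formed code
#' yields the `"UNCLASSIFIED"` sentinel.
#'
#' @param ingredient Ingredient identifier(s); vectorized.
#' @param mapping A [drug_mapping()]; every queried ingredient must be
#'   present.
#' @return Character vector of level-2 class codes (e.g. `"A10"`) or the
#'   unclassified sentinel.
#' @export
#' @examples
#' \dontrun{primary_class("metformin", mapping)  # "A10" for code A10BA02}
primary_class <- function(ingredient, mapping) {
  stopifnot(inherits(mapping, "polyrx_mapping"))
  info <- mapping$ingredient_info
  idx <- match(ingredient, info$ingredient)
  if (anyNA(idx))
    stop("ingredient(s) not in mapping: ",
         paste(ingredient[is.na(idx)], collapse = ", "), call. = FALSE)
  atc <- info$atc_code[idx]
  cls <- toupper(substr(atc, 1L, 3L))
  ok <- !is.na(atc) & grepl("^[A-Za-z][0-9][0-9]", atc)
  ifelse(ok, cls, .sentinel_unclassified)
}

#' Read a Data Record 3 style vocabulary
#'
#' Reads the two tab-delimited mapping files — per-ingredient vocabulary
#' identifiers plus primary ATC code (`drug_mappings_ingredients.tsv`:
#' columns `drug_name`, `rxcui`, `atc_code`, `atc_name`,
#' `estimate_drug_cost_per_day`, `UMLS_CUI`, `DrugBankID`) and the ATC
#' level-2 class list (`drug_mappings_atc_classes.tsv`: columns
#' `atc_class`, `atc_class_name`) — together with an optional
#' combination-product table (`combination_products.tsv`: columns
#' `drug_code`, `ingredient`, one row per constituent). Codes that are not
#' combination products map to themselves.
#'
#' @param dir Directory containing the files.
#' @return List: `mapping` (a [drug_mapping()]), `classes` (data.table
#'   `atc_class`, `atc_class_name`), `cost` (data.table `ingredient`,
#'   `cost_per_day` from the vocabulary's cost column, if present).
#' @export
read_vocabulary <- function(dir) {
  ing_path <- file.path(dir, "drug_mappings_ingredients.tsv")
  cls_path <- file.path(dir, "drug_mappings_atc_classes.tsv")
  if (!file.exists(ing_path) || !file.exists(cls_path))
    stop("vocabulary files not found under ", dir, call. = FALSE)
  ing <- fread(ing_path, sep = "\t", colClasses = "character")
  cls <- fread(cls_path, sep = "\t", colClasses = "character")
  info <- data.table(ingredient = ing$drug_name, rxcui = ing$rxcui,
                     umls_cui = ing$UMLS_CUI, drugbank_id = ing$DrugBankID,
                     atc_code = ing$atc_code, atc_name = ing$atc_name)
  combo_path <- file.path(dir, "combination_products.tsv")
  c2i <- as.list(info$ingredient)
  names(c2i) <- info$ingredient
  if (file.exists(combo_path)) {
    cp <- fread(combo_path, sep = "\t", colClasses = "character")
    combos <- split(cp$ingredient, cp$drug_code)
    c2i[names(combos)] <- combos
  }
  cost <- NULL
  if ("estimate_drug_cost_per_day" %in% names(ing)) {
    cost <- data.table(ingredient = ing$drug_name,
                       cost_per_day = suppressWarnings(
                         as.numeric(ing$estimate_drug_cost_per_day)))
    cost <- cost[!is.na(cost_per_day)]
  }
  list(mapping = drug_mapping(c2i, info),
       classes = data.table(atc_class = cls$atc_class,
                            atc_class_name = cls$atc_class_name),
       cost = cost)
}

#' Write a vocabulary in the Data Record 3 layout
#'
#' Inverse of [read_vocabulary()]: writes `drug_mappings_ingredients.tsv`,
#' `drug_mappings_atc_classes.tsv`, and `combination_products.tsv` (the
#' latter only when the mapping has any multi-ingredient code).
#'
#' @param mapping A [drug_mapping()].
#' @param classes data.table (`atc_class`, `atc_class_name`).
#' @param dir Output directory (created if needed).
#' @param cost Optional data.table (`ingredient`, `cost_per_day`) merged
#'   into the cost column.
#' @return Invisibly, the paths written.
#' @export
write_vocabulary <- function(mapping, classes, dir, cost = NULL) {
  stopifnot(inherits(mapping, "polyrx_mapping"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- mapping$ingredient_info
  out <- data.table(drug_name = info$ingredient, rxcui = info$rxcui,
                    atc_code = info$atc_code, atc_name = info$atc_name,
                    estimate_drug_cost_per_day = NA_character_,
                    UMLS_CUI = info$umls_cui, DrugBankID = info$drugbank_id)
  if (!is.null(cost)) {
    cost <- as.data.table(cost)
    m <- match(out$drug_name, cost$ingredient)
    out[!is.na(m), estimate_drug_cost_per_day :=
          format(cost$cost_per_day[m[!is.na(m)]], digits = 6)]
  }
  setorder(out, drug_name)
  paths <- file.path(dir, c("drug_mappings_ingredients.tsv",
                            "drug_mappings_atc_classes.tsv"))
  fwrite(out, paths[1L], sep = "\t", quote = FALSE, na = "")
  cls <- as.data.table(classes)
  setorder(cls, atc_class)
  fwrite(cls, paths[2L], sep = "\t", quote = FALSE, na = "")
  multi <- Filter(function(x) length(x) > 1L, mapping$code_to_ingredients)
  if (length(multi)) {
    cp <- data.table(drug_code = rep(names(multi), lengths(multi)),
                     ingredient = unlist(multi, use.names = FALSE))
    p3 <- file.path(dir, "combination_products.tsv")
    fwrite(cp, p3, sep = "\t", quote = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Bundled demonstration vocabulary
#'
#' A small synthetic vocabulary (20 common ingredients, 16 ATC level-2
#' classes, one combination product) shipped in the Data Record 3 layout
#' for examples and tests. Drug names and ATC class assignments follow the
#' public ATC hierarchy; the RxNorm/UMLS/DrugBank identifiers are synthetic
#' placeholders, not real registry entries.
#'
#' @return As [read_vocabulary()].
#' @export
demo_vocabulary <- function() {
  read_vocabulary(system.file("extdata", package = "polyrx"))
}
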