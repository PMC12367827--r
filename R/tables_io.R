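# Tabular data model: substance registry, product composition, sales,
# prediction tables and dose-response data. All files are UTF-8 CSV with a
# "." decimal point. Mass fractions live as fractions in [0, 1] in memory and
# as percentages in every file, so the file dialect matches how formulation
# recipes are written while the API stays unit-safe.

#' Validate CAS registry numbers
#'
#' A CAS number has the form `NNNNNNN-NN-R` (2-7 leading digits) where the
#' final digit is a checksum: the digits are weighted 1, 2, 3, ... from the
#' right (excluding the check digit) and summed; the check digit is that sum
#' modulo 10.
#'
#' @param cas character vector of candidate CAS strings.
#' @return logical vector; `NA` input gives `FALSE`.
#' @examples
#' cas_is_valid(c("7732-18-5", "14433-76-2", "123-45-6"))
#' @export
cas_is_valid <- function(cas) {
  ok <- !is.na(cas) & grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)
  if (!any(ok)) {
    return(ok)
  }
  check <- vapply(cas[ok], function(x) {
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    n <- length(digits)
    body <- digits[-n]
    sum(rev(body) * seq_along(body)) %% 10 == digits[n]
  }, logical(1), USE.NAMES = FALSE)
  ok[ok] <- check
  ok
}

substance_roles <- c("active_substance", "co_formulant")

read_mix_csv <- function(path, required, label) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(
      "schema error in ", label, " (", path, "): missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' Load a substance registry
#'
#' Reads `registry.csv` with columns `substance_id, cas, name, smiles, role`
#' and optionally `is_class` (marks polymers, minerals, natural extracts and
#' other substance classes without a discrete structure). A syntactically
#' invalid CAS is dropped with a warning (the record is kept, CAS set to
#' missing); duplicated `substance_id` is an error.
#'
#' @param path CSV file path.
#' @return tibble with columns `substance_id`, `cas`, `name`, `smiles`,
#'   `role`, `is_class`.
#' @export
load_registry <- function(path) {
  df <- read_mix_csv(
    path, c("substance_id", "cas", "name", "smiles", "role"), "registry"
  )
  if (!"is_class" %in% names(df)) {
    df$is_class <- FALSE
  }
  df <- tibble::as_tibble(df[, c(
    "substance_id", "cas", "name", "smiles", "role", "is_class"
  )])
  df$substance_id <- as.character(df$substance_id)
  df$cas <- as.character(df$cas)
  df$smiles <- as.character(df$smiles)
  df$cas[!is.na(df$cas) & df$cas == ""] <- NA_character_
  df$smiles[!is.na(df$smiles) & df$smiles == ""] <- NA_character_
  df$is_class <- as.logical(df$is_class)
  df$is_class[is.na(df$is_class)] <- FALSE
  dup <- df$substance_id[duplicated(df$substance_id)]
  if (length(dup) > 0) {
    stop(
      "schema error in registry: duplicate substance_id ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  bad_role <- setdiff(unique(df$role), substance_roles)
  if (length(bad_role) > 0) {
    stop(
      "schema error in registry: unknown role ",
      paste(bad_role, collapse = ", "),
      call. = FALSE
    )
  }
  bad_cas <- !is.na(df$cas) & !cas_is_valid(df$cas)
  if (any(bad_cas)) {
    warning(
      "malformed CAS dropped for substance(s): ",
      paste(df$substance_id[bad_cas], collapse = ", "),
      call. = FALSE
    )
    df$cas[bad_cas] <- NA_character_
  }
  df
}

#' Filter a registry to the unique, structure-bearing co-formulants
#'
#' Reproduces the triage that reduces a raw co-formulant list to the set a
#' structure-based (QSAR) workflow can handle: only co-formulants, only
#' entries with a SMILES, collapsed so that substances sharing a CAS (or,
#' when CAS is absent, sharing an identical SMILES string) count once with
#' the first-seen record kept. Substances excluded for lack of a SMILES
#' remain usable in the sales stream.
#'
#' @param registry tibble as returned by [load_registry()].
#' @return list with `eligible` (tibble of retained records) and `excluded`
#'   (tibble with an extra `reason` column, one of `not_coformulant`,
#'   `no_smiles`, `duplicate_cas`).
#' @export
filter_unique_coformulants <- function(registry) {
  stopifnot(nrow(registry) > 0)
  reason <- rep(NA_character_, nrow(registry))
  reason[registry$role != "co_formulant"] <- "not_coformulant"
  is_cof <- is.na(reason)
  reason[is_cof & is.na(registry$smiles)] <- "no_smiles"
  # collapse duplicates among the remaining candidates: CAS key when
  # present, exact SMILES string otherwise
  cand <- which(is.na(reason))
  key <- ifelse(
    is.na(registry$cas[cand]),
    paste0("smiles:", registry$smiles[cand]),
    paste0("cas:", registry$cas[cand])
  )
  dup <- duplicated(key)
  reason[cand[dup]] <- "duplicate_cas"
  eligible <- registry[is.na(reason), , drop = FALSE]
  excluded <- registry[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  list(eligible = eligible, excluded = excluded)
}

#' Load product sales
#'
#' Reads `products.csv` with columns `product_id, sales_kg` (annual sales in
#' kg of formulated product).
#'
#' @param path CSV file path.
#' @return tibble with `product_id`, `sales_kg`.
#' @export
load_products <- function(path) {
  df <- read_mix_csv(path, c("product_id", "sales_kg"), "products")
  df$product_id <- as.character(df$product_id)
  df$sales_kg <- as.numeric(df$sales_kg)
  if (any(is.na(df$sales_kg)) || any(df$sales_kg < 0)) {
    stop("schema error in products: sales_kg must be numeric and >= 0",
      call. = FALSE
    )
  }
  tibble::as_tibble(df[, c("product_id", "sales_kg")])
}

#' Load product composition
#'
#' Reads `composition.csv` with columns `product_id, substance_id, percent`
#' (mass percent of the substance in the formulated product). Percentages
#' are converted to fractions on load; per product the fractions must sum to
#' at most 1 (tolerance 1e-9).
#'
#' @param path CSV file path.
#' @return tibble with `product_id`, `substance_id`, `mass_fraction`.
#' @export
load_composition <- function(path) {
  df <- read_mix_csv(
    path, c("product_id", "substance_id", "percent"), "composition"
  )
  df$product_id <- as.character(df$product_id)
  df$substance_id <- as.character(df$substance_id)
  frac <- as.numeric(df$percent) / 100
  if (any(is.na(frac)) || any(frac < 0) || any(frac > 1)) {
    stop("schema error in composition: percent must be numeric in [0, 100]",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    product_id = df$product_id,
    substance_id = df$substance_id,
    mass_fraction = frac
  )
  sums <- tapply(out$mass_fraction, out$product_id, sum)
  if (any(sums > 1 + 1e-9)) {
    stop(
      "schema error in composition: fractions exceed 100% for product(s) ",
      paste(names(sums)[sums > 1 + 1e-9], collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Write product composition
#'
#' Inverse of [load_composition()]: emits percentages.
#'
#' @param composition tibble with `product_id`, `substance_id`,
#'   `mass_fraction`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(composition, path) {
  readr::write_csv(
    tibble::tibble(
      product_id = composition$product_id,
      substance_id = composition$substance_id,
      percent = composition$mass_fraction * 100
    ),
    path
  )
  invisible(path)
}

#' Load statistical-model alert table
#'
#' Reads `stat_alerts.csv` with columns
#' `substance_id, endpoint, submodel, alert` where `alert` is binary (0/1),
#' one row per sub-model of the endpoint suite (the hepatotoxicity suite has
#' four sub-models, the nephrotoxicity suite six).
#'
#' @param path CSV file path.
#' @return tibble with those four columns.
#' @export
load_stat_alerts <- function(path) {
  df <- read_mix_csv(
    path, c("substance_id", "endpoint", "submodel", "alert"), "stat_alerts"
  )
  df$substance_id <- as.character(df$substance_id)
  df$alert <- as.integer(df$alert)
  if (any(is.na(df$alert)) || !all(df$alert %in% c(0L, 1L))) {
    stop("schema error in stat_alerts: alert must be 0 or 1", call. = FALSE)
  }
  tibble::as_tibble(df[, c("substance_id", "endpoint", "submodel", "alert")])
}

#' Load expert-system likelihood table
#'
#' Reads `expert_calls.csv` with columns
#' `substance_id, endpoint, likelihood`; likelihood must come from the
#' nine-level vocabulary of [likelihood_levels()].
#'
#' @param path CSV file path.
#' @return tibble with those three columns.
#' @export
load_expert_calls <- function(path) {
  df <- read_mix_csv(
    path, c("substance_id", "endpoint", "likelihood"), "expert_calls"
  )
  df$substance_id <- as.character(df$substance_id)
  bad <- setdiff(unique(df$likelihood), likelihood_levels())
  if (length(bad) > 0) {
    stop(
      "schema error in expert_calls: unknown likelihood level ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::as_tibble(df[, c("substance_id", "endpoint", "likelihood")])
}

adme_targets <- c("CYP1A2", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A4", "P_gp")

#' Load ADME substrate/inhibitor predictions
#'
#' Reads `adme.csv` with columns
#' `substance_id, target, mode, in_scope, confidence`. `mode` is `substrate`
#' or `inhibitor`; `in_scope` marks predictions inside the model's
#' applicability domain; `confidence` is a fraction in \[0, 1\] and is only
#' meaningful when `in_scope` is true (out-of-scope rows carry no
#' confidence).
#'
#' @param path CSV file path.
#' @return tibble with those five columns.
#' @export
load_adme <- function(path) {
  df <- read_mix_csv(
    path, c("substance_id", "target", "mode", "in_scope", "confidence"),
    "adme"
  )
  df$substance_id <- as.character(df$substance_id)
  df$in_scope <- as.logical(df$in_scope)
  df$confidence <- as.numeric(df$confidence)
  bad_t <- setdiff(unique(df$target), adme_targets)
  if (length(bad_t) > 0) {
    stop("schema error in adme: unknown target ",
      paste(bad_t, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(df$mode %in% c("substrate", "inhibitor"))) {
    stop("schema error in adme: mode must be substrate or inhibitor",
      call. = FALSE
    )
  }
  if (any(df$in_scope & (is.na(df$confidence) | df$confidence < 0 |
    df$confidence > 1))) {
    stop("schema error in adme: in-scope rows need confidence in [0, 1]",
      call. = FALSE
    )
  }
  df$confidence[!df$in_scope] <- NA_real_
  tibble::as_tibble(
    df[, c("substance_id", "target", "mode", "in_scope", "confidence")]
  )
}

#' Load dose-response viability data
#'
#' Reads long-format `doseresponse.csv` with columns
#' `treatment, conc_mg_L, response_pct, replicate`. Concentrations are in
#' mg/L; `conc_mg_L == 0` rows are solvent controls; responses are percent
#' of the solvent control.
#'
#' @param path CSV file path.
#' @return tibble with those four columns, ordered by treatment then
#'   concentration.
#' @seealso [split_dose_response()] to break the table into one dataset per
#'   treatment label.
#' @export
load_dose_response <- function(path) {
  df <- read_mix_csv(
    path, c("treatment", "conc_mg_L", "response_pct", "replicate"),
    "doseresponse"
  )
  if (nrow(df) == 0) {
    return(tibble::tibble(
      treatment = character(), conc_mg_L = numeric(),
      response_pct = numeric(), replicate = character()
    ))
  }
  df$conc_mg_L <- as.numeric(df$conc_mg_L)
  df$response_pct <- as.numeric(df$response_pct)
  if (any(is.na(df$conc_mg_L)) || any(df$conc_mg_L < 0)) {
    stop("schema error in doseresponse: conc_mg_L must be numeric and >= 0",
      call. = FALSE
    )
  }
  if (any(is.na(df$response_pct))) {
    stop("schema error in doseresponse: response_pct must be numeric",
      call. = FALSE
    )
  }
  df$replicate <- as.character(df$replicate)
  out <- tibble::as_tibble(
    df[, c("treatment", "conc_mg_L", "response_pct", "replicate")]
  )
  out[order(out$treatment, out$conc_mg_L), ]
}

#' Split a dose-response table by treatment label
#'
#' @param data tibble as returned by [load_dose_response()].
#' @return named list of tibbles, one per treatment label.
#' @export
split_dose_response <- function(data) {
  split(data, data$treatment)
}

#' Write / read a priority report
#'
#' The report has one row per (product, trigger) call with the structured
#' detail serialised as JSON, deterministically ordered by product then
#' trigger code so repeated runs are byte-identical.
#'
#' @param calls tibble with `product_id`, `trigger`, `detail_json`.
#' @param path CSV path.
#' @return `write_priority_report()` returns `path` invisibly;
#'   `read_priority_report()` returns the calls tibble.
#' @export
write_priority_report <- function(calls, path) {
  stopifnot(all(c("product_id", "trigger", "detail_json") %in% names(calls)))
  out <- calls[
    order(calls$product_id, calls$trigger, calls$detail_json),
    c("product_id", "trigger", "detail_json")
  ]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_priority_report
#' @export
read_priority_report <- function(path) {
  df <- read_mix_csv(
    path, c("product_id", "trigger", "detail_json"), "priority_report"
  )
  df$product_id <- as.character(df$product_id)
  tibble::as_tibble(df[, c("product_id", "trigger", "detail_json")])
}
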