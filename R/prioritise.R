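# Rule-based prioritisation: two-source organ-toxicity scoring, formulation
# content thresholds, inhibitor-substrate pairing across CYP isoenzymes and
# P-gp, sales-weighted ranking, and the merged priority list.

#' Expert-system likelihood vocabulary
#'
#' The nine ordinal likelihood levels used by rule-based expert systems,
#' from strongest positive to "nothing to report", in decreasing order.
#' `equivocal` is the weakest level still treated as a positive structural
#' alert; everything below it counts as negative.
#'
#' @return character vector of the nine levels, strongest first.
#' @export
likelihood_levels <- function() {
  c(
    "certain", "probable", "plausible", "equivocal",
    "doubted", "improbable", "impossible",
    "inactive_or_no_alert", "nothing_to_report"
  )
}

#' @rdname likelihood_levels
#' @export
positive_likelihoods <- function() {
  c("certain", "probable", "plausible", "equivocal")
}

#' Two-source organ-toxicity score for one substance and endpoint
#'
#' Combines a statistical alert profile with an expert-system likelihood
#' into a score in \{0, 1, 2\}: one point if at least one statistical
#' sub-model fires, one point if the expert likelihood is at least
#' `equivocal`. Either source may be missing (`NA`) and then contributes 0.
#'
#' @param alerts integer count of positive statistical sub-model alerts
#'   (0-6), or a binary vector of per-sub-model alerts, or `NA` when the
#'   statistical source has no prediction.
#' @param likelihood one of [likelihood_levels()], or `NA` when the expert
#'   source has no prediction.
#' @return list with `statistical_hit`, `expert_hit` (logicals) and
#'   `score` (integer).
#' @examples
#' score_endpoint(2, "plausible")$score # 2
#' score_endpoint(0, "improbable")$score # 0
#' score_endpoint(1, "nothing_to_report")$score # 1
#' @export
score_endpoint <- function(alerts, likelihood) {
  if (length(alerts) > 1) {
    alerts <- sum(alerts)
  }
  if (!is.na(alerts) && (alerts < 0 || alerts != round(alerts))) {
    stop("alerts must be a non-negative integer count", call. = FALSE)
  }
  if (!is.na(likelihood) && !likelihood %in% likelihood_levels()) {
    stop("unknown likelihood level: ", likelihood, call. = FALSE)
  }
  stat_hit <- !is.na(alerts) && alerts >= 1
  exp_hit <- !is.na(likelihood) && likelihood %in% positive_likelihoods()
  list(
    statistical_hit = stat_hit,
    expert_hit = exp_hit,
    score = as.integer(stat_hit) + as.integer(exp_hit)
  )
}

#' Score every substance and endpoint from the two prediction tables
#'
#' Statistical alerts are summed over sub-models per substance and endpoint;
#' expert calls are reduced to the strongest likelihood level when a
#' substance has several. A substance present in only one table is scored
#' with the other source counted as a miss, but `expert_status`
#' distinguishes a genuinely absent expert prediction (`missing`) from an
#' explicit `nothing_to_report`.
#'
#' @param stat_alerts tibble from [load_stat_alerts()].
#' @param expert_calls tibble from [load_expert_calls()].
#' @return tibble with `substance_id`, `endpoint`, `n_alerts`,
#'   `expert_likelihood`, `expert_status`, `statistical_hit`, `expert_hit`,
#'   `score`.
#' @export
score_endpoints <- function(stat_alerts, expert_calls) {
  stat <- stat_alerts |>
    dplyr::group_by(.data$substance_id, .data$endpoint) |>
    dplyr::summarise(n_alerts = sum(.data$alert), .groups = "drop")
  lev <- likelihood_levels()
  expert <- expert_calls |>
    dplyr::group_by(.data$substance_id, .data$endpoint) |>
    dplyr::summarise(
      expert_likelihood = lev[min(match(.data$likelihood, lev))],
      .groups = "drop"
    )
  scored <- dplyr::full_join(
    stat, expert,
    by = c("substance_id", "endpoint")
  )
  scored$expert_status <- ifelse(
    is.na(scored$expert_likelihood), "missing", scored$expert_likelihood
  )
  scored$statistical_hit <- !is.na(scored$n_alerts) & scored$n_alerts >= 1
  scored$expert_hit <- !is.na(scored$expert_likelihood) &
    scored$expert_likelihood %in% positive_likelihoods()
  scored$score <- as.integer(scored$statistical_hit) +
    as.integer(scored$expert_hit)
  scored[order(scored$substance_id, scored$endpoint), ]
}

call_tibble <- function(product_id = character(), trigger = character(),
                        detail = list()) {
  tibble::tibble(
    product_id = product_id,
    trigger = trigger,
    detail_json = vapply(
      detail,
      function(d) {
        as.character(jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA))
      },
      character(1)
    )
  )
}

#' Flag products on organ-toxicity score and formulation content
#'
#' A product is called when it contains a co-formulant whose score for an
#' included endpoint is 2 and whose mass fraction strictly exceeds the
#' score-2 threshold (default 0.1%), or score 1 above the score-1 threshold
#' (default 10%). Nephrotoxicity is scored but excluded from the default
#' endpoint set because of the low sensitivity of the available
#' nephrotoxicity models; pass
#' `endpoints = c("hepatotoxicity", "nephrotoxicity")` to include it.
#'
#' @param scores tibble from [score_endpoints()].
#' @param composition tibble from [load_composition()].
#' @param registry tibble from [load_registry()]; only co-formulants are
#'   eligible.
#' @param thresholds named numeric, mass-fraction cut-offs per score
#'   (defaults `c("1" = 0.10, "2" = 0.001)`); comparisons are strict.
#' @param endpoints character vector of endpoints considered.
#' @return calls tibble (`product_id`, `trigger`, `detail_json`) with
#'   trigger `organ_tox_score2` or `organ_tox_score1`, one row per
#'   (product, co-formulant, endpoint).
#' @export
prioritise_organ_toxicity <- function(scores, composition, registry,
                                      thresholds = c("1" = 0.10, "2" = 0.001),
                                      endpoints = "hepatotoxicity") {
  cof <- registry$substance_id[registry$role == "co_formulant"]
  hits <- scores[
    scores$score > 0 & scores$endpoint %in% endpoints &
      scores$substance_id %in% cof,
  ]
  joined <- dplyr::inner_join(
    composition, hits[, c("substance_id", "endpoint", "score")],
    by = "substance_id", relationship = "many-to-many"
  )
  joined$threshold <- unname(thresholds[as.character(joined$score)])
  fired <- joined[joined$mass_fraction > joined$threshold, ]
  if (nrow(fired) == 0) {
    return(call_tibble())
  }
  fired <- fired[
    order(fired$product_id, fired$substance_id, fired$endpoint),
  ]
  call_tibble(
    product_id = fired$product_id,
    trigger = ifelse(fired$score == 2, "organ_tox_score2", "organ_tox_score1"),
    detail = lapply(seq_len(nrow(fired)), function(i) {
      list(
        substance_id = fired$substance_id[i],
        endpoint = fired$endpoint[i],
        score = fired$score[i],
        percent = fired$mass_fraction[i] * 100
      )
    })
  )
}

#' Flag products on in silico inhibitor-substrate pairing
#'
#' A product is called for a metabolic target (CYP isoenzyme or P-gp) when
#' it contains a co-formulant predicted as an in-scope inhibitor of that
#' target with confidence strictly above `conf_min`, present above
#' `frac_min` of the formulation, together with an active substance
#' predicted as an in-scope substrate of the same target above `conf_min`.
#' Out-of-scope predictions never qualify. One call per (product, target)
#' is emitted, listing every qualifying inhibitor-substrate pair.
#'
#' @param adme tibble from [load_adme()].
#' @param composition tibble from [load_composition()].
#' @param registry tibble from [load_registry()].
#' @param conf_min confidence cut-off (default 0.5, i.e. above 50%).
#' @param frac_min mass-fraction cut-off for the inhibitor co-formulant
#'   (default 0.001 = 0.1%).
#' @param substrate_ids optional character vector restricting the active
#'   substances considered as substrates (e.g. a hepatotoxic cumulative
#'   assessment group); default all active substances.
#' @return calls tibble with trigger `adme_pair`.
#' @export
prioritise_adme_pairs <- function(adme, composition, registry,
                                  conf_min = 0.5, frac_min = 0.001,
                                  substrate_ids = NULL) {
  roles <- setNames(registry$role, registry$substance_id)
  inh <- adme[
    adme$mode == "inhibitor" & adme$in_scope &
      !is.na(adme$confidence) & adme$confidence > conf_min &
      roles[adme$substance_id] == "co_formulant",
  ]
  sub <- adme[
    adme$mode == "substrate" & adme$in_scope &
      !is.na(adme$confidence) & adme$confidence > conf_min &
      roles[adme$substance_id] == "active_substance",
  ]
  if (!is.null(substrate_ids)) {
    sub <- sub[sub$substance_id %in% substrate_ids, ]
  }
  inh_in_prod <- dplyr::inner_join(
    composition, inh,
    by = "substance_id", relationship = "many-to-many"
  )
  inh_in_prod <- inh_in_prod[inh_in_prod$mass_fraction > frac_min, ]
  sub_in_prod <- dplyr::inner_join(
    composition[, c("product_id", "substance_id")], sub,
    by = "substance_id", relationship = "many-to-many"
  )
  pairs <- dplyr::inner_join(
    inh_in_prod, sub_in_prod,
    by = c("product_id", "target"),
    suffix = c("_inhibitor", "_substrate"),
    relationship = "many-to-many"
  )
  if (nrow(pairs) == 0) {
    return(call_tibble())
  }
  pairs <- pairs[order(
    pairs$product_id, pairs$target,
    pairs$substance_id_inhibitor, pairs$substance_id_substrate
  ), ]
  groups <- split(
    pairs, list(pairs$product_id, pairs$target),
    drop = TRUE, sep = "\r"
  )
  groups <- groups[order(names(groups))]
  call_tibble(
    product_id = vapply(groups, function(g) g$product_id[1], character(1)),
    trigger = rep("adme_pair", length(groups)),
    detail = lapply(groups, function(g) {
      list(
        target = g$target[1],
        pairs = lapply(seq_len(nrow(g)), function(i) {
          list(
            inhibitor = g$substance_id_inhibitor[i],
            inhibitor_confidence = g$confidence_inhibitor[i],
            inhibitor_percent = g$mass_fraction[i] * 100,
            substrate = g$substance_id_substrate[i],
            substrate_confidence = g$confidence_substrate[i]
          )
        })
      )
    })
  )
}

#' Sales-weighted co-formulant tonnage
#'
#' Per co-formulant, annual sales are product sales (kg) times the
#' co-formulant's mass fraction, summed over all products. Co-formulants
#' sharing a CAS number are treated as a single entry; substances without a
#' CAS aggregate under their substance id.
#'
#' @param products tibble from [load_products()].
#' @param composition tibble from [load_composition()].
#' @param registry tibble from [load_registry()].
#' @return tibble with `cas_key` (CAS when available, else substance id),
#'   `cas`, `name` (first seen) and `coformulant_sales_kg`, sorted by
#'   decreasing sales with ties broken by `cas_key`.
#' @export
compute_coformulant_sales <- function(products, composition, registry) {
  cof <- registry[registry$role == "co_formulant", ]
  contrib <- composition |>
    dplyr::inner_join(
      cof[, c("substance_id", "cas", "name")],
      by = "substance_id"
    ) |>
    dplyr::inner_join(products, by = "product_id")
  contrib$cas_key <- ifelse(
    is.na(contrib$cas), contrib$substance_id, contrib$cas
  )
  contrib$kg <- contrib$sales_kg * contrib$mass_fraction
  out <- contrib |>
    dplyr::group_by(.data$cas_key) |>
    dplyr::summarise(
      cas = .data$cas[1],
      name = .data$name[1],
      coformulant_sales_kg = sum(.data$kg),
      .groups = "drop"
    )
  out[order(-out$coformulant_sales_kg, out$cas_key), ]
}

#' Flag products containing a top-selling co-formulant
#'
#' Ranks co-formulants by sales-weighted tonnage (ties broken by CAS key in
#' lexicographic order) and calls every product containing one of the top
#' `n` above `frac_min`. One call per product, listing the qualifying
#' co-formulants with their sales rank.
#'
#' @param sales tibble from [compute_coformulant_sales()].
#' @param composition,registry as elsewhere.
#' @param n number of top co-formulants (default 10); larger than the list
#'   returns all.
#' @param frac_min mass-fraction cut-off (default 0: any positive content).
#' @return calls tibble with trigger `top_sales`.
#' @export
rank_top_sales <- function(sales, composition, registry, n = 10,
                           frac_min = 0) {
  stopifnot(n >= 1)
  ranked <- sales[order(-sales$coformulant_sales_kg, sales$cas_key), ]
  ranked$rank <- seq_len(nrow(ranked))
  top <- head(ranked, n)
  cof <- registry[registry$role == "co_formulant", ]
  cof$cas_key <- ifelse(is.na(cof$cas), cof$substance_id, cof$cas)
  members <- dplyr::inner_join(
    composition,
    cof[, c("substance_id", "cas_key")],
    by = "substance_id"
  )
  hits <- dplyr::inner_join(
    members, top[, c("cas_key", "rank", "coformulant_sales_kg")],
    by = "cas_key"
  )
  hits <- hits[hits$mass_fraction > frac_min, ]
  if (nrow(hits) == 0) {
    return(call_tibble())
  }
  hits <- hits[order(hits$product_id, hits$rank, hits$substance_id), ]
  groups <- split(hits, hits$product_id)
  call_tibble(
    product_id = names(groups),
    trigger = rep("top_sales", length(groups)),
    detail = lapply(groups, function(g) {
      list(coformulants = lapply(seq_len(nrow(g)), function(i) {
        list(
          substance_id = g$substance_id[i],
          cas_key = g$cas_key[i],
          rank = g$rank[i],
          percent = g$mass_fraction[i] * 100
        )
      }))
    })
  )
}

#' Merge priority calls from all triggers
#'
#' @param ... calls tibbles as produced by the `prioritise_*` and
#'   [rank_top_sales()] functions.
#' @return list with `calls` (concatenated tibble) and `summary` (tibble of
#'   unique product counts per trigger plus a `total_unique` row; a product
#'   with several triggers counts once in the total).
#' @export
merge_priorities <- function(...) {
  calls <- dplyr::bind_rows(...)
  if (nrow(calls) == 0) {
    return(list(
      calls = call_tibble(),
      summary = tibble::tibble(trigger = character(), n_products = integer())
    ))
  }
  per_trigger <- calls |>
    dplyr::group_by(.data$trigger) |>
    dplyr::summarise(
      n_products = dplyr::n_distinct(.data$product_id),
      .groups = "drop"
    )
  summary <- dplyr::bind_rows(
    per_trigger,
    tibble::tibble(
      trigger = "total_unique",
      n_products = dplyr::n_distinct(calls$product_id)
    )
  )
  list(calls = calls, summary = summary)
}
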