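# Seeded synthetic-data generators. The landscape generator emulates a
# national registry of formulated plant-protection products at realistic
# scale (~1600 products over ~1000 co-formulant entries) with known ground
# truth for every downstream stage: per-substance organ-toxicity labels for
# both prediction sources, ADME inhibitor/substrate calls with confidences,
# sales-weighted tonnage, and the product trigger sets the prioritisation
# rules should recover. Dose-response generators draw viability data from
# the exponential/Hill model families, with mixture synergy injected as a
# dose-potency multiplier s (>= 1) on the mixture's effective dose, so the
# expected model deviation ratio is exactly s.

#' Configuration of the synthetic formulation landscape
#'
#' Defaults mirror the scale of a national product registry: 1603 products,
#' 1048 co-formulant entries, 250 active substances, with roughly
#' two-thirds of co-formulants carrying a SMILES, some duplicated CAS
#' entries and some substance classes (polymers, mineral mixtures, plant
#' extracts) that have no discrete structure. Sales are log-normal with a
#' heavy right tail so a handful of co-formulants dominate tonnage.
#' Per-substance truth rates for the two organ-toxicity sources and the
#' ADME targets are set so that flagged fractions resemble what commercial
#' QSAR batteries report on such inventories (roughly 5-20% statistical
#' positives, a few percent expert positives, rare CYP inhibitors among
#' co-formulants but frequent substrates among active substances).
#'
#' @param n_products,n_coformulants,n_active_substances landscape size.
#' @param smiles_availability probability a (non-class) co-formulant has a
#'   SMILES.
#' @param duplicate_cas_rate fraction of co-formulant entries that repeat
#'   an earlier entry's CAS (duplicated registry rows).
#' @param class_rate fraction of co-formulant entries that are substance
#'   classes (no SMILES by construction).
#' @param sales_meanlog,sales_sdlog log-normal product sales parameters
#'   (log kg).
#' @param hepa_stat,hepa_expert,neph_stat,neph_expert per-substance truth
#'   rates of a positive call per source and endpoint.
#' @param inhibitor_rates,substrate_rates named per-target truth rates for
#'   co-formulant inhibitors / active-substance substrates.
#' @param seed integer; fully determines the landscape.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_products = 1603,
                             n_coformulants = 1048,
                             n_active_substances = 250,
                             smiles_availability = 0.65,
                             duplicate_cas_rate = 0.12,
                             class_rate = 0.15,
                             sales_meanlog = log(2000),
                             sales_sdlog = 1.5,
                             hepa_stat = 0.10, hepa_expert = 0.035,
                             neph_stat = 0.05, neph_expert = 0.08,
                             inhibitor_rates = c(
                               CYP1A2 = 0.015, CYP2C9 = 0.012,
                               CYP2C19 = 0.005, CYP2D6 = 0.002,
                               CYP3A4 = 0.006, P_gp = 0.04
                             ),
                             substrate_rates = c(
                               CYP1A2 = 0.11, CYP2C9 = 0.07,
                               CYP2C19 = 0.06, CYP2D6 = 0.015,
                               CYP3A4 = 0.12, P_gp = 0.20
                             ),
                             seed = 1L) {
  cfg <- list(
    n_products = n_products,
    n_coformulants = n_coformulants,
    n_active_substances = n_active_substances,
    smiles_availability = smiles_availability,
    duplicate_cas_rate = duplicate_cas_rate,
    class_rate = class_rate,
    sales_meanlog = sales_meanlog,
    sales_sdlog = sales_sdlog,
    hepa_stat = hepa_stat, hepa_expert = hepa_expert,
    neph_stat = neph_stat, neph_expert = neph_expert,
    inhibitor_rates = inhibitor_rates,
    substrate_rates = substrate_rates,
    seed = as.integer(seed)
  )
  fracs <- c(
    smiles_availability, duplicate_cas_rate, class_rate,
    hepa_stat, hepa_expert, neph_stat, neph_expert,
    inhibitor_rates, substrate_rates
  )
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("config error: all rates must be fractions in [0, 1]",
      call. = FALSE
    )
  }
  if (any(c(n_products, n_coformulants, n_active_substances) < 0) ||
    n_coformulants + n_active_substances == 0) {
    stop("config error: landscape counts must be non-negative and the ",
      "registry non-empty",
      call. = FALSE
    )
  }
  structure(cfg, class = "landscape_config")
}

# random syntactically valid CAS numbers (correct checksum), unique
gen_cas <- function(n) {
  body <- sprintf(
    "%d%02d",
    sample(100:9999999, n, replace = FALSE), sample(0:99, n, replace = TRUE)
  )
  vapply(body, function(b) {
    digits <- as.integer(strsplit(b, "")[[1]])
    chk <- sum(rev(digits) * seq_along(digits)) %% 10
    paste0(
      substr(b, 1, nchar(b) - 2), "-", substr(b, nchar(b) - 1, nchar(b)),
      "-", chk
    )
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a ground-truth-labelled formulation landscape
#'
#' Produces a substance registry, product sales, product compositions and a
#' truth bundle recording every latent label plus the product trigger sets
#' that the prioritisation rules (at their default thresholds) should
#' emit. Composition fractions are drawn log-uniformly so co-formulant
#' content straddles the 0.1% and 10% decision thresholds; per product the
#' fractions always sum to at most 1.
#'
#' @param config a [landscape_config()].
#' @return list with `registry`, `products`, `composition` (tibbles as the
#'   loaders return) and `truth` (list: `substances`, `adme`, `sales`,
#'   `triggers`, `config`).
#' @export
gen_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  withr::with_seed(config$seed, gen_landscape_impl(config))
}

gen_landscape_impl <- function(cfg) {
  n_as <- cfg$n_active_substances
  n_cf <- cfg$n_coformulants
  as_ids <- sprintf("AS%04d", seq_len(n_as))
  cf_ids <- sprintf("CF%04d", seq_len(n_cf))

  # CAS assignment: a duplicate entry reuses an earlier co-formulant CAS
  cas_pool <- gen_cas(n_as + n_cf)
  as_cas <- cas_pool[seq_len(n_as)]
  cf_cas <- cas_pool[n_as + seq_len(n_cf)]
  if (n_cf > 1) {
    dup <- runif(n_cf) < cfg$duplicate_cas_rate
    dup[1] <- FALSE
    for (i in which(dup)) {
      cf_cas[i] <- cf_cas[sample.int(i - 1, 1)]
    }
  }
  is_class <- runif(n_cf) < cfg$class_rate
  has_smiles <- !is_class & runif(n_cf) < cfg$smiles_availability
  # SMILES strings are opaque identifiers here; duplicated CAS entries
  # share a structure
  smiles_for <- paste0("C", gsub("-", "", cf_cas))
  cf_smiles <- ifelse(has_smiles, smiles_for, NA_character_)

  registry <- tibble::tibble(
    substance_id = c(as_ids, cf_ids),
    cas = c(as_cas, cf_cas),
    name = c(
      sprintf("active substance %04d", seq_len(n_as)),
      sprintf("co-formulant %04d", seq_len(n_cf))
    ),
    smiles = c(paste0("A", gsub("-", "", as_cas)), cf_smiles),
    role = c(
      rep("active_substance", n_as), rep("co_formulant", n_cf)
    ),
    is_class = c(rep(FALSE, n_as), is_class)
  )

  products <- tibble::tibble(
    product_id = sprintf("P%04d", seq_len(cfg$n_products)),
    sales_kg = rlnorm(cfg$n_products, cfg$sales_meanlog, cfg$sales_sdlog)
  )

  # composition: 1-2 active substances at 5-50%, 2-6 co-formulants with
  # log-uniform fractions from 0.02% to 40%, rescaled if the product
  # would exceed 100%
  comp <- vector("list", cfg$n_products)
  for (i in seq_len(cfg$n_products)) {
    k_as <- sample(1:2, 1)
    k_cf <- sample(2:6, 1)
    f_as <- runif(k_as, 0.05, 0.5) / k_as
    f_cf <- exp(runif(k_cf, log(2e-4), log(0.4)))
    avail <- 1 - sum(f_as)
    if (sum(f_cf) > avail) {
      f_cf <- f_cf * avail / sum(f_cf)
    }
    comp[[i]] <- tibble::tibble(
      product_id = products$product_id[i],
      substance_id = c(
        sample(as_ids, k_as),
        if (n_cf >= k_cf) sample(cf_ids, k_cf) else character(0)
      ),
      mass_fraction = c(f_as, if (n_cf >= k_cf) f_cf else numeric(0))
    )
  }
  composition <- dplyr::bind_rows(c(
    list(tibble::tibble(
      product_id = character(), substance_id = character(),
      mass_fraction = numeric()
    )),
    comp
  ))

  # per-substance truth labels for the two organ-toxicity sources
  substances <- tibble::tibble(
    substance_id = cf_ids,
    hepa_stat = runif(n_cf) < cfg$hepa_stat,
    hepa_expert = runif(n_cf) < cfg$hepa_expert,
    neph_stat = runif(n_cf) < cfg$neph_stat,
    neph_expert = runif(n_cf) < cfg$neph_expert
  )

  # ADME truth: drawn in-scope flags and confidences ARE the prediction
  # table; the trigger bookkeeping below uses the drawn values
  adme_rows <- list()
  for (target in names(cfg$inhibitor_rates)) {
    hit <- runif(n_cf) < cfg$inhibitor_rates[[target]]
    neg <- !hit & runif(n_cf) < 0.05
    idx <- which(hit | neg)
    if (length(idx) > 0) {
      in_scope <- runif(length(idx)) < 0.95
      conf <- ifelse(
        hit[idx], runif(length(idx), 0.55, 0.99),
        runif(length(idx), 0.05, 0.45)
      )
      adme_rows[[paste0("inh_", target)]] <- tibble::tibble(
        substance_id = cf_ids[idx], target = target, mode = "inhibitor",
        in_scope = in_scope,
        confidence = ifelse(in_scope, conf, NA_real_)
      )
    }
    s_hit <- runif(n_as) < cfg$substrate_rates[[target]]
    s_neg <- !s_hit & runif(n_as) < 0.05
    s_idx <- which(s_hit | s_neg)
    if (length(s_idx) > 0) {
      s_scope <- runif(length(s_idx)) < 0.95
      s_conf <- ifelse(
        s_hit[s_idx], runif(length(s_idx), 0.55, 0.99),
        runif(length(s_idx), 0.05, 0.45)
      )
      adme_rows[[paste0("sub_", target)]] <- tibble::tibble(
        substance_id = as_ids[s_idx], target = target, mode = "substrate",
        in_scope = s_scope,
        confidence = ifelse(s_scope, s_conf, NA_real_)
      )
    }
  }
  adme <- dplyr::bind_rows(adme_rows)
  adme <- adme[order(adme$substance_id, adme$target, adme$mode), ]

  truth <- list(
    substances = substances,
    adme = adme,
    config = cfg
  )
  truth$sales <- truth_sales(products, composition, registry)
  truth$triggers <- truth_triggers(
    registry, products, composition, substances, adme, truth$sales
  )
  list(
    registry = registry, products = products, composition = composition,
    truth = truth
  )
}

# straight-line bookkeeping of the trigger sets implied by the truth
# labels at the default rule parameters (hepatotoxicity endpoint only,
# thresholds 0.1% / 10%, confidence > 0.5, inhibitor content > 0.1%,
# top-10 sales)
truth_triggers <- function(registry, products, composition, substances,
                           adme, sales) {
  cof <- registry$substance_id[registry$role == "co_formulant"]
  score <- setNames(
    as.integer(substances$hepa_stat) + as.integer(substances$hepa_expert),
    substances$substance_id
  )
  comp_cf <- composition[composition$substance_id %in% cof, ]
  s <- score[comp_cf$substance_id]
  s[is.na(s)] <- 0L
  score2 <- unique(comp_cf$product_id[s == 2L & comp_cf$mass_fraction > 0.001])
  score1 <- unique(comp_cf$product_id[s == 1L & comp_cf$mass_fraction > 0.10])

  q_inh <- adme[
    adme$mode == "inhibitor" & adme$in_scope &
      !is.na(adme$confidence) & adme$confidence > 0.5,
  ]
  q_sub <- adme[
    adme$mode == "substrate" & adme$in_scope &
      !is.na(adme$confidence) & adme$confidence > 0.5,
  ]
  adme_products <- character(0)
  for (target in unique(adme$target)) {
    inh_ids <- q_inh$substance_id[q_inh$target == target]
    sub_ids <- q_sub$substance_id[q_sub$target == target]
    p_inh <- unique(composition$product_id[
      composition$substance_id %in% inh_ids & composition$mass_fraction > 0.001
    ])
    p_sub <- unique(composition$product_id[
      composition$substance_id %in% sub_ids
    ])
    adme_products <- union(adme_products, intersect(p_inh, p_sub))
  }

  top_keys <- head(sales$cas_key, 10)
  cof_tbl <- registry[registry$role == "co_formulant", ]
  key <- ifelse(is.na(cof_tbl$cas), cof_tbl$substance_id, cof_tbl$cas)
  top_ids <- cof_tbl$substance_id[key %in% top_keys]
  top_products <- unique(composition$product_id[
    composition$substance_id %in% top_ids & composition$mass_fraction > 0
  ])

  trig <- list(
    organ_tox_score2 = sort(score2),
    organ_tox_score1 = sort(score1),
    adme_pair = sort(adme_products),
    top_sales = sort(top_products)
  )
  trig$all <- sort(Reduce(union, trig))
  trig
}

truth_sales <- function(products, composition, registry) {
  cof <- registry[registry$role == "co_formulant", ]
  key <- setNames(
    ifelse(is.na(cof$cas), cof$substance_id, cof$cas), cof$substance_id
  )
  rows <- composition[composition$substance_id %in% cof$substance_id, ]
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      cas_key = character(), coformulant_sales_kg = numeric()
    ))
  }
  sales_kg <- setNames(products$sales_kg, products$product_id)
  kg <- sales_kg[rows$product_id] * rows$mass_fraction
  agg <- tapply(kg, key[rows$substance_id], sum)
  out <- tibble::tibble(
    cas_key = as.character(names(agg)), coformulant_sales_kg = as.numeric(agg)
  )
  out[order(-out$coformulant_sales_kg, out$cas_key), ]
}

#' Generate prediction tables from landscape truth
#'
#' Emits the statistical-alert, expert-likelihood and ADME tables a QSAR /
#' ADME battery would produce on the landscape. Statistical and expert
#' sources are imperfect observers of the truth labels with configurable
#' sensitivity and specificity (at 1/1 the tables encode the truth
#' exactly); a flagged substance receives one or more positive sub-model
#' alerts, respectively a likelihood level drawn from the positive
#' vocabulary. The ADME table is the truth bundle's drawn table itself
#' (confidences and applicability-domain flags were drawn at landscape
#' generation).
#'
#' @param truth the `truth` element of [gen_landscape()]'s result.
#' @param sensitivity,specificity named numeric with elements `stat` and
#'   `expert`, each in \[0, 1\].
#' @param seed integer seed for the observation noise.
#' @return list with `stat_alerts`, `expert_calls`, `adme` tibbles.
#' @export
gen_prediction_tables <- function(truth,
                                  sensitivity = c(stat = 1, expert = 1),
                                  specificity = c(stat = 1, expert = 1),
                                  seed = 1L) {
  rates <- c(sensitivity, specificity)
  if (any(rates < 0) || any(rates > 1)) {
    stop("sensitivity and specificity must be fractions in [0, 1]",
      call. = FALSE
    )
  }
  withr::with_seed(seed, {
    subs <- truth$substances
    n <- nrow(subs)
    endpoints <- list(
      hepatotoxicity = list(
        stat = subs$hepa_stat, expert = subs$hepa_expert, n_submodels = 4
      ),
      nephrotoxicity = list(
        stat = subs$neph_stat, expert = subs$neph_expert, n_submodels = 6
      )
    )
    stat_rows <- list()
    expert_rows <- list()
    neg_levels <- setdiff(likelihood_levels(), positive_likelihoods())
    for (ep in names(endpoints)) {
      e <- endpoints[[ep]]
      flag_stat <- ifelse(
        e$stat, runif(n) < sensitivity[["stat"]],
        runif(n) < 1 - specificity[["stat"]]
      )
      n_pos <- ifelse(
        flag_stat, 1L + rbinom(n, e$n_submodels - 1L, 0.3), 0L
      )
      alert_mat <- t(vapply(seq_len(n), function(i) {
        a <- rep(0L, e$n_submodels)
        if (n_pos[i] > 0) {
          a[sample.int(e$n_submodels, n_pos[i])] <- 1L
        }
        a
      }, integer(e$n_submodels)))
      stat_rows[[ep]] <- tibble::tibble(
        substance_id = rep(subs$substance_id, each = e$n_submodels),
        endpoint = ep,
        submodel = rep(
          paste0(ep, "_sub", seq_len(e$n_submodels)), n
        ),
        alert = as.integer(t(alert_mat))
      )
      flag_exp <- ifelse(
        e$expert, runif(n) < sensitivity[["expert"]],
        runif(n) < 1 - specificity[["expert"]]
      )
      expert_rows[[ep]] <- tibble::tibble(
        substance_id = subs$substance_id,
        endpoint = ep,
        likelihood = ifelse(
          flag_exp,
          sample(positive_likelihoods(), n,
            replace = TRUE, prob = c(0.05, 0.15, 0.5, 0.3)
          ),
          sample(neg_levels, n,
            replace = TRUE, prob = c(0.05, 0.1, 0.02, 0.23, 0.6)
          )
        )
      )
    }
    list(
      stat_alerts = dplyr::bind_rows(stat_rows),
      expert_calls = dplyr::bind_rows(expert_rows),
      adme = truth$adme
    )
  })
}

#' Default cytotoxicity dose design
#'
#' Eight two-fold serial dilutions from a 300 mg/L top concentration, the
#' usual design for a 96-well viability assay.
#'
#' @param top highest concentration (mg/L).
#' @param n number of concentrations.
#' @return numeric vector, increasing.
#' @export
default_doses <- function(top = 300, n = 8) {
  top * 0.5^((n - 1):0)
}

#' Generate single-substance dose-response data
#'
#' Draws viability responses from an exponential or Hill curve with
#' additive Gaussian noise, plus zero-dose solvent controls, in the long
#' format of [load_dose_response()]. Negative draws are truncated at 0 (a
#' viability readout cannot be negative).
#'
#' @param params named (a, b, c, d) true parameters.
#' @param model `"exponential"` or `"hill"`.
#' @param doses positive concentrations (mg/L).
#' @param reps technical replicates per concentration.
#' @param noise_sd Gaussian noise standard deviation (% viability).
#' @param seed integer seed.
#' @param treatment treatment label.
#' @param controls number of zero-dose control wells (default `reps`).
#' @return tibble `treatment, conc_mg_L, response_pct, replicate`.
#' @export
gen_dose_response <- function(params, model = "exponential",
                              doses = default_doses(), reps = 3,
                              noise_sd = 5, seed = 1L, treatment = "T",
                              controls = reps) {
  stopifnot(all(doses > 0), reps >= 1)
  fun <- ca_model_fun(model)
  p <- as.list(params)
  withr::with_seed(seed, {
    conc <- c(rep(0, controls), rep(doses, each = reps))
    mu <- fun(conc, p$a, p$b, p$c, p$d)
    y <- pmax(0, mu + rnorm(length(conc), 0, noise_sd))
    tibble::tibble(
      treatment = treatment,
      conc_mg_L = conc,
      response_pct = y,
      replicate = as.character(c(
        seq_len(controls), rep(seq_len(reps), times = length(doses))
      ))
    )
  })
}

#' Generate mixture dose-response data with controllable synergy
#'
#' Components must share (a, c, d); the mixture dosed at total
#' concentration D responds as the shared-shape curve with potency scale
#' `b_mix = 1 / sum(pi_i / b_i)` evaluated at the effective dose `s * D`.
#' The multiplier `s >= 1` is a toxicokinetic-interaction stand-in (e.g.
#' CYP inhibition raising internal exposure): `s = 1` reproduces exact
#' dose addition, and the observed EC50 is the additive EC50 divided by
#' `s`, so the model deviation ratio of a noiseless dataset is exactly
#' `s`.
#'
#' @param component_b named numeric, per-component potency scales b_i.
#' @param shared named (a, c, d) shared parameters.
#' @param fractions named mass fractions (same names as `component_b`),
#'   summing to 1.
#' @param synergy_s potency multiplier s >= 1 (s = 1: additive).
#' @param model,doses,reps,noise_sd,seed,treatment,controls as in
#'   [gen_dose_response()].
#' @return tibble `treatment, conc_mg_L, response_pct, replicate`.
#' @export
gen_mixture_response <- function(component_b, shared, fractions,
                                 synergy_s = 1, model = "exponential",
                                 doses = default_doses(), reps = 3,
                                 noise_sd = 5, seed = 1L,
                                 treatment = "mixture", controls = reps) {
  stopifnot(synergy_s > 0)
  if (is.null(names(fractions)) ||
    !all(names(fractions) %in% names(component_b))) {
    stop("fractions must be named by component", call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  b_mix <- 1 / sum(fractions / component_b[names(fractions)])
  p <- as.list(shared)
  gen_dose_response(
    params = c(a = p$a, b = b_mix / synergy_s, c = p$c, d = p$d),
    model = model, doses = doses, reps = reps, noise_sd = noise_sd,
    seed = seed, treatment = treatment, controls = controls
  )
}
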