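# Run orchestration behind the command-line tool: a single YAML config with
# documented defaults, three stages (simulate, prioritise, mixture), a run
# report reconciling record counts, and deterministic outputs.

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults:
#' \describe{
#'   \item{thresholds.score2 / thresholds.score1}{organ-toxicity content
#'     cut-offs as mass fractions (0.001 = 0.1%, 0.10 = 10%).}
#'   \item{endpoints_included}{endpoints driving organ-toxicity calls
#'     (default hepatotoxicity only).}
#'   \item{conf_min}{ADME confidence cut-off (0.5).}
#'   \item{frac_min}{content cut-off for inhibitor co-formulants (0.001).}
#'   \item{top_n_sales}{number of top-selling co-formulants (10).}
#'   \item{sales_frac_min}{content cut-off for the sales trigger (0).}
#'   \item{mdr_threshold}{fold-change calling synergy/antagonism (2).}
#'   \item{seed}{random seed for the simulate stage.}
#' }
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(
    registry = "registry.csv",
    products = "products.csv",
    composition = "composition.csv",
    stat_alerts = "stat_alerts.csv",
    expert_calls = "expert_calls.csv",
    adme = "adme.csv",
    doseresponse = "doseresponse.csv",
    mixtures = list(),
    thresholds = list(score1 = 0.10, score2 = 0.001),
    endpoints_included = "hepatotoxicity",
    conf_min = 0.5,
    frac_min = 0.001,
    top_n_sales = 10,
    sales_frac_min = 0,
    mdr_threshold = 2,
    model = "exponential",
    seed = 1
  )
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it over [default_run_config()]. Unknown
#' top-level keys are rejected so typos cannot silently fall back to a
#' default.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied last (e.g. CLI flags).
#' @return resolved config list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("config error: unknown key(s) ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  cfg[names(user)] <- user
  unknown2 <- setdiff(names(overrides), names(cfg))
  if (length(unknown2) > 0) {
    stop("config error: unknown key(s) ", paste(unknown2, collapse = ", "),
      call. = FALSE
    )
  }
  cfg[names(overrides)] <- overrides
  for (key in c(
    "conf_min", "frac_min", "sales_frac_min"
  )) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("config error: ", key, " must be a fraction in [0, 1]",
        call. = FALSE
      )
    }
  }
  if (!is.numeric(cfg$mdr_threshold) || cfg$mdr_threshold <= 1) {
    stop("config error: mdr_threshold must exceed 1", call. = FALSE)
  }
  cfg
}

write_manifest <- function(out_dir, files, extra = list()) {
  manifest <- c(
    list(
      tool = "mixtriage",
      version = as.character(utils::packageVersion("mixtriage")),
      files = lapply(files, function(f) {
        list(file = f, rows = nrow(readr::read_csv(
          file.path(out_dir, f),
          show_col_types = FALSE, progress = FALSE
        )))
      })
    ),
    extra
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
}

#' Simulate a complete fixture bundle
#'
#' Generates a ground-truth-labelled landscape plus prediction tables and
#' writes every input CSV the prioritise stage consumes, along with
#' `truth.json` and a manifest, into `out_dir`.
#'
#' @param config resolved config list (uses `seed`).
#' @param out_dir output directory (created if missing).
#' @param landscape_cfg optional [landscape_config()]; default uses
#'   `config$seed`.
#' @return invisibly, the landscape list.
#' @export
run_simulate <- function(config = default_run_config(), out_dir,
                         landscape_cfg = NULL) {
  if (is.null(landscape_cfg)) {
    landscape_cfg <- landscape_config(seed = config$seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  land <- gen_landscape(landscape_cfg)
  preds <- gen_prediction_tables(land$truth, seed = config$seed)
  readr::write_csv(land$registry, file.path(out_dir, "registry.csv"))
  readr::write_csv(land$products, file.path(out_dir, "products.csv"))
  write_composition(land$composition, file.path(out_dir, "composition.csv"))
  readr::write_csv(preds$stat_alerts, file.path(out_dir, "stat_alerts.csv"))
  readr::write_csv(preds$expert_calls, file.path(out_dir, "expert_calls.csv"))
  readr::write_csv(preds$adme, file.path(out_dir, "adme.csv"))
  jsonlite::write_json(
    list(
      triggers = land$truth$triggers,
      sales_top10 = head(land$truth$sales, 10)
    ),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(out_dir, c(
    "registry.csv", "products.csv", "composition.csv",
    "stat_alerts.csv", "expert_calls.csv", "adme.csv"
  ), extra = list(seed = landscape_cfg$seed))
  invisible(land)
}

#' Run the prioritisation pipeline
#'
#' Loads the input tables named in the config (relative paths are resolved
#' against `in_dir`), runs scoring, organ-toxicity thresholds, ADME
#' pairing, sales ranking and the merge, and writes
#' `priority_report.csv`, `coformulant_sales.csv` and `run_report.json`
#' to `out_dir`.
#'
#' @param config resolved config list.
#' @param in_dir directory holding the input CSVs.
#' @param out_dir output directory.
#' @return invisibly, the [merge_priorities()] result.
#' @export
run_prioritise <- function(config, in_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(key) {
    p <- config[[key]]
    if (file.exists(p)) p else file.path(in_dir, p)
  }
  registry <- load_registry(path("registry"))
  products <- load_products(path("products"))
  composition <- load_composition(path("composition"))
  stat_alerts <- load_stat_alerts(path("stat_alerts"))
  expert_calls <- load_expert_calls(path("expert_calls"))
  adme <- load_adme(path("adme"))

  scores <- score_endpoints(stat_alerts, expert_calls)
  thresholds <- c(
    "1" = config$thresholds$score1, "2" = config$thresholds$score2
  )
  organ <- prioritise_organ_toxicity(
    scores, composition, registry,
    thresholds = thresholds, endpoints = config$endpoints_included
  )
  adme_calls <- prioritise_adme_pairs(
    adme, composition, registry,
    conf_min = config$conf_min, frac_min = config$frac_min
  )
  sales <- compute_coformulant_sales(products, composition, registry)
  sales_calls <- rank_top_sales(
    sales, composition, registry,
    n = config$top_n_sales, frac_min = config$sales_frac_min
  )
  merged <- merge_priorities(organ, adme_calls, sales_calls)

  write_priority_report(
    merged$calls, file.path(out_dir, "priority_report.csv")
  )
  readr::write_csv(sales, file.path(out_dir, "coformulant_sales.csv"))
  report <- list(
    tool = "mixtriage",
    version = as.character(utils::packageVersion("mixtriage")),
    config = config[c(
      "thresholds", "endpoints_included", "conf_min", "frac_min",
      "top_n_sales", "sales_frac_min"
    )],
    counts = list(
      products = nrow(products),
      substances = nrow(registry),
      composition_rows = nrow(composition),
      priority_calls = nrow(merged$calls)
    ),
    summary = merged$summary
  )
  jsonlite::write_json(
    report, file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(merged)
}

#' Run the mixture dose-addition stage
#'
#' For every mixture in `config$mixtures` (a named list; each element has
#' `components`, a named list of mass fractions, and the mixture's own
#' treatment label as its name), fits all components jointly with shared
#' shape, builds the theoretical dose-addition curve, fits the observed
#' mixture data and classifies the deviation. Mixtures whose 50% level is
#' unreachable are skipped with a logged reason. Writes `fits.csv`,
#' `ca_calls.csv` and `run_report.json`.
#'
#' @param config resolved config list.
#' @param in_dir directory holding `doseresponse.csv`.
#' @param out_dir output directory.
#' @return invisibly, the `ca_calls` tibble.
#' @export
run_mixture <- function(config, in_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$doseresponse
  dr <- load_dose_response(if (file.exists(p)) p else file.path(in_dir, p))
  if (length(config$mixtures) == 0) {
    stop("config error: mixtures must name at least one mixture with its ",
      "component fractions",
      call. = FALSE
    )
  }
  all_fits <- list()
  calls <- list()
  skipped <- list()
  for (mix_label in names(config$mixtures)) {
    fractions <- unlist(config$mixtures[[mix_label]]$components)
    comp_data <- dr[dr$treatment %in% names(fractions), ]
    mix_data <- dr[dr$treatment == mix_label, ]
    par_fit <- fit_parallel_components(comp_data, model = config$model)
    pred <- ca_mixture_curve(par_fit, fractions)
    mix_fit <- select_model_aic(list(
      fit_model(mix_data, "exponential"), fit_model(mix_data, "hill")
    ))
    all_fits[[mix_label]] <- mix_fit
    if (is.na(pred$ec50_predicted) || is.na(mix_fit$ec50)) {
      skipped[[mix_label]] <- "50%-of-control level unreachable"
      next
    }
    done <- classify_deviation(mix_fit, pred, config$mdr_threshold)
    calls[[mix_label]] <- tibble::tibble(
      mixture = mix_label,
      ec50_pred = done$ec50_predicted,
      ec50_obs = done$ec50_observed,
      mdr = done$mdr,
      call = done$call
    )
  }
  ca_calls <- dplyr::bind_rows(calls)
  readr::write_csv(fits_table(all_fits), file.path(out_dir, "fits.csv"))
  readr::write_csv(ca_calls, file.path(out_dir, "ca_calls.csv"))
  jsonlite::write_json(
    list(
      tool = "mixtriage",
      version = as.character(utils::packageVersion("mixtriage")),
      config = config[c("mdr_threshold", "model")],
      counts = list(
        observations = nrow(dr),
        mixtures = length(config$mixtures),
        calls = nrow(ca_calls)
      ),
      skipped = skipped
    ),
    file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(ca_calls)
}
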