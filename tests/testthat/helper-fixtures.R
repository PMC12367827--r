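# Hand-built fixtures used across tests.

# A 20-product toy landscape whose priority calls are worked out by hand
# in test-prioritise.R and test-acceptance.R. All CAS numbers are real and
# checksum-valid. Percentages (file dialect) are converted to fractions by
# the loaders; builders here return the in-memory representation directly.
toy_registry <- function() {
  tibble::tibble(
    substance_id = c("A1", "A2", "C1", "C2", "C3", "C4", "C5"),
    cas = c(
      "107534-96-3", "178928-70-6", "14433-76-2", "57-55-6",
      "7732-18-5", "67-64-1", "108-88-3"
    ),
    name = c(
      "tebuconazole", "prothioconazole", "N,N-Dimethyldecan-1-amide",
      "propane-1,2-diol", "water", "acetone", "toluene"
    ),
    smiles = c("CC1", "CC2", "S1", "S2", NA, "S4", "S5"),
    role = c(
      "active_substance", "active_substance", rep("co_formulant", 5)
    ),
    is_class = FALSE
  )
}

toy_products <- function() {
  tibble::tibble(
    product_id = sprintf("P%02d", 1:20),
    sales_kg = c(1000, 2000, 500, 1000, 800, 600, 1000, 400, rep(100, 12))
  )
}

# composition as percent triples (product, substance, percent)
toy_composition <- function() {
  filler <- do.call(rbind, lapply(9:20, function(i) {
    data.frame(
      product_id = sprintf("P%02d", i),
      substance_id = c("A1", "C3", "C2"),
      percent = c(10, 50, 2)
    )
  }))
  df <- rbind(
    data.frame(
      product_id = c(
        "P01", "P01", "P01", "P02", "P02", "P03", "P03", "P04", "P04",
        "P05", "P05", "P06", "P06", "P07", "P07", "P07", "P08", "P08"
      ),
      substance_id = c(
        "A1", "C1", "C3", "A1", "C1", "A2", "C2", "A2", "C2",
        "A1", "C4", "A2", "C5", "A1", "C1", "C2", "A2", "C1"
      ),
      percent = c(
        10, 0.5, 80, 10, 0.05, 20, 12, 20, 5,
        5, 15, 10, 20, 10, 0.2, 11, 10, 0.5
      )
    ),
    filler
  )
  tibble::tibble(
    product_id = df$product_id,
    substance_id = df$substance_id,
    mass_fraction = df$percent / 100
  )
}

toy_stat_alerts <- function() {
  tibble::tibble(
    substance_id = c("C1", "C1", "C1", "C1", "C2", "C2", "C5"),
    endpoint = c(rep("hepatotoxicity", 6), "nephrotoxicity"),
    submodel = c("h1", "h2", "h3", "h4", "h1", "h2", "n1"),
    alert = c(1L, 1L, 0L, 0L, 1L, 0L, 1L)
  )
}

toy_expert_calls <- function() {
  tibble::tibble(
    substance_id = c("C1", "C2", "C4", "C5"),
    endpoint = c(
      "hepatotoxicity", "hepatotoxicity", "hepatotoxicity", "nephrotoxicity"
    ),
    likelihood = c("plausible", "improbable", "equivocal", "probable")
  )
}

toy_adme <- function() {
  # C4's P-gp inhibition sits below the 50% confidence cut-off and C5's
  # CYP3A4 inhibition is out of scope, so neither pairs at defaults even
  # though A1 / A2 are qualifying substrates of those targets
  tibble::tibble(
    substance_id = c("C1", "C4", "C5", "A1", "A1", "A2", "A2"),
    target = c(
      "CYP2C19", "P_gp", "CYP3A4", "CYP2C19", "P_gp", "CYP2C19", "CYP3A4"
    ),
    mode = c(rep("inhibitor", 3), rep("substrate", 4)),
    in_scope = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    confidence = c(0.8, 0.4, NA, 0.6, 0.9, 0.55, 0.9)
  )
}

# hand computation of the toy priority calls at default thresholds with
# hepatotoxicity only and top_n = 2 for the sales trigger:
# C1 score 2 (two stat alerts + "plausible"), C2 score 1 (one alert,
# expert negative), C4 score 1 (expert "equivocal" only); C5 scores only
# on nephrotoxicity, which is excluded. Co-formulant sales (kg):
# C3 1400, C2 244, C5 120, C4 120 (tie broken C5 first: "108-88-3" sorts
# before "67-64-1"), C1 10.
toy_expected <- function() {
  list(
    organ_tox_score2 = c("P01", "P07", "P08"),
    organ_tox_score1 = c("P03", "P05", "P07"),
    adme_pair = c("P01", "P07", "P08"),
    top_sales = sort(c("P01", "P03", "P04", "P07", sprintf("P%02d", 9:20))),
    sales_kg = c(
      "7732-18-5" = 1400, "57-55-6" = 244, "108-88-3" = 120,
      "67-64-1" = 120, "14433-76-2" = 10
    )
  )
}

write_toy_bundle <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(toy_registry(), file.path(dir, "registry.csv"))
  readr::write_csv(toy_products(), file.path(dir, "products.csv"))
  write_composition(toy_composition(), file.path(dir, "composition.csv"))
  readr::write_csv(toy_stat_alerts(), file.path(dir, "stat_alerts.csv"))
  readr::write_csv(toy_expert_calls(), file.path(dir, "expert_calls.csv"))
  readr::write_csv(toy_adme(), file.path(dir, "adme.csv"))
  dir
}

call_tibble_for_test <- function(product_ids, trigger) {
  tibble::tibble(
    product_id = product_ids, trigger = trigger, detail_json = "{}"
  )
}

# trigger sets actually emitted by the engine, as sorted unique ids
calls_by_trigger <- function(calls) {
  lapply(
    split(calls$product_id, calls$trigger),
    function(x) sort(unique(x))
  )
}
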