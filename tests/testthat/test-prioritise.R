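# Rule engine: two-source scoring, content thresholds, inhibitor-substrate
# pairing, sales aggregation and the merged priority list.

test_that("score_endpoint matches exhaustive truth-table enumeration", {
  # independent oracle: the stated rule, written out directly
  for (alerts in 0:6) {
    for (level in c(likelihood_levels(), NA)) {
      expected_stat <- alerts >= 1
      expected_exp <- !is.na(level) &&
        level %in% c("certain", "probable", "plausible", "equivocal")
      got <- score_endpoint(alerts, level)
      expect_identical(got$statistical_hit, expected_stat)
      expect_identical(got$expert_hit, expected_exp)
      expect_identical(got$score, as.integer(expected_stat) +
        as.integer(expected_exp))
    }
  }
  # missing statistical source contributes 0
  expect_equal(score_endpoint(NA, "plausible")$score, 1L)
  # binary sub-model vector accepted
  expect_equal(score_endpoint(c(0, 1, 1, 0), "equivocal")$score, 2L)
  expect_error(score_endpoint(1, "likely"), "unknown likelihood")
})

test_that("score_endpoints aggregates sub-models and keeps the strongest expert call", {
  scores <- score_endpoints(toy_stat_alerts(), toy_expert_calls())
  hep <- scores[scores$endpoint == "hepatotoxicity", ]
  expect_equal(
    setNames(hep$score, hep$substance_id),
    c(C1 = 2L, C2 = 1L, C4 = 1L)
  )
  # several expert rows -> max likelihood wins
  multi <- tibble::tibble(
    substance_id = "X", endpoint = "hepatotoxicity",
    likelihood = c("nothing_to_report", "equivocal", "improbable")
  )
  s <- score_endpoints(toy_stat_alerts()[0, ], multi)
  expect_equal(s$expert_likelihood, "equivocal")
  expect_equal(s$score, 1L)
  # expert_status distinguishes a missing prediction from nothing_to_report
  ntr <- tibble::tibble(
    substance_id = "Y", endpoint = "hepatotoxicity",
    likelihood = "nothing_to_report"
  )
  stat1 <- tibble::tibble(
    substance_id = c("Y", "Z"), endpoint = "hepatotoxicity",
    submodel = "h1", alert = 1L
  )
  s2 <- score_endpoints(stat1, ntr)
  expect_equal(
    setNames(s2$expert_status, s2$substance_id),
    c(Y = "nothing_to_report", Z = "missing")
  )
  expect_equal(s2$score, c(1L, 1L))
})

test_that("organ-toxicity thresholds are strict and score-dependent", {
  scores <- score_endpoints(toy_stat_alerts(), toy_expert_calls())
  calls <- prioritise_organ_toxicity(
    scores, toy_composition(), toy_registry()
  )
  got <- calls_by_trigger(calls)
  expect_equal(got$organ_tox_score2, c("P01", "P07", "P08"))
  expect_equal(got$organ_tox_score1, c("P03", "P05", "P07"))
  # P02: score-2 co-formulant at exactly 0.05% (= below 0.1%): no call
  expect_false("P02" %in% calls$product_id)
  # P04: score 1 at 5% <= 10%: no call
  expect_false("P04" %in% calls$product_id)
  # a fraction exactly at the threshold does not fire (strict >)
  comp <- tibble::tibble(
    product_id = "Q1", substance_id = c("A1", "C2"),
    mass_fraction = c(0.2, 0.10)
  )
  expect_equal(nrow(prioritise_organ_toxicity(
    scores, comp, toy_registry()
  )), 0)
  comp$mass_fraction[2] <- 0.10 + 1e-9
  expect_equal(prioritise_organ_toxicity(
    scores, comp, toy_registry()
  )$trigger, "organ_tox_score1")
})

test_that("nephrotoxicity is scored but excluded unless requested", {
  scores <- score_endpoints(toy_stat_alerts(), toy_expert_calls())
  expect_equal(
    scores$score[scores$substance_id == "C5" &
      scores$endpoint == "nephrotoxicity"], 2L
  )
  default_calls <- prioritise_organ_toxicity(
    scores, toy_composition(), toy_registry()
  )
  expect_false("P06" %in% default_calls$product_id)
  both <- prioritise_organ_toxicity(
    scores, toy_composition(), toy_registry(),
    endpoints = c("hepatotoxicity", "nephrotoxicity")
  )
  expect_true("P06" %in% both$product_id)
})

test_that("ADME pairing needs matching target, confidence and content", {
  calls <- prioritise_adme_pairs(
    toy_adme(), toy_composition(), toy_registry()
  )
  expect_equal(sort(unique(calls$product_id)), c("P01", "P07", "P08"))
  expect_true(all(calls$trigger == "adme_pair"))
  detail <- jsonlite::fromJSON(
    calls$detail_json[calls$product_id == "P01"],
    simplifyVector = FALSE
  )
  expect_equal(detail$target, "CYP2C19")
  expect_equal(detail$pairs[[1]]$inhibitor, "C1")
  expect_equal(detail$pairs[[1]]$substrate, "A1")
  # P05: C4 inhibits P-gp at confidence 0.4 (below 0.5): no call
  # P06: C5's CYP3A4 inhibition is out of scope: no call even though A2
  # is an in-scope CYP3A4 substrate
  expect_false(any(c("P05", "P06") %in% calls$product_id))
  # lowering conf_min can only add calls (monotonicity)
  lax <- prioritise_adme_pairs(
    toy_adme(), toy_composition(), toy_registry(),
    conf_min = 0.3
  )
  expect_true(all(calls$product_id %in% lax$product_id))
  expect_true("P05" %in% lax$product_id)
  # substrate whitelist restricts the active substances considered
  only_a1 <- prioritise_adme_pairs(
    toy_adme(), toy_composition(), toy_registry(),
    substrate_ids = "A1"
  )
  expect_equal(sort(unique(only_a1$product_id)), c("P01", "P07"))
})

test_that("raising a co-formulant's content never removes a call", {
  scores <- score_endpoints(toy_stat_alerts(), toy_expert_calls())
  base_comp <- toy_composition()
  base <- prioritise_organ_toxicity(scores, base_comp, toy_registry())
  for (mult in c(1.5, 3)) {
    comp <- base_comp
    sel <- comp$substance_id %in% c("C1", "C2", "C4")
    comp$mass_fraction[sel] <- pmin(comp$mass_fraction[sel] * mult, 0.9)
    more <- prioritise_organ_toxicity(scores, comp, toy_registry())
    expect_true(all(
      paste(base$product_id, base$trigger) %in%
        paste(more$product_id, more$trigger)
    ))
  }
})

test_that("co-formulant sales follow product sales times content, summed by CAS", {
  sales <- compute_coformulant_sales(
    toy_products(), toy_composition(), toy_registry()
  )
  expect_equal(
    setNames(sales$coformulant_sales_kg, sales$cas_key),
    toy_expected()$sales_kg
  )
  # one product, 1000 kg, co-formulant at 25% -> 250 kg
  p <- tibble::tibble(product_id = "P1", sales_kg = 1000)
  comp <- tibble::tibble(
    product_id = "P1", substance_id = c("A1", "C1"),
    mass_fraction = c(0.1, 0.25)
  )
  one <- compute_coformulant_sales(p, comp, toy_registry())
  expect_equal(one$coformulant_sales_kg, 250)
  # same CAS in two products: contributions sum under one entry
  reg <- toy_registry()
  reg <- rbind(reg, tibble::tibble(
    substance_id = "C9", cas = "14433-76-2", name = "NDA again",
    smiles = "S1", role = "co_formulant", is_class = FALSE
  ))
  p2 <- tibble::tibble(product_id = c("P1", "P2"), sales_kg = c(1000, 500))
  comp2 <- tibble::tibble(
    product_id = c("P1", "P1", "P2", "P2"),
    substance_id = c("A1", "C1", "A1", "C9"),
    mass_fraction = c(0.1, 0.25, 0.1, 0.1)
  )
  merged <- compute_coformulant_sales(p2, comp2, reg)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$coformulant_sales_kg, 300)
  # conservation: totals match a brute-force sweep over every entry
  brute <- sum(vapply(seq_len(nrow(toy_composition())), function(i) {
    row <- toy_composition()[i, ]
    if (!row$substance_id %in% c("A1", "A2")) {
      row$mass_fraction *
        toy_products()$sales_kg[toy_products()$product_id == row$product_id]
    } else {
      0
    }
  }, numeric(1)))
  expect_equal(sum(sales$coformulant_sales_kg), brute, tolerance = 1e-12)
})

test_that("top-sales ranking uses the printed tonnage table and CAS tie-break", {
  # on the published top-10 tonnage table, water ranks first
  tab <- readr::read_csv(
    system.file("extdata", "top10_coformulant_sales.csv",
      package = "mixtriage"
    ),
    show_col_types = FALSE
  )
  ranked <- tab[order(-tab$sales_tonnes, tab$cas), ]
  expect_equal(ranked$name[1], "Water")
  expect_equal(ranked$cas[1], "7732-18-5")
  expect_equal(ranked$sales_tonnes[1], 22962)

  sales <- compute_coformulant_sales(
    toy_products(), toy_composition(), toy_registry()
  )
  # tie at 120 kg between acetone (67-64-1) and toluene (108-88-3):
  # lexicographic CAS order puts toluene first
  expect_equal(sales$cas_key[3:4], c("108-88-3", "67-64-1"))
  top2 <- rank_top_sales(sales, toy_composition(), toy_registry(), n = 2)
  expect_equal(sort(unique(top2$product_id)), toy_expected()$top_sales)
  # n exceeding the list length saturates: identical call set
  all5 <- rank_top_sales(sales, toy_composition(), toy_registry(), n = 5)
  huge <- rank_top_sales(sales, toy_composition(), toy_registry(), n = 1e6)
  expect_equal(all5, huge)
  # all-equal sales: ranking equals CAS order
  flat <- sales
  flat$coformulant_sales_kg <- 1
  top1 <- rank_top_sales(flat, toy_composition(), toy_registry(), n = 1)
  detail <- jsonlite::fromJSON(top1$detail_json[1], simplifyVector = FALSE)
  expect_equal(detail$coformulants[[1]]$cas_key, sort(sales$cas_key)[1])
})

test_that("merge counts unique products once across triggers", {
  a <- call_tibble_for_test(c("A", "B"), "organ_tox_score2")
  b <- call_tibble_for_test(c("B", "C"), "adme_pair")
  m <- merge_priorities(a, b)
  expect_equal(
    m$summary$n_products[m$summary$trigger == "total_unique"], 3
  )
  expect_true(all(
    m$summary$n_products[m$summary$trigger != "total_unique"] <= 3
  ))
  empty <- merge_priorities()
  expect_equal(nrow(empty$calls), 0)
  expect_equal(nrow(empty$summary), 0)
})
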