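# Concentration-addition construction, the Loewe oracle and the model
# deviation ratio.

parallel_toy_fit <- function(b, shared = c(a = 100, c = 0, d = 1),
                             model = "exponential") {
  # exact parallel fit assembled directly, bypassing estimation, so the
  # CA construction can be tested against known parameters
  structure(
    list(
      model = model, shared = shared, b = b,
      rss = 0, n_obs = 0, k_params = 3L + length(b), aic = -Inf,
      converged = TRUE
    ),
    class = "parallel_fit"
  )
}

test_that("harmonic potency combination and predicted EC50 are exact", {
  pf <- parallel_toy_fit(c(A = 10, B = 40))
  pred <- ca_mixture_curve(pf, c(A = 0.5, B = 0.5))
  expect_equal(pred$b_mix, 16, tolerance = 1e-12)
  expect_equal(pred$ec50_predicted, 16 * log(2), tolerance = 1e-12)
  # invalid fractions are rejected
  expect_error(ca_mixture_curve(pf, c(A = 0.6, B = 0.6)), "sum to 1")
  expect_error(ca_mixture_curve(pf, c(A = 0.5, X = 0.5)), "named")
})

test_that("sham mixtures reproduce the single-substance curve", {
  doses <- c(0, default_doses())
  # single component at fraction 1
  pf <- parallel_toy_fit(c(A = 10, B = 40))
  pred <- ca_mixture_curve(pf, c(A = 1))
  expect_equal(pred$b_mix, 10, tolerance = 1e-12)
  expect_equal(
    pred$curve(doses), exp_response(doses, 100, 10, 0, 1),
    tolerance = 1e-9
  )
  # a compound mixed with itself at any split
  for (split in c(0.2, 0.5, 0.9)) {
    pf2 <- parallel_toy_fit(c(A = 10, A2 = 10))
    pred2 <- ca_mixture_curve(pf2, c(A = split, A2 = 1 - split))
    expect_equal(
      pred2$curve(doses), exp_response(doses, 100, 10, 0, 1),
      tolerance = 1e-9
    )
  }
  # three equal components keep the common potency
  pf3 <- parallel_toy_fit(c(A = 25, B = 25, C = 25))
  pred3 <- ca_mixture_curve(pf3, c(A = 1 / 3, B = 1 / 3, C = 1 / 3))
  expect_equal(pred3$b_mix, 25, tolerance = 1e-9)
})

test_that("parallel CA agrees with the general Loewe oracle on parallel curves", {
  shared <- c(a = 100, c = 0.05, d = 1.4)
  b <- c(A = 8, B = 55, C = 120)
  fractions <- c(A = 0.2, B = 0.5, C = 0.3)
  pf <- parallel_toy_fit(b, shared)
  pred <- ca_mixture_curve(pf, fractions)
  curves <- lapply(b, function(bi) {
    function(x) exp_response(x, shared["a"], bi, shared["c"], shared["d"])
  })
  levels <- seq(10, 90, length.out = 21) # attainable: a*c = 5, a = 100
  for (lv in levels) {
    d_oracle <- loewe_effective_dose(curves, fractions, lv)
    d_ca <- uniroot(
      function(x) pred$curve(x) - lv, c(1e-9, 1e7),
      tol = 1e-12
    )$root
    expect_equal(d_ca, d_oracle, tolerance = 1e-6)
  }
  # oracle sanity: single component and sham mixes
  expect_equal(
    loewe_effective_dose(curves["A"], c(A = 1), 50),
    uniroot(function(x) curves$A(x) - 50, c(1e-9, 1e7), tol = 1e-12)$root,
    tolerance = 1e-9
  )
  same <- list(curves$A, curves$A)
  expect_equal(
    loewe_effective_dose(same, c(0.3, 0.7), 50),
    loewe_effective_dose(same, c(1, 0), 50),
    tolerance = 1e-9
  )
  expect_error(
    loewe_effective_dose(curves, fractions, 2), # below the asymptote 5
    "unattainable"
  )
})

test_that("deviation classification follows the MDR thresholds", {
  pf <- parallel_toy_fit(c(A = 10, B = 40))
  pred <- ca_mixture_curve(pf, c(A = 0.5, B = 0.5))
  # predicted 16*log(2) ~ 11.09; force round observed EC50s through the
  # numeric path of classify_deviation
  pred16 <- pred
  pred16$ec50_predicted <- 16
  synergy <- classify_deviation(16 / 3.2, pred16)
  expect_equal(synergy$mdr, 3.2, tolerance = 1e-12)
  expect_equal(synergy$call, "more_than_additive")
  additive <- classify_deviation(16, pred16)
  expect_equal(additive$mdr, 1)
  expect_equal(additive$call, "additive")
  antagonism <- classify_deviation(64, pred16)
  expect_equal(antagonism$mdr, 0.25)
  expect_equal(antagonism$call, "less_than_additive")
  # threshold boundary is strict on both sides
  expect_equal(classify_deviation(8, pred16)$call, "additive")
  expect_equal(
    classify_deviation(8 - 1e-9, pred16, mdr_threshold = 2)$call,
    "more_than_additive"
  )
})

test_that("scaling observed mixture doses scales the MDR reciprocally", {
  pf <- parallel_toy_fit(c(A = 10, B = 40))
  pred <- ca_mixture_curve(pf, c(A = 0.5, B = 0.5))
  base <- gen_mixture_response(
    c(A = 10, B = 40), c(a = 100, c = 0, d = 1), c(A = 0.5, B = 0.5),
    synergy_s = 2, noise_sd = 0, seed = 9
  )
  fit0 <- fit_model(base, "exponential")
  mdr0 <- classify_deviation(fit0, pred)$mdr
  for (s in c(0.5, 3)) {
    scaled <- base
    scaled$conc_mg_L <- scaled$conc_mg_L * s
    fit_s <- fit_model(scaled, "exponential")
    expect_equal(fit_s$ec50, fit0$ec50 * s, tolerance = 1e-4)
    expect_equal(
      classify_deviation(fit_s, pred)$mdr, mdr0 / s,
      tolerance = 1e-4
    )
  }
})

test_that("the estimated parallel fit recovers shared shape and potencies", {
  d1 <- gen_dose_response(c(a = 100, b = 10, c = 0, d = 1.5),
    noise_sd = 0, seed = 1, treatment = "A"
  )
  d2 <- gen_dose_response(c(a = 100, b = 40, c = 0, d = 1.5),
    noise_sd = 0, seed = 2, treatment = "B",
    doses = default_doses(top = 600)
  )
  pf <- fit_parallel_components(rbind(d1, d2))
  expect_true(pf$converged)
  expect_equal(unname(pf$shared["a"]), 100, tolerance = 1e-4)
  expect_equal(unname(pf$shared["d"]), 1.5, tolerance = 1e-4)
  expect_equal(unname(pf$b[c("A", "B")]), c(10, 40), tolerance = 1e-3)
})

test_that("curve_table exports dense dose/response tables", {
  pf <- parallel_toy_fit(c(A = 10, B = 40))
  pred <- ca_mixture_curve(pf, c(A = 0.5, B = 0.5))
  doses <- default_doses()
  tab <- curve_table(pred, doses)
  expect_equal(tab$response_pct, exp_response(doses, 100, 16, 0, 1))
  tab_a <- curve_table(pf, doses, component = "A")
  expect_equal(tab_a$response_pct, exp_response(doses, 100, 10, 0, 1))
})
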