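# Concentration addition (Loewe) mixture modelling. The primary
# construction is the parallel-curve one: all components are fitted jointly
# with shared zero-dose level a, asymptote factor c and shape d, and a
# component-specific potency scale b_i. Under dose addition a mixture dosed
# at total concentration D with mass fractions pi_i then follows the same
# curve with scale b_mix = 1 / sum(pi_i / b_i) (the pi-weighted harmonic
# combination). A general Loewe solver over arbitrary monotone curves is
# kept as an independent numerical oracle.

#' Joint parallel fit of several treatments
#'
#' Fits one exponential (or Hill) model to several single-substance
#' dose-response datasets simultaneously, with shared `a`, `c`, `d` and a
#' per-treatment potency scale `b`. This relative-potency (parallel-curve)
#' assumption is what makes a closed-form dose-addition mixture curve
#' possible.
#'
#' @param data long tibble with `treatment`, `conc_mg_L`, `response_pct`
#'   covering two or more treatments.
#' @param model `"exponential"` or `"hill"`.
#' @return object of class `parallel_fit`: `model`, `shared` (named a, c,
#'   d), `b` (named per-treatment scales), `rss`, `n_obs`, `aic`,
#'   `converged`.
#' @export
fit_parallel_components <- function(data, model = c("exponential", "hill")) {
  model <- match.arg(model)
  stopifnot(all(c("treatment", "conc_mg_L", "response_pct") %in% names(data)))
  labels <- sort(unique(data$treatment))
  if (length(labels) < 1) {
    stop("no treatments in data", call. = FALSE)
  }
  for (lab in labels) {
    dr_check_data(data[data$treatment == lab, c("conc_mg_L", "response_pct")])
  }
  df <- data.frame(
    x = data$conc_mg_L,
    y = data$response_pct,
    tr = match(data$treatment, labels)
  )
  formula <- if (model == "exponential") {
    y ~ a * (c - (c - 1) * exp(-(x / b[tr])^d))
  } else {
    y ~ a * (1 + (c - 1) * x^d / (b[tr]^d + x^d))
  }
  # per-treatment geometric-mean dose as the b start; shared grid on (c, d)
  b0 <- vapply(seq_along(labels), function(i) {
    exp(mean(log(df$x[df$tr == i & df$x > 0])))
  }, numeric(1))
  ctrl <- df$y[df$x == 0]
  a0 <- if (length(ctrl) > 0) mean(ctrl) else max(df$y)
  grid <- expand.grid(c = c(0, 0.25), d = c(0.5, 1, 2, 4))
  nb <- length(labels)
  lower <- c(0, -10, 1e-3, rep(1e-9, nb))
  upper <- c(Inf, 10, 20, rep(Inf, nb))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      suppressWarnings(stats::nls(
        formula,
        data = df,
        start = list(a = a0, c = grid$c[i], d = grid$d[i], b = b0),
        algorithm = "port", lower = lower, upper = upper,
        control = stats::nls.control(
          maxiter = 500, warnOnly = TRUE, minFactor = 1e-10
        )
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cand <- list(
      params = coef(fit),
      rss = sum(resid(fit)^2),
      converged = fit$convInfo$isConv
    )
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  if (is.null(best)) {
    stop("parallel fit failed from every initial point", call. = FALSE)
  }
  p <- best$params
  b <- p[grepl("^b", names(p))]
  names(b) <- labels
  structure(
    list(
      model = model,
      shared = c(a = unname(p["a"]), c = unname(p["c"]), d = unname(p["d"])),
      b = b,
      rss = best$rss,
      n_obs = nrow(df),
      k_params = 3L + nb,
      aic = nrow(df) * log(best$rss / nrow(df)) + 2 * (3L + nb),
      converged = isTRUE(best$converged)
    ),
    class = "parallel_fit"
  )
}

#' @export
print.parallel_fit <- function(x, ...) {
  cat(
    "<parallel_fit>", x$model, "model, shared (a, c, d) =",
    paste(signif(x$shared, 5), collapse = ", "), "\n"
  )
  cat("  b:", paste(names(x$b), signif(x$b, 5), sep = " = ", collapse = ", "),
    "\n  rss:", signif(x$rss, 6), " converged:", x$converged, "\n"
  )
  invisible(x)
}

ca_model_fun <- function(model) {
  if (model == "exponential") exp_response else hill_response
}

ca_ec50_fun <- function(model) {
  if (model == "exponential") ec50_exponential else ec50_hill
}

#' Theoretical mixture curve under dose addition
#'
#' From a parallel fit of the mixture's components and the mixture's mass
#' fractions, builds the predicted dose-addition curve: the shared-shape
#' model with potency scale `b_mix = 1 / sum(pi_i / b_i)`, and its
#' predicted EC50 from the closed form.
#'
#' @param parallel_fit a `parallel_fit` covering every component.
#' @param fractions named numeric, mass fraction of each component in the
#'   dosed total (names must match fitted treatments; must sum to 1 within
#'   1e-9).
#' @return object of class `ca_prediction`: `model`, `shared`,
#'   `b_components`, `fractions`, `b_mix`, `ec50_predicted`, `curve`
#'   (function of total dose), plus `ec50_observed`, `mdr`, `call` slots
#'   filled in by [classify_deviation()].
#' @export
ca_mixture_curve <- function(parallel_fit, fractions) {
  stopifnot(inherits(parallel_fit, "parallel_fit"))
  if (is.null(names(fractions)) ||
    !all(names(fractions) %in% names(parallel_fit$b))) {
    stop("fractions must be named by fitted treatment labels", call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  b <- parallel_fit$b[names(fractions)]
  if (any(b <= 0)) {
    stop("component potency scales must be positive", call. = FALSE)
  }
  b_mix <- 1 / sum(fractions / b)
  sh <- parallel_fit$shared
  fun <- ca_model_fun(parallel_fit$model)
  ec50 <- tryCatch(
    ca_ec50_fun(parallel_fit$model)(c(b = b_mix, sh[c("c", "d")])),
    error = function(e) NA_real_
  )
  structure(
    list(
      model = parallel_fit$model,
      shared = sh,
      b_components = b,
      fractions = fractions,
      b_mix = b_mix,
      ec50_predicted = ec50,
      curve = function(dose) {
        fun(dose, sh["a"], b_mix, sh["c"], sh["d"])
      },
      ec50_observed = NA_real_,
      mdr = NA_real_,
      call = NA_character_
    ),
    class = "ca_prediction"
  )
}

#' @export
print.ca_prediction <- function(x, ...) {
  cat(
    "<ca_prediction>", x$model, "model, b_mix =", signif(x$b_mix, 6),
    "mg/L\n  predicted EC50:", signif(x$ec50_predicted, 6), "mg/L\n"
  )
  if (!is.na(x$mdr)) {
    cat(
      "  observed EC50:", signif(x$ec50_observed, 6),
      " MDR:", signif(x$mdr, 6), " call:", x$call, "\n"
    )
  }
  invisible(x)
}

invert_curve <- function(curve, level, upper = 1e8) {
  f <- function(x) curve(x) - level
  lo <- 1e-12
  if (f(lo) * f(upper) > 0) {
    stop("level unattainable for a component curve", call. = FALSE)
  }
  uniroot(f, c(lo, upper), tol = 1e-12)$root
}

#' Loewe effective dose of a mixture at a response level
#'
#' Independent numerical solver for dose addition over arbitrary strictly
#' monotone component curves: each curve is inverted at the requested
#' response level and the total mixture dose is
#' `D = 1 / sum(pi_i / ED_i(level))`, i.e. the dose whose components, at
#' their fractions, exhaust the Loewe isobole `sum(pi_i * D / ED_i) = 1`.
#' Used as a brute-force oracle for [ca_mixture_curve()]; for parallel
#' curves the two agree.
#'
#' @param curves list of functions mapping dose (mg/L) to response, one per
#'   component, each strictly monotone in dose.
#' @param fractions numeric mass fractions, same length, summing to 1.
#' @param level response value attainable by every component curve.
#' @return total mixture dose in mg/L.
#' @export
loewe_effective_dose <- function(curves, fractions, level) {
  stopifnot(length(curves) == length(fractions))
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  ed <- vapply(curves, invert_curve, numeric(1), level = level)
  active <- fractions > 0
  1 / sum(fractions[active] / ed[active])
}

#' Classify a mixture's deviation from dose addition
#'
#' Completes a `ca_prediction` with the observed mixture EC50 and the model
#' deviation ratio `MDR = EC50_predicted / EC50_observed`. The mixture is
#' called `more_than_additive` (synergistic, data left-shifted from the
#' theoretical curve) when MDR exceeds the threshold, `less_than_additive`
#' (antagonistic, right-shifted) when MDR is below its reciprocal, and
#' `additive` otherwise.
#'
#' @param mixture_fit `dr_fit` on the observed mixture data, with a defined
#'   EC50.
#' @param prediction `ca_prediction` from [ca_mixture_curve()].
#' @param mdr_threshold fold-change threshold (default 2).
#' @return the completed `ca_prediction`.
#' @export
classify_deviation <- function(mixture_fit, prediction, mdr_threshold = 2) {
  stopifnot(inherits(prediction, "ca_prediction"))
  obs <- if (inherits(mixture_fit, "dr_fit")) mixture_fit$ec50 else mixture_fit
  if (is.na(obs) || is.na(prediction$ec50_predicted)) {
    stop("classification needs a defined EC50 on both sides", call. = FALSE)
  }
  prediction$ec50_observed <- obs
  prediction$mdr <- prediction$ec50_predicted / obs
  prediction$call <- if (prediction$mdr > mdr_threshold) {
    "more_than_additive"
  } else if (prediction$mdr < 1 / mdr_threshold) {
    "less_than_additive"
  } else {
    "additive"
  }
  prediction
}

#' Export a fitted or predicted curve as a dense dose/response table
#'
#' @param object a `dr_fit`, `parallel_fit` component or `ca_prediction`.
#' @param doses numeric vector of doses (mg/L).
#' @param component for a `parallel_fit`, which treatment's curve.
#' @return tibble with `conc_mg_L` and `response_pct`.
#' @export
curve_table <- function(object, doses, component = NULL) {
  y <- if (inherits(object, "ca_prediction")) {
    object$curve(doses)
  } else if (inherits(object, "parallel_fit")) {
    stopifnot(!is.null(component), component %in% names(object$b))
    ca_model_fun(object$model)(
      doses, object$shared["a"], object$b[[component]],
      object$shared["c"], object$shared["d"]
    )
  } else if (inherits(object, "dr_fit") && object$model != "fourpl") {
    ca_model_fun(object$model)(
      doses, object$params[["a"]], object$params[["b"]],
      object$params[["c"]], object$params[["d"]]
    )
  } else if (inherits(object, "dr_fit")) {
    fourpl_response(
      log10(doses), object$params[["bottom"]], object$params[["top"]],
      object$params[["logic50"]], object$params[["hillslope"]]
    )
  } else {
    stop("unsupported object", call. = FALSE)
  }
  tibble::tibble(conc_mg_L = doses, response_pct = unname(y))
}
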