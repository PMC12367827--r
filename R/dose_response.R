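# Dose-response models and least-squares fitting. Three model families are
# supported on viability data expressed as % of the solvent control:
#
#   exponential  y = a * [c - (c - 1) * exp(-(x/b)^d)]
#   Hill         y = a * [1 + (c - 1) * x^d / (b^d + x^d)]
#   4PL          Y = Bottom + (Top - Bottom) / (1 + 10^((LogIC50 - X) * HillSlope))
#
# The exponential and Hill families share parameter semantics: a is the
# response at zero dose, a*c the asymptote at infinite dose, b a potency
# scale in mg/L and d a shape exponent. The 4PL is parameterised on
# X = log10(concentration), the convention of plate-reader software.

#' Dose-response model curves
#'
#' Evaluate the exponential, Hill or four-parameter logistic model.
#' For `exp_response()` and `hill_response()`, `a` is the zero-dose
#' response, `a * c` the infinite-dose asymptote (`c < 1` for declining
#' viability, `c > 1` for activation), `b > 0` a dose scale in mg/L and
#' `d > 0` a shape exponent. `fourpl_response()` takes `x10` =
#' log10(concentration).
#'
#' @param x dose in mg/L (non-negative).
#' @param a,b,c,d exponential / Hill parameters.
#' @param x10 log10 concentration.
#' @param bottom,top,logic50,hillslope 4PL parameters.
#' @return numeric response vector.
#' @export
exp_response <- function(x, a, b, c, d) {
  a * (c - (c - 1) * exp(-(x / b)^d))
}

#' @rdname exp_response
#' @export
hill_response <- function(x, a, b, c, d) {
  a * (1 + (c - 1) * x^d / (b^d + x^d))
}

#' @rdname exp_response
#' @export
fourpl_response <- function(x10, bottom, top, logic50, hillslope) {
  bottom + (top - bottom) / (1 + 10^((logic50 - x10) * hillslope))
}

dr_check_data <- function(data, min_doses = 5) {
  stopifnot(all(c("conc_mg_L", "response_pct") %in% names(data)))
  if ("treatment" %in% names(data) &&
    length(unique(data$treatment)) > 1) {
    stop("data contains several treatment labels; fit one at a time ",
      "(see split_dose_response())",
      call. = FALSE
    )
  }
  n_pos <- length(unique(data$conc_mg_L[data$conc_mg_L > 0]))
  if (n_pos < min_doses) {
    stop(
      "need at least ", min_doses, " distinct positive concentrations, got ",
      n_pos,
      call. = FALSE
    )
  }
  if (diff(range(data$response_pct)) == 0) {
    stop("degenerate data: all responses identical", call. = FALSE)
  }
  invisible(data)
}

dr_fit <- function(model, params, rss, n_obs, k_params, converged, ec50) {
  structure(
    list(
      model = model, params = params, rss = rss, n_obs = n_obs,
      k_params = k_params,
      aic = n_obs * log(rss / n_obs) + 2 * k_params,
      converged = converged, ec50 = ec50
    ),
    class = "dr_fit"
  )
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("<dr_fit>", x$model, "model,", x$n_obs, "observations\n")
  cat("  params:", paste(
    names(x$params), signif(x$params, 5),
    sep = " = ", collapse = ", "
  ), "\n")
  cat(
    "  rss:", signif(x$rss, 6), " aic:", signif(x$aic, 6),
    " converged:", x$converged, "\n"
  )
  if (!is.na(x$ec50)) {
    cat("  ec50:", signif(x$ec50, 6), "mg/L\n")
  }
  invisible(x)
}

# Deterministic multi-start grid: a from the controls (or the response at
# the lowest dose), b at the geometric mean of the positive doses,
# c in {0, 0.25} and d in {0.5, 1, 2, 4}.
dr_starts <- function(data) {
  ctrl <- data$response_pct[data$conc_mg_L == 0]
  a0 <- if (length(ctrl) > 0) {
    mean(ctrl)
  } else {
    mean(data$response_pct[data$conc_mg_L == min(data$conc_mg_L)])
  }
  pos <- data$conc_mg_L[data$conc_mg_L > 0]
  b0 <- exp(mean(log(pos)))
  grid <- expand.grid(c = c(0, 0.25), d = c(0.5, 1, 2, 4))
  lapply(seq_len(nrow(grid)), function(i) {
    list(a = a0, b = b0, c = grid$c[i], d = grid$d[i])
  })
}

try_nls <- function(formula, data, start, lower, upper) {
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula,
      data = data, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  # Levenberg-Marquardt cannot build its return object when the optimum is
  # an exact (zero-residual) fit; a port-constrained Gauss-Newton pass
  # covers that case and any other start nlsLM gives up on
  if (is.null(fit)) {
    port_args <- list(
      formula,
      data = data, start = start, algorithm = "port",
      control = stats::nls.control(
        maxiter = 200, warnOnly = TRUE, minFactor = 1e-10
      )
    )
    if (any(is.finite(lower)) || any(is.finite(upper))) {
      port_args$lower <- lower
      port_args$upper <- upper
    }
    fit <- tryCatch(
      suppressWarnings(do.call(stats::nls, port_args)),
      error = function(e) NULL
    )
  }
  if (!is.null(fit)) {
    return(list(
      params = coef(fit),
      rss = sum(resid(fit)^2),
      converged = isTRUE(fit$convInfo$isConv)
    ))
  }
  # last resort: direct RSS minimisation; slower but start-deterministic
  # and immune to the gradient-matrix pathologies of the nls builders
  lhs <- eval(formula[[2]], data)
  par0 <- unlist(start)
  rss_fn <- function(par) {
    pred <- tryCatch(
      eval(formula[[3]], c(as.list(data), as.list(par))),
      error = function(e) rep(NA_real_, length(lhs))
    )
    if (any(!is.finite(pred))) {
      return(.Machine$double.xmax)
    }
    sum((lhs - pred)^2)
  }
  opt <- tryCatch(
    optim(par0, rss_fn,
      method = "L-BFGS-B",
      lower = lower[names(par0)], upper = upper[names(par0)],
      control = list(maxit = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    return(NULL)
  }
  list(
    params = opt$par,
    rss = opt$value,
    converged = opt$convergence == 0
  )
}

#' Fit an exponential or Hill dose-response model
#'
#' Ordinary (unweighted) least squares via Levenberg-Marquardt, restarted
#' from a deterministic grid of eight initial points; the best residual sum
#' of squares wins. Requires at least five distinct positive concentrations
#' (four parameters plus one). The AIC reported is the Gaussian profile
#' form `n * log(rss / n) + 2k` with the additive constant dropped, which
#' is sufficient for comparing fits on identical observations.
#'
#' @param data tibble with `conc_mg_L` and `response_pct` for a single
#'   treatment (zero-dose rows are controls and enter the fit).
#' @param model `"exponential"` or `"hill"`.
#' @return a `dr_fit` object: `model`, named `params` (a, b, c, d), `rss`,
#'   `n_obs`, `k_params`, `aic`, `converged`, `ec50` (`NA` when the
#'   50%-of-control level is unreachable, i.e. `c >= 0.5`).
#' @export
fit_model <- function(data, model = c("exponential", "hill")) {
  model <- match.arg(model)
  dr_check_data(data)
  df <- data.frame(x = data$conc_mg_L, y = data$response_pct)
  formula <- if (model == "exponential") {
    y ~ a * (c - (c - 1) * exp(-(x / b)^d))
  } else {
    y ~ a * (1 + (c - 1) * x^d / (b^d + x^d))
  }
  lower <- c(a = 0, b = 1e-9, c = -10, d = 1e-3)
  upper <- c(a = Inf, b = Inf, c = 10, d = 20)
  best <- NULL
  for (st in dr_starts(df |> dplyr::rename(
    conc_mg_L = "x", response_pct = "y"
  ))) {
    cand <- try_nls(formula, df, st, lower, upper)
    if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("model fitting failed from every initial point", call. = FALSE)
  }
  p <- best$params[c("a", "b", "c", "d")]
  ec50 <- if (model == "exponential") {
    tryCatch(ec50_exponential(p), error = function(e) NA_real_)
  } else {
    tryCatch(ec50_hill(p), error = function(e) NA_real_)
  }
  dr_fit(
    model = model, params = p, rss = best$rss, n_obs = nrow(df),
    k_params = 4L, converged = best$converged, ec50 = ec50
  )
}

#' Select the best fit by AIC
#'
#' Returns the fit with the lowest AIC. All fits must be on the same
#' observations (equal `n_obs`). On an exact tie (|difference| < 1e-9) the
#' exponential model is preferred, then the earlier fit.
#'
#' @param fits list of `dr_fit` objects.
#' @return the selected `dr_fit`.
#' @export
select_model_aic <- function(fits) {
  if (length(fits) == 0) {
    stop("no fits supplied", call. = FALSE)
  }
  if (inherits(fits, "dr_fit")) {
    return(fits)
  }
  n <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n)) > 1) {
    stop("fits are not on identical observations", call. = FALSE)
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  best <- min(aic)
  tied <- which(aic < best + 1e-9)
  if (length(tied) > 1) {
    is_exp <- vapply(
      fits[tied], function(f) f$model == "exponential", logical(1)
    )
    if (any(is_exp)) {
      tied <- tied[is_exp]
    }
  }
  fits[[tied[1]]]
}

#' Closed-form EC50 of the exponential and Hill models
#'
#' The EC50 is the dose giving 50% of the zero-dose response (`y = a / 2`).
#' For the exponential model this is
#' `b * (-log((c - 0.5) / (c - 1)))^(1/d)`; for the Hill model
#' `b * (theta / (1 - theta))^(1/d)` with `theta = 0.5 / (1 - c)`. Both
#' require `c < 0.5`, otherwise the 50% level is never reached and an
#' unreachable-level error is raised.
#'
#' @param params named vector or list with `b`, `c`, `d` (and optionally
#'   `a`, which cancels).
#' @return EC50 in mg/L.
#' @examples
#' ec50_exponential(c(a = 100, b = 10, c = 0, d = 1)) # 10 * log(2)
#' @export
ec50_exponential <- function(params) {
  p <- as.list(params)
  if (p$c >= 0.5) {
    stop("50%-of-control level unreachable: c >= 0.5", call. = FALSE)
  }
  unname(p$b * (-log((p$c - 0.5) / (p$c - 1)))^(1 / p$d))
}

#' @rdname ec50_exponential
#' @export
ec50_hill <- function(params) {
  p <- as.list(params)
  if (p$c >= 0.5) {
    stop("50%-of-control level unreachable: c >= 0.5", call. = FALSE)
  }
  theta <- 0.5 / (1 - p$c)
  unname(p$b * (theta / (1 - theta))^(1 / p$d))
}

#' Fit a four-parameter logistic and derive the IC50
#'
#' Fits `Y = Bottom + (Top - Bottom) / (1 + 10^((LogIC50 - X) * HillSlope))`
#' on `X = log10(concentration)` by least squares with a deterministic
#' multi-start over HillSlope signs and magnitudes, and reports
#' `ic50 = 10^LogIC50` in mg/L. Zero-dose control rows cannot be placed on
#' the log axis and are excluded from this fit.
#'
#' @param data tibble with `conc_mg_L` (> 0 rows used) and `response_pct`.
#' @return a `dr_fit` object with model `"fourpl"`, params
#'   `bottom, top, logic50, hillslope`, and `ec50` holding the IC50 in
#'   mg/L.
#' @export
fit_fourpl_ic50 <- function(data) {
  dr_check_data(data)
  pos <- data[data$conc_mg_L > 0, ]
  df <- data.frame(
    x10 = log10(pos$conc_mg_L),
    y = pos$response_pct
  )
  lo <- min(df$y)
  hi <- max(df$y)
  mid <- median(df$x10)
  starts <- lapply(c(-2, -1, -0.5, 0.5, 1, 2), function(s) {
    list(bottom = lo, top = hi, logic50 = mid, hillslope = s)
  })
  formula <- y ~ bottom + (top - bottom) / (1 + 10^((logic50 - x10) * hillslope))
  lower <- c(bottom = -Inf, top = -Inf, logic50 = -Inf, hillslope = -Inf)
  upper <- c(bottom = Inf, top = Inf, logic50 = Inf, hillslope = Inf)
  best <- NULL
  for (st in starts) {
    cand <- try_nls(formula, df, st, lower, upper)
    if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("model fitting failed from every initial point", call. = FALSE)
  }
  p <- best$params[c("bottom", "top", "logic50", "hillslope")]
  dr_fit(
    model = "fourpl", params = p, rss = best$rss, n_obs = nrow(df),
    k_params = 4L, converged = best$converged,
    ec50 = unname(10^p["logic50"])
  )
}

#' Export fit results as a tidy table
#'
#' @param fits named list of `dr_fit` objects (names = treatment labels).
#' @return tibble with `treatment, model, a, b, c, d, rss, aic, ec50`
#'   (4PL parameters are reported in the `a..d` slots as
#'   bottom, top, logic50, hillslope).
#' @export
fits_table <- function(fits) {
  dplyr::bind_rows(lapply(names(fits), function(label) {
    f <- fits[[label]]
    p <- unname(f$params)
    tibble::tibble(
      treatment = label, model = f$model,
      a = p[1], b = p[2], c = p[3], d = p[4],
      rss = f$rss, aic = f$aic, ec50 = f$ec50
    )
  }))
}
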