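## Bounded nonlinear least-squares estimation of SKM parameters, linearized
## confidence intervals, NRMSE goodness of fit, and the named fitting
## protocols for the bundled datasets.

.MODEL_PARAMS <- list(model1 = c("lp0", "dh_over_r"),
                      model2 = c("lp0", "dh_over_r", "k"))
.DEFAULT_START <- c(lp0 = 1, dh_over_r = 1, k = 1)
.DEFAULT_LOWER <- c(lp0 = 0, dh_over_r = 0, k = 0.1)
.DEFAULT_UPPER <- c(lp0 = 15, dh_over_r = Inf, k = Inf)

#' Declare a fitting problem
#'
#' A fit specification names the flux model (`"model1"`, the explicit
#' pure-water pressure law with parameters `lp0` and `dh_over_r`; or
#' `"model2"`, the implicit polarized model adding the mass-transfer
#' coefficient `k`), which parameters are free, and the values of the fixed
#' complement.  The reflection coefficient `sigma` and the Arrhenius reference
#' temperature `t_ref` are always fixed.  Default starting guesses are 1 for
#' every parameter; default bounds are `lp0` in \[0, 15\] L/m2/h/bar,
#' `dh_over_r` in \[0, Inf) K and `k` in \[0.1, Inf) L/m2/h.
#'
#' @param model `"model1"` or `"model2"`.
#' @param free character vector of free parameter names, non-empty subset of
#'   the model's parameters.
#' @param fixed named list of values for the fixed parameters (the complement
#'   of `free`).
#' @param sigma reflection coefficient (fixed).
#' @param t_ref Arrhenius reference temperature, K (fixed).
#' @param start,lower,upper named numeric overrides of the defaults for the
#'   free parameters.
#' @param level confidence level for interval half-widths.
#' @param weighted if `TRUE`, residuals are scaled by `1/jv_sd` (weighted
#'   least squares); default unweighted.
#' @return An object of class `fit_spec`.
#' @examples
#' fit_spec("model2", free = "k",
#'          fixed = list(lp0 = 2.8, dh_over_r = 3181), sigma = 0.999)
#' @export
fit_spec <- function(model = c("model1", "model2"), free,
                     fixed = list(), sigma = 1, t_ref = 293.15,
                     start = NULL, lower = NULL, upper = NULL,
                     level = 0.95, weighted = FALSE) {
  model <- match.arg(model)
  pars <- .MODEL_PARAMS[[model]]
  if (missing(free)) free <- pars
  free <- as.character(free)
  if (length(free) == 0L || !all(free %in% pars))
    skm_stop(sprintf("free parameters must be a non-empty subset of {%s}",
                     paste(pars, collapse = ", ")), "skm_config_error")
  need_fixed <- setdiff(pars, free)
  if (!all(need_fixed %in% names(fixed)))
    skm_stop(sprintf("fixed values required for: %s",
                     paste(setdiff(need_fixed, names(fixed)), collapse = ", ")),
             "skm_config_error")
  if (!is.numeric(level) || length(level) != 1 || level < 0 || level >= 1)
    skm_stop("level must lie in [0, 1)", "skm_config_error")
  take <- function(def, ovr) {
    v <- def[free]
    if (!is.null(ovr)) v[names(ovr)[names(ovr) %in% free]] <-
        unlist(ovr)[names(ovr) %in% free]
    v
  }
  start <- take(.DEFAULT_START, start)
  lower <- take(.DEFAULT_LOWER, lower)
  upper <- take(.DEFAULT_UPPER, upper)
  if (any(start < lower | start > upper))
    skm_stop("starting guesses must lie within the bounds", "skm_config_error")
  structure(list(model = model, free = free,
                 fixed = fixed[need_fixed], sigma = sigma, t_ref = t_ref,
                 start = start, lower = lower, upper = upper,
                 level = level, weighted = isTRUE(weighted)),
            class = "fit_spec")
}

# Assemble a membrane_params from a fit_spec and a free-parameter vector.
# The optimizer may probe the boundary of the box (e.g. lp0 = 0), which the
# strict user-facing validator rejects, so the parameter object is built
# directly here.
.spec_params <- function(spec, theta) {
  full <- c(as.list(theta), spec$fixed)
  structure(list(lp0 = as.numeric(full$lp0),
                 dh_over_r = as.numeric(full$dh_over_r),
                 sigma = spec$sigma,
                 k = if (spec$model == "model2") as.numeric(full$k) else Inf,
                 ps = NA_real_, t_ref = spec$t_ref),
            class = "membrane_params")
}

#' Predicted permeate fluxes for a dataset
#'
#' Model 1 rows use the explicit pure-water law [water_flux()]; model 2 rows
#' solve the implicit polarized flux equation ([solve_flux()]) at each row's
#' observed feed and permeate concentrations (the permeate concentration is
#' treated as data, not predicted).
#'
#' @param params a [membrane_params].
#' @param data a [flux_data] (model 2 requires finite concentration columns).
#' @param model `"model1"` or `"model2"`.
#' @param on_no_root passed to [solve_flux()] for model 2.
#' @return Numeric vector of fluxes, one per row of `data`.
#' @export
predict_flux <- function(params, data, model = c("model1", "model2"),
                         on_no_root = c("error", "na")) {
  model <- match.arg(model)
  if (model == "model1")
    return(water_flux(params, data$tmp, data$temperature))
  if (any(!is.finite(data$c_feed) | !is.finite(data$c_permeate)))
    skm_stop("model2 requires finite feed and permeate concentrations",
             "skm_config_error")
  solve_flux(params, data$tmp, data$temperature, data$c_feed,
             data$c_permeate, on_no_root = match.arg(on_no_root))
}

# Forward finite-difference Jacobian of `fun` (returning a vector) w.r.t.
# theta, relative step 1e-6.
.fd_jacobian <- function(fun, theta) {
  f0 <- fun(theta)
  J <- matrix(0, length(f0), length(theta),
              dimnames = list(NULL, names(theta)))
  for (j in seq_along(theta)) {
    h <- 1e-6 * max(abs(theta[j]), 1e-6)
    th <- theta; th[j] <- th[j] + h
    J[, j] <- (fun(th) - f0) / h
  }
  J
}

# Linearized CI half-widths at the optimum.
.ci_half_widths <- function(J, ssr, n_obs, n_par, level) {
  jtj <- crossprod(J)
  sv <- svd(jtj)
  if (min(sv$d) < max(sv$d) * 1e-12) {
    worst <- colnames(J)[which.max(abs(sv$v[, which.min(sv$d)]))]
    skm_stop(sprintf(
      "J'J is numerically singular: parameter '%s' is not identifiable from these data",
      worst), "skm_rank_error")
  }
  s2 <- ssr / (n_obs - n_par)
  tq <- stats::qt(1 - (1 - level) / 2, df = n_obs - n_par)
  hw <- tq * sqrt(s2 * diag(solve(jtj)))
  names(hw) <- colnames(J)
  hw
}

#' Fit Spiegler-Kedem parameters by bounded nonlinear least squares
#'
#' Minimizes the unweighted (default) sum of squared flux residuals
#' `sum((jv_obs - jv_model)^2)` over the free parameters within the bounds of
#' the [fit_spec], using a Levenberg-Marquardt iteration with box projection
#' ([minpack.lm::nls.lm], step and objective tolerances 1e-12, at most 1000
#' iterations).
#' Confidence-interval half-widths are the standard linearized intervals
#' `t(1-(1-level)/2, n-p) * s * sqrt(diag((J'J)^-1))` with the Jacobian taken
#' by forward finite differences (relative step 1e-6) at the optimum; for the
#' implicit model every Jacobian column re-solves the flux equation.
#'
#' @param data a [flux_data].
#' @param spec a [fit_spec].
#' @return An object of class `skm_fit`: free-parameter `estimates`,
#'   `ci_half_widths`, the assembled full `parameters`, `fit_percent`
#'   ([goodness_of_fit()] of observed vs fitted fluxes), `residuals`
#'   (observed minus fitted, in data order), `fitted`, `n_obs`, `n_params`,
#'   `converged`, `objective` (sum of squared residuals as minimized).
#' @examples
#' fit_skm(load_water_fluxes("II"), fit_spec("model1"))
#' @export
fit_skm <- function(data, spec) {
  if (!inherits(spec, "fit_spec"))
    skm_stop("spec must be a fit_spec", "skm_config_error")
  data <- flux_data(data, attr(data, "provenance") %||% "user-supplied")
  # The objective is a plain sum over rows, so estimates must not depend on
  # row order.  Floating-point summation almost does, through the optimizer's
  # stopping point; evaluating in a canonical row order makes fits exactly
  # permutation-invariant.  Residuals are mapped back to the caller's order.
  ord <- do.call(order, unname(as.data.frame(data)[c(
    "tmp", "temperature", "c_feed", "c_permeate", "jv", "series")]))
  data_in <- data
  data <- flux_data(as.data.frame(data)[ord, , drop = FALSE],
                    attr(data, "provenance"))
  n <- nrow(data)
  p <- length(spec$free)
  if (n <= p)
    skm_stop(sprintf("need more observations (%d) than free parameters (%d)",
                     n, p), "skm_config_error")
  w <- if (spec$weighted) {
    if (any(!is.finite(data$jv_sd) | data$jv_sd <= 0))
      skm_stop("weighted fit requires positive jv_sd on every row",
               "skm_config_error")
    1 / data$jv_sd
  } else rep(1, n)
  pred_fun <- function(theta)
    predict_flux(.spec_params(spec, theta), data, spec$model)
  res_fun <- function(theta) w * (data$jv - pred_fun(theta))

  fit <- minpack.lm::nls.lm(
    par = spec$start, lower = spec$lower, upper = spec$upper, fn = res_fun,
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, ftol = 1e-12, ptol = 1e-12))
  if (fit$info == 5L || fit$niter >= 1000L)
    skm_stop("optimizer did not converge within 1000 iterations",
             "skm_convergence_error", best_par = fit$par,
             best_objective = fit$deviance)
  theta <- unlist(fit$par)[spec$free]

  # The projected-step LM iteration can stall on a box bound with an interior
  # descent direction left; a PORT (nlminb) pass from the LM solution handles
  # the active-set geometry and is kept only if it improves the objective.
  obj <- function(th) sum(res_fun(th)^2)
  grad <- function(th) {
    J <- -.fd_jacobian(res_fun, th)
    as.numeric(-2 * crossprod(J, res_fun(th)))
  }
  port <- stats::nlminb(theta, obj, gradient = grad, lower = spec$lower,
                        upper = spec$upper,
                        control = list(rel.tol = 1e-14, x.tol = 1e-13,
                                       iter.max = 500, eval.max = 1000))
  if (is.finite(port$objective) && port$objective <= obj(theta))
    theta <- stats::setNames(port$par, spec$free)

  # Gauss-Newton polish: iterate to the stationary point J'r = 0 so the
  # reported optimum is pinned to far better precision than either
  # optimizer's stopping rule (this is what makes fits invariant to row
  # permutation at the 1e-9 level).
  for (it in seq_len(50L)) {
    r0 <- res_fun(theta)
    J <- -.fd_jacobian(res_fun, theta)
    delta <- tryCatch(as.numeric(solve(crossprod(J), crossprod(J, r0))),
                      error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    base <- sum(r0^2)
    s <- 1; cand <- NULL
    for (h in seq_len(8L)) {
      try_th <- pmin(pmax(theta + s * delta, spec$lower), spec$upper)
      if (sum(res_fun(try_th)^2) <= base) { cand <- try_th; break }
      s <- s / 2
    }
    if (is.null(cand)) break
    moved <- max(abs(cand - theta) / pmax(abs(cand), 1e-8))
    theta <- cand
    if (moved < 1e-12) break
  }
  fitted <- pred_fun(theta)
  resid <- data$jv - fitted
  objective <- sum((w * resid)^2)
  J <- -.fd_jacobian(res_fun, theta)  # d(prediction)/d(theta), weighted scale
  hw <- .ci_half_widths(J, objective, n, p, spec$level)
  fitp <- tryCatch(goodness_of_fit(data$jv, fitted),
                   error = function(e) NA_real_)
  # back to the caller's row order
  fitted[ord] <- fitted
  resid[ord] <- resid
  structure(list(
    estimates = theta, ci_half_widths = hw,
    parameters = .spec_params(spec, theta),
    fit_percent = fitp, residuals = resid, fitted = fitted,
    n_obs = n, n_params = p,
    converged = fit$info %in% 1:3, objective = objective,
    optimizer = sprintf("minpack.lm::nls.lm (bounded LM), info=%d, %d iterations",
                        fit$info, fit$niter),
    spec = spec, data_provenance = attr(data, "provenance")),
    class = "skm_fit")
}

#' @export
print.skm_fit <- function(x, ...) {
  cat(sprintf("Spiegler-Kedem %s fit: %d observations, %d free parameter(s)\n",
              x$spec$model, x$n_obs, x$n_params))
  cat(sprintf("  data: %s\n", x$data_provenance))
  lev <- 100 * x$spec$level
  for (nm in names(x$estimates))
    cat(sprintf("  %-10s %10.4g +- %.4g  (%g%% CI)\n", nm,
                x$estimates[[nm]], x$ci_half_widths[[nm]], lev))
  cat(sprintf("  Fit%% = %.1f   SSR = %.4g   converged: %s\n",
              x$fit_percent, x$objective, x$converged))
  invisible(x)
}

#' @export
coef.skm_fit <- function(object, ...) object$estimates

#' @export
predict.skm_fit <- function(object, newdata, ...) {
  predict_flux(object$parameters, newdata, object$spec$model, ...)
}

#' NRMSE-based goodness of fit
#'
#' `Fit% = 100 * (1 - sqrt(sum((obs - pred)^2) / sum((obs - mean(obs))^2)))`.
#' 100 is a perfect fit; a model no better than the observed mean scores 0.
#'
#' @param jv_exp observed fluxes (length >= 2, not constant).
#' @param jv_theor predicted fluxes, same length and order.
#' @return Fit percentage (at most 100; unbounded below).
#' @export
goodness_of_fit <- function(jv_exp, jv_theor) {
  if (length(jv_exp) != length(jv_theor) || length(jv_exp) < 2L)
    skm_stop("need two flux vectors of equal length >= 2", "skm_domain_error")
  denom <- sum((jv_exp - mean(jv_exp))^2)
  if (denom == 0)
    skm_stop("observed fluxes are constant: NRMSE denominator is zero",
             "skm_domain_error")
  100 * (1 - sqrt(sum((jv_exp - jv_theor)^2) / denom))
}

.PROTOCOLS <- c("model1_series_I", "model1_series_II",
                "model2_full_C1", "model2_full_C2",
                "model2_k_only_C1", "model2_k_only_C2",
                "model2_lp0_k_C1", "model2_k_by_temperature_C2")

#' Run a named fitting protocol on the bundled datasets
#'
#' The protocols reproduce the estimation workflow for the bundled NF270
#' datasets.  All model-2 protocols fix `sigma = 0.999`; every protocol uses
#' `t_ref = 293.15 K` and the default starts and bounds of [fit_spec()].
#'
#' \describe{
#'   \item{model1_series_I / model1_series_II}{explicit water model, free
#'     `lp0` and `dh_over_r`, on the pure-water series.}
#'   \item{model2_full_C1 / model2_full_C2}{implicit model, free `lp0`,
#'     `dh_over_r`, `k`, on the lees solutions.}
#'   \item{model2_k_only_C1 / model2_k_only_C2}{free `k` only, with
#'     `lp0 = 2.8` and `dh_over_r = 3181` fixed at the series-II water
#'     values.}
#'   \item{model2_lp0_k_C1}{free `lp0` and `k`, `dh_over_r = 3181` fixed.}
#'   \item{model2_k_by_temperature_C2}{the k-only protocol applied separately
#'     to the C2 rows at each of the four temperatures; returns a list of
#'     fits keyed by temperature.}
#' }
#'
#' @param name one of the protocol names above.
#' @return An `skm_fit`, or for the by-temperature protocol a named list of
#'   four `skm_fit` objects.
#' @examples
#' run_protocol("model1_series_II")
#' @export
run_protocol <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% .PROTOCOLS))
    skm_stop(sprintf("unknown protocol '%s'; valid protocols: %s",
                     paste(name, collapse = ","),
                     paste(.PROTOCOLS, collapse = ", ")), "skm_usage_error")
  fixed_water <- list(lp0 = 2.8, dh_over_r = 3181)
  switch(name,
    model1_series_I = fit_skm(load_water_fluxes("I"), fit_spec("model1")),
    model1_series_II = fit_skm(load_water_fluxes("II"), fit_spec("model1")),
    model2_full_C1 = fit_skm(load_lees_dataset("C1"),
                             fit_spec("model2", sigma = 0.999)),
    model2_full_C2 = fit_skm(load_lees_dataset("C2"),
                             fit_spec("model2", sigma = 0.999)),
    model2_k_only_C1 = fit_skm(load_lees_dataset("C1"),
                               fit_spec("model2", free = "k",
                                        fixed = fixed_water, sigma = 0.999)),
    model2_k_only_C2 = fit_skm(load_lees_dataset("C2"),
                               fit_spec("model2", free = "k",
                                        fixed = fixed_water, sigma = 0.999)),
    model2_lp0_k_C1 = fit_skm(load_lees_dataset("C1"),
                              fit_spec("model2", free = c("lp0", "k"),
                                       fixed = list(dh_over_r = 3181),
                                       sigma = 0.999)),
    model2_k_by_temperature_C2 = {
      d <- load_lees_dataset("C2")
      temps <- sort(unique(d$temperature))
      fits <- lapply(temps, function(tt) {
        di <- flux_data(d[d$temperature == tt, , drop = FALSE],
                        sprintf("%s, T = %g K", attr(d, "provenance"), tt))
        fit_skm(di, fit_spec("model2", free = "k", fixed = fixed_water,
                             sigma = 0.999))
      })
      names(fits) <- as.character(temps)
      fits
    })
}

#' List the available fitting protocols
#' @return Character vector of protocol names accepted by [run_protocol()].
#' @export
skm_protocols <- function() .PROTOCOLS
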