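# Curve fitting for patch-clamp observables: Boltzmann activation,
# exponential deactivation, and plateau-anchored Hill dose-response.

lc_fit_result <- function(class, params, se, model, data, converged,
                          message = NA_character_) {
  structure(list(params = params, se = se, model = model, data = data,
                 converged = converged, message = message),
            class = c(class, "lc_fit"))
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1],
              if (x$converged) "converged" else paste("FAILED:", x$message)))
  if (x$converged)
    cat(paste(sprintf("  %s = %.6g +/- %.2g", names(x$params), x$params,
                      x$se[names(x$params)]), collapse = "\n"), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lc_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params),
         std.error = unname(x$se[names(x$params)]))
}

#' @exportS3Method generics::glance
glance.lc_fit <- function(x, ...) {
  tibble(converged = x$converged,
         sigma = if (x$converged) sqrt(mean(stats::residuals(x$model)^2)) else NA_real_,
         n = nrow(x$data), message = x$message)
}

#' Boltzmann voltage-activation model
#'
#' `I/Imax = 1 / (1 + exp((V1/2 - Vm) / k))`: the normalized tail current is
#' 0.5 at `Vm = V1/2` and approaches 1 at depolarized potentials; `k` (mV)
#' sets the steepness.
#'
#' @param v_mV membrane potential (mV).
#' @param v_half midpoint voltage (mV).
#' @param k slope factor (mV), positive for activation.
#' @return Normalized current in `[0, 1]`.
#' @export
boltzmann_activation <- function(v_mV, v_half, k) {
  1 / (1 + exp((v_half - v_mV) / k))
}

#' Fit a Boltzmann activation curve
#'
#' Nonlinear least squares of [boltzmann_activation()] to normalized tail
#' currents. Initial guesses: `V1/2` at the voltage whose response is
#' nearest 0.5, `k = 8` mV. Adding a constant to all voltages shifts the
#' fitted `V1/2` by that constant and leaves `k` unchanged.
#'
#' @param data data frame with columns `v_mV` and `i_norm`.
#' @return An `lc_boltzmann_fit` (see [tidy()] / [glance()]); when the
#'   optimizer fails or `k <= 0` at the optimum, a non-converged result with
#'   diagnostics rather than an error.
#' @export
fit_boltzmann <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("v_mV", "i_norm") %in% names(data)))
  if (nrow(data) < 4)
    stopf("lc_data_error", "need at least 4 voltage points")
  start <- list(v_half = data$v_mV[which.min(abs(data$i_norm - 0.5))], k = 8)
  fit <- tryCatch(
    minpack.lm::nlsLM(i_norm ~ 1 / (1 + exp((v_half - v_mV) / k)),
                      data = data, start = start,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(lc_fit_result("lc_boltzmann_fit", c(v_half = NA_real_, k = NA_real_),
                         c(v_half = NA_real_, k = NA_real_), NULL, data,
                         FALSE, conditionMessage(fit)))
  p <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, 2), names(p)))
  if (p[["k"]] <= 0)
    return(lc_fit_result("lc_boltzmann_fit", p, se, fit, data, FALSE,
                         "non-positive slope factor at optimum"))
  lc_fit_result("lc_boltzmann_fit", p, se, fit, data, TRUE)
}

#' Plateau-anchored Hill dose-response model
#'
#' `I/Icon(C) = s + (1 - s) / (1 + (C / IC50)^h)`: full current at zero
#' concentration, a residual plateau `s` at saturating inhibitor, and a
#' response of `(1 + s)/2` -- halfway between full current and plateau -- at
#' `C = IC50`. With `s = 0`, `h = 1` this is the standard one-site
#' inhibition curve.
#'
#' @param conc_uM concentration (uM).
#' @param ic50 half-maximal inhibitory concentration (uM).
#' @param h Hill coefficient.
#' @param s stable (plateau) residual current level, `0 <= s < 1`.
#' @return Residual current `I/Icon`.
#' @export
hill_residual <- function(conc_uM, ic50, h, s) {
  s + (1 - s) / (1 + (conc_uM / ic50)^h)
}

#' Fit a dose-response curve
#'
#' Least squares of [hill_residual()] with IC50 parameterized on the log
#' scale for stability. With only 3 distinct concentrations the plateau `s`
#' must be fixed via `fix_s`. Scaling all concentrations by a factor scales
#' the fitted IC50 by the same factor and leaves `h` and `s` unchanged.
#'
#' @param data data frame with columns `conc_uM` and `residual`
#'   (`I_treated / I_control`).
#' @param fix_s optional fixed plateau level.
#' @return An `lc_dose_fit` with parameters `ic50_uM`, `h`, `s`.
#'   Monotonically increasing responses are flagged as a fit failure.
#' @export
fit_dose_response <- function(data, fix_s = NULL) {
  data <- as_tibble(data)
  stopifnot(all(c("conc_uM", "residual") %in% names(data)))
  ncon <- length(unique(data$conc_uM))
  if (ncon < 3)
    stopf("lc_data_error", "need at least 3 distinct concentrations")
  if (ncon == 3 && is.null(fix_s))
    stopf("lc_config_error",
          "with only 3 concentrations the plateau s must be fixed (fix_s)")
  ord <- order(data$conc_uM)
  means <- tapply(data$residual[ord], data$conc_uM[ord], mean)
  if (all(diff(means) > 0)) {
    p <- c(ic50_uM = NA_real_, h = NA_real_, s = NA_real_)
    return(lc_fit_result("lc_dose_fit", p, p, NULL, data, FALSE,
                         "residual current increases with concentration"))
  }
  mid_target <- (1 + (fix_s %||% min(data$residual))) / 2
  start_ic50 <- data$conc_uM[which.min(abs(data$residual - mid_target))]
  fit <- tryCatch({
    if (is.null(fix_s)) {
      minpack.lm::nlsLM(
        residual ~ s + (1 - s) / (1 + (conc_uM / exp(log_ic50))^h),
        data = data,
        start = list(log_ic50 = log(start_ic50), h = 1,
                     s = max(min(data$residual) * 0.8, 1e-3)),
        lower = c(log_ic50 = -20, h = 0.05, s = 0),
        upper = c(log_ic50 = 20, h = 10, s = 0.999),
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                             maxiter = 500))
    } else {
      s_fixed <- fix_s
      minpack.lm::nlsLM(
        residual ~ s_fixed + (1 - s_fixed) / (1 + (conc_uM / exp(log_ic50))^h),
        data = data,
        start = list(log_ic50 = log(start_ic50), h = 1),
        lower = c(log_ic50 = -20, h = 0.05),
        upper = c(log_ic50 = 20, h = 10),
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                             maxiter = 500))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    p <- c(ic50_uM = NA_real_, h = NA_real_, s = NA_real_)
    return(lc_fit_result("lc_dose_fit", p, p, NULL, data, FALSE,
                         conditionMessage(fit)))
  }
  cf <- coef(fit)
  ic50 <- exp(cf[["log_ic50"]])
  p <- c(ic50_uM = ic50, h = cf[["h"]], s = fix_s %||% cf[["s"]])
  se_raw <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  se <- c(ic50_uM = unname(se_raw["log_ic50"]) * ic50,  # delta method
          h = unname(se_raw["h"]),
          s = if (is.null(fix_s)) unname(se_raw["s"]) else 0)
  lc_fit_result("lc_dose_fit", p, se, fit, data, TRUE)
}

#' Fit deactivation kinetics of a tail current
#'
#' Mono-exponential decay `I(t) = A exp(-t / tau) + C` fitted from the
#' current peak to the end of the trace, with `tau` parameterized on the
#' log scale so the fitted time constant is always positive. A
#' bi-exponential variant (amplitude-weighted tau reported) is available
#' explicitly, never chosen silently.
#'
#' @param data data frame with columns `t_ms` and `current`.
#' @param n_exp 1 (default) or 2 exponential components.
#' @return An `lc_deactivation_fit` with `tau_ms` (weighted for
#'   `n_exp = 2`), amplitude(s) and offset. Non-decaying traces are flagged
#'   as fit failures.
#' @export
fit_deactivation <- function(data, n_exp = 1) {
  data <- as_tibble(data)
  stopifnot(all(c("t_ms", "current") %in% names(data)),
            n_exp %in% c(1, 2))
  data <- dplyr::arrange(data, .data$t_ms)
  pk <- which.max(data$current)
  seg <- data[pk:nrow(data), ]
  if (nrow(seg) < 4 + 2 * (n_exp - 1) ||
      seg$current[nrow(seg)] >= seg$current[1]) {
    p <- c(tau_ms = NA_real_, A = NA_real_, C = NA_real_)
    return(lc_fit_result("lc_deactivation_fit", p, p, NULL, data, FALSE,
                         "trace does not decay"))
  }
  seg <- dplyr::mutate(seg, t0 = .data$t_ms - .data$t_ms[1])
  rng <- diff(range(seg$t_ms))
  fit <- tryCatch({
    if (n_exp == 1) {
      minpack.lm::nlsLM(current ~ A * exp(-t0 / exp(log_tau)) + C, data = seg,
                        start = list(A = seg$current[1] - min(seg$current),
                                     log_tau = log(rng / 3),
                                     C = min(seg$current)),
                        control = minpack.lm::nls.lm.control(
                          ftol = 1e-10, ptol = 1e-10, maxiter = 500))
    } else {
      minpack.lm::nlsLM(current ~ A1 * exp(-t0 / exp(log_tau1)) +
                          A2 * exp(-t0 / exp(log_tau2)) + C, data = seg,
                        start = list(A1 = (seg$current[1] - min(seg$current)) / 2,
                                     log_tau1 = log(rng / 10),
                                     A2 = (seg$current[1] - min(seg$current)) / 2,
                                     log_tau2 = log(rng / 2),
                                     C = min(seg$current)),
                        control = minpack.lm::nls.lm.control(
                          ftol = 1e-10, ptol = 1e-10, maxiter = 500))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    p <- c(tau_ms = NA_real_, A = NA_real_, C = NA_real_)
    return(lc_fit_result("lc_deactivation_fit", p, p, NULL, data, FALSE,
                         conditionMessage(fit)))
  }
  cf <- coef(fit)
  se_raw <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  if (n_exp == 1) {
    tau <- exp(cf[["log_tau"]])
    p <- c(tau_ms = tau, A = cf[["A"]], C = cf[["C"]])
    se <- c(tau_ms = unname(se_raw["log_tau"]) * tau,
            A = unname(se_raw["A"]), C = unname(se_raw["C"]))
  } else {
    t1 <- exp(cf[["log_tau1"]]); t2 <- exp(cf[["log_tau2"]])
    w <- abs(c(cf[["A1"]], cf[["A2"]]))
    p <- c(tau_ms = sum(w * c(t1, t2)) / sum(w),
           tau1_ms = t1, tau2_ms = t2,
           A1 = cf[["A1"]], A2 = cf[["A2"]], C = cf[["C"]])
    se <- setNames(rep(NA_real_, length(p)), names(p))
    se["tau1_ms"] <- unname(se_raw["log_tau1"]) * t1
    se["tau2_ms"] <- unname(se_raw["log_tau2"]) * t2
  }
  lc_fit_result("lc_deactivation_fit", p, se, fit, data, TRUE)
}

#' Control-minus-treated gating deltas and pIC50
#'
#' Pairs fitted gating parameters of matched variants and reports
#' `Delta = control - treated` for `V1/2` and deactivation tau, plus
#' `pIC50 = -log10(IC50 in molar)` when an IC50 (uM) column is present.
#'
#' @param control,treated data frames with a `variant` column and any of
#'   `v_half_mV`, `tau_ms`; `control` may also carry `ic50_uM`.
#' @return A tibble per variant: `delta_v_half_mV`, `delta_tau_ms`,
#'   `pic50` (when available).
#' @export
gating_deltas <- function(control, treated) {
  control <- as_tibble(control); treated <- as_tibble(treated)
  stopifnot("variant" %in% names(control), "variant" %in% names(treated))
  miss <- c(setdiff(control$variant, treated$variant),
            setdiff(treated$variant, control$variant))
  if (length(miss) > 0)
    stopf("lc_data_error", "unmatched variant labels: %s",
          paste(unique(miss), collapse = ", "))
  out <- dplyr::inner_join(control, treated, by = "variant",
                           suffix = c("_control", "_treated"))
  if (all(c("v_half_mV_control", "v_half_mV_treated") %in% names(out)))
    out$delta_v_half_mV <- out$v_half_mV_control - out$v_half_mV_treated
  if (all(c("tau_ms_control", "tau_ms_treated") %in% names(out)))
    out$delta_tau_ms <- out$tau_ms_control - out$tau_ms_treated
  ic50col <- intersect(c("ic50_uM", "ic50_uM_control"), names(out))
  if (length(ic50col) > 0)
    out$pic50 <- -log10(out[[ic50col[1]]] * 1e-6)
  out
}

#' Compare two binding free energies
#'
#' `DeltaDeltaG = DeltaG_closed - DeltaG_open` with the SD propagated in
#' quadrature; a negative value means the closed-state complex is the more
#' stable by that amount.
#'
#' @param dg_closed,dg_open binding free energies (kcal/mol).
#' @param sd_closed,sd_open their SDs (kcal/mol).
#' @return A one-row tibble: `ddg_kcal_mol`, `sd_kcal_mol`,
#'   `closed_stabilization_kcal_mol` (= `-ddg`).
#' @export
ddg_compare <- function(dg_closed, dg_open, sd_closed = 0, sd_open = 0) {
  ddg <- dg_closed - dg_open
  tibble(ddg_kcal_mol = ddg,
         sd_kcal_mol = sqrt(sd_closed^2 + sd_open^2),
         closed_stabilization_kcal_mol = -ddg)
}
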