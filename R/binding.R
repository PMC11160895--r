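new_fit_result <- function(parameters, stderr, residual_norm, converged,
                           model, notes = character(0)) {
  structure(list(parameters = parameters, stderr = stderr,
                 residual_norm = residual_norm, converged = converged,
                 model = model, notes = notes),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat("FitResult (", x$model, ")", if (!x$converged) " [NOT CONVERGED]",
      "\n", sep = "")
  for (p in names(x$parameters))
    cat(sprintf("  %-10s %.6g +/- %.3g\n", p, x$parameters[[p]],
                if (p %in% names(x$stderr)) x$stderr[[p]] else NA))
  cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

run_nls <- function(formula, data, start, lower = NULL, upper = NULL,
                    label = "model") {
  args <- list(formula = formula, data = data, start = start,
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
  if (!inherits(fit, "error")) return(fit)
  # rank-deficient solutions (e.g. a zero-amplitude component) make the
  # final nls-model construction fail on a singular gradient even though
  # the least-squares problem itself is fine; fall back to raw LM
  if (!grepl("singular gradient", conditionMessage(fit)))
    stop(label, " fit did not converge: ", conditionMessage(fit))
  rhs <- formula[[3]]
  obs <- eval(formula[[2]], data)
  par0 <- unlist(start)
  fn <- function(p) {
    obs - eval(rhs, c(as.list(data), as.list(setNames(p, names(par0)))))
  }
  out <- tryCatch(minpack.lm::nls.lm(
    par = par0, fn = fn,
    lower = if (is.null(lower)) rep(-Inf, length(par0)) else lower[names(par0)],
    upper = if (is.null(upper)) rep(Inf, length(par0)) else upper[names(par0)],
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(out, "error") || !(out$info %in% 1:4))
    stop(label, " fit did not converge")
  n <- length(obs); p <- length(par0)
  s2 <- out$deviance / max(n - p, 1)
  vc <- tryCatch(s2 * solve(out$hessian / 2), error = function(e) NULL)
  list(is_fallback = TRUE,
       coefficients = setNames(as.numeric(out$par), names(par0)),
       residuals = fn(out$par),
       se = if (is.null(vc)) setNames(rep(NA_real_, p), names(par0))
            else setNames(sqrt(pmax(diag(vc), 0)), names(par0)),
       convInfo = list(isConv = TRUE))
}

coef_of <- function(fit) {
  if (is.list(fit) && isTRUE(fit$is_fallback)) fit$coefficients
  else coef(fit)
}

resid_of <- function(fit) {
  if (is.list(fit) && isTRUE(fit$is_fallback)) fit$residuals
  else residuals(fit)
}

fit_se <- function(fit) {
  if (is.list(fit) && isTRUE(fit$is_fallback)) return(fit$se)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, length(coef(fit))))
  setNames(as.numeric(se), names(coef(fit)))
}

#' Construct a binding isotherm
#'
#' @param conc analyte concentrations, M (positive, strictly increasing per
#'   series).
#' @param response equilibrium responses (response units).
#' @param series optional replicate/series id.
#' @return data.frame of class `BindingIsotherm`.
#' @export
binding_isotherm <- function(conc, response, series = 1L) {
  stopifnot(length(conc) == length(response), all(conc > 0))
  d <- data.frame(conc = conc, response = response,
                  series = rep_len(series, length(conc)))
  for (s in unique(d$series)) {
    cs <- d$conc[d$series == s]
    if (any(diff(cs) <= 0))
      stop("concentrations must be strictly increasing within a series")
  }
  class(d) <- c("BindingIsotherm", "data.frame")
  d
}

#' Fit a 1:1 steady-state binding model
#'
#' Least-squares fit of R_eq(C) = R_max C / (K_D + C) to reference-
#' subtracted steady-state responses, the standard Langmuir analysis of
#' SPR equilibrium data. Replicate series share K_D and get per-series
#' R_max. A warning is attached when the fitted K_D exceeds the highest
#' tested concentration (extrapolated affinity).
#'
#' @param isotherm a [binding_isotherm()] data.frame (columns `conc` in M,
#'   `response`, optional `series`).
#' @return A `FitResult` with parameters `K_D` (M) and `R_max` (one per
#'   series).
#' @export
fit_steady_state <- function(isotherm) {
  d <- as.data.frame(isotherm)
  stopifnot(all(c("conc", "response") %in% names(d)))
  if (is.null(d$series)) d$series <- 1L
  if (length(unique(d$conc)) < 4 ||
      max(d$conc) / min(d$conc) < 10)
    stop("need >= 4 concentrations spanning >= 10-fold")
  d$series <- factor(d$series)
  ns <- nlevels(d$series)
  kd0 <- d$conc[which.min(abs(d$response - max(d$response) / 2))]
  if (ns == 1) {
    fit <- run_nls(response ~ Rmax * conc / (KD + conc), d,
                   start = list(KD = kd0, Rmax = max(d$response)),
                   lower = c(KD = 0, Rmax = 0), label = "steady-state")
    pars <- coef_of(fit)
    params <- c(K_D = unname(pars["KD"]), R_max = unname(pars["Rmax"]))
    se <- fit_se(fit); names(se) <- c("K_D", "R_max")
  } else {
    X <- model.matrix(~ series - 1, d)
    start <- c(list(KD = kd0),
               as.list(setNames(rep(max(d$response), ns),
                                paste0("Rmax", seq_len(ns)))))
    rhs <- paste(sprintf("Rmax%d * X[, %d]", seq_len(ns), seq_len(ns)),
                 collapse = " + ")
    fit <- run_nls(as.formula(paste0("response ~ (", rhs,
                                     ") * conc / (KD + conc)")),
                   d, start = start, label = "steady-state")
    pars <- coef_of(fit)
    params <- setNames(as.numeric(pars), sub("^KD$", "K_D",
                                             sub("^Rmax", "R_max_", names(pars))))
    se <- setNames(as.numeric(fit_se(fit)), names(params))
  }
  notes <- character(0)
  if (params[["K_D"]] > max(d$conc))
    notes <- "fitted K_D exceeds the highest tested concentration (extrapolated affinity)"
  if (length(notes)) warning(notes)
  new_fit_result(params, se,
                 residual_norm = sqrt(sum(resid_of(fit)^2)),
                 converged = fit$convInfo$isConv %||% TRUE,
                 model = "1:1 steady-state", notes = notes)
}

#' Construct a kinetic dissociation trace
#'
#' @param time time in seconds, strictly increasing, >= 10 points.
#' @param response response values.
#' @return data.frame of class `KineticTrace`.
#' @export
kinetic_trace <- function(time, response) {
  stopifnot(length(time) == length(response), length(time) >= 10,
            all(diff(time) > 0))
  d <- data.frame(time = time, response = response)
  class(d) <- c("KineticTrace", "data.frame")
  d
}

#' Fit single or biphasic exponential dissociation
#'
#' phases = 1: R(t) = A exp(-k_off t) + B.
#' phases = 2: R(t) = A (f exp(-k1 t) + (1 - f) exp(-k2 t)) + B with
#' k1 >= k2 and f in (0, 1); amplitudes constrained positive. The constant
#' offset B absorbs residual instrument baseline; fix it to 0 with
#' `fix_offset = TRUE` for strict replication of an offset-free model.
#'
#' @param trace a [kinetic_trace()] data.frame.
#' @param phases 1 or 2.
#' @param fix_offset force B = 0.
#' @return A `FitResult` with `k_off` (s^-1) (and `k2`, `fraction` for
#'   biphasic), `amplitude`, `offset`.
#' @export
fit_dissociation <- function(trace, phases = 1, fix_offset = FALSE) {
  d <- as.data.frame(trace)
  stopifnot(all(c("time", "response") %in% names(d)), phases %in% 1:2)
  d$t <- d$time - d$time[1]
  b0 <- if (fix_offset) 0 else min(d$response)
  a0 <- max(d$response) - b0
  span <- diff(range(d$t))
  k0 <- max(log(2) / (span / 3), 1e-6)
  if (phases == 1) {
    form <- if (fix_offset) response ~ A * exp(-k * t)
            else response ~ A * exp(-k * t) + B
    start <- if (fix_offset) list(A = a0, k = k0)
             else list(A = a0, k = k0, B = b0)
    lower <- if (fix_offset) c(A = 0, k = 1e-12)
             else c(A = 0, k = 1e-12, B = -Inf)
    fit <- run_nls(form, d, start, lower = lower, label = "dissociation")
    pars <- coef_of(fit)
    if (pars[["k"]] <= 0) stop("non-physical k_off <= 0")
    params <- c(k_off = unname(pars[["k"]]), amplitude = unname(pars[["A"]]),
                offset = if (fix_offset) 0 else unname(pars[["B"]]))
    se <- fit_se(fit)
    se <- c(k_off = unname(se["k"]), amplitude = unname(se["A"]),
            offset = if (fix_offset) NA_real_ else unname(se["B"]))
  } else {
    form <- if (fix_offset)
      response ~ A * (f * exp(-k1 * t) + (1 - f) * exp(-k2 * t))
    else response ~ A * (f * exp(-k1 * t) + (1 - f) * exp(-k2 * t)) + B
    start <- list(A = a0, f = 0.5, k1 = k0 * 5, k2 = k0 / 5)
    lower <- c(A = 0, f = 0, k1 = 1e-12, k2 = 1e-12)
    upper <- c(A = Inf, f = 1, k1 = Inf, k2 = Inf)
    if (!fix_offset) {
      start$B <- b0; lower <- c(lower, B = -Inf); upper <- c(upper, B = Inf)
    }
    fit <- run_nls(form, d, start, lower = lower, upper = upper,
                   label = "biphasic dissociation")
    pars <- coef_of(fit)
    k1 <- pars[["k1"]]; k2 <- pars[["k2"]]; f <- pars[["f"]]
    if (k1 < k2) { tmp <- k1; k1 <- k2; k2 <- tmp; f <- 1 - f }
    if (k1 <= 0) stop("non-physical rate <= 0")
    params <- c(k_off = k1, k2 = k2, fraction = f,
                amplitude = unname(pars[["A"]]),
                offset = if (fix_offset) 0 else unname(pars[["B"]]))
    se <- fit_se(fit)
    se <- c(k_off = unname(se["k1"]), k2 = unname(se["k2"]),
            fraction = unname(se["f"]), amplitude = unname(se["A"]),
            offset = if (fix_offset) NA_real_ else unname(se["B"]))
  }
  new_fit_result(params, se, sqrt(sum(resid_of(fit)^2)),
                 converged = fit$convInfo$isConv %||% TRUE,
                 model = sprintf("%d-phase exponential dissociation", phases))
}

#' Association rate from dissociation rate and affinity
#'
#' k_on = k_off / K_D, with first-order uncertainty propagation when both
#' inputs carry standard errors.
#'
#' @param k_off dissociation rate, s^-1 (> 0).
#' @param K_D equilibrium dissociation constant, M (> 0).
#' @param k_off_se,K_D_se optional standard errors.
#' @return list with `k_on` (M^-1 s^-1) and `k_on_se` (or `NA`).
#' @export
association_rate <- function(k_off, K_D, k_off_se = NULL, K_D_se = NULL) {
  if (k_off <= 0 || K_D <= 0) stop("k_off and K_D must be positive")
  k_on <- k_off / K_D
  se <- if (!is.null(k_off_se) && !is.null(K_D_se))
    k_on * sqrt((k_off_se / k_off)^2 + (K_D_se / K_D)^2) else NA_real_
  list(k_on = k_on, k_on_se = se)
}

#' Electrostatic destabilization from a pKa shift
#'
#' Delta-Delta-G = -2.303 R T (pKa_bound - pKa_free), evaluated with R in
#' cal/K/mol and returned in kcal/mol. Quantifies the free-energy penalty
#' of burying a titratable side chain (e.g. a histidine anchor) in a
#' hydrophobic pocket that suppresses its pKa.
#'
#' @param pka_bound,pka_free computed pKa values in the bound and free
#'   states.
#' @param temperature Kelvin (default 298.15).
#' @param gas_constant cal/K/mol (default 1.987).
#' @return Delta-Delta-G in kcal/mol.
#' @export
electrostatic_destabilization <- function(pka_bound, pka_free,
                                          temperature = 298.15,
                                          gas_constant = 1.987) {
  stopifnot(temperature > 0, gas_constant > 0)
  -2.303 * gas_constant * temperature * (pka_bound - pka_free) / 1000
}

#' Construct a DSF melt-derivative curve
#'
#' @param temperature degrees C, strictly increasing, >= 20 points.
#' @param signal d(F350/F330)/dT values.
#' @return data.frame of class `MeltCurve`.
#' @export
melt_curve <- function(temperature, signal) {
  stopifnot(length(temperature) == length(signal),
            length(temperature) >= 20, all(diff(temperature) > 0))
  d <- data.frame(temperature = temperature, signal = signal)
  class(d) <- c("MeltCurve", "data.frame")
  d
}

#' Fit a DSF first-derivative melt curve with 1 or 2 Gaussians
#'
#' The first derivative of the 350/330 nm fluorescence ratio peaks at each
#' unfolding transition; fitting a (bi-)Gaussian recovers the melting
#' temperature(s) T_m as the component centers (reported ascending).
#' Overlapping components (centers closer than the mean half-width) are
#' flagged in the notes.
#'
#' @param curve a [melt_curve()] data.frame.
#' @param components 1 or 2.
#' @return A `FitResult` with `T_m` (and `T_m_2`), `width` (Gaussian sigma,
#'   degrees C), `amplitude` per component.
#' @export
fit_melt_derivative <- function(curve, components = 2) {
  d <- as.data.frame(curve)
  stopifnot(all(c("temperature", "signal") %in% names(d)),
            components %in% 1:2)
  tm0 <- d$temperature[which.max(d$signal)]
  a0 <- max(d$signal)
  w0 <- diff(range(d$temperature)) / 15
  if (components == 1) {
    fit <- run_nls(signal ~ A * exp(-(temperature - Tm)^2 / (2 * w^2)), d,
                   start = list(A = a0, Tm = tm0, w = w0),
                   lower = c(A = 0, Tm = -Inf, w = 1e-6), label = "melt")
    pars <- coef_of(fit)
    params <- c(T_m = unname(pars[["Tm"]]), width = unname(pars[["w"]]),
                amplitude = unname(pars[["A"]]))
    se <- fit_se(fit)
    se <- c(T_m = unname(se["Tm"]), width = unname(se["w"]),
            amplitude = unname(se["A"]))
    notes <- character(0)
  } else {
    # second start center: strongest local maximum well separated from
    # the first; blended transitions fall back to an offset start and let
    # the optimizer split the merged peak
    y <- d$signal; n <- length(y)
    is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
                FALSE)
    sep_ok <- is_max & abs(d$temperature - tm0) > 1.5 * w0
    tm1 <- if (any(sep_ok))
      d$temperature[sep_ok][which.max(y[sep_ok])] else tm0 + w0
    amp_near <- function(tm) max(y[abs(d$temperature - tm) <= w0 / 2])
    starts <- list(tm = sort(c(tm0, tm1)))
    fit <- run_nls(
      signal ~ A1 * exp(-(temperature - T1)^2 / (2 * w1^2)) +
        A2 * exp(-(temperature - T2)^2 / (2 * w2^2)), d,
      start = list(A1 = amp_near(starts$tm[1]), T1 = starts$tm[1], w1 = w0,
                   A2 = amp_near(starts$tm[2]), T2 = starts$tm[2], w2 = w0),
      lower = c(A1 = 0, T1 = -Inf, w1 = 1e-6, A2 = 0, T2 = -Inf, w2 = 1e-6),
      label = "bi-Gaussian melt")
    pars <- coef_of(fit)
    ord <- order(c(pars[["T1"]], pars[["T2"]]))
    Tm <- c(pars[["T1"]], pars[["T2"]])[ord]
    wd <- c(pars[["w1"]], pars[["w2"]])[ord]
    am <- c(pars[["A1"]], pars[["A2"]])[ord]
    params <- c(T_m = Tm[1], T_m_2 = Tm[2], width = wd[1], width_2 = wd[2],
                amplitude = am[1], amplitude_2 = am[2])
    se_raw <- fit_se(fit)
    se <- setNames(c(se_raw[c("T1", "T2")][ord], se_raw[c("w1", "w2")][ord],
                     se_raw[c("A1", "A2")][ord]), names(params))
    notes <- if (abs(Tm[2] - Tm[1]) < mean(wd))
      "overlapping components: centers closer than the mean half-width"
    else character(0)
  }
  new_fit_result(params, se, sqrt(sum(resid_of(fit)^2)),
                 converged = fit$convInfo$isConv %||% TRUE,
                 model = sprintf("%d-Gaussian melt derivative", components),
                 notes = notes)
}
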