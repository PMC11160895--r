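#' Construct a 1D spectrum
#'
#' @param ppm chemical-shift axis (strictly monotone; stored descending,
#'   NMR convention).
#' @param intensity intensities (finite).
#' @return data.frame of class `Spectrum1D`.
#' @export
spectrum1d <- function(ppm, intensity) {
  stopifnot(length(ppm) == length(intensity), all(is.finite(intensity)))
  dppm <- diff(ppm)
  if (!(all(dppm > 0) || all(dppm < 0)))
    stop("ppm axis must be strictly monotone")
  if (all(dppm > 0)) { ppm <- rev(ppm); intensity <- rev(intensity) }
  d <- data.frame(ppm = ppm, intensity = intensity)
  class(d) <- c("Spectrum1D", "data.frame")
  d
}

lorentzian <- function(x, center, fwhm, height) {
  height * (fwhm / 2)^2 / ((x - center)^2 + (fwhm / 2)^2)
}

# area of a Lorentzian from height and FWHM: integral = pi * height * fwhm / 2
lorentzian_area <- function(height, fwhm) pi * height * fwhm / 2

# greedy local-maxima picking above 5x MAD, with a minimum separation so
# that noise ripples on one broad line do not claim several picks
pick_peaks <- function(spec, n_peaks, min_sep = NULL) {
  y <- spec$intensity
  thr <- median(y) + 5 * mad(y)
  n <- length(y)
  if (is.null(min_sep)) min_sep <- abs(diff(range(spec$ppm))) / 10
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE) & y > thr
  cand <- which(is_max)
  cand <- c(cand[order(y[cand], decreasing = TRUE)],
            setdiff(order(y, decreasing = TRUE), cand))
  picked <- numeric(0)
  for (i in cand) {
    if (length(picked) == n_peaks) break
    if (!length(picked) || all(abs(spec$ppm[i] - picked) >= min_sep))
      picked <- c(picked, spec$ppm[i])
  }
  if (length(picked) < n_peaks)
    picked <- c(picked, spec$ppm[order(y, decreasing = TRUE)][
      seq_len(n_peaks - length(picked))])
  picked
}

#' Deconvolve a 1D spectrum into Lorentzian peaks
#'
#' Least-squares fit of a sum of `n_peaks` Lorentzians plus a constant
#' baseline. Peak areas are integrated analytically from fitted height and
#' width (area = pi h w / 2) and reported with their fractions of the
#' fitted total. Initial centers come from local-maxima picking above 5x
#' the median absolute deviation, or can be supplied. The number of peaks
#' is user-chosen, not automatic.
#'
#' @param spec a [spectrum1d()] data.frame.
#' @param n_peaks number of Lorentzian components (>= 1).
#' @param init optional numeric vector of initial centers (ppm).
#' @return list with `peaks` (data.frame: center, fwhm, height, area,
#'   fraction; sorted by descending ppm), `baseline`, `fit` (a
#'   `FitResult`).
#' @export
fit_lorentzians <- function(spec, n_peaks, init = NULL) {
  d <- as.data.frame(spec)
  stopifnot(n_peaks >= 1)
  centers0 <- if (is.null(init)) pick_peaks(d, n_peaks) else init
  stopifnot(length(centers0) == n_peaks)
  step <- abs(median(diff(d$ppm)))
  w0 <- max(5 * step, abs(diff(range(d$ppm))) / 200)
  start <- list(); lower <- numeric(0); upper <- numeric(0)
  for (i in seq_len(n_peaks)) {
    h0 <- max(d$intensity[which.min(abs(d$ppm - centers0[i]))], 1e-6)
    start[[paste0("c", i)]] <- centers0[i]
    start[[paste0("w", i)]] <- w0
    start[[paste0("h", i)]] <- h0
    lower <- c(lower, setNames(c(min(d$ppm), step / 2, 0),
                               paste0(c("c", "w", "h"), i)))
    upper <- c(upper, setNames(c(max(d$ppm), abs(diff(range(d$ppm))), Inf),
                               paste0(c("c", "w", "h"), i)))
  }
  start$B <- median(d$intensity)
  lower <- c(lower, B = -Inf); upper <- c(upper, B = Inf)
  terms <- paste(sprintf("h%d * (w%d/2)^2 / ((ppm - c%d)^2 + (w%d/2)^2)",
                         seq_len(n_peaks), seq_len(n_peaks),
                         seq_len(n_peaks), seq_len(n_peaks)),
                 collapse = " + ")
  fit <- run_nls(as.formula(paste("intensity ~", terms, "+ B")), d, start,
                 lower = lower, upper = upper, label = "Lorentzian")
  pars <- coef_of(fit)
  pk <- data.frame(
    center = pars[paste0("c", seq_len(n_peaks))],
    fwhm = pars[paste0("w", seq_len(n_peaks))],
    height = pars[paste0("h", seq_len(n_peaks))])
  pk$area <- lorentzian_area(pk$height, pk$fwhm)
  pk <- pk[order(pk$center, decreasing = TRUE), ]
  rownames(pk) <- NULL
  if (n_peaks > 1) {
    sep <- abs(diff(pk$center))
    if (any(sep < pmin(head(pk$fwhm, -1), tail(pk$fwhm, -1)) / 4))
      warning("peaks collapsed onto nearly the same center; effective peak count ",
              n_peaks - sum(sep < pmin(head(pk$fwhm, -1), tail(pk$fwhm, -1)) / 4))
  }
  pk$fraction <- pk$area / sum(pk$area)
  res <- new_fit_result(
    setNames(as.numeric(pars), names(pars)), fit_se(fit),
    sqrt(sum(resid_of(fit)^2)),
    converged = fit$convInfo$isConv %||% TRUE,
    model = sprintf("%d-Lorentzian deconvolution", n_peaks))
  list(peaks = pk, baseline = unname(pars[["B"]]), fit = res)
}

#' Area fractions of a fitted peak set
#'
#' @param peaks data.frame with an `area` column (as from
#'   [fit_lorentzians()]), or a numeric vector of areas.
#' @return numeric fractions summing to 1.
#' @export
area_fractions <- function(peaks) {
  areas <- if (is.data.frame(peaks)) peaks$area else as.numeric(peaks)
  stopifnot(length(areas) >= 1)
  if (all(areas == 0)) stop("all-zero areas")
  areas / sum(areas)
}

#' Construct a slow-exchange model
#'
#' States with equilibrium populations and chemical shifts, plus pairwise
#' exchange rates. Detailed balance (p_i k_ij = p_j k_ji) is enforced at
#' construction: supply the upper-triangle rates k_ij (i < j, rate from
#' state i to state j); the reverse rates are derived.
#'
#' @param populations equilibrium populations (will be normalized to sum 1).
#' @param shifts chemical shifts, ppm, one per state.
#' @param rates either an n x n matrix whose upper triangle holds k_ij
#'   (s^-1), or a single rate applied to every pair.
#' @return An `ExchangeModel`: list with `p`, `shifts`, `k` (full rate
#'   matrix, zero diagonal).
#' @export
exchange_model <- function(populations, shifts, rates) {
  p <- populations / sum(populations)
  n <- length(p)
  stopifnot(length(shifts) == n, all(p >= 0))
  k <- matrix(0, n, n)
  if (is.matrix(rates)) {
    stopifnot(nrow(rates) == n, ncol(rates) == n)
    k[upper.tri(k)] <- rates[upper.tri(rates)]
  } else {
    stopifnot(length(rates) == 1)
    k[upper.tri(k)] <- rates
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (p[j] > 0) k[j, i] <- p[i] * k[i, j] / p[j]
      else k[j, i] <- 0
    }
  }
  stopifnot(all(k >= 0))
  structure(list(p = p, shifts = shifts, k = k), class = "ExchangeModel")
}

exchange_generator <- function(model) {
  k <- model$k
  diag(k) <- 0
  q <- k
  diag(q) <- -rowSums(k)
  q  # q[i, j]: rate from state i to state j; rows sum to 0
}

#' Simulate NMR saturation transfer (CEST-style) between exchanging states
#'
#' Magnetization-exchange kinetics with the irradiated state clamped to
#' zero: dM_i/dt = -(sum_j k_ij) M_i + sum_j k_ji M_j, starting from the
#' equilibrium populations, integrated over the saturation time. Exchange
#' into the saturated state destroys magnetization; the returned residual
#' M_i(t_sat) / p_i of each non-irradiated state drops below 1 whenever it
#' exchanges (directly or indirectly) with the irradiated one. Relaxation
#' is omitted; an optional uniform decay rate can be supplied.
#'
#' @param model an [exchange_model()].
#' @param irradiated index of the saturated state.
#' @param t_sat saturation time, s.
#' @param decay optional uniform decay rate (s^-1) applied to all states
#'   (default 0).
#' @param bandwidth irradiation half-bandwidth in ppm used only to warn if
#'   another peak center falls inside the irradiation window (default 0.5).
#' @return numeric vector of residual intensity fractions per state (the
#'   irradiated state reports 0).
#' @export
simulate_saturation_transfer <- function(model, irradiated, t_sat,
                                         decay = 0, bandwidth = 0.5) {
  stopifnot(inherits(model, "ExchangeModel"),
            irradiated %in% seq_along(model$p), t_sat >= 0)
  others <- setdiff(seq_along(model$p), irradiated)
  if (any(abs(model$shifts[others] - model$shifts[irradiated]) <= bandwidth))
    warning("another peak center lies inside the irradiation bandwidth; ",
            "selective saturation is not clean")
  q <- exchange_generator(model)
  # clamped system: drop the irradiated row/column but keep full outflow
  # on the diagonal (magnetization entering the saturated state is lost)
  qs <- q[others, others, drop = FALSE] - diag(decay, length(others))
  m0 <- model$p[others]
  mt <- as.numeric(Matrix::expm(t(qs) * t_sat) %*% m0)
  out <- numeric(length(model$p))
  out[others] <- ifelse(model$p[others] > 0, mt / model$p[others], 0)
  out[irradiated] <- 0
  out
}

#' Predict EXSY cross-peak fractions
#'
#' Matrix exponential of the exchange generator over the mixing time:
#' entry (i, j) is the fraction of magnetization starting in state i that
#' is detected at the frequency of state j. Rows sum to 1 (magnetization
#' conservation; relaxation omitted). Off-diagonal entries above a
#' detection threshold correspond to observable cross-peaks; zero exchange
#' yields the identity matrix (no cross-peaks).
#'
#' @param model an [exchange_model()].
#' @param mixing_time mixing time, s (> 0).
#' @return n x n matrix of transfer fractions.
#' @export
predict_exsy_crosspeaks <- function(model, mixing_time) {
  stopifnot(inherits(model, "ExchangeModel"), mixing_time > 0)
  q <- exchange_generator(model)
  as.matrix(Matrix::expm(q * mixing_time))
}
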