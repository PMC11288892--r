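# DSF melting-curve analysis: two-state unfolding model with linear
# pre/post-transition baselines, nonlinear least-squares Tm extraction,
# and derivative-based multi-transition detection.

#' Two-state unfolding model with linear baselines
#'
#' `S(T) = ((Sf + mf T) + (Su + mu T) exp(x)) / (1 + exp(x))` with
#' `x = (dHm / (R T)) ((T - Tm) / Tm)` and temperature in kelvin
#' internally.  `Sf`, `Su` are the folded/unfolded signals at 0 K, `mf`,
#' `mu` the baseline slopes (per K), `Tm` the melting temperature and
#' `dHm` the unfolding enthalpy at `Tm` (J/mol); `R = 8.314` J/(K mol) is
#' fixed.  Evaluated through the logistic function, so it cannot overflow.
#'
#' @param temp_c temperatures in degC.
#' @param Sf,Su,mf,mu,Tm_C,dHm model parameters (`Tm_C` in degC).
#' @return signal values.
#' @export
two_state_model <- function(temp_c, Sf, Su, mf, mu, Tm_C, dHm) {
  tk <- temp_c + KELVIN
  if (any(tk <= 0)) stop("temperatures must be above 0 K")
  tmk <- Tm_C + KELVIN
  x <- (dHm / (R_GAS * tk)) * ((tk - tmk) / tmk)
  w <- stats::plogis(x)                # fraction unfolded
  (Sf + mf * tk) * (1 - w) + (Su + mu * tk) * w
}

#' Min-max scale a melting curve
#'
#' `x' = (x - min(x)) / (max(x) - min(x))`; idempotent; a constant curve
#' is an error (it cannot be fitted).
#'
#' @param x raw fluorescence values.
#' @return scaled values with min exactly 0 and max exactly 1.
#' @export
scale_curve <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (rng[2] - rng[1] <= 0) stop("constant curve cannot be scaled")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Fit the two-state unfolding model to a scaled melting curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) on [two_state_model()].
#' Initialisation: `Tm` from [derivative_tm()] (mid-range fallback),
#' `dHm = 200` kJ/mol, baselines from linear fits of the first/last 15% of
#' points.  Bounds: `Tm` inside the data range, `dHm` in [10, 2000]
#' kJ/mol.  Up to 3 starts (jittered Tm) before giving up.  Replicates
#' may be supplied as extra rows with repeated temperatures; they are fit
#' jointly with shared parameters.
#'
#' @param temperature_c temperatures (degC), >= 20 points spanning the
#'   transition.
#' @param signal scaled signal (use [scale_curve()] first for raw data).
#' @return object of class `dsf_fit`: `par` (named estimates incl.
#'   `Tm_C`), `se`, `rss`, `rss_flat`, `converged`, plus data for the
#'   methods; on total failure `converged = FALSE` and no estimates.
#' @export
fit_two_state <- function(temperature_c, signal) {
  ok <- is.finite(temperature_c) & is.finite(signal)
  tc <- temperature_c[ok]; y <- signal[ok]
  if (length(y) < 20L) stop("need at least 20 points to fit a melting curve")
  o <- order(tc); tc <- tc[o]; y <- y[o]
  tk <- tc + KELVIN
  n_edge <- max(3L, ceiling(0.15 * length(y)))
  lo <- seq_len(n_edge); hi <- seq(length(y) - n_edge + 1L, length(y))
  cf_lo <- stats::coef(stats::lm(y[lo] ~ tk[lo]))
  cf_hi <- stats::coef(stats::lm(y[hi] ~ tk[hi]))
  dtm <- tryCatch(derivative_tm(tc, y), error = function(e) NULL)
  tm0 <- if (!is.null(dtm) && length(dtm$tm)) dtm$tm[1] else mean(range(tc))
  rss_flat <- sum((y - mean(y))^2)
  fit <- NULL
  for (jit in c(0, -5, 5)) {
    start <- list(Sf = unname(cf_lo[1]), mf = unname(cf_lo[2]),
                  Su = unname(cf_hi[1]), mu = unname(cf_hi[2]),
                  Tm_C = min(max(tm0 + jit, min(tc) + 1), max(tc) - 1),
                  dHm = 2e5)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ two_state_model(tc, Sf, Su, mf, mu, Tm_C, dHm),
        start = start,
        lower = c(Sf = -Inf, mf = -Inf, Su = -Inf, mu = -Inf,
                  Tm_C = min(tc), dHm = 1e4),
        upper = c(Sf = Inf, mf = Inf, Su = Inf, mu = Inf,
                  Tm_C = max(tc), dHm = 2e6),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(converged = FALSE, par = NULL, rss = NA_real_,
                          rss_flat = rss_flat), class = "dsf_fit"))
  }
  par <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(par)))
  rss <- sum(stats::resid(fit)^2)
  structure(list(converged = TRUE, par = par, se = se, rss = rss,
                 rss_flat = rss_flat, temperature_c = tc, signal = y,
                 nls = fit), class = "dsf_fit")
}

#' @export
print.dsf_fit <- function(x, ...) {
  if (!x$converged) { cat("dsf_fit: did not converge\n"); return(invisible(x)) }
  cat(sprintf("dsf_fit: Tm = %.2f degC, dHm = %.0f kJ/mol, RSS = %.4g\n",
              x$par[["Tm_C"]], x$par[["dHm"]] / 1000, x$rss))
  invisible(x)
}

#' @export
coef.dsf_fit <- function(object, ...) object$par

#' @export
summary.dsf_fit <- function(object, ...) {
  print(object)
  if (object$converged) {
    print(data.frame(estimate = object$par, std_error = object$se))
  }
  invisible(object)
}

#' @export
predict.dsf_fit <- function(object, temperature_c = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  if (is.null(temperature_c)) temperature_c <- object$temperature_c
  p <- as.list(object$par)
  two_state_model(temperature_c, p$Sf, p$Su, p$mf, p$mu, p$Tm_C, p$dHm)
}

#' @export
plot.dsf_fit <- function(x, ...) {
  plot(x$temperature_c, x$signal, pch = 16, cex = 0.5, col = "grey50",
       xlab = "temperature (degC)", ylab = "scaled signal", ...)
  if (x$converged) {
    tt <- seq(min(x$temperature_c), max(x$temperature_c), length.out = 400)
    graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
    graphics::abline(v = x$par[["Tm_C"]], lty = 2)
  }
  invisible(x)
}

#' Melting temperature(s) from the curve derivative
#'
#' Smooths the signal with a centred 5-point moving average, takes a
#' central-difference derivative, and reports the temperatures of local
#' maxima of |dS/dT| with prominence above `prominence` — multiple maxima
#' indicate multiple transitions (e.g. two-domain proteins).
#'
#' @param temperature_c temperatures (degC), >= 5 points.
#' @param signal scaled signal.
#' @param smooth moving-average window (odd, default 5).
#' @param prominence minimal peak prominence in derivative units
#'   (scaled signal per degC).
#' @return list: `tm` (peak temperatures, highest peak first),
#'   `prominence`, `derivative` (data.frame for inspection).
#' @export
derivative_tm <- function(temperature_c, signal, smooth = 5L,
                          prominence = 0.05) {
  ok <- is.finite(temperature_c) & is.finite(signal)
  tc <- temperature_c[ok]; y <- signal[ok]
  if (length(y) < 5L) stop("need at least 5 points")
  o <- order(tc); tc <- tc[o]; y <- y[o]
  if (anyDuplicated(tc)) {  # replicate curves: average per temperature
    y <- as.numeric(tapply(y, tc, mean)); tc <- sort(unique(tc))
  }
  ys <- stats::filter(y, rep(1 / smooth, smooth), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(tc)
  d <- numeric(n)
  d[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / (tc[3:n] - tc[1:(n - 2)])
  d[1] <- d[2]; d[n] <- d[n - 1]
  a <- abs(as.numeric(d))
  # local maxima with simple prominence: height above the higher of the
  # two bracketing minima towards taller neighbours
  peaks <- which(diff(sign(diff(a))) < 0) + 1L
  prom <- vapply(peaks, function(i) {
    lft <- a[seq_len(i)]; rgt <- a[i:length(a)]
    hl <- which(lft > a[i]); hr <- which(rgt > a[i])
    base_l <- min(lft[max(hl, 1L):i]); base_r <- min(rgt[1L:(if (length(hr)) min(hr) else length(rgt))])
    a[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= prominence
  tm <- tc[peaks[keep]][order(a[peaks[keep]], decreasing = TRUE)]
  list(tm = tm, prominence = prom[keep][order(a[peaks[keep]], decreasing = TRUE)],
       derivative = data.frame(temperature_C = tc, dS_dT = as.numeric(d)))
}
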