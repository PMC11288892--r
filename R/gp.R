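# Exact Gaussian-process regression with a constant mean, squared
# exponential kernel and Gaussian likelihood.  Hyperparameters (constant
# mean c, signal variance sf2, lengthscale ell, noise variance sn2) are
# found by maximising the exact marginal log likelihood with analytic
# gradients (L-BFGS-B on log-variances / log-lengthscale).  Data sets here
# are tiny (<= ~40 points per peptide) so everything is dense Cholesky.

GP_JITTER <- 1e-10

# Negative MLL and gradient at theta = (c, log sf2, log ell, log sn2).
# d2 is the precomputed squared distance matrix of the inputs.
gp_nmll <- function(theta, y, d2, fixed_sn2 = NULL) {
  n <- length(y)
  cmean <- theta[1]; sf2 <- exp(theta[2]); ell <- exp(theta[3])
  sn2 <- if (is.null(fixed_sn2)) exp(theta[4]) else fixed_sn2
  A <- exp(-d2 / (2 * ell^2))
  K <- sf2 * A + diag(sn2 + GP_JITTER, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, length(theta))))
  r <- y - cmean
  alpha <- backsolve(ch, forwardsolve(t(ch), r))
  nmll <- 0.5 * sum(r * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(ch)
  W <- alpha %*% t(alpha) - Kinv          # dMLL/dK = 0.5 * W
  dK_sf2 <- sf2 * A                        # d/d log sf2
  dK_ell <- sf2 * A * (d2 / ell^2)         # d/d log ell
  g_c <- -sum(alpha)
  g_sf2 <- -0.5 * sum(W * dK_sf2)
  g_ell <- -0.5 * sum(W * dK_ell)
  grad <- c(g_c, g_sf2, g_ell)
  if (is.null(fixed_sn2)) grad <- c(grad, -0.5 * sn2 * sum(diag(W)))
  list(value = nmll, grad = grad)
}

#' Fit a Gaussian-process thermal profile
#'
#' Exact GP regression of (scaled) peptide intensity on temperature with a
#' constant mean, squared exponential kernel `k(t, t') = sf2 *
#' exp(-(t-t')^2 / (2 ell^2))` and Gaussian observation noise.
#' Hyperparameters maximise the marginal log likelihood; on optimizer
#' failure a second start with a long lengthscale is tried, after which the
#' fit is flagged unfit.  A lengthscale floor of 1 degC prevents the kernel
#' from chasing replicate noise (the gradient spacing is 3.5-4.9 degC).
#'
#' @param temps temperatures (degC), >= 4 values (replicate observations
#'   repeat temperatures).
#' @param values observed (typically min-max scaled) intensities.
#' @param fixed_noise_var optional fixed noise variance (skips learning it).
#' @param ell_init initial lengthscale(s) tried in order (degC).
#' @param maxit L-BFGS-B iteration cap.
#' @return object of class `gp_profile`: hyperparameters, marginal log
#'   likelihood, residual sum of squares, and the cached solves needed by
#'   [predict.gp_profile()].
#' @export
fit_gp <- function(temps, values, fixed_noise_var = NULL,
                   ell_init = c(10, 30), maxit = 1000L) {
  ok <- is.finite(temps) & is.finite(values)
  temps <- as.numeric(temps[ok]); values <- as.numeric(values[ok])
  if (length(values) < 4L) stop("need at least 4 observations for a GP fit")
  d2 <- outer(temps, temps, "-")^2
  v <- stats::var(values)
  if (!is.finite(v) || v < 1e-12) v <- 1e-12
  lower <- c(-Inf, log(1e-10), log(1), log(1e-8))
  upper <- c(Inf, log(1e4), log(500), log(1e2))
  if (!is.null(fixed_noise_var)) { lower <- lower[1:3]; upper <- upper[1:3] }
  best <- NULL
  init_mll <- NA_real_
  for (ell0 in ell_init) {
    theta0 <- c(mean(values), log(v), log(max(1, ell0)))
    if (is.null(fixed_noise_var)) theta0 <- c(theta0, log(0.1 * v))
    f0 <- gp_nmll(theta0, values, d2, fixed_noise_var)
    if (is.na(init_mll)) init_mll <- -f0$value
    opt <- tryCatch(
      stats::optim(theta0,
                   fn = function(th) gp_nmll(th, values, d2, fixed_noise_var)$value,
                   gr = function(th) gp_nmll(th, values, d2, fixed_noise_var)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = 1e8)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9) {
      if (is.null(best) || opt$value < best$value) best <- opt
      if (opt$convergence == 0) break
    }
  }
  if (is.null(best)) {
    return(structure(list(unfit = TRUE, n = length(values)),
                     class = "gp_profile"))
  }
  th <- best$par
  cmean <- th[1]; sf2 <- exp(th[2]); ell <- exp(th[3])
  sn2 <- if (is.null(fixed_noise_var)) exp(th[4]) else fixed_noise_var
  K <- sf2 * exp(-d2 / (2 * ell^2)) + diag(sn2 + GP_JITTER, length(values))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), values - cmean))
  pred_train <- cmean + (sf2 * exp(-d2 / (2 * ell^2))) %*% alpha
  fit <- structure(list(
    unfit = FALSE,
    mean_const = cmean, signal_var = sf2, lengthscale = ell, noise_var = sn2,
    mll = -best$value, mll_init = init_mll,
    rss = sum((values - pred_train)^2),
    temps = temps, values = values, chol = ch, alpha = as.numeric(alpha),
    n = length(values)), class = "gp_profile")
  fit
}

#' @export
print.gp_profile <- function(x, ...) {
  if (isTRUE(x$unfit)) { cat("gp_profile: unfit (optimizer failure)\n"); return(invisible(x)) }
  cat(sprintf("gp_profile: n=%d  mean=%.3f  signal_var=%.4g  lengthscale=%.2f degC  noise_var=%.4g\n",
              x$n, x$mean_const, x$signal_var, x$lengthscale, x$noise_var))
  cat(sprintf("  MLL=%.3f  RSS=%.4g\n", x$mll, x$rss))
  invisible(x)
}

#' Predict a fitted thermal profile with a confidence band
#'
#' Posterior mean and a band of mean +/- 2 posterior standard deviations,
#' evaluated on `grid`.  By default the band is the posterior of the
#' observation distribution (latent-function variance plus learned noise
#' variance), which is the band the Gaussian likelihood implies and the
#' one the non-overlap scoring is calibrated on; `include_noise = FALSE`
#' gives the latent-function band.  Extrapolation outside 25-95 degC is
#' refused.
#'
#' @param object a `gp_profile` from [fit_gp()].
#' @param grid temperatures (degC) at which to evaluate.
#' @param include_noise add the noise variance to the band (default `TRUE`).
#' @param ... unused.
#' @return object of class `profile_curve`: list with `grid`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @export
predict.gp_profile <- function(object, grid = scoring_grid(),
                               include_noise = TRUE, ...) {
  if (isTRUE(object$unfit)) stop("cannot predict from an unfit gp_profile")
  if (any(grid < 25 | grid > 95)) stop("prediction grid outside [25, 95] degC")
  ks <- object$signal_var *
    exp(-outer(grid, object$temps, "-")^2 / (2 * object$lengthscale^2))
  mu <- object$mean_const + as.numeric(ks %*% object$alpha)
  v <- backsolve(object$chol, forwardsolve(t(object$chol), t(ks)))
  s2 <- pmax(object$signal_var - colSums(v * t(ks)), 1e-12)
  if (include_noise) s2 <- s2 + object$noise_var
  s <- sqrt(s2)
  structure(list(grid = as.numeric(grid), mean = mu, sd = s,
                 lower = mu - 2 * s, upper = mu + 2 * s),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("profile_curve: %d points on [%.1f, %.1f] degC, mean range [%.3f, %.3f]\n",
              length(x$grid), min(x$grid), max(x$grid), min(x$mean), max(x$mean)))
  invisible(x)
}

#' @export
plot.profile_curve <- function(x, add = FALSE, col = "grey30",
                               band_col = grDevices::adjustcolor(col, 0.25),
                               ylim = NULL, ...) {
  if (!add) {
    if (is.null(ylim)) ylim <- range(x$lower, x$upper)
    plot(x$grid, x$mean, type = "n", xlab = "temperature (degC)",
         ylab = "scaled intensity", ylim = ylim, ...)
  }
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$lower, rev(x$upper)),
                    border = NA, col = band_col)
  graphics::lines(x$grid, x$mean, col = col, lwd = 2)
  invisible(x)
}
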