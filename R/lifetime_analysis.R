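#' Fractional amplitudes of a multiexponential decay
#'
#' Converts raw amplitudes to intensity-fraction weights:
#' `beta_i = alpha_i tau_i / sum_j alpha_j tau_j`, which sum to 1 exactly.
#'
#' @param alpha amplitudes (same length as `tau`, not all zero).
#' @param tau lifetimes, ps, > 0.
#' @return numeric vector of fractional amplitudes.
#' @export
fractional_amplitudes <- function(alpha, tau) {
  if (length(alpha) != length(tau)) stop("'alpha' and 'tau' lengths differ")
  if (any(tau <= 0)) stop("lifetimes must be > 0")
  s <- sum(alpha * tau)
  if (s <= 0) stop("sum(alpha * tau) must be > 0")
  alpha * tau / s
}

#' Population-weighted mean fluorescence lifetime
#'
#' `tau_pop = sum_i beta_i tau_i` with `beta` the fractional (intensity)
#' amplitudes. The printed per-component percentages of a multiexponential
#' fluorescence-decay fit are interpreted as these fractional amplitudes.
#'
#' @param beta fractional amplitudes summing to 1 (tolerance 1e-6).
#' @param tau lifetimes, ps, > 0.
#' @return mean lifetime, ps.
#' @export
mean_lifetime_population <- function(beta, tau) {
  if (length(beta) != length(tau)) stop("'beta' and 'tau' lengths differ")
  if (any(tau <= 0)) stop("lifetimes must be > 0")
  if (abs(sum(beta) - 1) > 1e-6)
    stop("fractional amplitudes must sum to 1 (got ", sum(beta), ")")
  sum(beta * tau)
}

#' Amplitude-weighted mean decay lifetime
#'
#' `tau_avg = sum(tau_n A_n) / sum(A_n)`, the amplitude weighting used for
#' decay-associated spectra from streak-camera global analysis.
#'
#' @param amplitudes relative amplitudes `A_n` (sum must be nonzero).
#' @param tau lifetimes, ps.
#' @return mean lifetime, ps.
#' @export
mean_lifetime_amplitude <- function(amplitudes, tau) {
  if (length(amplitudes) != length(tau)) stop("lengths differ")
  s <- sum(amplitudes)
  if (s == 0) stop("amplitude sum is zero")
  sum(tau * amplitudes) / s
}

# discrete convolution of a (normalized) IRF histogram with a decay model
# on the same uniform channel grid; returns the first n channels
convolve_irf <- function(irf, model) {
  n <- length(irf)
  np <- stats::nextn(2L * n, 2)
  x <- c(irf, rep(0, np - n))
  y <- c(model, rep(0, np - n))
  out <- Re(stats::fft(stats::fft(x) * stats::fft(y), inverse = TRUE)) / np
  out[seq_len(n)]
}

# IRF (x) exp(-t/tau) evaluated at the channel times, with the quadrature
# carried out on an `os`-fold oversampled grid (spline-interpolated IRF);
# plain channel-rate sampling biases tau by ~1% when tau is only a few
# channels wide
convolve_irf_exp <- function(irf, t, tau, os = 8L) {
  n <- length(t)
  dt <- t[2] - t[1]
  tf <- seq(t[1], t[n], by = dt / os)
  irf_f <- stats::spline(t, irf, xout = tf)$y
  irf_f <- pmax(irf_f, 0)
  out_f <- convolve_irf(irf_f / sum(irf_f), exp(-tf / tau))
  out_f[seq(1, length(tf), by = os)][seq_len(n)]
}

shift_series <- function(x, t, shift) {
  if (shift == 0) return(x)
  stats::approx(t, x, xout = t - shift, rule = 2, yleft = 0)$y
}

irf_fwhm <- function(irf) {
  y <- irf$counts
  t <- irf$channel_times
  half <- max(y) / 2
  above <- which(y >= half)
  if (!length(above)) return(NA_real_)
  i1 <- min(above); i2 <- max(above)
  left <- if (i1 > 1)
    stats::approx(y[c(i1 - 1, i1)], t[c(i1 - 1, i1)], xout = half)$y else t[i1]
  right <- if (i2 < length(y))
    stats::approx(y[c(i2 + 1, i2)], t[c(i2 + 1, i2)], xout = half)$y else t[i2]
  right - left
}

#' Reconvolution fit of a fluorescence decay histogram
#'
#' Fits `I(t) = sum_i alpha_i exp(-t/tau_i)` convolved with the measured
#' IRF histogram on the channel grid, by weighted least squares with
#' Poisson weights `1/max(counts, 1)`. The amplitudes are solved linearly
#' at each trial of the nonlinear parameters (log lifetimes plus a scalar
#' time-origin shift between IRF and decay), so only `n + 1` parameters
#' are iterated. Channels before the IRF rise are included; reconvolution
#' accounts for them.
#'
#' Components with fitted lifetime below half the IRF full width at half
#' maximum are flagged `below_resolution`: such a value is reported but
#' not resolved by the measurement.
#'
#' @param decay a [decay_trace()].
#' @param irf a [decay_trace()] on the same channel grid (not all zero).
#' @param n number of exponential components (>= 1).
#' @param fit_shift fit the IRF/decay time-origin shift (default TRUE).
#' @param tau_init optional initial lifetimes, ps.
#' @return object of class `decay_fit`: `tau`, `alpha`, `beta`,
#'   `tau_pop`, `tau_avg`, `tau_se`, `chi2_reduced`, `residuals`
#'   (weighted), `shift`, `below_resolution`, `irf_fwhm`, `convergence`.
#' @export
fit_decay_reconvolution <- function(decay, irf, n, fit_shift = TRUE,
                                    tau_init = NULL) {
  stopifnot(inherits(decay, "decay_trace"), inherits(irf, "decay_trace"))
  if (n < 1) stop("'n' must be >= 1")
  t <- decay$channel_times
  if (length(t) != length(irf$channel_times) ||
      max(abs(t - irf$channel_times)) > 1e-6)
    stop("decay and IRF must share one channel grid")
  y <- decay$counts
  if (sum(y) <= 0) stop("decay trace holds no counts")
  if (sum(irf$counts) <= 0) stop("IRF is all zero")
  irf_n <- irf$counts / sum(irf$counts)
  w <- 1 / pmax(y, 1)
  sw <- sqrt(w)

  if (is.null(tau_init)) {
    # spread initial guesses around the empirical decay scale
    com <- sum(t * y) / sum(y) - sum(t * irf$counts) / sum(irf$counts)
    com <- max(com, decay$channel_width)
    tau_init <- com * 2^(seq_len(n) - (n + 1) / 2)
  }
  if (length(tau_init) != n) stop("'tau_init' must have length n")

  basis <- function(tau, shift) {
    irf_s <- shift_series(irf_n, t, shift)
    B <- vapply(tau, function(tt) convolve_irf_exp(irf_s, t, tt),
                numeric(length(t)))
    matrix(B, ncol = n)
  }
  solve_alpha <- function(B) {
    qr.coef(qr(B * sw), y * sw)
  }
  resid_fun <- function(p) {
    tau <- exp(p[seq_len(n)])
    shift <- if (fit_shift) p[n + 1L] else 0
    B <- basis(tau, shift)
    a <- tryCatch(solve_alpha(B), error = function(e) NULL)
    if (is.null(a) || anyNA(a)) return(rep(1e6, length(y)))
    (y - B %*% a) * sw
  }
  p0 <- log(tau_init)
  if (fit_shift) p0 <- c(p0, 0)
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  tau <- exp(fit$par[seq_len(n)])
  shift <- if (fit_shift) fit$par[n + 1L] else 0
  B <- basis(tau, shift)
  if (n > 1 && kappa(B) > 1e8)
    warning("component basis is ill-conditioned; n may exceed what the data resolve")
  alpha <- as.numeric(solve_alpha(B))
  ord <- order(tau)
  tau <- tau[ord]; alpha <- alpha[ord]
  r <- as.numeric((y - basis(tau, shift) %*% alpha) * sw)
  dof <- length(y) - (2 * n + as.integer(fit_shift))
  chi2 <- sum(r^2) / max(dof, 1)

  tau_se <- rep(NA_real_, n)
  # Poisson weights already carry the per-channel variance, so the
  # curvature is used unscaled (a chi2 rescale would be deflated by the
  # empty tail channels)
  cv <- tryCatch(diag(solve(fit$hessian, tol = 1e-30))[seq_len(n)],
                 error = function(e) NULL)
  if (!is.null(cv)) tau_se <- (sqrt(pmax(cv, 0)) * exp(fit$par[seq_len(n)]))[ord]

  fwhm <- irf_fwhm(irf)
  below <- if (is.na(fwhm)) rep(FALSE, n) else tau < fwhm / 2
  if (any(below))
    warning("component(s) below the resolution floor (IRF FWHM/2 = ",
            signif(fwhm / 2, 3), " ps): ",
            paste(signif(tau[below], 3), collapse = ", "))

  beta <- fractional_amplitudes(pmax(alpha, 0) + 1e-300 * (alpha <= 0), tau)
  structure(list(
    n = n, tau = tau, alpha = alpha, beta = beta,
    tau_pop = sum(beta * tau),
    tau_avg = sum(tau * alpha) / sum(alpha),
    tau_se = tau_se, chi2_reduced = chi2, residuals = r, shift = shift,
    below_resolution = below, irf_fwhm = fwhm,
    convergence = list(iterations = fit$niter,
                       converged = fit$info %in% 1:4,
                       message = fit$message)),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Reconvolution fit, %d component(s), chi2_red = %.3g\n",
              x$n, x$chi2_reduced))
  for (i in seq_len(x$n)) {
    cat(sprintf("  tau_%d = %.4g ps (beta %.1f%%)%s\n", i, x$tau[i],
                100 * x$beta[i],
                if (x$below_resolution[i]) "  [below resolution floor]" else ""))
  }
  cat(sprintf("  tau_pop = %.4g ps, tau_avg = %.4g ps\n", x$tau_pop, x$tau_avg))
  invisible(x)
}

#' Hill-model fit of a depolarization time course
#'
#' Least-squares fit of `F(t) = f0 + (f_max - f0) t^n / (t^n + t_half^n)`;
#' `t_half` is the reported depolarization time constant.
#'
#' @param times minutes, >= 0, at least 5 points.
#' @param intensities a.u., same length.
#' @param hill_n optional fixed Hill coefficient; fitted when `NULL`.
#' @return list with `t_half`, `hill_n`, `f0`, `f_max`, `t_half_se`,
#'   `identifiable` (FALSE when the trace has no resolvable rise) and
#'   `residuals`.
#' @export
fit_hill_depolarization <- function(times, intensities, hill_n = NULL) {
  if (length(times) < 5) stop("at least 5 time points are required")
  if (any(times < 0)) stop("times must be >= 0")
  if (length(times) != length(intensities)) stop("lengths differ")
  rng <- diff(range(intensities))
  scale <- max(abs(intensities), 1e-12)
  if (rng < 1e-8 * scale) {
    warning("intensity range is ~0; t_half is unidentifiable")
    return(list(t_half = NA_real_, hill_n = NA_real_,
                f0 = mean(intensities), f_max = mean(intensities),
                t_half_se = NA_real_, identifiable = FALSE,
                residuals = intensities - mean(intensities)))
  }
  if (any(diff(intensities) < -3 * stats::sd(diff(intensities))))
    warning("trace is non-monotone beyond noise; fitting anyway")
  fix_n <- !is.null(hill_n)
  p0 <- c(log(max(stats::median(times), min(times[times > 0]))),
          if (!fix_n) log(1.5), intensities[1], max(intensities))
  resid_fun <- function(p) {
    th <- exp(p[1])
    nn <- if (fix_n) hill_n else exp(p[2])
    f0 <- p[length(p) - 1L]; fm <- p[length(p)]
    intensities - hill_model(times, th, nn, f0, fm)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  th <- exp(fit$par[1])
  nn <- if (fix_n) hill_n else exp(fit$par[2])
  se <- tryCatch({
    s2 <- fit$deviance / max(length(times) - length(fit$par), 1)
    sqrt(diag(s2 * solve(fit$hessian))[1]) * th
  }, error = function(e) NA_real_)
  if (th > 10 * max(times))
    warning("t_half beyond the observed time range; poorly constrained")
  list(t_half = th, hill_n = nn,
       f0 = fit$par[length(fit$par) - 1L], f_max = fit$par[length(fit$par)],
       t_half_se = se, identifiable = TRUE,
       residuals = resid_fun(fit$par))
}
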