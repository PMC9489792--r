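#' Kinetic scheme for global analysis
#'
#' Describes the compartment model used both to simulate and to fit
#' time-resolved difference spectra: a chain of first-order transitions
#' (sequential), a set of independent decays (parallel), or a branched
#' scheme in which the excited compartment splits with fraction `phi` into a
#' photoproduct chain and with `1 - phi` into a spectrally silent recovered
#' ground state.
#'
#' Time constants are in the unit of the data (internally ps). The last
#' constant, and only the last, may be `Inf`; it denotes a non-decaying
#' terminal compartment (rate 0), i.e. a step response convolved with the
#' instrument response function (IRF).
#'
#' @param time_constants numeric vector of time constants; finite values
#'   must be strictly positive; at most one `Inf`, and only terminal.
#' @param topology one of `"sequential"`, `"parallel"`, `"branched"`.
#' @param branch_fraction branch fraction `phi` in `[0, 1]`; required for
#'   (and only allowed with) the branched topology.
#' @param irf_center,irf_sigma Gaussian IRF position and width (same time
#'   unit as the constants); `irf_sigma = 0` means a delta IRF.
#' @return an object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(time_constants,
                           topology = c("sequential", "parallel", "branched"),
                           branch_fraction = NULL,
                           irf_center = 0, irf_sigma = 0) {
  topology <- match.arg(topology)
  tau <- as.numeric(time_constants)
  if (length(tau) < 1L) stop("at least one time constant is required")
  inf <- is.infinite(tau)
  if (any(inf & seq_along(tau) < length(tau)) || sum(inf) > 1L)
    stop("at most one infinite time constant is allowed, and only terminal")
  if (any(tau[!inf] <= 0)) stop("finite time constants must be > 0")
  if (topology == "branched") {
    if (is.null(branch_fraction))
      stop("branched topology requires 'branch_fraction'")
    if (branch_fraction < 0 || branch_fraction > 1)
      stop("'branch_fraction' must lie in [0, 1]")
    if (length(tau) < 2L)
      stop("branched topology needs an excited compartment and a product chain")
  } else if (!is.null(branch_fraction)) {
    stop("'branch_fraction' is only meaningful for the branched topology")
  }
  if (irf_sigma < 0) stop("'irf_sigma' must be >= 0")
  structure(
    list(topology = topology, time_constants = tau,
         branch_fraction = branch_fraction,
         irf_center = irf_center, irf_sigma = irf_sigma),
    class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("Kinetic scheme: %s, %d compartment(s)\n",
              x$topology, length(x$time_constants)))
  cat("  tau:", paste(signif(x$time_constants, 4), collapse = ", "), "\n")
  if (!is.null(x$branch_fraction))
    cat("  branch fraction:", x$branch_fraction, "\n")
  cat(sprintf("  IRF: mu = %g, sigma = %g\n", x$irf_center, x$irf_sigma))
  invisible(x)
}

#' Exponential decay convolved with a Gaussian instrument response
#'
#' Analytic convolution of a unit-amplitude exponential step response
#' `exp(-(t - mu)/tau) * H(t - mu)` with a normalized Gaussian of width
#' `sigma` centered at `mu`:
#' \deqn{c(t) = \tfrac{1}{2}\, e^{-(t-\mu)^2/2\sigma^2}\,
#'   \mathrm{erfcx}\!\left(\frac{\mu + k\sigma^2 - t}{\sigma\sqrt{2}}\right),
#'   \quad k = 1/\tau,}
#' evaluated through the scaled complementary error function so the result
#' stays finite for `t - mu` tens of sigma from the IRF and for rate/width
#' ratios spanning many decades. `tau = Inf` (rate 0) returns the Gaussian
#' cumulative, the response of a non-decaying compartment.
#'
#' @param tau time constant (> 0, or `Inf` for a step).
#' @param mu IRF center.
#' @param sigma IRF Gaussian sigma (>= 0); 0 gives the sharp exponential.
#' @param t time grid.
#' @return numeric vector, same length as `t`.
#' @export
exp_conv_irf <- function(tau, mu, sigma, t) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (!is.infinite(tau) && tau <= 0) stop("finite 'tau' must be > 0")
  x <- t - mu
  if (is.infinite(tau)) {
    if (sigma == 0) return(as.numeric(x >= 0))
    return(stats::pnorm(x / sigma))
  }
  k <- 1 / tau
  if (sigma == 0) {
    out <- numeric(length(x))
    pos <- x >= 0
    out[pos] <- exp(-k * x[pos])
    return(out)
  }
  b <- (k * sigma^2 - x) / (sigma * sqrt(2))
  out <- numeric(length(x))
  pos <- b > 0
  # b > 0: scaled-erfc form; b <= 0: plain form whose exponent is then <= 0
  out[pos] <- 0.5 * exp(-x[pos]^2 / (2 * sigma^2)) * erfcx_safe(b[pos])
  if (any(!pos)) {
    a <- -k * x[!pos] + k^2 * sigma^2 / 2
    out[!pos] <- 0.5 * exp(a) * pracma::erfc(b[!pos])
  }
  out
}

# erfcx for nonnegative arguments; asymptotic series where the direct
# exp(x^2) * erfc(x) evaluation overflows
erfcx_safe <- function(x) {
  out <- rep(NaN, length(x))
  ok <- is.finite(x)
  small <- ok & x < 20
  large <- ok & x >= 20
  out[small] <- pracma::erfcx(x[small])
  out[x == Inf] <- 0
  if (any(large)) {
    z <- x[large]
    z2 <- z^2
    # erfcx(z) ~ (1 - 1/(2 z^2) + 3/(4 z^4) - 15/(8 z^6)) / (z sqrt(pi))
    out[large] <- (1 - 1 / (2 * z2) + 3 / (4 * z2^2) - 15 / (8 * z2^3)) /
      (z * sqrt(pi))
  }
  out
}

# Bateman coefficients for a first-order chain with rates k (distinct).
# c_j(t) = sum_{i<=j} A[i, j] * E_i(t) with E_i the IRF-convolved
# single-exponential of rate k_i. Handles a terminal zero rate.
bateman_coefficients <- function(k) {
  n <- length(k)
  A <- matrix(0, n, n)
  A[1, 1] <- 1
  if (n == 1L) return(A)
  for (j in 2:n) {
    num <- prod(k[seq_len(j - 1)])
    for (i in seq_len(j)) {
      den <- prod(k[setdiff(seq_len(j), i)] - k[i])
      A[i, j] <- num / den
    }
  }
  A
}

#' Compartment populations of a kinetic scheme
#'
#' Populations `c_k(t)` of each compartment of the scheme, each convolved
#' with the Gaussian IRF, computed from the closed-form first-order cascade
#' (Bateman) solution. For the branched topology the excited compartment
#' feeds the photoproduct chain with fraction `phi`; the recovered-ground
#' sink is spectrally silent and is not returned as a column. For the
#' parallel topology each compartment decays independently.
#'
#' Near-degenerate finite rates (relative gap below 1e-6) are perturbed by
#' 1e-6 relative, with a warning, to avoid the cascade singularity.
#'
#' @param scheme a [kinetic_scheme()].
#' @param t time grid.
#' @return matrix `[length(t) x n_compartments]`.
#' @export
sequential_populations <- function(scheme, t) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  tau <- scheme$time_constants
  n <- length(tau)
  k <- ifelse(is.infinite(tau), 0, 1 / tau)
  if (scheme$topology == "parallel") {
    C <- vapply(seq_len(n), function(i)
      exp_conv_irf(tau[i], scheme$irf_center, scheme$irf_sigma, t),
      numeric(length(t)))
    return(matrix(C, ncol = n))
  }
  # resolve near-degenerate rates (finite ones only)
  fin <- which(k > 0)
  if (length(fin) > 1L) {
    ks <- sort(k[fin])
    if (any(diff(ks) / ks[-length(ks)] < 1e-6)) {
      warning("near-degenerate rates perturbed by 1e-6 relative")
      for (i in seq_along(fin)[-1]) {
        while (any(abs(k[fin[i]] - k[fin[seq_len(i - 1)]]) /
                   k[fin[i]] < 1e-6)) {
          k[fin[i]] <- k[fin[i]] * (1 + 1e-6)
        }
      }
    }
  }
  A <- bateman_coefficients(k)
  E <- vapply(seq_len(n), function(i) {
    taui <- if (k[i] == 0) Inf else 1 / k[i]
    exp_conv_irf(taui, scheme$irf_center, scheme$irf_sigma, t)
  }, numeric(length(t)))
  E <- matrix(E, ncol = n)
  C <- E %*% A
  if (scheme$topology == "branched") {
    # compartments beyond the excited one carry the branch fraction
    phi <- scheme$branch_fraction
    if (n > 1L) C[, -1] <- C[, -1] * phi
  }
  C
}

#' Global variable-projection fit of time-resolved spectra
#'
#' Fits a compartment model to a wavelength-by-delay difference-absorbance
#' surface with all wavelengths sharing one set of time constants. The fit
#' is a variable projection: the outer nonlinear optimization (Levenberg-
#' Marquardt on `log(tau)`, optionally the IRF center and `log(sigma)`)
#' drives only the kinetic parameters, while the component spectra are the
#' exact linear least-squares solution at every trial. Sequential schemes
#' yield evolution-associated difference spectra (EADS); parallel schemes
#' yield decay-associated spectra (DAS).
#'
#' Time constants are reported sorted ascending (an infinite terminal
#' constant stays last); standard errors come from the local curvature of
#' the reduced objective.
#'
#' @param data a `time_resolved_spectra` object (see [time_resolved_spectra()]).
#' @param scheme_init a [kinetic_scheme()] holding the initial guess; when
#'   `NULL`, finite constants are initialized log-spaced across the decades
#'   spanned by the positive delays with an infinite terminal constant.
#' @param n_components number of compartments used when `scheme_init` is
#'   `NULL`.
#' @param fit_irf logical; also fit the IRF center and width.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return object of class `global_fit` with elements `scheme`
#'   (fitted), `component_spectra` (`n_comp x n_wavelengths`),
#'   `concentrations` (`n_delays x n_comp`), `residual_matrix`,
#'   `rms_residual`, `tau_se` (standard errors, `NA` for the infinite
#'   constant), and `convergence` (iterations, `converged` flag, message).
#' @export
fit_global <- function(data, scheme_init = NULL, n_components = NULL,
                       fit_irf = FALSE, max_iter = 200) {
  stopifnot(inherits(data, "time_resolved_spectra"))
  Y <- data$delta_a
  t <- data$delays
  if (is.null(scheme_init)) {
    if (is.null(n_components))
      stop("give either 'scheme_init' or 'n_components'")
    scheme_init <- default_init_scheme(t, n_components)
  }
  if (length(scheme_init$time_constants) > length(t))
    stop("more compartments than delay points")
  tau0 <- scheme_init$time_constants
  free <- !is.infinite(tau0)
  if (any(duplicated(tau0[free]))) stop("initial time constants must be distinct")

  build_scheme <- function(p) {
    tau <- tau0
    tau[free] <- exp(p[seq_len(sum(free))])
    mu <- scheme_init$irf_center
    sig <- scheme_init$irf_sigma
    if (fit_irf) {
      mu <- p[sum(free) + 1L]
      sig <- exp(p[sum(free) + 2L])
    }
    kinetic_scheme(tau, scheme_init$topology,
                   branch_fraction = scheme_init$branch_fraction,
                   irf_center = mu, irf_sigma = sig)
  }
  resid_fun <- function(p) {
    sch <- tryCatch(build_scheme(p), error = function(e) NULL)
    if (is.null(sch)) return(rep(1e6, length(Y)))
    C <- suppressWarnings(sequential_populations(sch, t))
    if (!all(is.finite(C))) return(rep(1e6, length(Y)))
    fit <- tryCatch(qr(C), error = function(e) NULL)
    if (is.null(fit) || fit$rank < ncol(C))
      return(rep(1e6, length(Y)))
    S <- qr.coef(fit, Y)
    as.vector(Y - C %*% S)
  }
  p0 <- log(tau0[free])
  t_span <- diff(range(t))
  lower <- rep(log(1e-6), sum(free))
  upper <- rep(log(1e9), sum(free))
  if (fit_irf) {
    p0 <- c(p0, scheme_init$irf_center,
            log(max(scheme_init$irf_sigma, 1e-6)))
    lower <- c(lower, min(t), log(1e-7))
    upper <- c(upper, max(t), log(t_span))
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                    ptol = 1e-12,
                                    maxfev = 100 * (length(p0) + 1) * 5)
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fun,
                            lower = lower, upper = upper, control = ctl)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("global fit did not converge: ", fit$message)

  scheme_hat <- build_scheme(fit$par)
  # report constants sorted ascending, infinite terminal last
  ord <- order(scheme_hat$time_constants)
  scheme_hat <- kinetic_scheme(scheme_hat$time_constants[ord],
                               scheme_hat$topology,
                               branch_fraction = scheme_hat$branch_fraction,
                               irf_center = scheme_hat$irf_center,
                               irf_sigma = scheme_hat$irf_sigma)
  C <- sequential_populations(scheme_hat, t)
  qrC <- qr(C)
  S <- qr.coef(qrC, Y)
  R <- Y - C %*% S

  # standard errors of tau from the LM curvature, delta method on log-tau
  tau_se <- rep(NA_real_, length(tau0))
  cv <- tryCatch({
    dof <- length(Y) - length(fit$par) - length(tau0) * ncol(Y)
    s2 <- fit$deviance / max(dof, 1)
    diag(s2 * solve(fit$hessian))
  }, error = function(e) NULL)
  if (!is.null(cv)) {
    se_log <- sqrt(pmax(cv[seq_len(sum(free))], 0))
    tau_free_unsorted <- exp(fit$par[seq_len(sum(free))])
    se_abs <- se_log * tau_free_unsorted
    # map onto sorted order
    m <- match(scheme_hat$time_constants[!is.infinite(scheme_hat$time_constants)],
               tau_free_unsorted)
    tau_se[which(!is.infinite(scheme_hat$time_constants))] <- se_abs[m]
  }

  structure(list(
    scheme = scheme_hat,
    component_spectra = S,
    concentrations = C,
    residual_matrix = R,
    rms_residual = sqrt(mean(R^2)),
    tau_se = tau_se,
    wavelengths = data$wavelengths,
    delays = t,
    convergence = list(iterations = fit$niter, converged = converged,
                       message = fit$message)),
    class = "global_fit")
}

default_init_scheme <- function(t, n_components) {
  tp <- t[t > 0]
  lo <- max(min(tp), 1e-3)
  hi <- max(tp)
  nf <- n_components - 1L
  tau <- c(exp(seq(log(lo * 2), log(hi / 5), length.out = max(nf, 1))), Inf)
  if (nf == 0L) tau <- Inf
  kinetic_scheme(tau, "sequential", irf_center = 0,
                 irf_sigma = max(lo / 5, 1e-4))
}

#' @export
print.global_fit <- function(x, ...) {
  tau <- x$scheme$time_constants
  cat(sprintf("Global %s fit, %d compartments, rms residual %.3g\n",
              x$scheme$topology, length(tau), x$rms_residual))
  for (i in seq_along(tau)) {
    se <- if (is.na(x$tau_se[i])) "" else sprintf(" (se %.3g)", x$tau_se[i])
    cat(sprintf("  tau_%d = %s%s\n", i - 1,
                if (is.infinite(tau[i])) "Inf" else signif(tau[i], 4), se))
  }
  cat(sprintf("  converged: %s after %d iterations\n",
              x$convergence$converged, x$convergence$iterations))
  invisible(x)
}

#' Photoproduct yield from the terminal-to-initial bleach ratio
#'
#' Estimates the fraction of excited chromophores that end in a long-lived
#' photoproduct rather than recovering the initial ground state: the ratio
#' of the terminal component spectrum to the earliest component spectrum,
#' both evaluated at the ground-state-bleach wavelength. With a spectrally
#' isolated bleach band the ratio equals the branch fraction of the
#' underlying scheme.
#'
#' @param result a [fit_global()] result with at least two components.
#' @param gsb_wavelength bleach band center, nm; must lie inside the fitted
#'   wavelength range (nearest grid point is used).
#' @return yield as a fraction in `[0, 1]` (tolerance overshoot allowed).
#' @export
estimate_photoproduct_yield <- function(result, gsb_wavelength) {
  stopifnot(inherits(result, "global_fit"))
  S <- result$component_spectra
  if (nrow(S) < 2L) stop("need at least two fitted components")
  wl <- result$wavelengths
  if (gsb_wavelength < min(wl) || gsb_wavelength > max(wl))
    stop("'gsb_wavelength' outside the fitted wavelength range")
  j <- which.min(abs(wl - gsb_wavelength))
  # earliest post-IRF component: sub-IRF constants are coherent-spike
  # artifacts, not populations
  tau <- result$scheme$time_constants
  first <- which(tau >= 3 * result$scheme$irf_sigma)[1]
  if (is.na(first)) first <- 1L
  a0 <- S[first, j]
  if (abs(a0) < 1e-12 * max(abs(S)))
    stop("initial bleach amplitude is near zero; yield undefined")
  abs(S[nrow(S), j]) / abs(a0)
}
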