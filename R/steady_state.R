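#' Nernst membrane-voltage calibration
#'
#' `V = (RT / zF) ln([K]_out / [K]_in)` in millivolts, with
#' `R = 8.314 J mol^-1 K^-1` and `F = 96485 C mol^-1`. The default
#' temperature, 293.15 K (room temperature), reproduces the standard
#' proteoliposome calibration points (-75, 0 and 68 mV for 0.5/10, 10/10
#' and 150/10 mM potassium gradients) within a millivolt.
#'
#' @param k_out,k_in potassium concentrations, mM, > 0.
#' @param temperature K, > 0.
#' @param z ion valence (default +1).
#' @return membrane voltage, mV.
#' @export
nernst_voltage <- function(k_out, k_in, temperature = 293.15, z = 1) {
  if (any(c(k_out, k_in) <= 0)) stop("concentrations must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  R <- 8.314; F <- 96485
  1000 * R * temperature / (z * F) * log(k_out / k_in)
}

#' Relative fluorescence quantum yield
#'
#' `Phi_s = Phi_ref * f_ref/f_s * F_s/F_ref * n_s^2/n_ref^2` with
#' `f = 1 - 10^(-A)` the absorbed fraction at the excitation wavelength
#' (decadic absorbance convention), `F` the integrated fluorescence and
#' `n` the solvent refractive index. Absorbances above ~0.05 violate the
#' dilute-sample assumption and draw a warning.
#'
#' @param absorbance_sample,absorbance_ref OD at the excitation wavelength.
#' @param f_sample,f_ref integrated fluorescence counts, > 0.
#' @param phi_ref quantum yield of the reference standard.
#' @param n_sample,n_ref refractive indices (defaults: water 1.333,
#'   ethanol 1.361).
#' @return quantum yield of the sample, unitless fraction.
#' @export
relative_quantum_yield <- function(absorbance_sample, absorbance_ref,
                                   f_sample, f_ref, phi_ref,
                                   n_sample = 1.333, n_ref = 1.361) {
  if (absorbance_sample <= 0 || absorbance_ref <= 0)
    stop("absorbances must be > 0 (f = 0 otherwise)")
  if (f_sample <= 0 || f_ref <= 0) stop("fluorescence counts must be > 0")
  if (absorbance_sample > 0.05 || absorbance_ref > 0.05)
    warning("absorbance above 0.05; reabsorption may bias the yield")
  fr_sample <- 1 - 10^(-absorbance_sample)
  fr_ref <- 1 - 10^(-absorbance_ref)
  phi_ref * (fr_ref / fr_sample) * (f_sample / f_ref) * (n_sample / n_ref)^2
}

#' Two-state Henderson-Hasselbalch pKa fit
#'
#' Fits `A(pH) = a_deprot + (a_prot - a_deprot) / (1 + 10^(n (pH - pKa)))`
#' to an absorbance-vs-pH series by Levenberg-Marquardt least squares.
#'
#' @param series a [titration_series()].
#' @param hill_n optional fixed Hill coefficient; fitted when `NULL`
#'   (default start 1, a single protonatable site).
#' @return list with `pka`, `hill_n`, `a_protonated`, `a_deprotonated`,
#'   `pka_se`, `trusted` (from the series coverage flag) and `residuals`.
#' @export
fit_pka <- function(series, hill_n = NULL) {
  stopifnot(inherits(series, "titration_series"))
  ph <- series$ph; a <- series$absorbance
  if (diff(range(a)) < 1e-12 * max(abs(a), 1))
    stop("no transition within the pH range; asymptote-only data")
  fix_n <- !is.null(hill_n)
  # midpoint guess: pH where absorbance crosses its mid-range
  mid <- (max(a) + min(a)) / 2
  p0 <- c(ph[which.min(abs(a - mid))], if (!fix_n) 0, a[1], a[length(a)])
  resid_fun <- function(p) {
    nn <- if (fix_n) hill_n else exp(p[2])
    a - titration_model(ph, p[1], nn, p[length(p) - 1L], p[length(p)])
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  se <- tryCatch({
    s2 <- fit$deviance / max(length(ph) - length(fit$par), 1)
    sqrt(diag(s2 * solve(fit$hessian))[1])
  }, error = function(e) NA_real_)
  if (!series$trusted)
    warning("titration coverage is thin (<5 points or <2 pH units)")
  list(pka = fit$par[1],
       hill_n = if (fix_n) hill_n else exp(fit$par[2]),
       a_protonated = fit$par[length(fit$par) - 1L],
       a_deprotonated = fit$par[length(fit$par)],
       pka_se = se, trusted = series$trusted,
       residuals = resid_fun(fit$par))
}

#' Isomer fractions by baseline-corrected peak integration
#'
#' Integrates each labelled retention-time window by the trapezoid rule
#' after subtracting a linear baseline fitted through the window edges,
#' then normalizes areas to fractions. Negative corrected areas are
#' clipped to zero with a warning.
#'
#' @param chrom a [chromatogram()].
#' @param windows data.frame with columns `start`, `end` (min) and
#'   `label`; windows must be non-overlapping and inside the time range.
#' @param baseline `"linear"` (edge-fitted segment, default) or `"none"`.
#' @return data.frame with `label`, `area`, `fraction` (summing to 1).
#' @export
integrate_isomer_peaks <- function(chrom, windows,
                                   baseline = c("linear", "none")) {
  stopifnot(inherits(chrom, "chromatogram"))
  baseline <- match.arg(baseline)
  windows <- as.data.frame(windows)
  if (!all(c("start", "end", "label") %in% names(windows)))
    stop("windows need columns start, end, label")
  if (any(windows$end <= windows$start)) stop("window end must exceed start")
  o <- order(windows$start)
  if (any(windows$start[o][-1] < windows$end[o][-nrow(windows)]))
    stop("windows must be non-overlapping")
  t <- chrom$retention_time; y <- chrom$signal
  if (any(windows$start < min(t)) || any(windows$end > max(t)))
    stop("window outside the chromatogram time range")
  areas <- vapply(seq_len(nrow(windows)), function(i) {
    inw <- t >= windows$start[i] & t <= windows$end[i]
    tw <- t[inw]; yw <- y[inw]
    if (length(tw) < 2) stop("window contains fewer than 2 samples")
    if (baseline == "linear") {
      # anchor the segment on short averaged edge regions so single-sample
      # noise does not tilt the baseline across the whole window
      ne <- max(3L, round(0.05 * length(tw)))
      ne <- min(ne, floor(length(tw) / 2))
      i1 <- seq_len(ne); i2 <- seq(length(tw) - ne + 1L, length(tw))
      t1 <- mean(tw[i1]); y1 <- mean(yw[i1])
      t2 <- mean(tw[i2]); y2 <- mean(yw[i2])
      b <- y1 + (y2 - y1) * (tw - t1) / (t2 - t1)
      yw <- yw - b
    }
    sum(diff(tw) * (yw[-1] + yw[-length(yw)]) / 2)
  }, numeric(1))
  if (any(areas < 0)) {
    warning("negative baseline-corrected area clipped to 0")
    areas <- pmax(areas, 0)
  }
  total <- sum(areas)
  if (total <= 0) stop("all window areas are zero")
  data.frame(label = windows$label, area = areas, fraction = areas / total)
}

#' Stern-Volmer quenching fit
#'
#' Linear least squares of `F0/F` against quencher concentration; the
#' slope is the Stern-Volmer constant `K_sv` and the intercept should be
#' near 1 for a well-behaved series.
#'
#' @param quencher_conc mM, at least 3 values including one near zero.
#' @param f0_over_f unitless ratios, same length.
#' @return list with `k_sv` (per mM), `intercept`, `k_sv_se` and the `lm`
#'   fit object.
#' @export
stern_volmer_fit <- function(quencher_conc, f0_over_f) {
  if (length(quencher_conc) < 3) stop("at least 3 concentrations required")
  if (length(quencher_conc) != length(f0_over_f)) stop("lengths differ")
  if (diff(range(quencher_conc)) == 0)
    stop("quencher concentrations are all equal; slope unidentifiable")
  fit <- stats::lm(f0_over_f ~ quencher_conc)
  cf <- suppressWarnings(stats::coef(summary(fit)))  # exact data warns
  list(k_sv = cf["quencher_conc", "Estimate"],
       intercept = cf["(Intercept)", "Estimate"],
       k_sv_se = cf["quencher_conc", "Std. Error"],
       fit = fit)
}
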