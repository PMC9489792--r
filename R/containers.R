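#' Time-resolved difference-absorbance surface
#'
#' Container for a transient-absorption dataset: a `[n_delays x
#' n_wavelengths]` matrix of difference absorbances on strictly increasing
#' wavelength and delay axes. Delays are normalized internally to
#' picoseconds from the declared unit.
#'
#' @param wavelengths nm, strictly increasing.
#' @param delays delay axis in `time_unit`, strictly increasing.
#' @param delta_a matrix `[length(delays) x length(wavelengths)]`.
#' @param time_unit one of `"fs"`, `"ps"`, `"ns"`, `"us"`.
#' @return object of class `time_resolved_spectra`; `$delays` is in ps.
#' @export
time_resolved_spectra <- function(wavelengths, delays, delta_a,
                                  time_unit = c("ps", "fs", "ns", "us")) {
  time_unit <- match.arg(time_unit)
  wavelengths <- as.numeric(wavelengths)
  delays <- as.numeric(delays) * time_unit_to_ps(time_unit)
  delta_a <- as.matrix(delta_a)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  if (!all(is.finite(delta_a))) stop("delta_a must be finite")
  if (nrow(delta_a) != length(delays) || ncol(delta_a) != length(wavelengths))
    stop("delta_a dimensions must be [n_delays x n_wavelengths]")
  structure(list(wavelengths = wavelengths, delays = delays,
                 delta_a = delta_a, time_unit = "ps"),
            class = "time_resolved_spectra")
}

time_unit_to_ps <- function(unit) {
  switch(unit, fs = 1e-3, ps = 1, ns = 1e3, us = 1e6,
         stop("unknown time unit: ", unit))
}

#' @export
print.time_resolved_spectra <- function(x, ...) {
  cat(sprintf(
    "Time-resolved spectra: %d delays (%.4g to %.4g ps) x %d wavelengths (%g to %g nm)\n",
    length(x$delays), min(x$delays), max(x$delays),
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Fluorescence decay histogram
#'
#' Photon-count (or expected-count) decay trace on a uniform channel grid,
#' as produced by time-correlated single photon counting or a streak
#' camera.
#'
#' @param channel_times ps, uniform spacing.
#' @param counts nonnegative counts, same length.
#' @param channel_width ps; defaults to the grid spacing.
#' @param excitation_nm optional metadata.
#' @return object of class `decay_trace`.
#' @export
decay_trace <- function(channel_times, counts, channel_width = NULL,
                        excitation_nm = NA_real_) {
  channel_times <- as.numeric(channel_times)
  counts <- as.numeric(counts)
  if (length(channel_times) != length(counts))
    stop("'channel_times' and 'counts' must have the same length")
  dt <- diff(channel_times)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("channel spacing must be uniform")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(channel_width)) channel_width <- if (length(dt)) dt[1] else NA_real_
  structure(list(channel_times = channel_times, counts = counts,
                 channel_width = channel_width, excitation_nm = excitation_nm),
            class = "decay_trace")
}

#' HPLC chromatogram
#'
#' @param retention_time minutes, strictly increasing.
#' @param signal detector signal, a.u.
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(retention_time, signal) {
  retention_time <- as.numeric(retention_time)
  signal <- as.numeric(signal)
  if (any(diff(retention_time) <= 0))
    stop("retention_time must be strictly increasing")
  if (length(retention_time) != length(signal))
    stop("axis and signal lengths differ")
  structure(list(retention_time = retention_time, signal = signal),
            class = "chromatogram")
}

#' Protonation titration series
#'
#' Absorbance at a fixed wavelength across a pH series, for two-state
#' Henderson-Hasselbalch fitting of the Schiff-base pKa.
#'
#' @param ph pH values, increasing.
#' @param absorbance same length.
#' @return object of class `titration_series`. A series with fewer than 5
#'   points or spanning under 2 pH units carries `trusted = FALSE`.
#' @export
titration_series <- function(ph, absorbance) {
  ph <- as.numeric(ph)
  absorbance <- as.numeric(absorbance)
  if (!length(ph)) stop("empty pH grid")
  if (any(diff(ph) <= 0)) stop("pH grid must be strictly increasing")
  if (length(ph) != length(absorbance)) stop("lengths differ")
  trusted <- length(ph) >= 5 && diff(range(ph)) >= 2
  structure(list(ph = ph, absorbance = absorbance, trusted = trusted),
            class = "titration_series")
}

#' Coordinate trajectory
#'
#' Ordered frames of labelled atom coordinates (angstrom), the object the
#' hydrogen-bond, side-chain-orientation and pocket-water analyses consume.
#' The atom roster (serial, name, residue, chain) must be identical across
#' frames.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `resno`, `chain` describing the per-frame atom roster.
#' @param coords numeric array `[n_frames, n_atoms, 3]` of coordinates.
#' @param times frame times in ns, strictly increasing.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, times) {
  atoms <- as.data.frame(atoms)
  need <- c("serial", "name", "resname", "resno", "chain")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  atoms$chain <- as.character(atoms$chain)
  coords <- unclass(coords)
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be [n_frames, n_atoms, 3]")
  if (dim(coords)[2] != nrow(atoms))
    stop("coords atom dimension does not match roster")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  times <- as.numeric(times)
  if (length(times) != dim(coords)[1]) stop("one time per frame required")
  if (any(diff(times) <= 0) && length(times) > 1)
    stop("frame times must be strictly increasing")
  structure(list(atoms = atoms, coords = coords, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms, t = %g to %g ns\n",
              length(x$times), nrow(x$atoms), min(x$times), max(x$times)))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

# index of a single atom given "resno:atomname" or (resno, name)
atom_index <- function(traj, spec) {
  if (is.character(spec) && length(spec) == 1L) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      resno <- as.integer(parts[1]); name <- parts[2]
    } else if (length(parts) == 3L) {
      resno <- as.integer(parts[2]); name <- parts[3]
    } else stop("atom spec must be 'resno:atom' or 'chain:resno:atom'")
  } else if (is.list(spec)) {
    resno <- spec$resno; name <- spec$name
  } else stop("unrecognized atom spec")
  idx <- which(traj$atoms$resno == resno & traj$atoms$name == name)
  if (length(idx) != 1L)
    stop("atom spec matches ", length(idx), " atoms: ", resno, ":", name)
  idx
}
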