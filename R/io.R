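#' Write a time-resolved spectra matrix as CSV
#'
#' Layout: `#`-prefixed metadata comments (always including
#' `time_unit`), then a header row holding the wavelength axis, then one
#' row per delay with the delay in the first column.
#'
#' @param x a [time_resolved_spectra()].
#' @param path output file.
#' @param metadata optional named character vector of extra `# key=value`
#'   comments (e.g. the generating seed).
#' @export
write_matrix_csv <- function(x, path, metadata = NULL) {
  stopifnot(inherits(x, "time_resolved_spectra"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# time_unit=%s", x$time_unit), con)
  for (k in names(metadata))
    writeLines(sprintf("# %s=%s", k, metadata[[k]]), con)
  writeLines(paste(c("delay", format(x$wavelengths, digits = 15)),
                   collapse = ","), con)
  for (i in seq_along(x$delays)) {
    writeLines(paste(format(c(x$delays[i], x$delta_a[i, ]), digits = 17),
                     collapse = ","), con)
  }
  invisible(path)
}

read_hash_metadata <- function(lines) {
  meta <- character()
  cm <- grep("^#", lines, value = TRUE)
  for (l in cm) {
    m <- regmatches(l, regexec("^#\\s*([^=]+)=(.*)$", l))[[1]]
    if (length(m) == 3) meta[trimws(m[2])] <- trimws(m[3])
  }
  meta
}

#' Read a time-resolved spectra matrix from CSV
#'
#' Inverse of [write_matrix_csv()]: the first non-comment row is the
#' wavelength axis, the first column the delay axis, and a
#' `# time_unit=` comment declares the unit (`ps` assumed, with a
#' warning, when absent). Ragged rows are rejected with the offending
#' line number.
#'
#' @param path CSV file.
#' @return a [time_resolved_spectra()] (delays normalized to ps).
#' @export
read_matrix_csv <- function(path) {
  lines <- readLines(path)
  meta <- read_hash_metadata(lines)
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body_idx) < 2) stop("no data rows in ", path)
  unit <- if ("time_unit" %in% names(meta)) meta[["time_unit"]] else NA
  if (is.na(unit)) {
    warning("no time_unit declared; assuming ps")
    unit <- "ps"
  }
  split_row <- function(l) strsplit(l, ",", fixed = TRUE)[[1]]
  header <- split_row(lines[body_idx[1]])
  ncol_exp <- length(header)
  wavelengths <- as.numeric(header[-1])
  rows <- lapply(body_idx[-1], function(i) {
    v <- split_row(lines[i])
    if (length(v) != ncol_exp)
      stop("ragged row at line ", i, ": expected ", ncol_exp,
           " fields, got ", length(v))
    as.numeric(v)
  })
  m <- do.call(rbind, rows)
  time_resolved_spectra(wavelengths, m[, 1], m[, -1, drop = FALSE], unit)
}

#' Write a two-column trace as CSV
#'
#' Generic writer for decay, IRF, chromatogram and titration series:
#' `#` metadata comments, a header, then two numeric columns.
#'
#' @param x_values,y_values equal-length numeric vectors.
#' @param path output file.
#' @param names column names (length 2).
#' @param metadata optional named character vector of `# key=value`
#'   comments.
#' @export
write_trace_csv <- function(x_values, y_values, path,
                            names = c("x", "y"), metadata = NULL) {
  stopifnot(length(x_values) == length(y_values), length(names) == 2)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in base::names(metadata))
    writeLines(sprintf("# %s=%s", k, metadata[[k]]), con)
  writeLines(paste(names, collapse = ","), con)
  writeLines(paste(format(x_values, digits = 17),
                   format(y_values, digits = 17), sep = ","), con)
  invisible(path)
}

#' Read a two-column trace CSV
#'
#' @param path CSV written by [write_trace_csv()] (or any two-column CSV
#'   with an optional header and `#` comments).
#' @return list with `x`, `y` and `metadata`.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta <- read_hash_metadata(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  start <- if (length(body) && !grepl("^[-0-9. +eE]+,", body[1])) 2L else 1L
  vals <- lapply(seq(start, length(body)), function(i) {
    v <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(v) != 2) stop("expected 2 fields in row: ", body[i])
    as.numeric(v)
  })
  m <- do.call(rbind, vals)
  list(x = m[, 1], y = m[, 2], metadata = meta)
}

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz) {
  namef <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, namef, resname, chain, resno, xyz[1], xyz[2], xyz[3],
          1.0, 0.0)
}

#' Write a trajectory as a multi-MODEL PDB
#'
#' One MODEL/ENDMDL block per frame, fixed-column ATOM records, frame
#' times recorded as `REMARK 250 FRAME_TIMES_NS`.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK 250 FRAME_TIMES_NS %s",
                     paste(format(traj$times, digits = 10), collapse = " ")),
             con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", f), con)
    for (i in seq_len(nrow(traj$atoms))) {
      writeLines(pdb_atom_line(traj$atoms$serial[i], traj$atoms$name[i],
                               traj$atoms$resname[i], traj$atoms$chain[i],
                               traj$atoms$resno[i], traj$coords[f, i, ]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-MODEL PDB trajectory
#'
#' Parses MODEL-delimited frames in file order, validating that every
#' model carries the identical atom roster (a mismatch is rejected naming
#' the first differing atom). Frame times are taken from the
#' `REMARK 250 FRAME_TIMES_NS` header when present, else 0, 1, 2, ... ns.
#'
#' @param path PDB file.
#' @return a [trajectory()].
#' @export
read_pdb_trajectory <- function(path) {
  lines <- readLines(path)
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    frames <- list(which(atom_lines))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    frames <- lapply(seq_along(model_starts), function(i) {
      idx <- seq(model_starts[i], model_ends[i])
      idx[atom_lines[idx]]
    })
  }
  if (!length(frames[[1]])) stop("no ATOM records in ", path)
  parse_atoms <- function(idx) {
    l <- lines[idx]
    ok <- nchar(l) >= 54
    if (any(!ok)) stop("malformed ATOM record: ", l[which(!ok)[1]])
    data.frame(
      serial = as.integer(substr(l, 7, 11)),
      name = trimws(substr(l, 13, 16)),
      resname = trimws(substr(l, 18, 20)),
      chain = trimws(substr(l, 22, 22)),
      resno = as.integer(substr(l, 23, 26)),
      x = as.numeric(substr(l, 31, 38)),
      y = as.numeric(substr(l, 39, 46)),
      z = as.numeric(substr(l, 47, 54)))
  }
  first <- parse_atoms(frames[[1]])
  roster_key <- function(df) paste(df$name, df$resname, df$chain, df$resno)
  key0 <- roster_key(first)
  nf <- length(frames)
  coords <- array(NA_real_, dim = c(nf, nrow(first), 3))
  coords[1, , ] <- as.matrix(first[, c("x", "y", "z")])
  if (nf > 1) for (f in 2:nf) {
    df <- parse_atoms(frames[[f]])
    keyf <- roster_key(df)
    if (length(keyf) != length(key0)) {
      missing <- setdiff(key0, keyf)
      extra <- setdiff(keyf, key0)
      stop("atom roster mismatch in MODEL ", f, ": ",
           if (length(missing)) paste("missing", missing[1]) else
             paste("extra", extra[1]))
    }
    if (any(keyf != key0))
      stop("atom roster mismatch in MODEL ", f, ": ",
           keyf[which(keyf != key0)[1]], " vs ", key0[which(keyf != key0)[1]])
    coords[f, , ] <- as.matrix(df[, c("x", "y", "z")])
  }
  tm_line <- grep("^REMARK 250 FRAME_TIMES_NS", lines, value = TRUE)
  times <- if (length(tm_line)) {
    as.numeric(strsplit(sub("^REMARK 250 FRAME_TIMES_NS\\s+", "", tm_line[1]),
                        "\\s+")[[1]])
  } else seq_len(nf) - 1
  if (length(times) != nf) times <- seq_len(nf) - 1
  trajectory(first[, c("serial", "name", "resname", "resno", "chain")],
             coords, times)
}

#' Write a key-value fit report
#'
#' Plain-text `key = value` lines, one per entry, for fit summaries.
#'
#' @param values named list of scalars (numbers formatted at full
#'   precision).
#' @param path output file.
#' @export
write_report <- function(values, path) {
  lines <- vapply(names(values), function(k) {
    v <- values[[k]]
    sprintf("%s = %s", k,
            if (is.numeric(v)) format(v, digits = 15) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
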