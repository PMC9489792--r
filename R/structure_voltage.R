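#' Hydrogen-bond detection criteria
#'
#' Geometric criteria for counting a donor-H...acceptor contact as a
#' hydrogen bond: donor-acceptor distance at or below `max_distance`
#' (default 3 angstrom) and donor-hydrogen-acceptor interior angle at or
#' above `min_angle` (default 150 degrees; 180 = linear). With
#' `carboxylate_dedup` on, a donor satisfying the criteria with both
#' carboxyl oxygens of one Asp/Glu counts one bond, not two.
#'
#' @param max_distance angstrom, > 0.
#' @param min_angle degrees in (0, 180].
#' @param carboxylate_dedup logical (default TRUE).
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.0, min_angle = 150,
                           carboxylate_dedup = TRUE) {
  if (max_distance <= 0) stop("'max_distance' must be > 0")
  if (min_angle <= 0 || min_angle > 180)
    stop("'min_angle' must be in (0, 180]")
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 carboxylate_dedup = carboxylate_dedup),
            class = "hbond_criteria")
}

vec_norm <- function(v) sqrt(sum(v^2))

dha_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

carboxylate_pairs <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect hydrogen bonds in one frame
#'
#' Tests every donor against every acceptor with the distance and angle
#' criteria. Donors are given as pairs of atom indices (heavy atom plus
#' its hydrogen); acceptors as atom indices.
#'
#' @param traj a [trajectory()].
#' @param frame frame index (1-based).
#' @param donors data.frame with columns `donor` and `hydrogen` (atom row
#'   indices into `traj$atoms`).
#' @param acceptors integer vector of acceptor atom row indices.
#' @param criteria an [hbond_criteria()].
#' @return data.frame of bonded pairs: `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle` (after carboxylate deduplication when enabled,
#'   keeping the closer oxygen).
#' @export
detect_hbonds_frame <- function(traj, frame, donors, acceptors,
                                criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "trajectory"), inherits(criteria, "hbond_criteria"))
  donors <- as.data.frame(donors)
  if (!all(c("donor", "hydrogen") %in% names(donors)))
    stop("donors need columns 'donor' and 'hydrogen'")
  na <- nrow(traj$atoms)
  idx <- c(donors$donor, donors$hydrogen, acceptors)
  if (any(idx < 1 | idx > na)) stop("atom index outside the roster")
  xyz <- traj$coords[frame, , , drop = TRUE]
  hits <- list()
  for (i in seq_len(nrow(donors))) {
    d <- xyz[donors$donor[i], ]; h <- xyz[donors$hydrogen[i], ]
    for (a in acceptors) {
      dist <- vec_norm(xyz[a, ] - d)
      if (dist > criteria$max_distance) next
      ang <- dha_angle(d, h, xyz[a, ])
      if (ang < criteria$min_angle) next
      hits[[length(hits) + 1L]] <- data.frame(
        donor = donors$donor[i], hydrogen = donors$hydrogen[i],
        acceptor = a, distance = dist, angle = ang)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
               distance = numeric(), angle = numeric())
  if (criteria$carboxylate_dedup && nrow(out) > 1) {
    at <- traj$atoms
    grp <- vapply(seq_len(nrow(out)), function(i) {
      a <- out$acceptor[i]
      rn <- at$resname[a]
      ox <- carboxylate_pairs[[rn]]
      if (!is.null(ox) && at$name[a] %in% ox)
        paste(out$donor[i], rn, at$resno[a], at$chain[a], "COO", sep = ":")
      else paste(out$donor[i], "atom", a, sep = ":")
    }, character(1))
    keep <- unlist(lapply(split(seq_len(nrow(out)), grp), function(rows) {
      rows[which.min(out$distance[rows])]
    }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Hydrogen-bond probability of a donor-acceptor pair
#'
#' Evaluates the bond criteria in every frame (brute force) and reports
#' the bonded fraction. For a carboxylate acceptor pass both oxygens; the
#' deduplication rule makes them one contact.
#'
#' @param traj a [trajectory()].
#' @param donor,hydrogen atom specs (`"resno:atom"`) or row indices.
#' @param acceptors vector of atom specs or row indices.
#' @param criteria an [hbond_criteria()].
#' @param frames optional frame subset (default all).
#' @return list of class `hbond_stats`: `series` (logical per frame),
#'   `probability`, `n_frames`, `pair` label.
#' @export
hbond_probability <- function(traj, donor, hydrogen, acceptors,
                              criteria = hbond_criteria(), frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (!length(frames)) stop("empty frame selection")
  di <- if (is.numeric(donor)) donor else atom_index(traj, donor)
  hi <- if (is.numeric(hydrogen)) hydrogen else atom_index(traj, hydrogen)
  ai <- if (is.numeric(acceptors)) acceptors else
    vapply(acceptors, atom_index, traj = traj, integer(1))
  donors <- data.frame(donor = di, hydrogen = hi)
  series <- vapply(frames, function(f) {
    nrow(detect_hbonds_frame(traj, f, donors, ai, criteria)) > 0
  }, logical(1))
  structure(list(series = series, probability = mean(series),
                 n_frames = length(frames),
                 pair = paste0(traj$atoms$resname[di], traj$atoms$resno[di],
                               ":", traj$atoms$name[di], " -> ",
                               paste(traj$atoms$name[ai], collapse = "/"))),
            class = "hbond_stats")
}

#' Inward/outward side-chain orientation classification
#'
#' Per frame, the probe atom is classified `inward` when its minimal
#' distance to the inward reference set is strictly smaller than its
#' minimal distance to the outward set; ties classify as `outward`
#' (deterministic rule).
#'
#' @param traj a [trajectory()].
#' @param probe atom spec or row index (e.g. Cz of residue 92).
#' @param inward_refs,outward_refs nonempty vectors of atom specs or row
#'   indices.
#' @param frames optional frame subset.
#' @return list of class `orientation_series`: `class` (character per
#'   frame), `fractions` (named, summing to 1), `d_inward`, `d_outward`.
#' @export
classify_side_chain_orientation <- function(traj, probe, inward_refs,
                                            outward_refs, frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (!length(inward_refs) || !length(outward_refs))
    stop("reference sets must be nonempty")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  pi_ <- if (is.numeric(probe)) probe else atom_index(traj, probe)
  ii <- if (is.numeric(inward_refs)) inward_refs else
    vapply(inward_refs, atom_index, traj = traj, integer(1))
  oi <- if (is.numeric(outward_refs)) outward_refs else
    vapply(outward_refs, atom_index, traj = traj, integer(1))
  d_in <- numeric(length(frames)); d_out <- numeric(length(frames))
  for (k in seq_along(frames)) {
    xyz <- traj$coords[frames[k], , , drop = TRUE]
    p <- xyz[pi_, ]
    d_in[k] <- min(apply(xyz[ii, , drop = FALSE], 1,
                         function(r) vec_norm(r - p)))
    d_out[k] <- min(apply(xyz[oi, , drop = FALSE], 1,
                          function(r) vec_norm(r - p)))
  }
  cls <- ifelse(d_in < d_out, "inward", "outward")
  fr <- c(inward = mean(cls == "inward"), outward = mean(cls == "outward"))
  structure(list(class = cls, fractions = fr,
                 d_inward = d_in, d_outward = d_out),
            class = "orientation_series")
}

#' Distance-angle distribution of a donor-hydrogen-acceptor triple
#'
#' Bins the per-frame (donor-acceptor distance, donor-hydrogen-acceptor
#' angle) pairs into a 2-D histogram whose mass equals the frame count.
#'
#' @param traj a [trajectory()].
#' @param donor,hydrogen,acceptor atom specs or row indices.
#' @param distance_breaks,angle_breaks strictly increasing bin edges
#'   (angstrom / degrees); samples outside are clamped to the edge bins.
#' @param frames optional frame subset.
#' @return list: `counts` matrix `[n_dist_bins x n_angle_bins]`,
#'   `distance_breaks`, `angle_breaks`, `distances`, `angles`.
#' @export
distance_angle_distribution <- function(traj, donor, hydrogen, acceptor,
                                        distance_breaks = seq(1, 8, 0.25),
                                        angle_breaks = seq(0, 180, 5),
                                        frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (any(diff(distance_breaks) <= 0) || any(diff(angle_breaks) <= 0))
    stop("bin edges must be strictly increasing")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  di <- if (is.numeric(donor)) donor else atom_index(traj, donor)
  hi <- if (is.numeric(hydrogen)) hydrogen else atom_index(traj, hydrogen)
  ai <- if (is.numeric(acceptor)) acceptor else atom_index(traj, acceptor)
  dist <- numeric(length(frames)); ang <- numeric(length(frames))
  for (k in seq_along(frames)) {
    xyz <- traj$coords[frames[k], , , drop = TRUE]
    dist[k] <- vec_norm(xyz[ai, ] - xyz[di, ])
    ang[k] <- dha_angle(xyz[di, ], xyz[hi, ], xyz[ai, ])
  }
  bin <- function(x, breaks) {
    i <- findInterval(x, breaks, rightmost.closed = TRUE)
    pmin(pmax(i, 1L), length(breaks) - 1L)
  }
  counts <- matrix(0L, length(distance_breaks) - 1L, length(angle_breaks) - 1L)
  ij <- cbind(bin(dist, distance_breaks), bin(ang, angle_breaks))
  for (r in seq_len(nrow(ij))) counts[ij[r, 1], ij[r, 2]] <-
    counts[ij[r, 1], ij[r, 2]] + 1L
  list(counts = counts, distance_breaks = distance_breaks,
       angle_breaks = angle_breaks, distances = dist, angles = ang)
}

#' Count water oxygens inside a pocket sphere
#'
#' Per frame, counts atoms named `O` of residues named `HOH`/`WAT`/`SOL`
#' within `radius` of the center. The center is either a fixed point
#' (length-3 numeric) or a set of atom specs whose per-frame midpoint
#' defines it.
#'
#' @param traj a [trajectory()].
#' @param center numeric xyz, or vector of atom specs / row indices.
#' @param radius angstrom, >= 0.
#' @param frames optional frame subset.
#' @return integer vector of per-frame counts.
#' @export
count_pocket_waters <- function(traj, center, radius = 5, frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (radius < 0) stop("'radius' must be >= 0")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  wat <- which(traj$atoms$resname %in% c("HOH", "WAT", "SOL") &
               traj$atoms$name == "O")
  if (!length(wat)) {
    warning("no water oxygen records; returning zeros")
    return(integer(length(frames)))
  }
  # character specs or non-length-3 numerics are atom selections whose
  # midpoint moves with the frame; a length-3 numeric is a fixed point
  ci <- NULL
  if (is.character(center)) {
    ci <- vapply(center, atom_index, traj = traj, integer(1))
  } else if (is.numeric(center) && length(center) != 3) {
    ci <- as.integer(center)
  }
  vapply(frames, function(f) {
    xyz <- traj$coords[f, , , drop = TRUE]
    ctr <- if (is.null(ci)) as.numeric(center) else colMeans(xyz[ci, , drop = FALSE])
    sum(vapply(wat, function(w) vec_norm(xyz[w, ] - ctr) <= radius,
               logical(1)))
  }, integer(1))
}

#' Keep the equilibrated tail of a trajectory
#'
#' Frames with `t >= t_end - window` (closed interval), order preserved;
#' the standard last-window rule for discarding equilibration.
#'
#' @param traj a [trajectory()].
#' @param window_ns duration to keep, ns; must not exceed the trajectory
#'   duration. `0` keeps the final frame only.
#' @return a [trajectory()].
#' @export
trajectory_tail <- function(traj, window_ns) {
  stopifnot(inherits(traj, "trajectory"))
  dur <- max(traj$times) - min(traj$times)
  if (window_ns > dur) stop("window exceeds the trajectory duration")
  keep <- which(traj$times >= max(traj$times) - window_ns)
  trajectory(traj$atoms, traj$coords[keep, , , drop = FALSE],
             traj$times[keep])
}
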