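# Shared fixtures: canonical schemes and generator settings used across
# test files. Values mirror the generators' study-condition defaults.

quasar2_scheme <- function(irf_sigma = 0.034) {
  kinetic_scheme(c(0.183, 4, 40, 288, Inf), "sequential",
                 irf_center = 0, irf_sigma = irf_sigma)
}

quasar2_surface <- function(noise_frac = 0, seed = 42, n_wl = 150,
                            t_max = 2e4) {
  sch <- quasar2_scheme()
  wl <- seq(360, 720, length.out = n_wl)
  grid <- tas_delay_grid(t_max = t_max)
  bands <- tas_default_bands(5)
  noise_sd <- 0
  if (noise_frac > 0) {
    clean <- simulate_tas(tas_sim_spec(sch, bands, wl, grid, 0, seed))
    noise_sd <- noise_frac * max(abs(clean$delta_a))
  }
  simulate_tas(tas_sim_spec(sch, bands, wl, grid, noise_sd, seed))
}

branched_surface <- function(phi, noise_frac = 0, seed = 42) {
  sch <- kinetic_scheme(c(40, 288, 2000, Inf), "branched",
                        branch_fraction = phi,
                        irf_center = 0, irf_sigma = 0.034)
  wl <- seq(360, 720, length.out = 150)
  grid <- tas_delay_grid(t_max = 2e4)
  bands <- branched_default_bands()
  noise_sd <- 0
  if (noise_frac > 0) {
    clean <- simulate_tas(tas_sim_spec(sch, bands, wl, grid, 0, seed))
    noise_sd <- noise_frac * max(abs(clean$delta_a))
  }
  simulate_tas(tas_sim_spec(sch, bands, wl, grid, noise_sd, seed))
}

# independent brute-force hydrogen-bond oracle: plain double loop over
# donor-acceptor pairs with its own geometry code
oracle_hbonds <- function(xyz, donors, acceptors, max_dist, min_angle,
                          atoms = NULL, dedup = FALSE) {
  hits <- data.frame(donor = integer(), acceptor = integer())
  for (i in seq_len(nrow(donors))) {
    d <- xyz[donors$donor[i], ]; h <- xyz[donors$hydrogen[i], ]
    for (a in acceptors) {
      v <- xyz[a, ] - d
      dist <- sqrt(sum(v * v))
      u1 <- d - h; u2 <- xyz[a, ] - h
      ang <- acos(min(1, max(-1, sum(u1 * u2) /
        sqrt(sum(u1^2) * sum(u2^2))))) * 180 / pi
      if (dist <= max_dist && ang >= min_angle)
        hits <- rbind(hits, data.frame(donor = donors$donor[i], acceptor = a))
    }
  }
  if (dedup && nrow(hits) > 1 && !is.null(atoms)) {
    coo <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
    key <- vapply(seq_len(nrow(hits)), function(r) {
      a <- hits$acceptor[r]
      ox <- coo[[atoms$resname[a]]]
      if (!is.null(ox) && atoms$name[a] %in% ox)
        paste(hits$donor[r], atoms$resname[a], atoms$resno[a], "COO")
      else paste(hits$donor[r], a)
    }, character(1))
    hits <- hits[!duplicated(key), , drop = FALSE]
  }
  hits
}

lines_to_file <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigid_transform_traj <- function(traj, R, shift) {
  co <- traj$coords
  for (f in seq_len(dim(co)[1])) {
    co[f, , ] <- t(R %*% t(co[f, , , drop = TRUE])) +
      matrix(shift, dim(co)[2], 3, byrow = TRUE)
  }
  trajectory(traj$atoms, co, traj$times)
}
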