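make_frame_traj <- function(xyz, atoms) {
  co <- array(0, dim = c(1, nrow(atoms), 3))
  co[1, , ] <- xyz
  trajectory(atoms, co, 0)
}

simple_atoms <- data.frame(
  serial = 1:4,
  name = c("N", "H", "OD1", "OD2"),
  resname = c("LYS", "LYS", "ASP", "ASP"),
  resno = c(1, 1, 2, 2), chain = "A")

test_that("hydrogen-bond detection applies both geometric cutoffs", {
  don <- data.frame(donor = 1, hydrogen = 2)
  # linear N-H...O at 2.8 A: one bond
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0), c(9, 9, 9))
  tr <- make_frame_traj(xyz, simple_atoms)
  expect_identical(nrow(detect_hbonds_frame(tr, 1, don, c(3, 4))), 1L)
  # distance failure at 3.5 A
  xyz2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.5, 0, 0), c(9, 9, 9))
  tr2 <- make_frame_traj(xyz2, simple_atoms)
  expect_identical(nrow(detect_hbonds_frame(tr2, 1, don, c(3, 4))), 0L)
  # angle failure: acceptor at 90 degrees from the N-H axis
  xyz3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0), c(9, 9, 9))
  tr3 <- make_frame_traj(xyz3, simple_atoms)
  expect_identical(nrow(detect_hbonds_frame(tr3, 1, don, c(3, 4))), 0L)
})

test_that("carboxylate oxygens of one residue count once with dedup", {
  don <- data.frame(donor = 1, hydrogen = 2)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0), c(2.9, 0.3, 0))
  tr <- make_frame_traj(xyz, simple_atoms)
  on <- detect_hbonds_frame(tr, 1, don, c(3, 4), hbond_criteria())
  off <- detect_hbonds_frame(tr, 1, don, c(3, 4),
                             hbond_criteria(carboxylate_dedup = FALSE))
  expect_identical(nrow(on), 1L)
  expect_identical(nrow(off), 2L)
  # dedup keeps the closer oxygen and never increases the count
  expect_equal(on$acceptor, 3)
  expect_lte(nrow(on), nrow(off))
})

test_that("detector equals the brute-force oracle on random fixtures", {
  set.seed(31)
  atoms <- data.frame(
    serial = 1:8,
    name = c("N", "H", "OD1", "OD2", "N", "H", "OE1", "OE2"),
    resname = c("LYS", "LYS", "ASP", "ASP", "ARG", "ARG", "GLU", "GLU"),
    resno = c(1, 1, 2, 2, 3, 3, 4, 4), chain = "A")
  don <- data.frame(donor = c(1, 5), hydrogen = c(2, 6))
  acc <- c(3, 4, 7, 8)
  for (rep in 1:25) {
    xyz <- matrix(runif(24, 0, 5), 8, 3)
    xyz[2, ] <- xyz[1, ] + c(1, 0, 0); xyz[6, ] <- xyz[5, ] + c(1, 0, 0)
    tr <- make_frame_traj(xyz, atoms)
    for (dedup in c(TRUE, FALSE)) {
      got <- detect_hbonds_frame(tr, 1, don, acc,
                                 hbond_criteria(carboxylate_dedup = dedup))
      want <- oracle_hbonds(xyz, don, acc, 3.0, 150, atoms, dedup)
      expect_identical(nrow(got), nrow(want))
      if (nrow(got))
        expect_setequal(paste(got$donor, got$acceptor),
                        paste(want$donor, want$acceptor))
    }
  }
})

test_that("pair probability equals the scripted occupancy", {
  tr <- simulate_trajectory(traj_sim_spec(200, 1, hbond_occupancy = 0.3,
                                          seed = 12))
  hb <- hbond_probability(tr, "1:N", "1:H", c("2:OD1", "2:OD2"))
  expect_equal(hb$probability, 0.3)
  expect_identical(sum(hb$series), 60L)
  expect_equal(hb$probability, mean(hb$series))
  # a vacuous criterion yields zero everywhere
  hb0 <- hbond_probability(tr, "1:N", "1:H", c("2:OD1", "2:OD2"),
                           hbond_criteria(max_distance = 1e-6))
  expect_equal(hb0$probability, 0)
  expect_error(hbond_probability(tr, "1:N", "1:H", "2:OD1", frames = integer()),
               "empty")
})

test_that("orientation classification uses minimal distances and tie rule", {
  atoms <- data.frame(serial = 1:3, name = c("CZ", "CG", "CD"),
                      resname = c("ARG", "GLN", "GLU"),
                      resno = c(92, 95, 204), chain = "A")
  near_in <- make_frame_traj(rbind(c(6, 0, 0), c(10, 0, 0), c(20, 0, 0)),
                             atoms)
  o1 <- classify_side_chain_orientation(near_in, "92:CZ", "95:CG", "204:CD")
  expect_identical(o1$class, "inward")
  # exactly equidistant: outward by the documented tie rule
  tie <- make_frame_traj(rbind(c(15, 0, 0), c(10, 0, 0), c(20, 0, 0)), atoms)
  o2 <- classify_side_chain_orientation(tie, "92:CZ", "95:CG", "204:CD")
  expect_identical(o2$class, "outward")
  expect_equal(sum(o2$fractions), 1)
  expect_error(classify_side_chain_orientation(tie, "92:CZ", character(0),
                                               "204:CD"), "nonempty")
  # scripted 50/50 fixture
  tr <- simulate_trajectory(traj_sim_spec(100, 1, 0.5, 0.5, seed = 2))
  fr <- classify_side_chain_orientation(tr, "92:CZ", "95:CG",
                                        "204:CD")$fractions
  expect_equal(unname(fr), c(0.5, 0.5))
})

test_that("distance-angle histograms conserve frame mass", {
  tr <- simulate_trajectory(traj_sim_spec(60, 1, 0.5, 0.5, seed = 13))
  h <- distance_angle_distribution(tr, "1:N", "1:H", "2:OD1")
  expect_identical(sum(h$counts), 60L)
  # static geometry: all mass in one bin
  tr1 <- simulate_trajectory(traj_sim_spec(20, 1, hbond_occupancy = 1,
                                           seed = 14))
  h1 <- distance_angle_distribution(tr1, "1:N", "1:H", "2:OD1")
  expect_identical(max(h1$counts), 20L)
  # alternating bimodal distances: two equal modes
  tr2 <- simulate_trajectory(traj_sim_spec(40, 1, hbond_occupancy = 0.5,
                                           seed = 15))
  h2 <- distance_angle_distribution(tr2, "1:N", "1:H", "2:OD1")
  modes <- sort(h2$counts[h2$counts > 0], decreasing = TRUE)
  expect_identical(modes[1:2], c(20L, 20L))
  expect_error(distance_angle_distribution(tr2, "1:N", "1:H", "2:OD1",
                                           distance_breaks = c(1, 1)),
               "increasing")
})

test_that("pocket-water counts follow the schedule and radius monotonicity", {
  sched <- c(0, 1, 2, 3, 2, 1)
  tr <- simulate_trajectory(traj_sim_spec(6, 1, 0.5, 0.5,
                                          water_schedule = sched, seed = 16))
  gt <- attr(tr, "ground_truth")
  expect_identical(count_pocket_waters(tr, gt$pocket_center,
                                       gt$pocket_radius),
                   as.integer(sched))
  expect_identical(count_pocket_waters(tr, gt$pocket_center, 0),
                   rep(0L, 6))
  c1 <- count_pocket_waters(tr, gt$pocket_center, gt$pocket_radius)
  c2 <- count_pocket_waters(tr, gt$pocket_center, 2 * gt$pocket_radius)
  expect_true(all(c2 >= c1))
  # no waters at all: zeros with a warning
  no_wat <- simulate_trajectory(traj_sim_spec(3, 1, 0.5, 0.5,
                                              water_schedule = 0L, seed = 1))
  no_wat$atoms$resname[no_wat$atoms$resname == "HOH"] <- "XXX"
  expect_warning(z <- count_pocket_waters(no_wat, c(0, 0, 0), 5), "no water")
  expect_identical(z, rep(0L, 3))
})

test_that("geometry analyses are invariant under rigid motions", {
  tr <- simulate_trajectory(traj_sim_spec(40, 1, 0.35, 0.6,
                                          water_schedule = c(1, 2),
                                          geometry_noise = 0.02, seed = 17))
  R <- random_rotation(99)
  moved <- rigid_transform_traj(tr, R, c(12.3, -4.5, 7.7))
  hb0 <- hbond_probability(tr, "1:N", "1:H", c("2:OD1", "2:OD2"))
  hb1 <- hbond_probability(moved, "1:N", "1:H", c("2:OD1", "2:OD2"))
  expect_identical(hb0$series, hb1$series)
  o0 <- classify_side_chain_orientation(tr, "92:CZ", "95:CG", "204:CD")
  o1 <- classify_side_chain_orientation(moved, "92:CZ", "95:CG", "204:CD")
  expect_identical(o0$class, o1$class)
  h0 <- distance_angle_distribution(tr, "1:N", "1:H", "2:OD1")
  h1 <- distance_angle_distribution(moved, "1:N", "1:H", "2:OD1")
  expect_identical(h0$counts, h1$counts)
  # pocket center defined from atoms moves with the frame
  w0 <- count_pocket_waters(tr, c("95:CG", "204:CD"), 40)
  w1 <- count_pocket_waters(moved, c("95:CG", "204:CD"), 40)
  expect_identical(w0, w1)
})

test_that("tail selection keeps the closed last-window interval", {
  tr <- simulate_trajectory(traj_sim_spec(201, 1, 0.5, 0.5, seed = 18))
  # 0..200 ns; last 100 ns keeps t >= 100
  tail_tr <- trajectory_tail(tr, 100)
  expect_true(all(tail_tr$times >= 100))
  expect_identical(length(tail_tr$times), 101L)
  # full window is the identity
  expect_identical(trajectory_tail(tr, 200)$times, tr$times)
  # zero window keeps the final frame only
  expect_identical(trajectory_tail(tr, 0)$times, 200)
  expect_error(trajectory_tail(tr, 500), "duration")
})
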