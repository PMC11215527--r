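# Salt-bridge / hydrogen-bond / hydrophobic detectors and occupancy.

# minimal Arg / Glu pair with controllable N-O distance: guanidinium
# nitrogens at x = 0, carboxylate oxygens at x = d
arg_glu_frame <- function(d) {
  atoms <- data.frame(
    chain = c("A", "A", "A", "A", "B", "B", "B"),
    resno = c(10, 10, 10, 10, 40, 40, 40),
    resname = c("ARG", "ARG", "ARG", "ARG", "GLU", "GLU", "GLU"),
    atom = c("CA", "NE", "NH1", "NH2", "CA", "OE1", "OE2"))
  xyz <- rbind(c(-2, 0, 0), c(0, 0, 0), c(0, 1.5, 0), c(0, -1.5, 0),
               c(d + 2, 0, 0), c(d, 0, 0), c(d, 2, 0))
  structure_frame(atoms, xyz)
}

sb_pair <- contact_pair("salt_bridge", list(chain = "A", resno = 10),
                        list(chain = "B", resno = 40))

test_that("salt bridges follow the 4-A closed boundary", {
  expect_true(detect_salt_bridge(arg_glu_frame(3.9), sb_pair))
  expect_true(detect_salt_bridge(arg_glu_frame(4.0), sb_pair))
  expect_false(detect_salt_bridge(arg_glu_frame(4.1), sb_pair))
})

test_that("salt-bridge detection matches a brute-force oracle on random frames", {
  set.seed(70)
  crit <- contact_criteria()
  for (i in 1:300) {
    fr <- random_pair_frame(runif(1, 2, 8))
    got <- detect_salt_bridge(fr, sb_pair, crit)
    ia <- which(fr$atoms$resname == "ARG" &
                  fr$atoms$atom %in% c("NE", "NH1", "NH2"))
    ib <- which(fr$atoms$resname == "GLU" &
                  fr$atoms$atom %in% c("OE1", "OE2"))
    expect_identical(got, brute_min_dist(fr$xyz, ia, ib) <= 4.0)
  }
})

test_that("histidine participates as a basic nitrogen unless disabled", {
  atoms <- data.frame(chain = c("A", "A", "B", "B"),
                      resno = c(1, 1, 2, 2),
                      resname = c("HIS", "HIS", "ASP", "ASP"),
                      atom = c("CA", "NE2", "CA", "OD1"))
  fr <- structure_frame(atoms, rbind(c(-2, 0, 0), c(0, 0, 0),
                                     c(5.5, 0, 0), c(3.5, 0, 0)))
  pr <- contact_pair("salt_bridge", list(chain = "A", resno = 1),
                     list(chain = "B", resno = 2))
  expect_true(detect_salt_bridge(fr, pr))
  expect_error(detect_salt_bridge(fr, pr,
                                  contact_criteria(his_is_basic = FALSE)),
               "resolve")
})

test_that("hydrogen bonds require both the distance and the angle criterion", {
  mk_hb <- function(d, angle_deg) {
    th <- angle_deg * pi / 180
    atoms <- data.frame(chain = c("A", "A", "A", "B", "B"),
                        resno = c(1, 1, 1, 2, 2),
                        resname = c("SER", "SER", "SER", "GLU", "GLU"),
                        atom = c("CA", "OG", "HG1", "CA", "OE1"))
    xyz <- rbind(c(-2, 0, 0), c(0, 0, 0),
                 c(cos(th), sin(th), 0),       # H at the given D-H angle
                 c(d + 2, 0, 0), c(d, 0, 0))   # acceptor along +x
    structure_frame(atoms, xyz)
  }
  pr <- contact_pair("hbond",
                     list(chain = "A", resno = 1, donor_atom = "OG",
                          hydrogen = "HG1"),
                     list(chain = "B", resno = 2, acceptor_atom = "OE1"))
  expect_true(detect_hbond(mk_hb(3.4, 25), pr))
  expect_false(detect_hbond(mk_hb(3.4, 35), pr))
  expect_false(detect_hbond(mk_hb(3.6, 10), pr))
  expect_true(detect_hbond(mk_hb(3.5, 30), pr))   # closed boundary
  # missing explicit hydrogen is an error, not an inference
  broken <- mk_hb(3.4, 25)
  broken$atoms$atom[3] <- "XX1"
  expect_error(detect_hbond(broken, pr), "hydrogen")
})

test_that("hydrophobic contacts use side-chain carbons only", {
  mk_phe <- function(d_cb, d_backbone) {
    atoms <- data.frame(chain = c("A", "A", "A", "B", "B", "B"),
                        resno = c(1, 1, 1, 2, 2, 2),
                        resname = c("LEU", "LEU", "LEU", "PHE", "PHE", "PHE"),
                        atom = c("C", "CA", "CB", "C", "CA", "CB"))
    xyz <- rbind(c(0, 5, 0), c(0, 3, 0), c(0, 0, 0),
                 c(d_backbone, 5, 0), c(d_backbone, 3, 0), c(d_cb, 0, 0))
    structure_frame(atoms, xyz)
  }
  pr <- contact_pair("hydrophobic", list(chain = "A", resno = 1),
                     list(chain = "B", resno = 2))
  expect_true(detect_hydrophobic(mk_phe(7.5, 20), pr))
  expect_true(detect_hydrophobic(mk_phe(8.0, 20), pr))
  # backbone carbons at 6 A do not count when side chains are apart
  expect_false(detect_hydrophobic(mk_phe(9, 6), pr))
  # glycine partner has no side-chain carbon
  gly <- mk_phe(7, 7)
  gly$atoms$resname[4:6] <- "GLY"
  gly$atoms <- gly$atoms[-6, ]; gly$xyz <- gly$xyz[-6, ]
  expect_error(detect_hydrophobic(gly, pr), "side-chain")
})

test_that("hydrophobic detection matches a brute-force oracle on random frames", {
  set.seed(71)
  crit <- contact_criteria()
  pr <- contact_pair("hydrophobic", list(chain = "A", resno = 10),
                     list(chain = "B", resno = 40))
  for (i in 1:300) {
    fr <- random_pair_frame(runif(1, 4, 12))
    got <- detect_hydrophobic(fr, pr, crit)
    side <- function(ch) which(fr$atoms$chain == ch &
                                 substr(fr$atoms$atom, 1, 1) == "C" &
                                 !fr$atoms$atom %in% c("C", "CA"))
    expect_identical(got, brute_min_dist(fr$xyz, side("A"), side("B")) <= 8.0)
  }
})

test_that("contact detection is invariant under global rotation and translation", {
  set.seed(72)
  for (i in 1:50) {
    fr <- random_pair_frame(runif(1, 3, 6))
    R <- rot_oracle(rnorm(3), runif(1, 0, 360))
    fr2 <- fr
    fr2$xyz <- sweep(fr$xyz %*% t(R), 2, rnorm(3, sd = 20), "+")
    expect_identical(detect_salt_bridge(fr, sb_pair),
                     detect_salt_bridge(fr2, sb_pair))
  }
})

test_that("occupancy is exact on programmed contact schedules", {
  # frames alternate between a bridged (3 A) and a broken (6 A) geometry
  sched <- rep(c(TRUE, FALSE), 500)
  frames <- lapply(sched, function(on) arg_glu_frame(if (on) 3 else 6))
  traj <- md_trajectory(frames)
  occ <- contact_occupancy(traj, sb_pair)
  expect_equal(occ$pooled, 0.5)
  expect_identical(occ$n_frames, 1000L)
  # contact in every frame
  occ1 <- contact_occupancy(md_trajectory(list(arg_glu_frame(3),
                                               arg_glu_frame(3))), sb_pair)
  expect_equal(occ1$pooled, 1)
  # pooling across equal-length trajectories averages the fractions
  t_a <- md_trajectory(lapply(c(3, 6, 6, 6, 6), arg_glu_frame))
  t_b <- md_trajectory(lapply(c(3, 3, 3, 3, 6), arg_glu_frame))
  occ2 <- contact_occupancy(list(t_a, t_b), sb_pair)
  expect_equal(occ2$per_trajectory, c(0.2, 0.8))
  expect_equal(occ2$pooled, 0.5)
})
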