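# Generators: trap traces, tracks, rigid-body trajectories.

test_that("unbound bead force variance obeys equipartition", {
  # var(F) = k^2 var(x) = k * kBT for an Ornstein-Uhlenbeck bead; sampled
  # at 50 kHz so block-average attenuation is negligible
  p <- motor_trap_params(reattach_rate = 0, sample_rate = 50000,
                         duration = 5, seed = 2)
  tr <- simulate_trap_trace(p)
  expect_equal(var(tr$force), p$trap_stiffness * p$thermal_energy,
               tolerance = 0.05)
})

test_that("noise-free motor rises monotonically and plateaus at the stall force", {
  p <- motor_trap_params(thermal_energy = 0, stall_force = 4,
                         detach_rate_at_stall = 0, reattach_rate = 1e9,
                         duration = 3, seed = 3)
  tr <- simulate_trap_trace(p)
  expect_false(is.unsorted(tr$force))
  expect_lte(max(tr$force), 4)
  expect_equal(max(tr$force), 4, tolerance = 0.01)
})

test_that("trap trace generation is seed-deterministic", {
  a <- simulate_trap_trace(motor_trap_params(seed = 7, duration = 1))
  b <- simulate_trap_trace(motor_trap_params(seed = 7, duration = 1))
  expect_identical(a$force, b$force)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("ground-truth annotations exactly tile the trace", {
  tr <- simulate_trap_trace(ddb_trap_params("mutant", duration = 6, seed = 9))
  gt <- tr$ground_truth
  expect_equal(gt$start_s[1], 0)
  expect_equal(gt$end_s[nrow(gt)], length(tr$force) / tr$sample_rate,
               tolerance = 1e-9)
  expect_equal(gt$start_s[-1], gt$end_s[-nrow(gt)], tolerance = 1e-12)
})

test_that("unbound trace autocorrelation decays with the bead relaxation time", {
  p <- motor_trap_params(reattach_rate = 0, sample_rate = 50000,
                         duration = 20, seed = 4)
  tr <- simulate_trap_trace(p)
  tau_true <- p$bead_drag / p$trap_stiffness
  ac <- stats::acf(tr$force, lag.max = 60, plot = FALSE)$acf[, 1, 1]
  lags <- (0:60) / p$sample_rate
  # fit log-acf over the first decade of decay
  sel <- ac > 0.05
  tau_hat <- -1 / coef(stats::lm(log(ac[sel]) ~ lags[sel]))[2]
  expect_equal(unname(tau_hat), tau_true, tolerance = 0.1)
})

test_that("simulator rejects an integration step above the relaxation time", {
  p <- motor_trap_params(bead_drag = 1e-7)   # relax time ~1.7e-6 s
  expect_error(simulate_trap_trace(p), "relaxation")
})

test_that("processive and static tracks follow their programmed law", {
  p <- track_params("processive", velocity = 500, duration = 2,
                    localization_noise_sd = 0, seed = 1)
  tr <- simulate_track(p)
  expect_equal(tr$position[length(tr$position)] - tr$position[1], 1000)
  p2 <- track_params("static", localization_noise_sd = 0, duration = 2,
                     seed = 1)
  tr2 <- simulate_track(p2)
  expect_true(all(tr2$position == tr2$position[1]))
})

test_that("diffusive tracks satisfy the 1-D MSD closed form", {
  D <- 1e4
  set.seed(10)
  lag <- 5                                   # frames
  msd <- replicate(200, {
    tr <- simulate_track(track_params("diffusive", diffusion_coeff = D,
                                      duration = 10, frame_interval = 0.1,
                                      localization_noise_sd = 0))
    mean((tr$position[-(1:lag)] - head(tr$position, -lag))^2)
  })
  expect_equal(mean(msd), 2 * D * lag * 0.1, tolerance = 0.1)
})

test_that("track generation is seed-deterministic", {
  a <- simulate_track(track_params("diffusive", seed = 5))
  b <- simulate_track(track_params("diffusive", seed = 5))
  expect_identical(a$position, b$position)
})

test_that("rigid-body trajectory generator honours its programmed rotations", {
  ref <- demo_mtbd_reference()
  # zero rotation, zero noise: every frame identical to the reference
  tp <- trajectory_params(ref$frame, n_frames = 3, seed = 1)
  traj <- simulate_mtbd_trajectory(tp)
  for (i in 1:3)
    expect_equal(traj$coords[, , i], ref$frame$xyz, ignore_attr = TRUE)
  # fixed +10 degree rotation of the dynein only, zero noise
  tp2 <- trajectory_params(ref$frame,
                           angle_components = data.frame(weight = 1,
                                                         mean_deg = 10,
                                                         sd_deg = 0),
                           axis = c(0, 0, 1), n_frames = 2,
                           mobile = ref$mobile, seed = 1)
  traj2 <- simulate_mtbd_trajectory(tp2)
  R <- rot_oracle(c(0, 0, 1), 10)
  expect_equal(traj2$coords[ref$mobile, , 1],
               ref$frame$xyz[ref$mobile, ] %*% t(R), ignore_attr = TRUE,
               tolerance = 1e-12)
  # tubulin untouched
  expect_equal(traj2$coords[ref$tubulin, , 1], ref$frame$xyz[ref$tubulin, ],
               ignore_attr = TRUE)
})

test_that("isotropic positional noise gives RMSF sqrt(3) sigma", {
  ref <- demo_mtbd_reference()
  tp <- trajectory_params(ref$frame, positional_noise_sd = 0.5,
                          n_frames = 10000, seed = 6)
  traj <- simulate_mtbd_trajectory(tp)
  # report atoms within the alignment body so the residual alignment
  # error (noise-limited) stays negligible against the closed form
  prof <- rmsf_profile(traj, align_sel = ref$tubulin,
                       report_sel = ref$tubulin,
                       reference = ref$frame)
  expect_equal(mean(prof$rmsf_A), sqrt(3) * 0.5, tolerance = 0.02)
})

test_that("ground-truth rotation angles reproduce the programmed mixture", {
  ref <- demo_mtbd_reference()
  comp <- data.frame(weight = c(0.6, 0.4), mean_deg = c(11.5, -7.9),
                     sd_deg = c(4, 4))
  tp <- trajectory_params(ref$frame, angle_components = comp,
                          n_frames = 4000, mobile = ref$mobile, seed = 8)
  traj <- simulate_mtbd_trajectory(tp)
  gt <- traj$ground_truth
  for (k in 1:2) {
    a <- gt$angle_deg[gt$component == k]
    expect_equal(mean(a), comp$mean_deg[k], tolerance = 0.2)
    expect_equal(sd(a), comp$sd_deg[k], tolerance = 0.1)
  }
  expect_equal(mean(gt$component == 1), 0.6, tolerance = 0.05)
})

test_that("degenerate rotation axis is rejected", {
  ref <- demo_mtbd_reference()
  expect_error(trajectory_params(ref$frame, axis = c(0, 0, 0)), "axis")
})

test_that("trap traces round-trip through delimited text with ground truth", {
  tr <- simulate_trap_trace(ddb_trap_params("wt", duration = 0.5, seed = 12),
                            label = "rt")
  path <- withr::local_tempfile(fileext = ".txt")
  write_trap_trace(tr, path)
  back <- read_trap_trace(path)
  expect_equal(back$force, tr$force, tolerance = 1e-8)
  expect_equal(back$sample_rate, tr$sample_rate)
  expect_equal(back$spring_constant, tr$spring_constant)
  expect_equal(back$label, "rt")
  expect_equal(back$ground_truth$kind, tr$ground_truth$kind)
})

test_that("tracks round-trip through CSV", {
  trk <- simulate_track(track_params("processive", seed = 3), track_id = "a",
                        microtubule_id = "mt1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(list(trk), path)
  back <- read_tracks_csv(path)
  expect_equal(back[["a"]]$position, trk$position, tolerance = 1e-8)
})
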