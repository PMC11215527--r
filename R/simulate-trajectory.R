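#' Parameters for the rigid-body MTBD trajectory generator
#'
#' Each generated frame is the reference structure rotated about a given
#' axis (through a given origin) by an angle drawn from a Gaussian mixture,
#' plus isotropic Gaussian positional noise per atom.  The drawn angles are
#' stored as ground truth, which makes the generator a controlled input for
#' the angle, RMSF and contact analyses.
#'
#' @param reference A [structure_frame()]; the unrotated conformation.
#' @param angle_components Data frame with columns `weight`, `mean_deg`,
#'   `sd_deg`; weights must sum to 1.
#' @param axis Length-3 rotation axis (need not be unit length).
#' @param origin Point the rotation axis passes through (default: origin).
#' @param positional_noise_sd Isotropic per-atom noise, Angstrom.
#' @param n_frames Number of frames.
#' @param mobile Indices of atoms subjected to the rotation (default: all);
#'   atoms outside `mobile` receive noise only.  Use this to keep a tubulin
#'   body static while the MTBD rocks.
#' @param contact_schedule Optional logical vector (length `n_frames`);
#'   stored as ground truth for contact-occupancy tests.
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(reference,
                              angle_components = data.frame(
                                weight = 1, mean_deg = 0, sd_deg = 0),
                              axis = c(0, 0, 1), origin = c(0, 0, 0),
                              positional_noise_sd = 0, n_frames = 1,
                              mobile = NULL, contact_schedule = NULL,
                              seed = NULL) {
  stopifnot(inherits(reference, "structure_frame"))
  if (nrow(reference$atoms) == 0) stop("reference must be non-empty")
  if (abs(sum(angle_components$weight) - 1) > 1e-9)
    stop("mixture weights must sum to 1")
  if (any(angle_components$sd_deg < 0)) stop("component sds must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (sqrt(sum(axis^2)) < 1e-12) stop("degenerate rotation axis")
  if (positional_noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(reference = reference, angle_components = angle_components,
                 axis = axis / sqrt(sum(axis^2)), origin = origin,
                 positional_noise_sd = positional_noise_sd,
                 n_frames = n_frames, mobile = mobile,
                 contact_schedule = contact_schedule, seed = seed),
            class = "trajectory_params")
}

# Rotation matrix for angle theta (deg) about unit axis u (Rodrigues)
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Simulate a rigid-body MTBD-like trajectory
#'
#' @param params A [trajectory_params()] object.
#' @return A [md_trajectory()] whose `ground_truth` data frame carries the
#'   drawn rotation angle (`angle_deg`), mixture component, and (when a
#'   schedule was supplied) the programmed contact state per frame.
#' @export
simulate_mtbd_trajectory <- function(params) {
  stopifnot(inherits(params, "trajectory_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  ref <- params$reference
  n <- nrow(ref$xyz)
  mobile <- params$mobile %||% seq_len(n)
  comp <- params$angle_components
  nf <- params$n_frames
  which_comp <- sample.int(nrow(comp), nf, replace = TRUE, prob = comp$weight)
  angles <- rnorm(nf, mean = comp$mean_deg[which_comp],
                  sd = comp$sd_deg[which_comp])
  coords <- array(NA_real_, c(n, 3, nf))
  origin <- matrix(params$origin, n, 3, byrow = TRUE)
  for (i in seq_len(nf)) {
    xyz <- ref$xyz
    R <- rotation_matrix(params$axis, angles[i])
    xyz[mobile, ] <- sweep((sweep(xyz[mobile, , drop = FALSE], 2,
                                  params$origin) %*% t(R)), 2,
                           params$origin, "+")
    if (params$positional_noise_sd > 0)
      xyz <- xyz + matrix(rnorm(n * 3, sd = params$positional_noise_sd), n, 3)
    coords[, , i] <- xyz
  }
  gt <- data.frame(frame = seq_len(nf), angle_deg = angles,
                   component = which_comp)
  if (!is.null(params$contact_schedule))
    gt$contact <- rep_len(params$contact_schedule, nf)
  structure(list(atoms = ref$atoms, coords = coords, frame_interval = 1,
                 ground_truth = gt),
            class = "md_trajectory")
}

#' Synthetic MTBD-tubulin reference structure
#'
#' Builds a small, fully synthetic stand-in for the MTBD-tubulin system:
#' a rod of pseudo-tubulin atoms along +z (the protofilament long axis,
#' PA1), and a dynein stalk-base/MTBD assembly offset along +x (the radial
#' axis, PA2) carrying the Calpha anchor residues used by the angle
#' analyses (A3295/W3395 defining the anchor centre, A3288/Y3402 the MTBD
#' vector tip, and R3191/S3501 the stalk vector tip).  This object is a
#' synthetic fixture generator, not a deposited structure.
#'
#' @param n_tubulin Number of pseudo-tubulin atoms in the rod.  The
#'   default (200) gives the body enough transverse extent that frame
#'   alignment against it is well conditioned in all three rotations.
#' @param rod_length Rod length along z, Angstrom.
#' @param rod_radius Transverse radius of the rod, Angstrom; must stay
#'   well below `rod_length` so the inertia tensor is clearly prolate.
#' @param anchor_offset Distance of the stalk-base anchor centre from the
#'   rod axis, Angstrom.
#' @param mtbd_length Length of the MTBD vector, Angstrom.
#' @param stalk_length Length of the stalk vector, Angstrom.
#' @param stalk_angle_deg Angle of the stalk vector to the rod long axis
#'   (PA1), degrees.
#' @return A list with elements `frame` (a [structure_frame()]),
#'   `tubulin` / `dynein` (atom index vectors) and `mobile` (the dynein
#'   indices; suitable as `mobile` in [trajectory_params()]).
#' @export
demo_mtbd_reference <- function(n_tubulin = 200, rod_length = 80,
                                rod_radius = 10, anchor_offset = 30,
                                mtbd_length = 20, stalk_length = 100,
                                stalk_angle_deg = 60) {
  # deterministic helical cloud, symmetrized in quadruplets
  # (x,y,z) / (-x,-y,z) / (x,y,-z) / (-x,-y,-z) so the centroid and the
  # xz / yz inertia products vanish exactly: +z is then an exact
  # principal axis, while the transverse spread pins the azimuth
  m <- max(2L, ceiling(n_tubulin / 4))
  n_tubulin <- 4L * m
  zb <- seq(rod_length / 8, rod_length / 2, length.out = m)
  phi <- 2.399963 * seq_len(m)
  r <- rod_radius * sqrt(seq_len(m) %% 5 + 1) / sqrt(5)
  base <- cbind(r * cos(phi), r * sin(phi), zb)
  tub <- rbind(base,
               cbind(-base[, 1], -base[, 2], base[, 3]),
               cbind(base[, 1], base[, 2], -base[, 3]),
               -base)
  tub_atoms <- data.frame(chain = "T", resno = seq_len(n_tubulin),
                          resname = "TUB", atom = "CA", element = "C")
  # anchor centre at (anchor_offset, 0, 0); A3295 / W3395 straddle it
  anchor <- c(anchor_offset, 0, 0)
  a3295 <- anchor + c(0, 0, 3)
  w3395 <- anchor - c(0, 0, 3)
  # MTBD vector tip: +x of the anchor centre (radially outward)
  tip <- anchor + c(mtbd_length, 0, 0)
  a3288 <- tip + c(0, 0, 2)
  y3402 <- tip - c(0, 0, 2)
  # stalk tip at stalk_angle_deg from +z (PA1), in the x-z plane
  th <- stalk_angle_deg * pi / 180
  stalk_tip <- anchor + stalk_length * c(sin(th), 0, cos(th))
  r3191 <- stalk_tip + c(0, 0, 1.5)
  s3501 <- stalk_tip - c(0, 0, 1.5)
  dyn_xyz <- rbind(a3295, w3395, a3288, y3402, r3191, s3501)
  dyn_atoms <- data.frame(chain = "D",
                          resno = c(3295, 3395, 3288, 3402, 3191, 3501),
                          resname = c("ALA", "TRP", "ALA", "TYR",
                                      "ARG", "SER"),
                          atom = "CA", element = "C")
  frame <- structure_frame(rbind(tub_atoms, dyn_atoms), rbind(tub, dyn_xyz))
  list(frame = frame, tubulin = seq_len(n_tubulin),
       dynein = n_tubulin + seq_len(6), mobile = n_tubulin + seq_len(6))
}
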