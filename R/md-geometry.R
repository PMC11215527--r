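#' Least-squares superposition (Kabsch)
#'
#' RMSD-minimizing rigid transform of `mobile` onto `reference` over a
#' selection, with a proper rotation enforced (det = +1; reflections are
#' never returned).
#'
#' @param mobile,reference [structure_frame()] objects (or plain `n x 3`
#'   matrices).
#' @param sel_mobile,sel_reference Atom indices of the fitted selection
#'   (defaults: all atoms; lengths must match, at least 3 non-collinear
#'   points).
#' @return A list of class `rigid_transform`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom, over the selection).
#'   Apply with [apply_transform()].
#' @export
superpose <- function(mobile, reference, sel_mobile = NULL,
                      sel_reference = NULL) {
  P <- if (inherits(mobile, "structure_frame")) mobile$xyz else as.matrix(mobile)
  Q <- if (inherits(reference, "structure_frame")) reference$xyz else as.matrix(reference)
  if (!is.null(sel_mobile)) P <- P[sel_mobile, , drop = FALSE]
  if (!is.null(sel_reference)) Q <- Q[sel_reference, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selections must have equal length")
  if (nrow(P) < 3) stop("need at least 3 atoms to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(t(Pc) %*% Qc)
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("degenerate (collinear) selection: superposition is not unique")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param xyz `n x 3` matrix or [structure_frame()].
#' @param transform A `rigid_transform` from [superpose()].
#' @return Transformed coordinates (same type as the input).
#' @export
apply_transform <- function(xyz, transform) {
  if (inherits(xyz, "structure_frame")) {
    xyz$xyz <- apply_transform(xyz$xyz, transform)
    return(xyz)
  }
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Microtubule-referenced principal axes
#'
#' Axes of the tubulin body, referenced to the bound dynein: the origin is
#' the tubulin centre of mass; PA1 is the long (protofilament) axis, i.e.
#' the smallest-moment principal axis of the unit-mass inertia tensor,
#' with its sign matched to a reference; PA2 is the radial axis, the
#' component of the vector from the origin to the dynein anchor centre
#' (centre of the A3295 and W3395 Calpha atoms) orthogonal to PA1,
#' normalized; PA3 = PA1 x PA2 is the tangential axis, completing a
#' right-handed orthonormal triad.
#'
#' @param tubulin_xyz `n x 3` coordinates of the tubulin selection.
#' @param anchor_center Length-3 centre of the dynein anchor atoms.
#' @param reference A `principal_axes` object used only to fix the sign of
#'   PA1 (dot product > 0); when `NULL` the sign makes the largest-
#'   magnitude component of PA1 positive.
#' @return A list of class `principal_axes`: `origin`, `PA1`, `PA2`,
#'   `PA3` (unit vectors).
#' @export
principal_axes <- function(tubulin_xyz, anchor_center, reference = NULL) {
  X <- unname(as.matrix(tubulin_xyz))
  if (nrow(X) < 3) stop("tubulin selection too small")
  anchor_center <- unname(as.numeric(anchor_center))
  origin <- colMeans(X)
  Xc <- sweep(X, 2, origin)
  # unit-mass inertia tensor: I = tr(C) * Id - C with C the gyration tensor
  C <- t(Xc) %*% Xc
  I <- diag(3) * sum(diag(C)) - C
  e <- eigen(I, symmetric = TRUE)
  mom <- e$values            # descending
  if ((mom[2] - mom[3]) / mom[1] < 1e-6)
    stop("near-spherical inertia tensor: the long axis is ambiguous")
  pa1 <- e$vectors[, 3]      # smallest moment = long axis
  if (!is.null(reference)) {
    if (sum(pa1 * reference$PA1) < 0) pa1 <- -pa1
  } else if (pa1[which.max(abs(pa1))] < 0) pa1 <- -pa1
  radial <- anchor_center - origin
  radial <- radial - sum(radial * pa1) * pa1
  nr <- sqrt(sum(radial^2))
  if (nr < 1e-8) stop("anchor centre lies on the long axis; PA2 undefined")
  pa2 <- radial / nr
  pa3 <- c(pa1[2] * pa2[3] - pa1[3] * pa2[2],
           pa1[3] * pa2[1] - pa1[1] * pa2[3],
           pa1[1] * pa2[2] - pa1[2] * pa2[1])
  structure(list(origin = origin, PA1 = pa1, PA2 = pa2, PA3 = pa3),
            class = "principal_axes")
}

# signed angle (deg) from u to w around unit normal nrm, all in one plane
signed_angle <- function(u, w, nrm) {
  cross <- c(u[2] * w[3] - u[3] * w[2],
             u[3] * w[1] - u[1] * w[3],
             u[1] * w[2] - u[2] * w[1])
  atan2(sum(nrm * cross), sum(u * w)) * 180 / pi
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# centre of the Calpha atoms of the given residues
anchor_center_of <- function(frame, resno, chain = NULL) {
  idx <- select_atoms(frame, chain = chain, resno = resno, atom = "CA")
  if (length(idx) < length(resno))
    stop("anchor residues not all present: ", paste(resno, collapse = ", "))
  colMeans(frame$xyz[idx, , drop = FALSE])
}

#' Per-frame MTBD orientation angle
#'
#' The MTBD vector points from the centre of the A3295/W3395 Calpha atoms
#' to the centre of the A3288/Y3402 Calpha atoms.  It is projected onto
#' the configured plane and the signed angle to PA2 is reported, positive
#' ("clockwise") for rotation from PA2 towards +PA3 when viewed down +PA1.
#' The default plane is PA2-PA3, the plane perpendicular to the
#' microtubule long axis, which is the plane in which MTBD tilting around
#' the protofilament is defined; the literal PA1-PA2 projection is also
#' available.
#'
#' @param frame A [structure_frame()].
#' @param axes A [principal_axes()] object.
#' @param plane `"PA2PA3"` (default) or `"PA1PA2"`.
#' @param reference_zero Angle subtracted from the raw value so that a
#'   chosen reference conformation reads 0 degrees.
#' @param base_resno,tip_resno Calpha anchor residues of the vector base
#'   and tip.
#' @param chain Optional chain restriction for the anchors.
#' @return Signed angle in degrees, in (-180, 180].
#' @export
mtbd_angle <- function(frame, axes, plane = c("PA2PA3", "PA1PA2"),
                       reference_zero = 0,
                       base_resno = c(3295, 3395),
                       tip_resno = c(3288, 3402), chain = NULL) {
  plane <- match.arg(plane)
  v <- anchor_center_of(frame, tip_resno, chain) -
    anchor_center_of(frame, base_resno, chain)
  if (plane == "PA2PA3") {
    b <- sum(v * axes$PA2); c3 <- sum(v * axes$PA3)
    proj <- b * axes$PA2 + c3 * axes$PA3
    nrm <- axes$PA1
  } else {
    a <- sum(v * axes$PA1); b <- sum(v * axes$PA2)
    proj <- a * axes$PA1 + b * axes$PA2
    nrm <- axes$PA3
  }
  if (sqrt(sum(proj^2)) < 1e-9)
    stop("projected MTBD vector is near zero; angle undefined")
  wrap_angle(signed_angle(axes$PA2, proj, nrm) - reference_zero)
}

#' MTBD angle series over a trajectory
#'
#' @param traj A [md_trajectory()].
#' @param axes A [principal_axes()] object (from the reference structure).
#' @param ... Passed to [mtbd_angle()].
#' @return A data frame of class `angle_series` with columns `frame` and
#'   `angle_deg`.
#' @export
mtbd_angles <- function(traj, axes, ...) {
  ang <- vapply(seq_len(n_frames(traj)), function(i)
    mtbd_angle(trajectory_frame(traj, i), axes, ...), numeric(1))
  out <- data.frame(frame = seq_along(ang), angle_deg = ang)
  class(out) <- c("angle_series", class(out))
  out
}

#' Stalk angle relative to the microtubule long axis
#'
#' The stalk tip (R3191/S3501) is not part of the simulated MTBD-stalk
#' fragment, so a full-length structure is first superposed onto the
#' frame via the Calpha atoms of the stalk base; the stalk vector then
#' runs from the centre of the frame's A3295/W3395 Calpha atoms to the
#' centre of R3191/S3501 of the superposed full structure.  The reported
#' angle is the unsigned angle between the stalk vector and PA1, in
#' [0, 180).
#'
#' @param frame A [structure_frame()] (one MD conformation).
#' @param axes A [principal_axes()] object.
#' @param full_structure A [structure_frame()] containing the stalk tip
#'   residues.
#' @param align_resno Calpha residues used for the superposition (present
#'   in both `frame` and `full_structure`).
#' @param base_resno,tip_resno Stalk vector base (in the frame) and tip
#'   (in the superposed full structure) residues.
#' @param chain Optional chain restriction.
#' @param max_align_rmsd Superposition RMSD (Angstrom) above which the
#'   frame is flagged with a warning.
#' @return Angle in degrees.
#' @export
stalk_angle <- function(frame, axes, full_structure,
                        align_resno = c(3288, 3295, 3395, 3402),
                        base_resno = c(3295, 3395),
                        tip_resno = c(3191, 3501), chain = NULL,
                        max_align_rmsd = 2) {
  sel_f <- select_atoms(frame, chain = chain, resno = align_resno, atom = "CA")
  sel_s <- select_atoms(full_structure, chain = chain, resno = align_resno,
                        atom = "CA")
  if (length(sel_f) < 3 || length(sel_f) != length(sel_s))
    stop("alignment selection must resolve to matching Calpha sets")
  tr <- superpose(full_structure$xyz, frame$xyz, sel_s, sel_f)
  if (tr$rmsd > max_align_rmsd)
    warning(sprintf("stalk-base superposition RMSD %.2f A exceeds %.2f A",
                    tr$rmsd, max_align_rmsd))
  fitted <- apply_transform(full_structure, tr)
  v <- anchor_center_of(fitted, tip_resno, chain) -
    anchor_center_of(frame, base_resno, chain)
  v <- v / sqrt(sum(v^2))
  acos(pmin(pmax(sum(v * axes$PA1), -1), 1)) * 180 / pi
}

#' Stalk angle series over a trajectory
#' @param traj A [md_trajectory()].
#' @param axes A [principal_axes()] object.
#' @param full_structure Passed to [stalk_angle()].
#' @param ... Passed to [stalk_angle()].
#' @return A data frame of class `angle_series`.
#' @export
stalk_angles <- function(traj, axes, full_structure, ...) {
  ang <- vapply(seq_len(n_frames(traj)), function(i)
    stalk_angle(trajectory_frame(traj, i), axes, full_structure, ...),
    numeric(1))
  out <- data.frame(frame = seq_along(ang), angle_deg = ang)
  class(out) <- c("angle_series", class(out))
  out
}

#' Gaussian fit of an angular orientation histogram
#'
#' Normalizes the angle histogram and fits one or two Gaussians by
#' nonlinear least squares with deterministic initialization at the
#' largest modes of the smoothed histogram.  Peaks are reported relative
#' to `reference_zero`.
#'
#' @param angles Numeric vector of angles (deg) or an `angle_series`.
#' @param n_components 1 or 2.
#' @param bin_width Histogram bin width, deg.
#' @param reference_zero Subtracted from the fitted peak positions.
#' @return An object of class `angle_histogram_fit`: `peaks` (data frame
#'   `mean_deg`, `sd_deg`, `weight`), `histogram`, `residual_rms`,
#'   `mode_collapse` flag (for `n_components = 2`).
#' @export
angle_histogram_fit <- function(angles, n_components = 1, bin_width = 1,
                                reference_zero = 0) {
  if (inherits(angles, "angle_series") || is.data.frame(angles))
    angles <- angles$angle_deg
  if (length(angles) < 100) stop("need at least 100 angle samples")
  if (!n_components %in% 1:2) stop("n_components must be 1 or 2")
  lo <- floor(min(angles) / bin_width) * bin_width
  hi <- ceiling(max(angles) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  counts <- tabulate(findInterval(angles, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  x <- breaks[-length(breaks)] + bin_width / 2
  y <- counts / sum(counts)
  ys <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  is_max <- ys >= c(-Inf, ys[-n]) & ys >= c(ys[-1], -Inf) & ys > 0
  cand <- which(is_max)[order(ys[is_max], decreasing = TRUE)]
  if (length(cand) < n_components) cand <- c(cand, order(ys, decreasing = TRUE))
  mu0 <- sort(x[utils::head(unique(cand), n_components)])
  sd0 <- max(sd(angles) / n_components, bin_width)
  start <- list(); lower <- c(); upper <- c()
  for (i in seq_len(n_components)) {
    start[[paste0("w", i)]] <- 1 / n_components
    start[[paste0("m", i)]] <- mu0[i]
    start[[paste0("s", i)]] <- sd0
    lower <- c(lower, 1e-6, lo, bin_width / 4)
    upper <- c(upper, 2, hi, hi - lo)
  }
  form <- paste0("w", seq_len(n_components), " * ", bin_width,
                 " * dnorm(x, m", seq_len(n_components),
                 ", s", seq_len(n_components), ")", collapse = " + ")
  fit <- minpack.lm::nlsLM(stats::as.formula(paste("y ~", form)),
                           data = data.frame(x = x, y = y), start = start,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  peaks <- data.frame(
    mean_deg = cf[paste0("m", seq_len(n_components))] - reference_zero,
    sd_deg = cf[paste0("s", seq_len(n_components))],
    weight = cf[paste0("w", seq_len(n_components))])
  peaks <- peaks[order(peaks$mean_deg), ]
  rownames(peaks) <- NULL
  collapse <- n_components == 2 &&
    abs(diff(peaks$mean_deg)) < mean(peaks$sd_deg)
  if (collapse) warning("two-component fit collapsed onto a single mode")
  structure(list(peaks = peaks,
                 histogram = data.frame(angle_deg = x, probability = y),
                 residual_rms = sqrt(mean(residuals(fit)^2)),
                 mode_collapse = collapse,
                 reference_zero = reference_zero),
            class = "angle_histogram_fit")
}

#' @export
print.angle_histogram_fit <- function(x, ...) {
  cat("<angle_histogram_fit>\n")
  for (i in seq_len(nrow(x$peaks)))
    cat(sprintf("  peak %.1f deg +- %.1f (w = %.2f)\n",
                x$peaks$mean_deg[i], x$peaks$sd_deg[i], x$peaks$weight[i]))
  invisible(x)
}

#' Per-residue RMSF after alignment to a reference
#'
#' Every frame is superposed onto the reference via `align_sel` (typically
#' the tubulin body, so fluctuations are measured with respect to the
#' microtubule), then the per-atom RMSF
#' `sqrt(mean(|r_i - <r_i>|^2))` over frames is computed for
#' `report_sel` and averaged per residue.
#'
#' @param traj A [md_trajectory()] with at least 2 frames.
#' @param align_sel Atom indices used for the superposition.
#' @param report_sel Atom indices reported (typically Calpha).
#' @param reference A [structure_frame()]; defaults to frame 1.
#' @return A data frame of class `rmsf_profile` with columns `chain`,
#'   `resno` and `rmsf_A`.
#' @export
rmsf_profile <- function(traj, align_sel, report_sel, reference = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF is undefined for a single frame")
  if (is.null(reference)) reference <- trajectory_frame(traj, 1)
  nrep <- length(report_sel)
  fitted <- array(NA_real_, c(nrep, 3, nf))
  for (i in seq_len(nf)) {
    fr <- traj$coords[, , i]
    tr <- superpose(fr, reference$xyz, align_sel, align_sel)
    fitted[, , i] <- apply_transform(fr[report_sel, , drop = FALSE], tr)
  }
  mean_pos <- apply(fitted, c(1, 2), mean)
  dev2 <- vapply(seq_len(nf), function(i)
    rowSums((fitted[, , i] - mean_pos)^2), numeric(nrep))
  if (is.null(dim(dev2))) dev2 <- matrix(dev2, nrow = nrep)
  atom_rmsf <- sqrt(rowMeans(dev2))
  a <- traj$atoms[report_sel, ]
  out <- aggregate(atom_rmsf,
                   by = list(chain = a$chain, resno = a$resno), FUN = mean)
  names(out)[3] <- "rmsf_A"
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  class(out) <- c("rmsf_profile", class(out))
  out
}

#' Mean percent change between two RMSF profiles
#'
#' `mean(100 * (b - a) / a)` over residues shared by the two profiles
#' (matched on chain and residue number).
#'
#' @param a,b [rmsf_profile()] data frames (a = reference, b = comparison).
#' @return Mean percent change.
#' @export
rmsf_percent_change <- function(a, b) {
  m <- merge(a, b, by = c("chain", "resno"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("profiles share no residues")
  mean(100 * (m$rmsf_A_b - m$rmsf_A_a) / m$rmsf_A_a)
}
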