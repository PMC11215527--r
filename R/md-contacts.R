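#' Contact detection criteria
#'
#' Distance (and angle) cutoffs for frame-wise interaction detection:
#' salt bridges at a maximum 4 A between basic nitrogens and acidic
#' oxygens; hydrophobic contacts at 8 A between side-chain carbons;
#' hydrogen bonds at a maximum 3.5 A donor-acceptor distance with the
#' hydrogen-donor-acceptor angle within 30 degrees.  All cutoffs are
#' inclusive (a pair at exactly the cutoff counts).
#'
#' @param salt_bridge_cutoff A (default 4.0).
#' @param hydrophobic_cutoff A (default 8.0).
#' @param hbond_distance_cutoff A (default 3.5).
#' @param hbond_angle_cutoff deg (default 30).
#' @param his_is_basic Count histidine ND1/NE2 as basic nitrogens for
#'   salt bridges (default TRUE).
#' @return An object of class `contact_criteria`.
#' @export
contact_criteria <- function(salt_bridge_cutoff = 4.0,
                             hydrophobic_cutoff = 8.0,
                             hbond_distance_cutoff = 3.5,
                             hbond_angle_cutoff = 30,
                             his_is_basic = TRUE) {
  cuts <- c(salt_bridge_cutoff, hydrophobic_cutoff, hbond_distance_cutoff,
            hbond_angle_cutoff)
  if (any(cuts <= 0)) stop("all cutoffs must be > 0")
  structure(list(salt_bridge_cutoff = salt_bridge_cutoff,
                 hydrophobic_cutoff = hydrophobic_cutoff,
                 hbond_distance_cutoff = hbond_distance_cutoff,
                 hbond_angle_cutoff = hbond_angle_cutoff,
                 his_is_basic = his_is_basic),
            class = "contact_criteria")
}

#' Residue pair specification for contact detection
#'
#' @param kind `"salt_bridge"`, `"hbond"` or `"hydrophobic"`.
#' @param a,b Lists `list(chain =, resno =)` identifying the two residues
#'   (chain may be omitted).  For hydrogen bonds, `a` is the donor side
#'   and must also name `donor_atom` and `hydrogen`; `b` must name
#'   `acceptor_atom`.
#' @return An object of class `contact_pair`.
#' @export
contact_pair <- function(kind = c("salt_bridge", "hbond", "hydrophobic"),
                         a, b) {
  kind <- match.arg(kind)
  if (identical(a$chain, b$chain) && identical(a$resno, b$resno))
    stop("a contact pair needs two distinct residues")
  if (kind == "hbond" &&
      (is.null(a$donor_atom) || is.null(a$hydrogen) || is.null(b$acceptor_atom)))
    stop("hbond pairs require a$donor_atom, a$hydrogen and b$acceptor_atom")
  structure(list(kind = kind, a = a, b = b), class = "contact_pair")
}

# basic nitrogen / acidic oxygen atom names by residue type
basic_n_atoms <- function(resname, his_is_basic) {
  switch(resname,
         LYS = "NZ",
         ARG = c("NE", "NH1", "NH2"),
         HIS = , HSD = , HSE = , HSP = if (his_is_basic)
           c("ND1", "NE2") else character(0),
         character(0))
}

acidic_o_atoms <- function(resname) {
  base <- switch(resname, ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                 character(0))
  c(base, "OXT")             # C-terminal carboxylate oxygens always count
}

residue_atoms <- function(frame, spec, atom_names = NULL) {
  idx <- select_atoms(frame, chain = spec$chain, resno = spec$resno)
  if (!is.null(atom_names))
    idx <- idx[frame$atoms$atom[idx] %in% atom_names]
  idx
}

min_pair_dist <- function(frame, ia, ib) {
  A <- frame$xyz[ia, , drop = FALSE]
  B <- frame$xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Detect a salt bridge in one frame
#'
#' TRUE iff the minimum distance between the basic nitrogens of one
#' residue (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2 unless disabled) and the
#' acidic oxygens of the other (Asp OD1/OD2; Glu OE1/OE2; terminal OXT)
#' is at most the cutoff.
#'
#' @param frame A [structure_frame()].
#' @param pair A [contact_pair()] of kind `"salt_bridge"`.
#' @param criteria A [contact_criteria()] object.
#' @return Logical.
#' @export
detect_salt_bridge <- function(frame, pair, criteria = contact_criteria()) {
  res_a <- frame$atoms$resname[residue_atoms(frame, pair$a)][1]
  res_b <- frame$atoms$resname[residue_atoms(frame, pair$b)][1]
  if (is.na(res_a) || is.na(res_b)) stop("pair residues not found in frame")
  ia <- residue_atoms(frame, pair$a,
                      basic_n_atoms(res_a, criteria$his_is_basic))
  ib <- residue_atoms(frame, pair$b, acidic_o_atoms(res_b))
  if (!length(ia) || !length(ib)) {   # try the opposite polarity
    ia <- residue_atoms(frame, pair$a, acidic_o_atoms(res_a))
    ib <- residue_atoms(frame, pair$b,
                        basic_n_atoms(res_b, criteria$his_is_basic))
  }
  if (!length(ia) || !length(ib))
    stop("pair does not resolve to basic-N / acidic-O atom sets")
  min_pair_dist(frame, ia, ib) <= criteria$salt_bridge_cutoff
}

#' Detect a hydrogen bond in one frame
#'
#' TRUE iff the donor-acceptor heavy-atom distance is within the cutoff
#' and the angle at the donor between the donor-hydrogen and
#' donor-acceptor directions is within the angle cutoff.  Hydrogens must
#' be explicit; no hydrogen positions are inferred.
#'
#' @inheritParams detect_salt_bridge
#' @param pair A [contact_pair()] of kind `"hbond"`.
#' @export
detect_hbond <- function(frame, pair, criteria = contact_criteria()) {
  id <- residue_atoms(frame, pair$a, pair$a$donor_atom)
  ih <- residue_atoms(frame, pair$a, pair$a$hydrogen)
  ia <- residue_atoms(frame, pair$b, pair$b$acceptor_atom)
  if (!length(id) || !length(ia))
    stop("donor or acceptor heavy atom not found")
  if (!length(ih))
    stop("explicit hydrogen '", pair$a$hydrogen,
         "' not found; hydrogen positions are not inferred")
  D <- frame$xyz[id[1], ]; H <- frame$xyz[ih[1], ]; A <- frame$xyz[ia[1], ]
  dist <- sqrt(sum((D - A)^2))
  if (dist > criteria$hbond_distance_cutoff) return(FALSE)
  u <- H - D; w <- A - D
  ang <- acos(pmin(pmax(sum(u * w) /
                          (sqrt(sum(u^2)) * sqrt(sum(w^2))), -1), 1)) * 180 / pi
  ang <= criteria$hbond_angle_cutoff
}

#' Detect a hydrophobic contact in one frame
#'
#' TRUE iff any side-chain carbon of one residue lies within the cutoff
#' of a side-chain carbon of the other.  Backbone carbons (`C`, `CA`) are
#' excluded; a glycine partner (no side-chain carbon) is an error.
#'
#' @inheritParams detect_salt_bridge
#' @param pair A [contact_pair()] of kind `"hydrophobic"`.
#' @export
detect_hydrophobic <- function(frame, pair, criteria = contact_criteria()) {
  side_c <- function(spec) {
    idx <- residue_atoms(frame, spec)
    idx <- idx[frame$atoms$element[idx] == "C" &
                 !frame$atoms$atom[idx] %in% c("C", "CA")]
    idx
  }
  ia <- side_c(pair$a); ib <- side_c(pair$b)
  if (!length(ia) || !length(ib))
    stop("residue without side-chain carbons (glycine?) in hydrophobic pair")
  min_pair_dist(frame, ia, ib) <= criteria$hydrophobic_cutoff
}

detect_contact <- function(frame, pair, criteria) {
  switch(pair$kind,
         salt_bridge = detect_salt_bridge(frame, pair, criteria),
         hbond = detect_hbond(frame, pair, criteria),
         hydrophobic = detect_hydrophobic(frame, pair, criteria))
}

#' Contact occupancy across trajectories
#'
#' Fraction of frames in which the contact is present, per trajectory and
#' pooled over all frames.  The per-trajectory fractions address the
#' per-simulation reading of occupancy; the pooled fraction the per-frame
#' reading; both are reported.
#'
#' @param trajectories A [md_trajectory()] or list of them.
#' @param pair A [contact_pair()].
#' @param criteria A [contact_criteria()] object.
#' @return An object of class `occupancy_result`: `per_trajectory`
#'   (numeric vector of fractions), `pooled` (fraction over all frames),
#'   `n_frames`, `n_trajectories`.
#' @export
contact_occupancy <- function(trajectories, pair,
                              criteria = contact_criteria()) {
  if (inherits(trajectories, "md_trajectory"))
    trajectories <- list(trajectories)
  per <- numeric(length(trajectories))
  tot_on <- 0; tot <- 0
  for (k in seq_along(trajectories)) {
    traj <- trajectories[[k]]
    nf <- n_frames(traj)
    on <- vapply(seq_len(nf), function(i)
      detect_contact(trajectory_frame(traj, i), pair, criteria), logical(1))
    per[k] <- mean(on)
    tot_on <- tot_on + sum(on); tot <- tot + nf
  }
  structure(list(per_trajectory = per, pooled = tot_on / tot,
                 n_frames = as.integer(tot),
                 n_trajectories = length(trajectories)),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy_result> pooled %.3f over %d frames (%d trajectories)\n",
              x$pooled, x$n_frames, x$n_trajectories))
  invisible(x)
}
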