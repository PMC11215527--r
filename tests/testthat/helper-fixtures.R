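# Shared fixture builders and independent oracles.

# trace with force values given explicitly (uniform sampling)
make_trace <- function(force, rate = 250, k = 0.06, label = "fix") {
  trap_trace(force, sample_rate = rate, spring_constant = k, label = label)
}

# noise-free stall fixture: linear ramp, plateau, instantaneous drop to 0
ramp_plateau_trace <- function(plateau_pN = 3.5, ramp_s = 0.4, plateau_s = 0.5,
                               tail_s = 0.3, rate = 250) {
  f <- c(seq(0, plateau_pN, length.out = ramp_s * rate),
         rep(plateau_pN, plateau_s * rate),
         rep(0, tail_s * rate))
  make_trace(f, rate = rate)
}

# independent rotation-matrix oracle (Rodrigues, coded separately from the
# package's internal helper)
rot_oracle <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  c1 <- cos(th); s1 <- sin(th); v <- 1 - c1
  matrix(c(c1 + ux^2 * v, ux * uy * v - uz * s1, ux * uz * v + uy * s1,
           uy * ux * v + uz * s1, c1 + uy^2 * v, uy * uz * v - ux * s1,
           uz * ux * v - uy * s1, uz * uy * v + ux * s1, c1 + uz^2 * v),
         3, 3, byrow = TRUE)
}

# brute-force minimum distance between two atom index sets: plain loops
brute_min_dist <- function(xyz, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# random two-residue frame for contact property tests: an ARG and a GLU
# with full side chains at controlled separation, plus explicit amide H
random_pair_frame <- function(center_dist) {
  place <- function(origin, atoms) {
    n <- length(atoms)
    xyz <- matrix(rnorm(n * 3, sd = 1.2), n, 3)
    sweep(xyz, 2, origin, "+")
  }
  arg_atoms <- c("N", "H", "CA", "C", "O", "CB", "CG", "CD", "NE", "NH1", "NH2")
  glu_atoms <- c("N", "H", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2")
  o1 <- c(0, 0, 0)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  o2 <- center_dist * dir
  atoms <- data.frame(
    chain = c(rep("A", length(arg_atoms)), rep("B", length(glu_atoms))),
    resno = c(rep(10L, length(arg_atoms)), rep(40L, length(glu_atoms))),
    resname = c(rep("ARG", length(arg_atoms)), rep("GLU", length(glu_atoms))),
    atom = c(arg_atoms, glu_atoms))
  structure_frame(atoms, rbind(place(o1, arg_atoms), place(o2, glu_atoms)))
}
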