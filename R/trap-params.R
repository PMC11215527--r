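#' Parameters for the bead-in-trap motor simulator
#'
#' Bundles the physical and kinetic parameters of the synthetic optical-trap
#' experiment: a bead held in a harmonic trap of stiffness
#' `trap_stiffness`, pulled along the microtubule axis by a motor obeying a
#' linear force-velocity law `v(F) = unloaded_velocity * (1 - F /
#' stall_force)` (clipped to `[0, unloaded_velocity]`).  At stall the motor
#' dwells with exponential detachment kinetics; detachment snaps the bead
#' back to the trap centre, after which the motor re-engages with rate
#' `reattach_rate`.  Mutant-like low-force pausing is modelled as a
#' force-gated two-state switch: while moving, the motor pauses with hazard
#' `pause_entry_rate * min(F / stall_force, 1)`; a pause ends with rate
#' `pause_exit_rate`, upon which the motor detaches with probability
#' `pause_exit_detach_prob` or resumes stepping.
#'
#' @param trap_stiffness Trap spring constant, pN/nm.
#' @param bead_drag Bead drag coefficient, pN s/nm.  Default corresponds to
#'   a 1-um-radius polystyrene bead in water (6 pi eta r).
#' @param thermal_energy k_B T in pN nm; default 4.114 (298 K).  Set to 0
#'   for noise-free traces.
#' @param unloaded_velocity Motor speed at zero load, nm/s.
#' @param stall_force Load at which forward stepping ceases, pN.
#' @param detach_rate_at_stall Detachment rate while stalled, 1/s.
#' @param pause_entry_rate Maximum pausing hazard (reached at stall load),
#'   1/s; 0 disables pausing.
#' @param pause_exit_rate Rate of leaving a pause, 1/s.
#' @param pause_exit_detach_prob Probability that a pause ends in
#'   detachment rather than resumed motion.
#' @param reattach_rate Microtubule rebinding rate while unbound, 1/s.
#' @param sample_rate Recording rate of the force signal, Hz.
#' @param duration Trace length, s.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return An object of class `motor_trap_params`.
#' @seealso [simulate_trap_trace()], [ddb_trap_params()]
#' @export
motor_trap_params <- function(trap_stiffness = 0.06,
                              bead_drag = 1.68e-5,
                              thermal_energy = .kBT_room,
                              unloaded_velocity = 800,
                              stall_force = 4.3,
                              detach_rate_at_stall = 2,
                              pause_entry_rate = 0,
                              pause_exit_rate = 12,
                              pause_exit_detach_prob = 0.25,
                              reattach_rate = 2,
                              sample_rate = 5000,
                              duration = 10,
                              seed = NULL) {
  p <- list(trap_stiffness = trap_stiffness, bead_drag = bead_drag,
            thermal_energy = thermal_energy,
            unloaded_velocity = unloaded_velocity, stall_force = stall_force,
            detach_rate_at_stall = detach_rate_at_stall,
            pause_entry_rate = pause_entry_rate,
            pause_exit_rate = pause_exit_rate,
            pause_exit_detach_prob = pause_exit_detach_prob,
            reattach_rate = reattach_rate, sample_rate = sample_rate,
            duration = duration, seed = seed)
  num <- p[setdiff(names(p), "seed")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), logical(1))))
    stop("all motor_trap_params fields must be finite scalars")
  if (trap_stiffness <= 0) stop("trap_stiffness must be > 0")
  if (bead_drag <= 0) stop("bead_drag must be > 0")
  if (thermal_energy < 0) stop("thermal_energy must be >= 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (stall_force <= 0) stop("stall_force must be > 0")
  if (pause_exit_detach_prob < 0 || pause_exit_detach_prob > 1)
    stop("pause_exit_detach_prob must lie in [0, 1]")
  rates <- c(detach_rate_at_stall, pause_entry_rate, pause_exit_rate,
             reattach_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  structure(p, class = "motor_trap_params")
}

#' Trap-parameter presets for wild-type- and mutant-like DDB motors
#'
#' Returns [motor_trap_params()] with stall forces of 4.3 pN (wild type) or
#' 2.9 pN (S-to-C mutant), the experimentally reported means, and with
#' force-gated low-force pausing enabled for the mutant.  The mutant preset
#' also carries a reduced unloaded velocity.
#'
#' @param construct `"wt"` or `"mutant"`.
#' @param ... Overrides passed on to [motor_trap_params()].
#' @return A `motor_trap_params` object.
#' @export
ddb_trap_params <- function(construct = c("wt", "mutant"), ...) {
  construct <- match.arg(construct)
  defaults <- if (construct == "wt") {
    list(stall_force = 4.3, unloaded_velocity = 800, pause_entry_rate = 0)
  } else {
    list(stall_force = 2.9, unloaded_velocity = 600, pause_entry_rate = 0.4)
  }
  do.call(motor_trap_params, modifyList(defaults, list(...)))
}
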