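#' Simulate a bead-force trace from the trap-motor model
#'
#' Integrates overdamped Langevin dynamics of the bead coordinate `x` (nm,
#' displacement from trap centre), `drag * dx/dt = -k * (x - m) +
#' sqrt(2 * kBT * drag) * white noise`, where `m` is the motor attachment
#' coordinate advancing at `v(F) = v0 * (1 - F / Fs)` (clipped to
#' `[0, v0]`) under the quasi-static load `F = k * m`.  At stall the motor
#' freezes and detaches with exponential kinetics; detachment resets the
#' link force to zero so the bead relaxes back to the trap centre within
#' the bead relaxation time `drag / k`.  Integration uses a fixed internal
#' Euler-Maruyama step of 2e-6 s and decimates to `sample_rate` by
#' non-overlapping block averaging (emulating detector anti-alias
#' filtering); `1 / (sample_rate * dt)` must be a whole number.
#'
#' The recorded force is `k * x`.  Programmed state intervals (`unbound`,
#' `moving`, `pause`, `stall`) are returned as ground truth; they tile the
#' trace without gaps or overlaps.
#'
#' @param params A [motor_trap_params()] object.
#' @param label Construct identifier stored on the trace.
#' @param dt Internal integration step, s.  The step must resolve the bead
#'   relaxation time `bead_drag / trap_stiffness`.
#' @return A [trap_trace()] with `ground_truth` populated.
#' @examples
#' p <- motor_trap_params(duration = 0.5, seed = 1)
#' tr <- simulate_trap_trace(p)
#' @export
simulate_trap_trace <- function(params, label = "sim", dt = 2e-6) {
  stopifnot(inherits(params, "motor_trap_params"))
  relax_time <- params$bead_drag / params$trap_stiffness
  if (dt > relax_time)
    stop(sprintf(paste("integration step %.3g s exceeds the bead relaxation",
                       "time drag/k = %.3g s; reduce dt"), dt, relax_time))
  block <- 1 / (params$sample_rate * dt)
  if (abs(block - round(block)) > 1e-9)
    stop("1 / (sample_rate * dt) must be an integer (block decimation)")
  if (!is.null(params$seed)) set.seed(params$seed)
  out <- sim_trap_trace_cpp(params$trap_stiffness, params$bead_drag,
                            params$thermal_energy, params$unloaded_velocity,
                            params$stall_force, params$detach_rate_at_stall,
                            params$pause_entry_rate, params$pause_exit_rate,
                            params$pause_exit_detach_prob,
                            params$reattach_rate, params$sample_rate,
                            params$duration, dt, 0.995)
  kinds <- c("unbound", "moving", "pause", "stall")
  gt <- data.frame(start_s = out$gt_start, end_s = out$gt_end,
                   kind = kinds[out$gt_kind + 1L],
                   level_pN = out$gt_level)
  trap_trace(out$force, sample_rate = params$sample_rate,
             spring_constant = params$trap_stiffness, label = label,
             ground_truth = gt)
}
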