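#' Force-velocity analysis parameters
#'
#' @param median_window Running-median window, samples (default 200; even
#'   values are adjusted up to the next odd number internally).
#' @param bin_centers Force-bin centres, pN (default 2, 3, 4, 5).
#' @param bin_width Bin width, pN (default 1).  Bins must not overlap.
#' @param spring_constant Spring constant used to convert force changes to
#'   velocities, pN/nm (default 0.06).
#' @param min_event_samples Shortest retained bin event, samples (default
#'   25, i.e. 5 ms at 5 kHz), suppressing single-crossing noise events.
#' @return An object of class `fv_params`.
#' @export
fv_params <- function(median_window = 200, bin_centers = c(2, 3, 4, 5),
                      bin_width = 1, spring_constant = 0.06,
                      min_event_samples = 25) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (spring_constant <= 0) stop("spring_constant must be > 0")
  if (length(bin_centers) > 1 && min(diff(sort(bin_centers))) < bin_width)
    stop("force bins overlap")
  structure(list(median_window = median_window, bin_centers = bin_centers,
                 bin_width = bin_width, spring_constant = spring_constant,
                 min_event_samples = min_event_samples),
            class = "fv_params")
}

#' Running-median filter of a trace
#'
#' Running median with an odd-adjusted window; edges are handled by window
#' truncation (shrinking windows), so output length equals input length.
#'
#' @param trace A [trap_trace()] (typically at the 5 kHz recording rate).
#' @param window Window size in samples.
#' @return A filtered [trap_trace()].
#' @export
median_filter_trace <- function(trace, window = 200) {
  stopifnot(inherits(trace, "trap_trace"))
  if (window < 3) stop("median window must be at least 3 samples")
  if (window > length(trace$force)) stop("window exceeds trace length")
  k <- as.integer(window)
  if (k %% 2 == 0) k <- k + 1L
  f <- runmed(trace$force, k, endrule = "median")
  trap_trace(as.numeric(f), sample_rate = trace$sample_rate,
             spring_constant = trace$spring_constant, label = trace$label,
             ground_truth = trace$ground_truth, t0 = trace$time[1])
}

#' Extract force-bin events from a filtered trace
#'
#' Finds the maximal contiguous runs in which the filtered force lies in
#' the half-open interval `[center - width/2, center + width/2)` of each
#' bin; runs shorter than `min_event_samples` are dropped.  `delta_force`
#' is the force at exit minus the force at entry.
#'
#' @param trace A median-filtered [trap_trace()].
#' @param params An [fv_params()] object.
#' @return A data frame of class `bin_events` with columns `trace_id`,
#'   `bin_center_pN`, `t_enter_s`, `t_exit_s`, `delta_force_pN`,
#'   `duration_s`, `velocity_nm_s`.
#' @export
extract_bin_events <- function(trace, params = fv_params()) {
  stopifnot(inherits(trace, "trap_trace"), inherits(params, "fv_params"))
  f <- trace$force
  rows <- list()
  for (ctr in params$bin_centers) {
    inbin <- f >= ctr - params$bin_width / 2 & f < ctr + params$bin_width / 2
    r <- rle(inbin)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= params$min_event_samples
    for (j in which(keep)) {
      i1 <- starts[j]; i2 <- ends[j]
      dur <- trace$time[i2] - trace$time[i1]
      df <- f[i2] - f[i1]
      rows[[length(rows) + 1]] <- data.frame(
        trace_id = trace$label, bin_center_pN = ctr,
        t_enter_s = trace$time[i1], t_exit_s = trace$time[i2],
        delta_force_pN = df, duration_s = dur,
        velocity_nm_s = if (dur > 0)
          event_velocity(df, dur, params$spring_constant) else NA_real_)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trace_id = character(), bin_center_pN = numeric(),
               t_enter_s = numeric(), t_exit_s = numeric(),
               delta_force_pN = numeric(), duration_s = numeric(),
               velocity_nm_s = numeric())
  class(out) <- c("bin_events", class(out))
  out
}

#' Average velocity of one bin event
#'
#' `velocity = delta_force / (spring_constant * duration)`: the force
#' change across the event divided by the spring constant gives the bead
#' displacement, and dividing by the event duration gives the mean
#' velocity in nm/s.  Events with negative velocity are excluded
#' downstream (detachment, not motor-driven motion), so the returned
#' value may be negative here.
#'
#' @param delta_force Force change over the event, pN.
#' @param duration Event duration, s (> 0).
#' @param spring_constant Trap spring constant, pN/nm.
#' @return Velocity, nm/s.
#' @export
event_velocity <- function(delta_force, duration, spring_constant = 0.06) {
  if (any(duration <= 0)) stop("event duration must be > 0")
  delta_force / (spring_constant * duration)
}

#' Force-velocity curve over fixed 1-pN bins
#'
#' Median-filters every trace, extracts bin events per trace (traces are
#' processed individually and pooled, so no event spans a concatenation
#' joint), discards events with negative velocity, and reports the mean
#' velocity with SEM and event count per force bin.
#'
#' @param traces A [trap_trace()] or list of them, at the recording rate.
#' @param params An [fv_params()] object.
#' @return A data frame of class `fv_curve` with columns `bin_center_pN`,
#'   `mean_velocity_nm_s`, `sem_nm_s`, `n_events` (empty bins have
#'   `n_events = 0` and `NA` means).
#' @export
force_velocity_curve <- function(traces, params = fv_params()) {
  if (inherits(traces, "trap_trace")) traces <- list(traces)
  if (length(traces) < 1) stop("need at least one trace")
  ev <- do.call(rbind, lapply(traces, function(tr)
    extract_bin_events(median_filter_trace(tr, params$median_window),
                       params)))
  ev <- ev[!is.na(ev$velocity_nm_s) & ev$velocity_nm_s >= 0, ]
  rows <- lapply(params$bin_centers, function(ctr) {
    v <- ev$velocity_nm_s[ev$bin_center_pN == ctr]
    n <- length(v)
    data.frame(bin_center_pN = ctr,
               mean_velocity_nm_s = if (n) mean(v) else NA_real_,
               sem_nm_s = if (n > 1) sd(v) / sqrt(n) else
                 if (n == 1) 0 else NA_real_,
               n_events = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fv_curve", class(out))
  out
}

#' @export
plot.fv_curve <- function(x, ...) {
  plot(x$bin_center_pN, x$mean_velocity_nm_s, pch = 19,
       xlab = "force (pN)", ylab = "velocity (nm/s)", ...)
  invisible(x)
}
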