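#' Stall detection criteria
#'
#' Operational definition of a stall: a maximal interval of the
#' (downsampled) trace in which the force exceeds `min_force` and a
#' centred rolling standard deviation over `stationarity_window` stays at
#' or below `stationarity_sd_max`, lasting longer than `min_duration`.
#' The event outcome is `detach` when the force falls by at least
#' `snap_drop_fraction` of the stall force within `snap_max_time` after
#' the interval (the bead snapping back to the trap centre), `censored`
#' when the trace ends inside or immediately after the interval, and
#' `resume` otherwise.
#'
#' Presets: `"wt"` uses forces > 2.5 pN and durations > 100 ms; `"mutant"`
#' uses forces > 1 pN and durations > 150 ms.  Both analyse at 250 Hz.
#'
#' @param preset `"wt"`, `"mutant"`, or `NULL` for fully manual criteria.
#' @param min_force Force threshold, pN.
#' @param min_duration Minimum event duration, ms.
#' @param stationarity_sd_max Rolling-SD bound defining "stationary", pN.
#' @param stationarity_window Rolling-SD window, ms.
#' @param snap_drop_fraction Fractional force drop identifying detachment.
#' @param snap_max_time Window after the event in which the drop must
#'   occur, ms.
#' @param analysis_rate Analysis sampling rate, Hz.
#' @return An object of class `stall_criteria`.
#' @export
stall_criteria <- function(preset = NULL, min_force = 2.5,
                           min_duration = 100, stationarity_sd_max = 0.35,
                           stationarity_window = 40,
                           snap_drop_fraction = 0.8, snap_max_time = 20,
                           analysis_rate = 250) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("wt", "mutant"))
    if (preset == "wt") {
      min_force <- 2.5; min_duration <- 100
    } else {
      min_force <- 1; min_duration <- 150
    }
  }
  if (min_force <= 0) stop("min_force must be > 0")
  if (min_duration <= 0) stop("min_duration must be > 0")
  if (snap_drop_fraction <= 0 || snap_drop_fraction > 1)
    stop("snap_drop_fraction must lie in (0, 1]")
  if (stationarity_window > min_duration)
    stop("stationarity_window must not exceed min_duration")
  structure(list(min_force = min_force, min_duration = min_duration,
                 stationarity_sd_max = stationarity_sd_max,
                 stationarity_window = stationarity_window,
                 snap_drop_fraction = snap_drop_fraction,
                 snap_max_time = snap_max_time,
                 analysis_rate = analysis_rate),
            class = "stall_criteria")
}

#' Downsample a trace by non-overlapping block means
#'
#' The target rate must divide the source rate; each output sample is the
#' mean of `sample_rate / target_rate` consecutive input samples, so the
#' trace mean is preserved exactly.
#'
#' @param trace A [trap_trace()].
#' @param target_rate Target sampling rate, Hz.
#' @return A [trap_trace()] at `target_rate`.
#' @export
downsample_trace <- function(trace, target_rate) {
  stopifnot(inherits(trace, "trap_trace"))
  if (target_rate == trace$sample_rate) return(trace)
  ratio <- trace$sample_rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("target_rate must divide sample_rate")
  ratio <- as.integer(round(ratio))
  n_out <- length(trace$force) %/% ratio
  f <- colMeans(matrix(trace$force[seq_len(n_out * ratio)], nrow = ratio))
  trap_trace(f, sample_rate = target_rate,
             spring_constant = trace$spring_constant, label = trace$label,
             ground_truth = trace$ground_truth, t0 = trace$time[1])
}

# centred rolling SD with window w (odd); edge positions (half-window) NA
rolling_sd <- function(x, w) {
  n <- length(x)
  if (w > n) return(rep(NA_real_, n))
  c1 <- cumsum(c(0, x))
  c2 <- cumsum(c(0, x^2))
  s <- (c1[(w + 1):(n + 1)] - c1[1:(n - w + 1)])
  s2 <- (c2[(w + 1):(n + 1)] - c2[1:(n - w + 1)])
  v <- pmax((s2 - s^2 / w) / (w - 1), 0)
  half <- (w - 1) %/% 2
  out <- rep(NA_real_, n)
  out[(half + 1):(n - w + half + 1)] <- sqrt(v)
  out
}

#' Detect stall events in a trap trace
#'
#' Applies the criteria of [stall_criteria()] to a trace.  If the trace is
#' sampled faster than `criteria$analysis_rate` it is first downsampled by
#' block averaging.  Events are returned in time order and do not overlap.
#' For each event the stall force is the mean force over the last 20% of
#' the event ([stall_force()]) and the stall time is the dwell at or above
#' 80% of the stall force ([stall_time()]).
#'
#' @param trace A [trap_trace()].
#' @param criteria A [stall_criteria()] object.
#' @param stall_time_method Passed to [stall_time()].
#' @param qc When `TRUE`, flag borderline events (stall force within 10%
#'   of `min_force`, or duration within 10% of `min_duration`) in a
#'   `qc_flag` column in place of manual review.
#' @return A data frame of class `stall_events` with columns `trace_id`,
#'   `start_s`, `end_s`, `stall_force_pN`, `stall_time_s`, `outcome`.
#' @export
detect_stalls <- function(trace, criteria,
                          stall_time_method = c("contiguous", "total"),
                          qc = FALSE) {
  stopifnot(inherits(trace, "trap_trace"), inherits(criteria, "stall_criteria"))
  stall_time_method <- match.arg(stall_time_method)
  if (length(trace$force) == 0) stop("empty trace")
  if (trace$sample_rate != criteria$analysis_rate)
    trace <- downsample_trace(trace, criteria$analysis_rate)
  rate <- trace$sample_rate
  f <- trace$force
  n <- length(f)
  w <- max(3L, as.integer(round(criteria$stationarity_window / 1000 * rate)))
  if (w %% 2 == 0) w <- w + 1L
  rsd <- rolling_sd(f, w)
  cond <- !is.na(rsd) & rsd <= criteria$stationarity_sd_max &
    f > criteria$min_force
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / rate > criteria$min_duration / 1000)
  starts <- starts[keep]; ends <- ends[keep]
  rows <- lapply(seq_along(starts), function(i) {
    i1 <- starts[i]; i2 <- ends[i]
    seg <- f[i1:i2]
    sf <- stall_force(seg)
    st <- stall_time(seg, sf, rate, method = stall_time_method)
    # the rolling-SD guard truncates events about half a stationarity
    # window before the force drop, so the snap lookahead spans
    # snap_max_time plus one stationarity window
    ns <- as.integer(round((criteria$snap_max_time +
                              criteria$stationarity_window) / 1000 * rate))
    hi <- min(n, i2 + ns)
    after <- if (i2 < hi) f[(i2 + 1):hi] else numeric(0)
    outcome <- if (i2 >= n - (w %/% 2)) "censored"
      else if (length(after) &&
               any(after <= sf * (1 - criteria$snap_drop_fraction))) "detach"
      else "resume"
    data.frame(trace_id = trace$label,
               start_s = trace$time[i1], end_s = trace$time[i2],
               stall_force_pN = sf, stall_time_s = st, outcome = outcome)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trace_id = character(), start_s = numeric(),
               end_s = numeric(), stall_force_pN = numeric(),
               stall_time_s = numeric(), outcome = character())
  if (qc && nrow(out)) {
    out$qc_flag <- out$stall_force_pN < 1.1 * criteria$min_force |
      (out$end_s - out$start_s) < 1.1 * criteria$min_duration / 1000
  }
  class(out) <- c("stall_events", class(out))
  out
}

#' Stall force: mean force over the last 20% of an event
#'
#' The averaged window is the final `ceiling(0.2 * n)` samples.
#'
#' @param samples Force samples of one stall event, pN.
#' @return Stall force, pN.
#' @export
stall_force <- function(samples) {
  n <- length(samples)
  if (n < 5) stop("stall event must have at least 5 samples")
  m <- ceiling(0.2 * n)
  mean(samples[(n - m + 1):n])
}

#' Stall time: dwell at >= 80% of the stall force
#'
#' With `method = "contiguous"` (default) the dwell is the contiguous run
#' of samples with force at or above `0.8 * stall_force` that ends at the
#' event end (detachment); if the very last sample dips below threshold,
#' the run ending at the last supra-threshold sample is used.  With
#' `method = "total"` the dwell is the total supra-threshold time anywhere
#' in the event.
#'
#' @param samples Force samples of one stall event, pN.
#' @param stall_force Stall force from [stall_force()], pN.
#' @param rate Sampling rate of `samples`, Hz.
#' @param method `"contiguous"` or `"total"`.
#' @return Dwell time, s (a run of `m` samples counts as `m / rate`).
#' @export
stall_time <- function(samples, stall_force, rate,
                       method = c("contiguous", "total")) {
  method <- match.arg(method)
  above <- samples >= 0.8 * stall_force
  if (!any(above)) return(0)
  if (method == "total") return(sum(above) / rate)
  last <- max(which(above))
  below_before <- which(!above[seq_len(last)])
  start <- if (length(below_before)) max(below_before) + 1 else 1
  (last - start + 1) / rate
}
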