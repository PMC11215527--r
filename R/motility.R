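#' Motility classification parameters
#'
#' Kymograph counting rules: binding events shorter than
#' `min_binding_duration` (1.5 s, 3 pixels on the time axis) are excluded;
#' a track is processive when its best forward run reaches
#' `min_processive_run` (500 nm, ~5 pixels at 105 nm/pixel).  Remaining
#' tracks are static when their total positional range stays within
#' `static_displacement_max` (default 250 nm, sub-2.5-pixel wander that is
#' indistinguishable from localization noise), else diffusive.  A forward
#' run is a maximal stretch in which the position never drops more than
#' `segment_tolerance` below its running maximum; the same tolerance is
#' the RMS residual bound of the piecewise-linear velocity segmenter.
#'
#' @param min_binding_duration s (default 1.5).
#' @param min_processive_run nm (default 500).
#' @param static_displacement_max nm (default 250).
#' @param segment_tolerance nm (default 50).
#' @return An object of class `motility_params`.
#' @export
motility_params <- function(min_binding_duration = 1.5,
                            min_processive_run = 500,
                            static_displacement_max = 250,
                            segment_tolerance = 50) {
  vals <- c(min_binding_duration, min_processive_run,
            static_displacement_max, segment_tolerance)
  if (any(vals <= 0)) stop("all motility parameters must be > 0")
  structure(list(min_binding_duration = min_binding_duration,
                 min_processive_run = min_processive_run,
                 static_displacement_max = static_displacement_max,
                 segment_tolerance = segment_tolerance),
            class = "motility_params")
}

# best forward run: max displacement accumulated while the position never
# drops more than tol below its running maximum
best_forward_run <- function(pos, tol) {
  best <- 0
  run_start <- pos[1]
  run_max <- pos[1]
  for (x in pos[-1]) {
    if (x < run_max - tol) {      # run broken; restart here
      run_start <- x
      run_max <- x
    } else {
      run_max <- max(run_max, x)
    }
    best <- max(best, run_max - run_start)
  }
  best
}

#' Classify a track as processive, static or diffusive
#'
#' @param track A [motor_track()].
#' @param params A [motility_params()] object.
#' @return One of `"excluded"`, `"processive"`, `"static"`, `"diffusive"`.
#'   Thresholds are inclusive: a track of exactly 1.5 s is counted and a
#'   forward run of exactly 500 nm is processive.
#' @export
classify_track <- function(track, params = motility_params()) {
  stopifnot(inherits(track, "motor_track"))
  dur <- track$time[length(track$time)] - track$time[1]
  if (dur < params$min_binding_duration) return("excluded")
  if (best_forward_run(track$position, params$segment_tolerance) >=
      params$min_processive_run) return("processive")
  if (diff(range(track$position)) <= params$static_displacement_max)
    return("static")
  "diffusive"
}

#' Piecewise-linear velocity segments of a track
#'
#' Bottom-up segmentation: the track starts as two-point segments and
#' adjacent segments are merged greedily while the merged least-squares
#' line keeps an RMS residual at or below `tolerance`.  Each segment's
#' velocity is its displacement over its duration; the track mean velocity
#' is the unweighted mean of the segment velocities (motors change speed
#' within runs, and the per-segment mean follows the kymograph convention
#' rather than net displacement over total time).
#'
#' @param track A [motor_track()] with at least 3 points.
#' @param tolerance RMS residual bound, nm.
#' @return A data frame of class `velocity_segments` with columns
#'   `t_start_s`, `t_end_s`, `displacement_nm`, `velocity_nm_s`; the
#'   unweighted mean velocity is stored in attribute `mean_velocity`.
#' @export
segment_velocities <- function(track, tolerance = 50) {
  stopifnot(inherits(track, "motor_track"))
  t <- track$time; x <- track$position
  n <- length(t)
  if (n < 3) stop("track must have at least 3 points to segment")
  # breakpoints as indices; segment i spans bp[i] .. bp[i+1]
  bp <- seq_len(n)
  seg_rms <- function(i1, i2) {
    tt <- t[i1:i2]; xx <- x[i1:i2]
    fit <- stats::lm.fit(cbind(1, tt), xx)
    sqrt(mean(fit$residuals^2))
  }
  repeat {
    if (length(bp) <= 2) break
    # cost of removing each interior breakpoint
    costs <- vapply(seq(2, length(bp) - 1), function(j)
      seg_rms(bp[j - 1], bp[j + 1]), numeric(1))
    jmin <- which.min(costs)
    if (costs[jmin] <= tolerance) bp <- bp[-(jmin + 1)] else break
  }
  segs <- data.frame(
    t_start_s = t[bp[-length(bp)]], t_end_s = t[bp[-1]],
    displacement_nm = x[bp[-1]] - x[bp[-length(bp)]])
  segs$velocity_nm_s <- segs$displacement_nm / (segs$t_end_s - segs$t_start_s)
  attr(segs, "mean_velocity") <- mean(segs$velocity_nm_s)
  class(segs) <- c("velocity_segments", class(segs))
  segs
}

#' Run length of a processive track
#'
#' Net minus-end-directed displacement from the first to the last point
#' (default), or the total path length when `method = "total"`.
#'
#' @param track A [motor_track()] classified as processive.
#' @param method `"net"` or `"total"`.
#' @return Run length, nm.
#' @export
run_length <- function(track, method = c("net", "total")) {
  method <- match.arg(method)
  p <- track$position
  if (method == "net") p[length(p)] - p[1] else sum(abs(diff(p)))
}

#' Per-microtubule motility summary
#'
#' Fractions of processive, static and diffusive tracks (over counted,
#' i.e. non-excluded, tracks) per microtubule, with mean segment velocity
#' and mean run length of the processive fraction.
#'
#' @param tracks List of [motor_track()] objects.
#' @param params A [motility_params()] object.
#' @return A data frame of class `motility_summary`, one row per
#'   microtubule: `microtubule_id`, `n_tracks`, `frac_processive`,
#'   `frac_static`, `frac_diffusive`, `mean_velocity_nm_s`,
#'   `mean_run_length_nm`.
#' @export
summarize_motility <- function(tracks, params = motility_params()) {
  if (inherits(tracks, "motor_track")) tracks <- list(tracks)
  cls <- vapply(tracks, classify_track, character(1), params = params)
  counted <- cls != "excluded"
  if (!any(counted)) stop("all tracks excluded (shorter than the minimum binding duration)")
  mt <- vapply(tracks, `[[`, character(1), "microtubule_id")
  rows <- lapply(split(seq_along(tracks)[counted], mt[counted]), function(idx) {
    ci <- cls[idx]
    proc <- idx[ci == "processive"]
    mv <- if (length(proc)) mean(vapply(proc, function(i)
      attr(segment_velocities(tracks[[i]], params$segment_tolerance),
           "mean_velocity"), numeric(1))) else NA_real_
    rl <- if (length(proc)) mean(vapply(proc, function(i)
      run_length(tracks[[i]]), numeric(1))) else NA_real_
    data.frame(microtubule_id = tracks[[idx[1]]]$microtubule_id,
               n_tracks = length(idx),
               frac_processive = mean(ci == "processive"),
               frac_static = mean(ci == "static"),
               frac_diffusive = mean(ci == "diffusive"),
               mean_velocity_nm_s = mv, mean_run_length_nm = rl)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("motility_summary", class(out))
  out
}
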