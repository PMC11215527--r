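#' Single-particle track from a TIRF kymograph
#'
#' Ordered (time, position) pairs for one particle; positions are in nm
#' with the microtubule minus-end direction positive.
#'
#' @param time_s Strictly increasing times, s.
#' @param position_nm Positions, nm.
#' @param pixel_size Camera pixel size, nm (105 for the reference setup).
#' @param frame_interval Frame interval, s.
#' @param track_id,microtubule_id Identifiers.
#' @return An object of class `motor_track`.
#' @export
motor_track <- function(time_s, position_nm, pixel_size = 105,
                        frame_interval = NULL, track_id = "track",
                        microtubule_id = "mt") {
  if (length(time_s) < 2) stop("a track needs at least 2 points")
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (length(time_s) != length(position_nm))
    stop("time and position lengths differ")
  structure(list(time = as.numeric(time_s),
                 position = as.numeric(position_nm),
                 pixel_size = pixel_size,
                 frame_interval = frame_interval %||% median(diff(time_s)),
                 track_id = track_id, microtubule_id = microtubule_id),
            class = "motor_track")
}

#' @export
print.motor_track <- function(x, ...) {
  cat(sprintf("<motor_track '%s'> %d points over %.2f s, net %.0f nm\n",
              x$track_id, length(x$time), diff(range(x$time)),
              x$position[length(x$position)] - x$position[1]))
  invisible(x)
}

#' Parameters for the synthetic track generator
#'
#' @param mode `"processive"` (constant drift plus localization noise),
#'   `"static"` (noise only) or `"diffusive"` (Brownian steps).
#' @param velocity Drift speed for processive tracks, nm/s.
#' @param diffusion_coeff Diffusion coefficient for diffusive tracks,
#'   nm^2/s.
#' @param duration Track duration, s.
#' @param frame_interval Frame interval, s.
#' @param localization_noise_sd Per-frame localization error, nm.
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `track_params`.
#' @export
track_params <- function(mode = c("processive", "static", "diffusive"),
                         velocity = 300, diffusion_coeff = 2000,
                         duration = 10, frame_interval = 0.5,
                         localization_noise_sd = 20, seed = NULL) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (localization_noise_sd < 0) stop("localization noise must be >= 0")
  structure(list(mode = mode, velocity = velocity,
                 diffusion_coeff = diffusion_coeff, duration = duration,
                 frame_interval = frame_interval,
                 localization_noise_sd = localization_noise_sd, seed = seed),
            class = "track_params")
}

#' Simulate a single-particle track
#'
#' Generates positions on a regular frame grid: `processive` tracks drift
#' at constant velocity, `static` tracks carry localization noise only, and
#' `diffusive` tracks take Gaussian Brownian steps with variance
#' `2 * D * dt` per frame.  Localization noise is added independently to
#' every frame.
#'
#' @param params A [track_params()] object.
#' @param track_id,microtubule_id Identifiers for the returned track.
#' @return A [motor_track()].
#' @export
simulate_track <- function(params, track_id = "sim", microtubule_id = "mt") {
  stopifnot(inherits(params, "track_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  t <- seq(0, params$duration, by = params$frame_interval)
  n <- length(t)
  base <- switch(params$mode,
    processive = params$velocity * t,
    static = rep(0, n),
    diffusive = c(0, cumsum(rnorm(n - 1,
      sd = sqrt(2 * params$diffusion_coeff * params$frame_interval)))))
  pos <- base + rnorm(n, sd = params$localization_noise_sd)
  motor_track(t, pos, frame_interval = params$frame_interval,
              track_id = track_id, microtubule_id = microtubule_id)
}

#' Write / read tracks as CSV
#'
#' Long-format CSV with columns `track_id`, `microtubule_id`, `time_s`,
#' `position_nm`.
#'
#' @param tracks A list of [motor_track()] objects.
#' @param path CSV path.
#' @return `path` invisibly; `read_tracks_csv` returns a list of tracks.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "motor_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$track_id, microtubule_id = tr$microtubule_id,
               time_s = tr$time, position_nm = tr$position)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path)
  need <- c("track_id", "microtubule_id", "time_s", "position_nm")
  if (!all(need %in% names(df)))
    stop("tracks CSV must have columns ", paste(need, collapse = ", "))
  lapply(split(df, df$track_id), function(d)
    motor_track(d$time_s, d$position_nm, track_id = d$track_id[1],
                microtubule_id = d$microtubule_id[1]))
}
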