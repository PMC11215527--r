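#' Segment-averaged power spectrum of a trapped bead
#'
#' One-sided, segment-averaged periodogram (Welch-style with non-overlapping
#' rectangular segments) of the bead position signal `x = force /
#' spring_constant`.  Each segment is mean-subtracted before the FFT.  The
#' density is scaled so that `sum(density) * df` equals the mean segment
#' variance (Parseval), in nm^2/Hz.
#'
#' @param trace A [trap_trace()].
#' @param segment_length Samples per segment (default 2^13).
#' @return An object of class `power_spectrum` with fields `frequency`
#'   (Hz), `density` (nm^2/Hz) and `n_segments_averaged`.
#' @export
power_spectrum <- function(trace, segment_length = 8192) {
  stopifnot(inherits(trace, "trap_trace"))
  x <- trace$force / trace$spring_constant
  n <- length(x)
  L <- as.integer(segment_length)
  if (L > n) stop("segment_length exceeds trace length")
  nseg <- n %/% L
  dt <- 1 / trace$sample_rate
  nfreq <- L %/% 2 - 1
  acc <- numeric(nfreq)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * L + 1):(s * L)]
    seg <- seg - mean(seg)
    ft <- fft(seg)
    # one-sided density, excluding DC and Nyquist bins
    acc <- acc + 2 * dt / L * Mod(ft[2:(nfreq + 1)])^2
  }
  structure(list(frequency = (1:nfreq) / (L * dt),
                 density = acc / nseg,
                 n_segments_averaged = nseg),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.2f-%.1f Hz, %d segment(s)\n",
              length(x$frequency), x$frequency[1],
              x$frequency[length(x$frequency)], x$n_segments_averaged))
  invisible(x)
}

#' Lorentzian fit of a trapped-bead power spectrum
#'
#' Least-squares fit of `S(f) = D / (2 * pi^2 * (fc^2 + f^2))` to the
#' spectrum within `fit_band`, performed in log-density space with uniform
#' weights so high-frequency bins do not dominate.  When the bead drag is
#' supplied the trap stiffness follows from the corner frequency,
#' `k = 2 * pi * drag * fc`; otherwise the equipartition estimate
#' `k = kBT / var(x)` (with `var(x)` from the spectral integral) is
#' reported as a cross-check.  Note the fitted amplitude `D` follows the
#' stated (two-sided) convention, so on a one-sided spectrum of a physical
#' bead it is about twice `kBT / drag`; the corner frequency and the
#' stiffness are unaffected by this convention.
#'
#' @param psd A [power_spectrum()].
#' @param fit_band Numeric length-2 `c(lo, hi)` in Hz; must lie within the
#'   spectrum.
#' @param drag Bead drag, pN s/nm, or `NULL`.
#' @param thermal_energy k_B T in pN nm (used only for the equipartition
#'   route).
#' @return An object of class `calibration_result` with
#'   `corner_frequency` (Hz), `diffusion_coefficient` (nm^2/s, fitted
#'   amplitude), `stiffness` (pN/nm), `stiffness_method`, and
#'   `fit_residual` (RMS of log-density residuals).
#' @export
fit_lorentzian <- function(psd, fit_band = c(20, 2000), drag = NULL,
                           thermal_energy = .kBT_room) {
  stopifnot(inherits(psd, "power_spectrum"))
  if (fit_band[1] >= fit_band[2]) stop("fit_band must be increasing")
  if (fit_band[1] < psd$frequency[1] ||
      fit_band[2] > psd$frequency[length(psd$frequency)])
    stop("fit_band outside the spectrum range")
  sel <- psd$frequency >= fit_band[1] & psd$frequency <= fit_band[2]
  f <- psd$frequency[sel]
  S <- psd$density[sel]
  if (any(S <= 0) || diff(range(S)) == 0 || !all(is.finite(log(S))))
    stop("degenerate spectrum: no corner frequency can be fit")
  # deterministic initialization: plateau from the lowest decile of the
  # band, corner where the density first falls to half the plateau
  nlow <- max(3L, length(f) %/% 10)
  S0 <- mean(S[seq_len(nlow)])
  below <- which(S <= S0 / 2)
  fc0 <- if (length(below)) f[below[1]] else mean(range(f))
  D0 <- S0 * 2 * pi^2 * fc0^2
  dat <- data.frame(f = f, logS = log(S))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      logS ~ log_D - log(2 * pi^2 * (exp(2 * log_fc) + f^2)),
      data = dat, start = list(log_D = log(D0), log_fc = log(fc0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Lorentzian fit failed: ", conditionMessage(e)))
  fc <- exp(coef(fit)[["log_fc"]])
  D <- exp(coef(fit)[["log_D"]])
  if (fc < fit_band[1] || fc > fit_band[2])
    stop(sprintf("fitted corner frequency %.3g Hz lies outside the fit band",
                 fc))
  if (!is.null(drag)) {
    stiffness <- 2 * pi * drag * fc
    method <- "lorentzian"
  } else {
    var_x <- sum(psd$density) * (psd$frequency[2] - psd$frequency[1])
    stiffness <- thermal_energy / var_x
    method <- "equipartition"
  }
  structure(list(corner_frequency = fc, diffusion_coefficient = D,
                 stiffness = stiffness, stiffness_method = method,
                 fit_residual = sqrt(mean(residuals(fit)^2))),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("<calibration_result> fc = %.1f Hz, D = %.3g nm^2/s,",
                     " k = %.4g pN/nm (%s)\n"),
              x$corner_frequency, x$diffusion_coefficient, x$stiffness,
              x$stiffness_method))
  invisible(x)
}

#' Equipartition stiffness estimate
#'
#' `k = kBT / var(x)` from the time-domain variance of the bead position.
#'
#' @param trace A [trap_trace()].
#' @param thermal_energy k_B T, pN nm.
#' @return Stiffness in pN/nm.
#' @export
equipartition_stiffness <- function(trace, thermal_energy = .kBT_room) {
  x <- trace$force / trace$spring_constant
  thermal_energy / var(x)
}
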