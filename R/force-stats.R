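#' Pooled force-probability histogram
#'
#' Pools force samples across traces and bins them at `bin_width`;
#' probabilities are normalized to unit total, so each bin holds the
#' probability that a bead samples that force.
#'
#' @param traces A [trap_trace()] or list of them.
#' @param bin_width Bin width, pN (default 0.2).
#' @return A data frame of class `force_histogram` with columns
#'   `bin_center_pN` and `probability`; bin width stored as an attribute.
#' @export
force_histogram <- function(traces, bin_width = 0.2) {
  if (inherits(traces, "trap_trace")) traces <- list(traces)
  if (length(traces) < 1) stop("need at least one trace")
  f <- unlist(lapply(traces, `[[`, "force"))
  lo <- floor(min(f) / bin_width) * bin_width
  hi <- ceiling(max(f) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- tabulate(findInterval(f, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  out <- data.frame(bin_center_pN = breaks[-length(breaks)] + bin_width / 2,
                    probability = counts / sum(counts))
  attr(out, "bin_width") <- bin_width
  class(out) <- c("force_histogram", class(out))
  out
}

#' Gaussian-mixture fit to a force histogram
#'
#' Nonlinear least squares of a sum of `n_components` Gaussians,
#' `sum_i w_i * bin_width * dnorm(x, mu_i, sigma_i)`, to the (bin centre,
#' probability) pairs.  Initialization is deterministic: component means at
#' the `n_components` largest local maxima of the 5-bin-smoothed histogram,
#' SDs at 0.5 pN, equal weights.  The unbound component is the one whose
#' fitted mean lies closest to 0 pN (beads detached from the microtubule
#' dwell at zero force).
#'
#' @param hist A [force_histogram()].
#' @param n_components Number of Gaussians (default 3).
#' @return An object of class `gaussian_mixture_fit`: `components` (data
#'   frame `weight`, `mean_pN`, `sd_pN`, ordered by mean),
#'   `unbound_component_index`, `residual_rms`.
#' @export
fit_gaussian_mixture <- function(hist, n_components = 3) {
  stopifnot(inherits(hist, "force_histogram"))
  x <- hist$bin_center_pN
  y <- hist$probability
  bw <- attr(hist, "bin_width")
  if (sum(y > 0) < 3 * n_components)
    stop("histogram has too few non-empty bins for the requested fit")
  ys <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  is_max <- ys >= c(-Inf, ys[-n]) & ys >= c(ys[-1], -Inf) & ys > 0
  cand <- which(is_max)[order(ys[is_max], decreasing = TRUE)]
  if (length(cand) < n_components)
    cand <- c(cand, order(ys, decreasing = TRUE))
  mu0 <- sort(x[utils::head(unique(cand), n_components)])
  start <- list()
  for (i in seq_len(n_components)) {
    start[[paste0("w", i)]] <- 1 / n_components
    start[[paste0("m", i)]] <- mu0[i]
    start[[paste0("s", i)]] <- 0.5
  }
  form <- paste0("w", seq_len(n_components), " * ", bw,
                 " * dnorm(x, m", seq_len(n_components),
                 ", s", seq_len(n_components), ")", collapse = " + ")
  lower <- unlist(lapply(seq_len(n_components),
                         function(i) c(1e-6, min(x), 0.02)))
  upper <- unlist(lapply(seq_len(n_components),
                         function(i) c(2, max(x), diff(range(x)))))
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(paste("y ~", form)),
                      data = data.frame(x = x, y = y), start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("mixture fit did not converge: ", conditionMessage(e)))
  cf <- coef(fit)
  comp <- data.frame(
    weight = cf[paste0("w", seq_len(n_components))],
    mean_pN = cf[paste0("m", seq_len(n_components))],
    sd_pN = cf[paste0("s", seq_len(n_components))])
  comp <- comp[order(comp$mean_pN), ]
  rownames(comp) <- NULL
  structure(list(components = comp,
                 unbound_component_index = which.min(abs(comp$mean_pN)),
                 residual_rms = sqrt(mean(residuals(fit)^2)),
                 bin_width = bw),
            class = "gaussian_mixture_fit")
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat("<gaussian_mixture_fit>\n")
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  %s mu = %6.2f pN, sd = %5.2f pN, w = %.3f%s\n",
                if (i == x$unbound_component_index) "*" else " ",
                x$components$mean_pN[i], x$components$sd_pN[i],
                x$components$weight[i],
                if (i == x$unbound_component_index) "  (unbound)" else ""))
  cat(sprintf("  residual RMS %.2e\n", x$residual_rms))
  invisible(x)
}

#' Subtract the unbound (0-pN) peak from a force histogram
#'
#' Removes the predicted probability of the unbound Gaussian from every
#' bin, flooring at zero, so the remaining mass describes the bead while
#' it is driven along the microtubule.  The result is not renormalized
#' unless requested.
#'
#' @param hist A [force_histogram()].
#' @param fit A [fit_gaussian_mixture()] result on the same histogram.
#' @param renormalize Rescale the remaining mass to 1.
#' @return A `force_histogram` (probabilities may sum to < 1).
#' @export
subtract_unbound_peak <- function(hist, fit, renormalize = FALSE) {
  stopifnot(inherits(hist, "force_histogram"),
            inherits(fit, "gaussian_mixture_fit"))
  u <- fit$components[fit$unbound_component_index, ]
  pred <- u$weight * fit$bin_width *
    dnorm(hist$bin_center_pN, u$mean_pN, u$sd_pN)
  out <- hist
  out$probability <- pmax(hist$probability - pred, 0)
  if (renormalize && sum(out$probability) > 0)
    out$probability <- out$probability / sum(out$probability)
  out
}

#' Double-exponential fit of the stall-time survival function
#'
#' Fits the empirical inverse cumulative distribution (1-CDF), evaluated
#' at the observed event times with uniform weights and no binning, to
#' `A * exp(-t / tau_fast) + (1 - A) * exp(-t / tau_slow)`.  Standard
#' errors come from the fit covariance.  Components are ordered so
#' `tau_fast <= tau_slow`.
#'
#' @param stall_times Stall durations, s (at least 20 events).
#' @return An object of class `survival_fit`: `amplitude_fast`,
#'   `tau_fast`, `tau_slow`, `sems` (named numeric), `n_events`,
#'   `degenerate` flag (tau collapse).
#' @export
stall_time_survival <- function(stall_times) {
  t <- sort(as.numeric(stall_times))
  n <- length(t)
  if (n < 20) stop("need at least 20 events for a survival fit")
  if (diff(range(t)) == 0)
    stop("degenerate input: all stall times identical")
  S <- (n - seq_len(n) + 0.5) / n
  mt <- mean(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(S ~ A * exp(-t / tf) + (1 - A) * exp(-t / ts),
                      data = data.frame(t = t, S = S),
                      start = list(A = 0.5, tf = mt / 3, ts = 1.5 * mt),
                      lower = c(0, 1e-6, 1e-6), upper = c(1, Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("survival fit did not converge: ", conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  names(se) <- names(cf)
  A <- cf[["A"]]; tf <- cf[["tf"]]; ts <- cf[["ts"]]
  if (tf > ts) {             # enforce tau_fast <= tau_slow
    tmp <- tf; tf <- ts; ts <- tmp
    A <- 1 - A
    se <- se[c("A", "ts", "tf")]
    names(se) <- c("A", "tf", "ts")
  }
  degenerate <- abs(ts - tf) / ts < 0.05
  if (degenerate)
    warning("time constants collapsed; distribution may be single-exponential")
  structure(list(amplitude_fast = A, tau_fast = tf, tau_slow = ts,
                 sems = c(amplitude_fast = unname(se["A"]),
                          tau_fast = unname(se["tf"]),
                          tau_slow = unname(se["ts"])),
                 n_events = n, degenerate = degenerate),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf(paste0("<survival_fit> A_fast = %.2f, tau_fast = %.3f s, ",
                     "tau_slow = %.3f s (n = %d)\n"),
              x$amplitude_fast, x$tau_fast, x$tau_slow, x$n_events))
  invisible(x)
}

#' Per-construct stall summary
#'
#' Mean stall force with SEM (`sd / sqrt(n)`) and mean stall time over
#' detachment-terminated events.  Censored and resume events are excluded
#' by default: a censored stall has no observed end, and a resume event is
#' not followed by the detachment snap that defines a stall.
#'
#' @param events A `stall_events` data frame from [detect_stalls()]
#'   (possibly row-bound across traces).
#' @param construct Label for the summary row.
#' @param outcomes Outcomes included in the statistics.
#' @return A data frame of class `stall_summary` with columns `construct`,
#'   `mean_stall_force_pN`, `sem_pN`, `n_stalls`, `mean_stall_time_s`,
#'   `single_event` (TRUE when SEM is reported as 0 because n = 1).
#' @export
summarize_stalls <- function(events, construct = "construct",
                             outcomes = "detach") {
  ev <- events[events$outcome %in% outcomes, ]
  if (nrow(ev) < 1) stop("no events with outcome in: ",
                         paste(outcomes, collapse = ", "))
  n <- nrow(ev)
  sem <- if (n == 1) 0 else sd(ev$stall_force_pN) / sqrt(n)
  if (n == 1) warning("single event: SEM reported as 0")
  out <- data.frame(construct = construct,
                    mean_stall_force_pN = mean(ev$stall_force_pN),
                    sem_pN = sem, n_stalls = n,
                    mean_stall_time_s = mean(ev$stall_time_s),
                    single_event = n == 1)
  class(out) <- c("stall_summary", class(out))
  out
}
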