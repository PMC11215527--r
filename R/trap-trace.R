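#' Force time series from a fixed optical trap
#'
#' Container for a uniformly sampled force trace.  Force is in pN, positive
#' when the load opposes the motor (bead displaced from trap centre towards
#' the microtubule minus end).
#'
#' @param force Numeric vector of forces, pN.
#' @param sample_rate Sampling rate, Hz.
#' @param spring_constant Trap spring constant used to convert bead
#'   displacement to force, pN/nm.
#' @param label Construct identifier.
#' @param ground_truth Optional data frame of programmed intervals with
#'   columns `start_s`, `end_s`, `kind` (one of `"unbound"`, `"moving"`,
#'   `"pause"`, `"stall"`) and `level_pN`.
#' @param t0 Time of the first sample, s.
#' @return An object of class `trap_trace` with elements `time`, `force`,
#'   `sample_rate`, `spring_constant`, `label`, `ground_truth`.
#' @export
trap_trace <- function(force, sample_rate, spring_constant,
                       label = "trace", ground_truth = NULL, t0 = 0) {
  if (!all(is.finite(force))) stop("force values must be finite")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (spring_constant <= 0) stop("spring_constant must be > 0")
  structure(list(time = t0 + (seq_along(force) - 1) / sample_rate,
                 force = as.numeric(force),
                 sample_rate = sample_rate,
                 spring_constant = spring_constant,
                 label = label,
                 ground_truth = ground_truth),
            class = "trap_trace")
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf("<trap_trace '%s'> %d samples at %g Hz (%.3f s), k = %g pN/nm\n",
              x$label, length(x$force), x$sample_rate,
              length(x$force) / x$sample_rate, x$spring_constant))
  cat(sprintf("  force: mean %.3f pN, range [%.3f, %.3f] pN\n",
              mean(x$force), min(x$force), max(x$force)))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: %d programmed intervals\n",
                nrow(x$ground_truth)))
  invisible(x)
}

#' @export
plot.trap_trace <- function(x, ...) {
  plot(x$time, x$force, type = "l", xlab = "time (s)", ylab = "force (pN)",
       main = x$label, ...)
  invisible(x)
}

#' Write / read a trap trace as delimited text
#'
#' Two-column text (`time_s`, `force_pN`) preceded by `# key=value` metadata
#' lines (`spring_constant_pN_per_nm`, `sample_rate_hz`, `label`).  Any
#' ground-truth annotation travels in a sidecar CSV (columns `start_s`,
#' `end_s`, `kind`, `level_pN`) next to the trace file.
#'
#' @param trace A [trap_trace()] object.
#' @param path Output file.
#' @param ground_truth_path Optional sidecar CSV path; defaults to
#'   `<path>.truth.csv` when the trace carries annotations.
#' @return `path`, invisibly (`write_trap_trace`); a `trap_trace`
#'   (`read_trap_trace`).
#' @export
write_trap_trace <- function(trace, path, ground_truth_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spring_constant_pN_per_nm=%.10g", trace$spring_constant),
               sprintf("# sample_rate_hz=%.10g", trace$sample_rate),
               sprintf("# label=%s", trace$label),
               "time_s\tforce_pN"), con)
  write.table(data.frame(time_s = trace$time, force_pN = trace$force),
              con, sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(trace$ground_truth)) {
    if (is.null(ground_truth_path))
      ground_truth_path <- paste0(path, ".truth.csv")
    write.csv(trace$ground_truth, ground_truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_trap_trace
#' @param path Input file written by [write_trap_trace()].
#' @export
read_trap_trace <- function(path, ground_truth_path = NULL) {
  lines <- readLines(path, n = 10)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^# ", "", ml), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  dat <- read.table(path, skip = length(meta_lines) + 1, sep = "\t",
                    col.names = c("time_s", "force_pN"))
  gt <- NULL
  if (is.null(ground_truth_path) && file.exists(paste0(path, ".truth.csv")))
    ground_truth_path <- paste0(path, ".truth.csv")
  if (!is.null(ground_truth_path) && file.exists(ground_truth_path))
    gt <- read.csv(ground_truth_path)
  trap_trace(dat$force_pN,
             sample_rate = as.numeric(meta$sample_rate_hz),
             spring_constant = as.numeric(meta$spring_constant_pN_per_nm),
             label = meta$label %||% "trace",
             ground_truth = gt,
             t0 = dat$time_s[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
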