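#' Compare two construct stall summaries
#'
#' Fractional reduction of the mean stall force of `b` relative to `a`,
#' `(mean_a - mean_b) / mean_a`, with its SEM from first-order error
#' propagation, plus stall-time contrast.
#'
#' @param summary_a,summary_b [summarize_stalls()] rows (a = reference,
#'   typically wild type).
#' @return A list of class `construct_comparison`: `reduction`,
#'   `reduction_sem`, `force_ratio`, `stall_time_ratio`.
#' @export
compare_constructs <- function(summary_a, summary_b) {
  ma <- summary_a$mean_stall_force_pN; mb <- summary_b$mean_stall_force_pN
  if (ma == 0) stop("reference mean stall force is zero")
  red <- (ma - mb) / ma
  sem <- sqrt((mb / ma^2)^2 * summary_a$sem_pN^2 +
                (1 / ma)^2 * summary_b$sem_pN^2)
  structure(list(reduction = red, reduction_sem = sem,
                 force_ratio = mb / ma,
                 stall_time_ratio =
                   summary_b$mean_stall_time_s / summary_a$mean_stall_time_s),
            class = "construct_comparison")
}

#' @export
print.construct_comparison <- function(x, ...) {
  cat(sprintf("<construct_comparison> reduction %.3f +- %.3f (force ratio %.3f)\n",
              x$reduction, x$reduction_sem, x$force_ratio))
  invisible(x)
}

#' Demo pipeline configuration
#'
#' Two-construct optical-trap comparison (wild-type-like vs mutant-like
#' motors) plus a small synthetic motility cohort; suitable for
#' [run_pipeline()] smoke runs.
#'
#' @param seed Integer seed for all stages.
#' @param n_traces Traces per construct.
#' @param duration Trace duration, s.
#' @return A pipeline configuration list.
#' @export
demo_config <- function(seed = 1, n_traces = 20, duration = 12) {
  list(seed = seed,
       constructs = list(
         wt = list(preset = "wt", n_traces = n_traces, duration = duration),
         mutant = list(preset = "mutant", n_traces = n_traces,
                       duration = duration)),
       motility = list(n_per_class = c(processive = 12, static = 6,
                                       diffusive = 6)),
       stages = c("trap", "motility"))
}

#' Run the analysis pipeline on a configuration
#'
#' Executes the requested stages in dependency order.  The `trap` stage
#' simulates traces per construct (using the named stall-criteria preset,
#' `"wt"` or `"mutant"`), detects stalls, summarizes stall forces and
#' times, fits the stall-time survival function (when enough events), and
#' compares constructs when exactly two are configured.  The `motility`
#' stage simulates and classifies a track cohort.  All randomness derives
#' from `config$seed`; given the same configuration the report is
#' identical.  Failure of one stage is recorded in `warnings` without
#' corrupting the others.
#'
#' @param config A configuration list; see [demo_config()].
#' @return A list of class `run_report`: per-stage summaries, the package
#'   version, the configuration echo, and accumulated warnings.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config must supply a seed")
  report <- list(version = as.character(utils::packageVersion("motorforge")),
                 config = config, warnings = character())
  stages <- config$stages %||% "trap"
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      report$warnings <<- c(report$warnings,
                            sprintf("stage '%s' failed: %s", name,
                                    conditionMessage(e)))
      NULL
    })
  }
  if ("trap" %in% stages) {
    report$trap <- run_stage("trap", function() {
      out <- list()
      for (cname in names(config$constructs)) {
        cc <- config$constructs[[cname]]
        preset <- cc$preset %||% "wt"
        if (!preset %in% c("wt", "mutant"))
          stop("unknown preset '", preset, "'")
        params <- ddb_trap_params(preset,
                                  duration = cc$duration %||% 12,
                                  seed = NULL)
        set.seed(config$seed + match(cname, names(config$constructs)))
        events <- do.call(rbind, lapply(seq_len(cc$n_traces %||% 20),
          function(i) {
            tr <- simulate_trap_trace(params,
                                      label = sprintf("%s_%03d", cname, i))
            detect_stalls(tr, stall_criteria(preset))
          }))
        summ <- summarize_stalls(events, construct = cname)
        surv <- if (sum(events$outcome == "detach") >= 20)
          stall_time_survival(events$stall_time_s[events$outcome == "detach"])
        else NULL
        out[[cname]] <- list(summary = summ, survival = surv,
                             n_events = nrow(events))
      }
      if (length(out) == 2)
        out$comparison <- compare_constructs(out[[1]]$summary,
                                             out[[2]]$summary)
      out
    })
  }
  if ("motility" %in% stages) {
    report$motility <- run_stage("motility", function() {
      set.seed(config$seed + 1000)
      npc <- config$motility$n_per_class %||%
        c(processive = 12, static = 6, diffusive = 6)
      tracks <- list()
      for (mode in names(npc)) {
        for (i in seq_len(npc[[mode]])) {
          p <- track_params(mode = mode,
                            duration = if (mode == "processive") 6 else 20)
          tracks[[length(tracks) + 1]] <-
            simulate_track(p, track_id = sprintf("%s_%02d", mode, i),
                           microtubule_id = sprintf("mt%d", (i %% 3) + 1))
        }
      }
      summarize_motility(tracks)
    })
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> motorforge %s\n", x$version))
  if (!is.null(x$trap)) {
    for (cname in setdiff(names(x$trap), "comparison")) {
      s <- x$trap[[cname]]$summary
      cat(sprintf("  %s: stall force %.2f +- %.2f pN (n = %d)\n",
                  cname, s$mean_stall_force_pN, s$sem_pN, s$n_stalls))
    }
    if (!is.null(x$trap$comparison))
      cat(sprintf("  force reduction: %.3f +- %.3f\n",
                  x$trap$comparison$reduction,
                  x$trap$comparison$reduction_sem))
  }
  if (!is.null(x$motility))
    cat(sprintf("  motility: %d microtubule(s) summarized\n",
                nrow(x$motility)))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report A [run_pipeline()] result.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
    }
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
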