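#' Session configuration for a timer-based incubation session
#'
#' Builds and validates the parameter set controlling one targeted dream
#' incubation (TDI) session.  A session cues a participant to think of an
#' everyday object (Fork or Tree) while in hypnagogia or in wakeful freely
#' moving thought (FMT), then prompts short thought reports at scheduled
#' times.  All timing is in whole seconds.
#'
#' @param participant_id opaque participant identifier.
#' @param condition `"hypnagogia"` or `"fmt"`.
#' @param cue_object `"Fork"` or `"Tree"`.
#' @param latency_min_s,latency_max_s participant-chosen preparatory window
#'   (seconds) within which the first incubation cue is scheduled at a
#'   uniformly drawn time.
#' @param dwell_s seconds spent in the target state before each report
#'   prompt (default 180).
#' @param n_trials number of dwell/report rounds (default 4).
#' @param report_s duration of each report window in seconds (default 60).
#' @param return_s seconds allowed to fall back into the target state
#'   between trials (default 420).
#' @param rng_seed integer seed driving the latency draw, making an
#'   at-home session reproducible.
#' @return an object of class `tdi_config` (a validated named list).
#' @seealso [draw_latency()], [build_timeline()]
#' @export
session_config <- function(participant_id,
                           condition = c("hypnagogia", "fmt"),
                           cue_object = c("Fork", "Tree"),
                           latency_min_s,
                           latency_max_s,
                           dwell_s = 180,
                           n_trials = 4,
                           report_s = 60,
                           return_s = 420,
                           rng_seed = 1L) {
  condition <- match.arg(condition)
  cue_object <- match.arg(cue_object)
  stopifnot(length(participant_id) == 1L, nchar(as.character(participant_id)) > 0)
  latency_min_s <- as.numeric(latency_min_s)
  latency_max_s <- as.numeric(latency_max_s)
  if (is.na(latency_min_s) || is.na(latency_max_s) ||
      latency_min_s < 0 || latency_min_s > latency_max_s) {
    stop("latency window must satisfy 0 <= latency_min_s <= latency_max_s")
  }
  if (dwell_s <= 0 || report_s <= 0 || return_s <= 0) {
    stop("dwell_s, report_s and return_s must be positive")
  }
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("n_trials must be >= 1")
  structure(
    list(participant_id = as.character(participant_id),
         condition = condition, cue_object = cue_object,
         latency_min_s = latency_min_s, latency_max_s = latency_max_s,
         dwell_s = dwell_s, n_trials = n_trials,
         report_s = report_s, return_s = return_s,
         rng_seed = as.integer(rng_seed)),
    class = "tdi_config")
}

#' @export
print.tdi_config <- function(x, ...) {
  cat("TDI session config:", x$participant_id, "|", x$condition,
      "| cue:", x$cue_object, "\n")
  cat(sprintf("  latency %g-%g s, %d trial(s) of %g s dwell + %g s report, %g s return\n",
              x$latency_min_s, x$latency_max_s, x$n_trials,
              x$dwell_s, x$report_s, x$return_s))
  invisible(x)
}

#' Cue script for a session
#'
#' The two self-recorded messages replayed during a session: the incubation
#' message naming the cued object, and the report message prompting a
#' verbal thought report.
#'
#' @param cue_object `"Fork"` or `"Tree"`.
#' @param incubation_text message template; must mention the cue object
#'   exactly once.
#' @param report_text report prompt message.
#' @return a list with class `tdi_cue_script`.
#' @export
cue_script <- function(cue_object = c("Fork", "Tree"),
                       incubation_text = paste("Remember to think of a", cue_object),
                       report_text = "Tell me what is going through your mind") {
  cue_object <- match.arg(cue_object)
  if (!nzchar(incubation_text) || !nzchar(report_text)) {
    stop("cue script texts must be non-empty")
  }
  n_mentions <- lengths(regmatches(
    incubation_text,
    gregexpr(paste0("\\b", tolower(cue_object), "s?\\b"),
             tolower(incubation_text))))
  if (n_mentions != 1L) {
    stop("incubation_text must mention the cue object exactly once")
  }
  structure(list(cue_object = cue_object,
                 incubation_text = incubation_text,
                 report_text = report_text),
            class = "tdi_cue_script")
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Draw the incubation latency for a session
#'
#' Picks an integer number of seconds uniformly within the participant's
#' chosen latency window, reproducibly from the config's seed.
#'
#' @param config a [session_config()] object.
#' @param n number of draws (the first is the session's latency; more are
#'   useful for calibration checks).
#' @return integer vector of length `n`, each in
#'   `[latency_min_s, latency_max_s]`.
#' @export
draw_latency <- function(config, n = 1L) {
  stopifnot(inherits(config, "tdi_config"), n >= 1L)
  lo <- as.integer(round(config$latency_min_s))
  hi <- as.integer(round(config$latency_max_s))
  with_local_seed(config$rng_seed, lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L)
}

#' Build the scheduled event timeline of a session
#'
#' Expands a session configuration and a realized latency into the full
#' ordered event schedule: session start, an incubation cue at the end of
#' the latency period and at the start of every between-trial return
#' period, and for each trial a dwell period followed by a report window.
#' The session ends right after the last report window, with no trailing
#' return period.
#'
#' @param config a [session_config()] object.
#' @param latency_s realized latency in seconds; must lie within the
#'   config's window.
#' @return a data frame of class `tdi_timeline` with columns `offset_s`
#'   (seconds from session start, non-decreasing), `event` and `trial`.
#' @export
build_timeline <- function(config, latency_s) {
  stopifnot(inherits(config, "tdi_config"))
  latency_s <- as.numeric(latency_s)
  if (is.na(latency_s) || latency_s < config$latency_min_s ||
      latency_s > config$latency_max_s) {
    stop(sprintf("latency_s = %s outside the configured window [%g, %g]",
                 format(latency_s), config$latency_min_s, config$latency_max_s))
  }
  rows <- list(data.frame(offset_s = 0, event = "session_start", trial = NA_integer_))
  t <- latency_s
  for (trial in seq_len(config$n_trials)) {
    rows[[length(rows) + 1L]] <- data.frame(
      offset_s = t, event = "incubation_cue", trial = trial)
    rows[[length(rows) + 1L]] <- data.frame(
      offset_s = t, event = "dwell_start", trial = trial)
    t <- t + config$dwell_s
    rows[[length(rows) + 1L]] <- data.frame(
      offset_s = t, event = "report_prompt", trial = trial)
    t <- t + config$report_s
    rows[[length(rows) + 1L]] <- data.frame(
      offset_s = t, event = "report_end", trial = trial)
    if (trial < config$n_trials) {
      rows[[length(rows) + 1L]] <- data.frame(
        offset_s = t, event = "return_start", trial = trial)
      t <- t + config$return_s
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    offset_s = t, event = "session_end", trial = NA_integer_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("tdi_timeline", "data.frame"),
            config = config, latency_s = latency_s)
}

#' @export
print.tdi_timeline <- function(x, ...) {
  cat(sprintf("TDI timeline: %d events over %g s (latency %g s)\n",
              nrow(x), max(x$offset_s), attr(x, "latency_s")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Simulated and real-time clocks
#'
#' A clock is an environment-backed object with `now()` (POSIXct) and
#' `advance_to(offset_s)` which returns the realized timestamp for a
#' scheduled offset.  The simulated clock realizes every offset exactly;
#' the real-time clock sleeps until the scheduled time, optionally sped up.
#'
#' @param start session start time.
#' @param speedup divide all real waits by this factor.
#' @return a clock object (list of functions).
#' @export
simulated_clock <- function(start = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  list(kind = "simulated",
       now = function() start,
       advance_to = function(offset_s) start + offset_s)
}

#' @rdname simulated_clock
#' @export
realtime_clock <- function(speedup = 1) {
  stopifnot(speedup > 0)
  t0 <- NULL
  list(kind = "realtime",
       now = function() Sys.time(),
       advance_to = function(offset_s) {
         if (is.null(t0)) t0 <<- Sys.time()
         target <- t0 + offset_s / speedup
         wait <- as.numeric(difftime(target, Sys.time(), units = "secs"))
         if (wait > 0) Sys.sleep(wait)
         Sys.time()
       })
}

#' Execute a session timeline
#'
#' Emits every scheduled event exactly once, in order, stamped with its
#' realized time.  With the default simulated clock, realized offsets
#' equal scheduled offsets exactly; with [realtime_clock()] the function
#' blocks until each event is due.  Sub-second jitter in real-time mode is
#' recorded in the log but never alters the schedule.
#'
#' @param timeline a [build_timeline()] result.
#' @param clock a clock object; defaults to [simulated_clock()].
#' @param event_sink optional function called with each event row as it is
#'   emitted (e.g. to play a cue).
#' @return the event log: a data frame with `timestamp`, `offset_s`
#'   (realized), `scheduled_s`, `event`, `trial`.
#' @export
run_session <- function(timeline, clock = simulated_clock(), event_sink = NULL) {
  stopifnot(inherits(timeline, "tdi_timeline"))
  if (nrow(timeline) == 0L) stop("empty timeline")
  start <- clock$now()
  last <- start
  log <- vector("list", nrow(timeline))
  for (i in seq_len(nrow(timeline))) {
    stamp <- clock$advance_to(timeline$offset_s[i])
    if (stamp < last) stop("clock went backwards during session execution")
    last <- stamp
    row <- data.frame(
      timestamp = stamp,
      offset_s = as.numeric(difftime(stamp, start, units = "secs")),
      scheduled_s = timeline$offset_s[i],
      event = timeline$event[i],
      trial = timeline$trial[i])
    if (!is.null(event_sink)) event_sink(row)
    log[[i]] <- row
  }
  out <- do.call(rbind, log)
  rownames(out) <- NULL
  out
}

.vigilance_levels <- c("fully_asleep", "half_asleep", "did_not_sleep")

#' Vigilance-based analysis inclusion screen
#'
#' After each condition participants self-report how deeply they slept
#' ("fully asleep", "half asleep", "did not sleep").  A participant is
#' retained for analysis only if they stayed completely awake during the
#' FMT condition and experienced at least some sleep (fully or halfway)
#' during the hypnagogia condition.
#'
#' @param hyp_level,fmt_level vigilance levels reported after the
#'   hypnagogia and FMT conditions (vectorized).
#' @return logical: `TRUE` for participants meeting both criteria.
#' @export
inclusion_filter <- function(hyp_level, fmt_level) {
  if (length(hyp_level) != length(fmt_level)) {
    stop("one response per condition is required")
  }
  if (any(is.na(hyp_level)) || any(is.na(fmt_level)) ||
      !all(hyp_level %in% .vigilance_levels) ||
      !all(fmt_level %in% .vigilance_levels)) {
    stop("vigilance levels must be one of: ",
         paste(.vigilance_levels, collapse = ", "))
  }
  fmt_level == "did_not_sleep" & hyp_level %in% c("fully_asleep", "half_asleep")
}

#' Apply the inclusion screen to a cohort vigilance table
#'
#' @param vigilance data frame with columns `participant_id`, `condition`
#'   (`"hypnagogia"`/`"fmt"`) and `level`.
#' @return data frame `participant_id`, `included`.
#' @export
screen_cohort <- function(vigilance) {
  stopifnot(all(c("participant_id", "condition", "level") %in% names(vigilance)))
  hyp <- vigilance[vigilance$condition == "hypnagogia", ]
  fmt <- vigilance[vigilance$condition == "fmt", ]
  ids <- sort(unique(vigilance$participant_id))
  if (!setequal(hyp$participant_id, ids) || !setequal(fmt$participant_id, ids)) {
    stop("every participant needs one vigilance response per condition")
  }
  hyp <- hyp[match(ids, hyp$participant_id), ]
  fmt <- fmt[match(ids, fmt$participant_id), ]
  data.frame(participant_id = ids,
             included = inclusion_filter(hyp$level, fmt$level))
}

#' Read/write session configs and event logs
#'
#' Session configs are stored as flat `key=value` text files; event logs
#' as tab-separated text with one event per line (ISO-8601 timestamp,
#' realized offset, scheduled offset, event kind, trial index).
#'
#' @param config a `tdi_config`; `path` a file path.
#' @return `read_session_config()` returns a `tdi_config`;
#'   `read_event_log()` a data frame.
#' @name session_io
NULL

#' @rdname session_io
#' @param path file path.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "tdi_config"))
  writeLines(paste0(names(config), "=", unlist(config)), path)
  invisible(path)
}

#' @rdname session_io
#' @export
read_session_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                                 character(1)),
                          vapply(kv, `[[`, character(1), 1L))
  session_config(participant_id = vals[["participant_id"]],
                 condition = vals[["condition"]],
                 cue_object = vals[["cue_object"]],
                 latency_min_s = as.numeric(vals[["latency_min_s"]]),
                 latency_max_s = as.numeric(vals[["latency_max_s"]]),
                 dwell_s = as.numeric(vals[["dwell_s"]]),
                 n_trials = as.integer(vals[["n_trials"]]),
                 report_s = as.numeric(vals[["report_s"]]),
                 return_s = as.numeric(vals[["return_s"]]),
                 rng_seed = as.integer(vals[["rng_seed"]]))
}

#' @rdname session_io
#' @param log an event log from [run_session()].
#' @export
write_event_log <- function(log, path) {
  out <- log
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%OS3%z")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_event_log <- function(path) {
  log <- utils::read.delim(path, stringsAsFactors = FALSE)
  log$timestamp <- as.POSIXct(log$timestamp, format = "%Y-%m-%dT%H:%M:%OS%z",
                              tz = "UTC")
  log
}
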