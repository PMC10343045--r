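#' Build and validate a reproducible run configuration
#'
#' A run configuration names the stages to execute, the seed, the output
#' directory and the per-stage parameters (all defaulting to the values used
#' throughout the package). Unknown stage names or parameters are rejected
#' here, before anything runs, so a typo cannot silently fall back to a
#' default.
#'
#' @param stages stages to run, in order, from `"simulate"`, `"precision"`,
#'   `"sync"`, `"evoked"`, `"resp"`. The default simulation mirrors a
#'   marking-precision assessment: a background-noise recording (no
#'   breathing) with five push-button presses; override `sim` (e.g.
#'   `breath_times = NULL` to restore a breathing schedule) for the other
#'   stages.
#' @param seed integer seed applied to the whole run.
#' @param out_dir output directory (`NULL` = keep results in memory only).
#' @param strict propagate strict mode to epoching operations.
#' @param sim named list of [session_config()] overrides.
#' @param precision,sync,evoked,resp named lists of per-stage parameters:
#'   `precision$threshold_fraction`; `sync$half_window`, `sync$max_lag`;
#'   `evoked$max_shift`, `evoked$pre`, `evoked$post`; `resp$window`,
#'   `resp$step`, `resp$edge_gap`, `resp$threshold_frac`.
#' @return validated list of class `ms_run_config`.
#' @export
run_config <- function(stages = c("simulate", "precision"),
                       seed = 1L, out_dir = NULL, strict = FALSE,
                       sim = list(), precision = list(), sync = list(),
                       evoked = list(), resp = list()) {
  known_stages <- c("simulate", "precision", "sync", "evoked", "resp")
  if (!all(stages %in% known_stages)) {
    ms_abort(sprintf("unknown stage(s): %s",
      paste(setdiff(stages, known_stages), collapse = ", ")), "config")
  }
  check_params <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      ms_abort(sprintf("unknown parameter(s) in %s: %s", where,
        paste(bad, collapse = ", ")), "config")
    }
  }
  check_params(sim, names(formals(session_config)), "sim")
  check_params(precision, "threshold_fraction", "precision")
  check_params(sync, c("half_window", "max_lag"), "sync")
  check_params(evoked, c("max_shift", "pre", "post"), "evoked")
  check_params(resp, c("window", "step", "edge_gap", "threshold_frac"), "resp")
  structure(
    list(
      stages = stages, seed = as.integer(seed), out_dir = out_dir,
      strict = strict, sim = sim, precision = precision, sync = sync,
      evoked = evoked, resp = resp
    ),
    class = "ms_run_config"
  )
}

#' Read a run configuration from JSON (or YAML)
#'
#' @param path config file; `.json`, or `.yaml`/`.yml` when the yaml package
#'   is available.
#' @return a validated `ms_run_config` (see [run_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ms_abort(sprintf("no such file: %s", path), "io")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      ms_abort("YAML configs need the yaml package; use JSON", "config")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  bad <- setdiff(names(raw), names(formals(run_config)))
  if (length(bad)) {
    ms_abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
      "config")
  }
  do.call(run_config, raw)
}

#' Execute a configured simulate-and-analyse run
#'
#' Simulates a session under the configured seed and runs the requested
#' analysis stages on it. The returned report records the package version,
#' the seed, every parameter actually used, per-stage headline numbers,
#' per-stage timing and (when files are written) MD5 hashes of the outputs
#' — enough to reproduce the run exactly from the report alone. Input
#' objects are never mutated. A stage that errors is marked `failed` in the
#' report and later stages still run.
#'
#' @param config a `ms_run_config` from [run_config()] / [read_run_config()].
#' @return a list of class `ms_report`; element `ok` is `FALSE` if any stage
#'   failed.
#' @examples
#' rep <- run_pipeline(run_config(
#'   stages = c("simulate", "precision"),
#'   sim = list(duration = 30, press_times = c(5, 15, 25))
#' ))
#' rep$stages$precision$outputs
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ms_run_config"))
  report <- list(
    tool = "multisync",
    version = as.character(utils::packageVersion("multisync")),
    seed = config$seed,
    stages = list(),
    ok = TRUE
  )
  session <- NULL
  results <- list()

  run_stage <- function(name, params, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(
      list(status = "ok", outputs = fun()),
      error = function(e) list(status = "failed", error = conditionMessage(e))
    )
    out$params <- params
    out$elapsed_s <- proc.time()[["elapsed"]] - t0
    report$stages[[name]] <<- out
    if (out$status != "ok") report$ok <<- FALSE
    out
  }

  sim_params <- utils::modifyList(
    list(
      duration = 60, press_times = c(10, 20, 30, 40, 50),
      breath_times = numeric(0), ip_noise_sd = 0.02
    ),
    config$sim
  )
  st <- run_stage("simulate", sim_params, function() {
    session <<- simulate_session(do.call(session_config, sim_params),
      seed = config$seed)
    list(
      n_events = nrow(session$monitor_events),
      channels = c(names(session$research), names(session$monitor))
    )
  })

  if (!is.null(session) && "precision" %in% config$stages) {
    p <- utils::modifyList(list(threshold_fraction = 0.03), config$precision)
    run_stage("precision", p, function() {
      lat <- marking_precision(session$monitor$ip, session$monitor_events,
        threshold_fraction = p$threshold_fraction)
      ps <- precision_stats(lat$latency_s)
      results$precision <<- ps
      list(mean_s = ps$mean, sd_s = ps$sd, min_s = ps$min, max_s = ps$max,
        n = ps$n)
    })
  }
  if (!is.null(session) && "sync" %in% config$stages) {
    p <- utils::modifyList(list(half_window = 5, max_lag = 2.5), config$sync)
    run_stage("sync", p, function() {
      a <- preprocess_research_ecg(session$research$ecg)
      b <- preprocess_monitor_ecg(session$monitor$ecg)
      ev <- session$research_events$time_s
      covered <- vapply(ev, function(tt) {
        !is.null(extract_epoch(a, tt, p$half_window, p$half_window)) &&
          !is.null(extract_epoch(b, tt, p$half_window, p$half_window))
      }, logical(1))
      if (!all(covered)) {
        warning(sprintf("%d event(s) without full epoch coverage skipped",
          sum(!covered)))
      }
      ev <- ev[covered]
      lags <- vapply(ev, function(tt) {
        estimate_event_lag(a, b, tt, half_window = p$half_window,
          max_lag = p$max_lag)
      }, numeric(1))
      lr <- session_sync_offset(lags)
      results$sync <<- lr
      list(session_mean_s = lr$session_mean,
        session_abs_mean_s = lr$session_abs_mean, n = length(lags))
    })
  }
  if (!is.null(session) && "evoked" %in% config$stages) {
    p <- utils::modifyList(list(max_shift = 0.1, pre = 0.5, post = 1),
      config$evoked)
    run_stage("evoked", p, function() {
      ev <- session$research_events
      ev <- ev$time_s[ev$label == "visual"]
      es <- epoch_signal(session$research$eeg, ev, pre = p$pre, post = p$post,
        strict = config$strict)
      avg <- average_epochs(es)
      wd <- woody_align(avg, session$config$eeg_template,
        max_shift = p$max_shift)
      results$evoked <<- wd
      list(n_trials = length(attr(es, "events")), shift_s = wd$shift,
        magnitude = wd$magnitude, correlation = wd$correlation)
    })
  }
  if (!is.null(session) && "resp" %in% config$stages) {
    p <- utils::modifyList(
      list(window = 20, step = 1, edge_gap = 1.5, threshold_frac = 0.5),
      config$resp
    )
    run_stage("resp", p, function() {
      clean <- remove_cardiac_interference(session$monitor$ip,
        session$monitor$ecg)
      ibi <- detect_breaths(clean, threshold_frac = p$threshold_frac)
      rr <- windowed_rr(ibi, window = p$window, step = p$step,
        edge_gap = p$edge_gap,
        span = c(sig_start(clean), sig_start(clean) + sig_duration(clean)))
      results$resp <<- rr
      list(n_breaths = nrow(ibi),
        median_rr_bpm = stats::median(rr$rr_bpm, na.rm = TRUE))
    })
  }

  if (!is.null(config$out_dir) && !is.null(session)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session(session, file.path(config$out_dir, "session"))
    files <- list.files(file.path(config$out_dir, "session"), full.names = TRUE)
    report$output_hashes <- as.list(tools::md5sum(files))
    names(report$output_hashes) <- basename(files)
    strip <- rapply(report$stages, function(x) x, how = "list")
    jsonlite::write_json(
      list(
        tool = report$tool, version = report$version, seed = report$seed,
        stages = strip, output_hashes = report$output_hashes, ok = report$ok
      ),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
    )
  }

  report$results <- results
  report$session <- session
  class(report) <- "ms_report"
  report
}

#' @export
print.ms_report <- function(x, ...) {
  cat(sprintf("<ms_report> multisync %s, seed %d, %s\n", x$version, x$seed,
    if (x$ok) "all stages ok" else "STAGE FAILURES"))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-10s %-6s %.2fs\n", nm, st$status, st$elapsed_s))
  }
  invisible(x)
}
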