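#' Read and write signal CSV files
#'
#' The on-disk dialect is a UTF-8 CSV with header `time_s,value`, '.'
#' decimal separator and times printed with 6 fractional digits
#' (microsecond resolution, so millisecond semantics survive a round trip).
#' On read the time stamps must form a uniform grid: a deviation above 0.1%
#' of the sampling interval is treated as a corrupt file.
#'
#' @param sig a [signal_ts()].
#' @param path CSV file path.
#' @return `write_signal_csv()` returns `path` invisibly;
#'   `read_signal_csv()` returns a [signal_ts()].
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "ms_signal"))
  out <- data.frame(
    time_s = sprintf("%.6f", sig$time),
    value = sprintf("%.10g", sig$value)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @param rate expected sampling rate in Hz (`NULL` to infer from the time
#'   stamps).
#' @param label,units channel metadata to attach.
#' @export
read_signal_csv <- function(path, rate = NULL, label = NULL, units = "a.u.") {
  if (!file.exists(path)) ms_abort(sprintf("no such file: %s", path), "io")
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      ms_abort(sprintf("cannot parse %s: %s", path, conditionMessage(e)), "parse")
    }
  )
  if (!all(c("time_s", "value") %in% names(df))) {
    ms_abort(sprintf("%s: expected header 'time_s,value'", path), "parse")
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$value) ||
    anyNA(df$time_s) || anyNA(df$value)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))[1]
    ms_abort(
      sprintf("%s: non-numeric data%s", path,
        if (!is.na(bad)) sprintf(" near line %d", bad + 1L) else ""),
      "parse"
    )
  }
  as_signal(df, rate = rate, label = label %||% basename(path), units = units)
}

#' Write / read a simulated session as a directory of text files
#'
#' One CSV per channel (`research_<name>.csv`, `monitor_<name>.csv`), the
#' two event lists as JSON, and the ground truth as `truth.json`.
#'
#' @param session a `ms_session` from [simulate_session()].
#' @param dir output directory (created if missing).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a list with `research`, `monitor` (lists of signals, rates
#'   inferred), `research_events`, `monitor_events` and `truth`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ms_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(session$research)) {
    write_signal_csv(session$research[[nm]],
      file.path(dir, paste0("research_", nm, ".csv")))
  }
  for (nm in names(session$monitor)) {
    write_signal_csv(session$monitor[[nm]],
      file.path(dir, paste0("monitor_", nm, ".csv")))
  }
  write_events(session$research_events, file.path(dir, "research_events.json"))
  write_events(session$monitor_events, file.path(dir, "monitor_events.json"))
  jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  research <- list()
  monitor <- list()
  for (f in files) {
    nm <- sub("\\.csv$", "", basename(f))
    sig <- read_signal_csv(f, label = sub("^(research|monitor)_", "", nm))
    if (startsWith(nm, "research_")) {
      research[[sub("^research_", "", nm)]] <- sig
    } else if (startsWith(nm, "monitor_")) {
      monitor[[sub("^monitor_", "", nm)]] <- sig
    }
  }
  truth_path <- file.path(dir, "truth.json")
  list(
    research = research, monitor = monitor,
    research_events = read_events(file.path(dir, "research_events.json")),
    monitor_events = read_events(file.path(dir, "monitor_events.json")),
    truth = if (file.exists(truth_path)) jsonlite::fromJSON(truth_path)
  )
}
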