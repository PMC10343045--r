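#' Canonical stimulus marker labels
#'
#' The event bridge distinguishes six canonical markers: the clinically
#' required heel lance, experimental visual, tactile, auditory and noxious
#' stimuli, and a push-button device. Arbitrary user labels are also accepted
#' everywhere a marker is taken.
#'
#' @return character vector of the six canonical labels.
#' @export
marker_labels <- function() {
  c(
    "heel_lance", "visual", "tactile", "auditory",
    "noxious_experimental", "push_button"
  )
}

#' Default marker-to-payload mapping
#'
#' Each trigger line carries a user-defined text payload on the wire; this
#' table provides one short payload per canonical marker.
#'
#' @return tibble with columns `label`, `payload`.
#' @export
default_marker_mapping <- function() {
  tibble::tibble(
    label = marker_labels(),
    payload = c("LANCE", "VIS", "TACT", "AUD", "NOX", "PUSH")
  )
}

as_marker_mapping <- function(mapping) {
  if (is.character(mapping) && !is.null(names(mapping))) {
    mapping <- tibble::tibble(label = names(mapping), payload = unname(mapping))
  }
  if (!is.data.frame(mapping) || !all(c("label", "payload") %in% names(mapping))) {
    ms_abort("`mapping` must be a data frame with columns `label`, `payload`", "argument")
  }
  if (anyDuplicated(mapping$label)) {
    ms_abort("duplicate marker labels in mapping", "ambiguous_mapping")
  }
  mapping
}

#' Encode a stimulus marker as an annotation message
#'
#' Looks the marker up in the payload mapping and wraps the payload in a
#' transport-tagged message. UDP-like and TCP-like transports behave
#' identically at this abstraction level (no sockets are opened); the tag is
#' carried so a downstream consumer can tell which path stamped the event.
#'
#' @param marker marker label (see [marker_labels()]; custom labels allowed).
#' @param mapping marker-to-payload table, as in [default_marker_mapping()],
#'   or a named character vector `c(label = payload)`.
#' @param transport `"udp_like"` (default) or `"tcp_like"`.
#' @param seq message sequence number carried in the serialised envelope.
#' @param timestamp send time in seconds carried in the envelope.
#' @return an object of class `ms_message` with fields `marker`, `payload`,
#'   `transport`, `seq`, `timestamp`.
#' @seealso [decode_event()], [message_to_json()]
#' @examples
#' encode_event("visual")
#' @export
encode_event <- function(marker, mapping = default_marker_mapping(),
                         transport = c("udp_like", "tcp_like"),
                         seq = 1L, timestamp = 0) {
  transport <- match.arg(transport)
  mapping <- as_marker_mapping(mapping)
  if (!is.character(marker) || length(marker) != 1L || !nzchar(marker)) {
    ms_abort("`marker` must be a single non-empty label", "argument")
  }
  hit <- match(marker, mapping$label)
  if (is.na(hit)) {
    ms_abort(sprintf("marker '%s' has no payload in the mapping", marker),
      "unmapped_marker")
  }
  structure(
    list(
      marker = marker, payload = mapping$payload[hit],
      transport = transport, seq = as.integer(seq), timestamp = as.double(timestamp)
    ),
    class = "ms_message"
  )
}

#' Decode an annotation message back to its marker label
#'
#' @param msg a `ms_message`, or a bare payload string.
#' @inheritParams encode_event
#' @return the marker label whose payload matches.
#' @export
decode_event <- function(msg, mapping = default_marker_mapping()) {
  mapping <- as_marker_mapping(mapping)
  payload <- if (inherits(msg, "ms_message")) msg$payload else msg
  if (!is.character(payload) || length(payload) != 1L) {
    ms_abort("`msg` must be a ms_message or a single payload string", "argument")
  }
  hits <- which(mapping$payload == payload)
  if (length(hits) == 0L) {
    ms_abort(sprintf("payload '%s' matches no marker in the mapping", payload),
      "unknown_message")
  }
  if (length(hits) > 1L) {
    ms_abort(sprintf("payload '%s' is mapped by several markers", payload),
      "ambiguous_mapping")
  }
  mapping$label[hits]
}

#' Serialise / parse the wire form of an annotation message
#'
#' The wire form is a versioned JSON envelope
#' `{"v": 1, "payload": ..., "seq": ..., "time_s": ...}` so the protocol is
#' self-describing; the transport tag is not part of the envelope.
#'
#' @param msg a `ms_message`.
#' @return `message_to_json()` returns a JSON string; `message_from_json()`
#'   returns the payload envelope as a list.
#' @export
message_to_json <- function(msg) {
  stopifnot(inherits(msg, "ms_message"))
  jsonlite::toJSON(
    list(v = 1L, payload = msg$payload, seq = msg$seq, time_s = msg$timestamp),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname message_to_json
#' @param json JSON envelope string.
#' @export
message_from_json <- function(json) {
  env <- jsonlite::fromJSON(json)
  if (is.null(env$v) || is.null(env$payload)) {
    ms_abort("not a valid annotation envelope", "unknown_message")
  }
  env
}

#' Per-device clock and marking-latency model
#'
#' Each recording device keeps its own clock, modelled as an affine transform
#' of true time, `device_time = offset + (1 + drift) * true_time`, plus a
#' stochastic marking latency added when an event is stamped onto that
#' device's recording. The latency is a normal distribution truncated below
#' at `latency_floor` (marks cannot precede their trigger path's minimum
#' transit time).
#'
#' Defaults for the two devices mirror the measured behaviour of the trigger
#' paths: the research path stamps events with sub-millisecond delay
#' (mean 0.5 ms, sd 0), while the monitor path via the network annotation
#' route has mean 105 ms, sd 19 ms.
#'
#' @param offset clock offset in seconds.
#' @param drift clock drift in seconds per second (0 = ideal).
#' @param latency_mean,latency_sd mean and sd of marking latency, seconds.
#' @param latency_floor truncation bound (>= 0), seconds.
#' @return object of class `ms_clock`.
#' @export
clock_model <- function(offset = 0, drift = 0, latency_mean = 0,
                        latency_sd = 0, latency_floor = 0) {
  if (latency_sd < 0) ms_abort("`latency_sd` must be >= 0", "argument")
  if (latency_floor < 0) ms_abort("`latency_floor` must be >= 0", "argument")
  structure(
    list(
      offset = offset, drift = drift, latency_mean = latency_mean,
      latency_sd = latency_sd, latency_floor = latency_floor
    ),
    class = "ms_clock"
  )
}

#' @rdname clock_model
#' @export
research_clock_default <- function() {
  clock_model(latency_mean = 5e-4, latency_sd = 0)
}

#' @rdname clock_model
#' @export
monitor_clock_default <- function() {
  clock_model(latency_mean = 0.105, latency_sd = 0.019, latency_floor = 0)
}

#' @rdname clock_model
#' @param clock a `ms_clock`.
#' @param true_time true time(s) in seconds.
#' @export
device_time <- function(clock, true_time) {
  clock$offset + (1 + clock$drift) * true_time
}

# truncated-normal marking-latency draws (rejection sampling; sd 0 degenerate)
draw_latency <- function(clock, n) {
  if (clock$latency_sd == 0) {
    return(rep(max(clock$latency_mean, clock$latency_floor), n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), clock$latency_mean, clock$latency_sd)
    ok <- draw >= clock$latency_floor
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Stamp triggers onto two device timelines
#'
#' Models the event-bridge path: a trigger fired at `true_times` is stamped
#' onto the research recording and onto the monitor recording, each after its
#' clock transform and a draw from its marking-latency distribution.
#'
#' @param true_times trigger times in seconds (true clock).
#' @param research_clock,monitor_clock `ms_clock` models for the two devices.
#' @param labels marker label(s), recycled across triggers.
#' @param seed optional integer seed for the latency draws.
#' @return tibble with one row per (trigger, device): columns `event`,
#'   `label`, `device`, `time_s` (mark time on that device's clock) and
#'   `latency_s` (the latency actually drawn).
#' @examples
#' bridge_trigger(c(10, 20), seed = 1)
#' @export
bridge_trigger <- function(true_times,
                           research_clock = research_clock_default(),
                           monitor_clock = monitor_clock_default(),
                           labels = "push_button", seed = NULL) {
  if (!is.numeric(true_times) || !all(is.finite(true_times))) {
    ms_abort("`true_times` must be finite numbers", "argument")
  }
  n <- length(true_times)
  labels <- rep_len(labels, n)
  with_seed_if(seed, {
    lat_r <- draw_latency(research_clock, n)
    lat_m <- draw_latency(monitor_clock, n)
    dplyr::bind_rows(
      tibble::tibble(
        event = seq_len(n), label = labels, device = "research",
        time_s = device_time(research_clock, true_times) + lat_r,
        latency_s = lat_r
      ),
      tibble::tibble(
        event = seq_len(n), label = labels, device = "monitor",
        time_s = device_time(monitor_clock, true_times) + lat_m,
        latency_s = lat_m
      )
    ) |> dplyr::arrange(.data$event, .data$device)
  })
}

#' Read / write event-annotation files
#'
#' Events are stored either as a JSON array of objects
#' `{"label": ..., "time_s": ..., "device": ...}` or as CSV with header
#' `label,time_s,device`; the format follows the file extension. Times are
#' written with at least 6 fractional digits so millisecond semantics survive
#' a round trip.
#'
#' @param events data frame with columns `label`, `time_s`, `device`.
#' @param path file path ending in `.json` or `.csv`.
#' @return `read_events()` returns a tibble with columns `label`, `time_s`,
#'   `device`; `write_events()` returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("label", "time_s", "device") %in% names(events)))
  ev <- tibble::as_tibble(events)[, c("label", "time_s", "device")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(ev, path, dataframe = "rows", digits = NA)
  } else {
    out <- data.frame(
      label = ev$label, time_s = sprintf("%.6f", ev$time_s), device = ev$device
    )
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) ms_abort(sprintf("no such file: %s", path), "io")
  ev <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (length(ev) == 0L) { # an empty event list is valid
    return(tibble::tibble(label = character(), time_s = double(),
      device = character()))
  }
  if (!all(c("label", "time_s", "device") %in% names(ev))) {
    ms_abort(sprintf("%s: expected fields label, time_s, device", path), "parse")
  }
  tibble::tibble(
    label = as.character(ev$label),
    time_s = as.double(ev$time_s),
    device = as.character(ev$device)
  )
}

#' Read a marker-mapping config (JSON object label -> payload)
#'
#' @param path JSON file path.
#' @return tibble with columns `label`, `payload`.
#' @export
read_marker_mapping <- function(path) {
  obj <- jsonlite::fromJSON(path)
  as_marker_mapping(unlist(obj))
}
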