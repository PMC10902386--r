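#' Reading and normalizing raw sensor streams
#'
#' Raw AWARE-style tables carry Unix UTC timestamps (milliseconds or seconds),
#' numeric state codes, and duplicated logging rows. Normalization converts
#' timestamps to local time, drops exact duplicates and payload-less rows,
#' maps state codes to labels, and sorts by (subject, time).
#'
#' @name sensor_ingest
NULL

SCREEN_CODES <- c("0" = "off", "1" = "on", "2" = "lock", "3" = "unlock")
SCREEN_STATES <- c("on", "off", "unlock", "lock")

payload_cols <- function(kind) {
  switch(kind,
    gps = c("double_latitude", "double_longitude"),
    screen = "screen_status",
    comm = c("comm_type", "comm_direction", "duration_s", "contact"))
}

#' Normalize a raw sensor table into a canonical event stream
#'
#' @param raw data frame with `subject` and `timestamp` columns plus the
#'   kind-specific payload (`double_latitude`/`double_longitude` for GPS,
#'   `screen_status` for screen, `comm_type`/`comm_direction`/`duration_s`/
#'   `contact` for communication). Timestamps are Unix UTC in milliseconds
#'   (values > 1e11) or seconds.
#' @param kind one of `"gps"`, `"screen"`, `"comm"`.
#' @param tz valid IANA timezone for local-time conversion.
#' @return data frame of class `event_stream` sorted by (subject, t) with a
#'   POSIXct `t` column in `tz`; attribute `n_dropped` counts rows removed
#'   for unparseable timestamps or missing payload.
#' @export
normalize_stream <- function(raw, kind = c("gps", "screen", "comm"),
                             tz = "America/Los_Angeles") {
  kind <- match.arg(kind)
  if (!all(c("subject", "timestamp") %in% names(raw)))
    stop("normalize_stream: raw table needs 'subject' and 'timestamp' columns")
  if (!tz %in% OlsonNames())
    stop("normalize_stream: invalid timezone: ", tz)

  n0 <- nrow(raw)
  raw <- unique(raw)                                  # exact duplicate rows
  ts <- suppressWarnings(as.numeric(raw$timestamp))
  bad <- is.na(ts)
  # milliseconds vs seconds: anything past ~5138 AD in seconds is ms
  ts <- ifelse(!bad & abs(ts) > 1e11, ts / 1000, ts)

  pc <- intersect(payload_cols(kind), names(raw))
  if (length(pc) == 0)
    stop("normalize_stream: no ", kind, " payload columns found")
  core <- if (kind == "comm") setdiff(pc, c("duration_s", "contact")) else pc
  miss_payload <- rowSums(is.na(raw[, core, drop = FALSE]) |
                          (raw[, core, drop = FALSE] == "")) > 0
  drop <- bad | miss_payload
  out <- raw[!drop, , drop = FALSE]
  ts <- ts[!drop]

  t_local <- as.POSIXct(ts, origin = "1970-01-01", tz = tz)
  out$t <- t_local
  if (kind == "screen") {
    st <- out$screen_status
    if (is.numeric(st)) st <- SCREEN_CODES[as.character(st)]
    st <- as.character(st)
    if (any(!st %in% SCREEN_STATES, na.rm = TRUE))
      stop("normalize_stream: unknown screen state(s)")
    out$state <- st
    out$screen_status <- NULL
  }
  if (kind == "comm") {
    if (any(!out$comm_type %in% c("call", "sms")) ||
        any(!out$comm_direction %in% c("incoming", "outgoing")))
      stop("normalize_stream: unknown comm channel or direction")
  }
  out$timestamp <- NULL
  out <- out[order(out$subject, out$t), , drop = FALSE]
  rownames(out) <- NULL
  # deduplicate again on normalized form (e.g. one row logged in s, one in ms)
  out <- unique(out)
  rownames(out) <- NULL
  structure(out, kind = kind, tz = tz, n_dropped = sum(drop),
            class = c("event_stream", "data.frame"))
}

#' Local study day and minute-of-day of events
#'
#' @param stream normalized event stream.
#' @param origin_date local date of study day 1.
#' @return data frame `stream` with added `day` (integer study day) and
#'   `min_of_day` (minutes after local midnight, fractional).
#' @export
annotate_days <- function(stream, origin_date) {
  tz <- attr(stream, "tz")
  if (is.null(tz)) tz <- attr(stream$t, "tzone")
  lt <- as.POSIXlt(stream$t, tz = tz)
  stream$day <- as.integer(as.Date(lt) - as.Date(origin_date)) + 1L
  stream$min_of_day <- lt$hour * 60 + lt$min + lt$sec / 60
  stream
}

#' Partition one day's events into night / day / evening windows
#'
#' Windows follow the local clock: night 00:00-08:00, day 08:00-16:00,
#' evening 16:00-24:00, each half-open `[start, end)` so an event exactly on
#' a boundary goes to the later window.
#'
#' @param stream normalized event stream (one subject).
#' @param day integer study day.
#' @param origin_date local date of study day 1.
#' @return named list of three event-stream subsets (`night`, `day`,
#'   `evening`) whose union is the day's events.
#' @export
day_windows <- function(stream, day, origin_date) {
  s <- annotate_days(stream, origin_date)
  s <- s[s$day == day, , drop = FALSE]
  m <- s$min_of_day
  list(night = s[m >= 0 & m < 480, , drop = FALSE],
       day = s[m >= 480 & m < 960, , drop = FALSE],
       evening = s[m >= 960, , drop = FALSE])
}

#' Read a raw sensor CSV and normalize it
#'
#' @param path CSV with the documented column schema for `kind`.
#' @inheritParams normalize_stream
#' @return normalized `event_stream`.
#' @export
read_sensor_csv <- function(path, kind, tz = "America/Los_Angeles") {
  normalize_stream(utils::read.csv(path, stringsAsFactors = FALSE), kind, tz)
}
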