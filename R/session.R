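#' Recording-session configuration
#'
#' Holds the session clock and lighting schedule that every downstream
#' windowing operation uses. The defaults reproduce the standard housing
#' regime: a 12:12 light-dark cycle with lights on at 08:00 and off at
#' 20:00, and a 72-h continuous recording starting at lights-on.
#'
#' @param session_start Session start, a `POSIXct` or a string parseable by
#'   [lubridate::ymd_hms()] (e.g. `"2023-01-10 08:00:00"`).
#' @param session_hours Session length in hours. Default 72.
#' @param lights_on,lights_off Times of day as `"HH:MM"` strings.
#'   Must differ; together they partition each 24 h into one light and one
#'   dark interval.
#' @param expected_tags Optional character vector of tag IDs expected in the
#'   session; tags never detected trigger a warning during forward fill.
#' @param tz Time zone of the session clock. Default `"UTC"` (timestamps are
#'   treated as local wall-clock time).
#' @return An object of class `session_config`.
#' @examples
#' cfg <- session_config("2023-01-10 08:00:00")
#' cfg
#' @export
session_config <- function(session_start = "2023-01-10 08:00:00",
                           session_hours = 72,
                           lights_on = "08:00",
                           lights_off = "20:00",
                           expected_tags = NULL,
                           tz = "UTC") {
  if (is.character(session_start)) {
    session_start <- lubridate::ymd_hms(session_start, tz = tz)
  }
  stopifnot(inherits(session_start, "POSIXct"),
            is.numeric(session_hours), session_hours > 0)
  on_s <- .parse_tod(lights_on)
  off_s <- .parse_tod(lights_off)
  if (on_s == off_s) stop("lights_on and lights_off must differ")
  start_sec <- as.integer(floor(as.numeric(session_start)))
  len_sec <- as.integer(round(session_hours * 3600))
  structure(
    list(session_start = session_start,
         session_hours = as.numeric(session_hours),
         start_sec = start_sec,
         end_sec = start_sec + len_sec,      # exclusive
         lights_on = lights_on, lights_off = lights_off,
         lights_on_sec = on_s, lights_off_sec = off_s,
         expected_tags = expected_tags,
         tz = tz),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> start %s (%s), %g h; light %s-%s\n",
              format(x$session_start, "%Y-%m-%d %H:%M:%S"), x$tz,
              x$session_hours, x$lights_on, x$lights_off))
  invisible(x)
}

# "HH:MM" or "HH:MM:SS" -> seconds past midnight
.parse_tod <- function(s) {
  p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
  if (length(p) == 2L) p <- c(p, 0L)
  stopifnot(length(p) == 3L, !anyNA(p), p[1] < 24L, p[2] < 60L, p[3] < 60L)
  p[1] * 3600L + p[2] * 60L + p[3]
}

# seconds past local midnight for epoch seconds under the config's clock
.tod_of <- function(seconds, config) {
  mid <- as.integer(floor(as.numeric(lubridate::floor_date(
    config$session_start, "day"))))
  as.integer((as.numeric(seconds) - mid) %% 86400)
}

#' Lighting phase at given epoch seconds
#'
#' @param seconds Integer epoch seconds.
#' @param config A [session_config()].
#' @return Character vector, `"light"` or `"dark"`.
#' @export
phase_at <- function(seconds, config) {
  tod <- .tod_of(seconds, config)
  on_s <- config$lights_on_sec; off_s <- config$lights_off_sec
  light <- if (on_s < off_s) tod >= on_s & tod < off_s else tod >= on_s | tod < off_s
  ifelse(light, "light", "dark")
}

# first second >= from whose time-of-day equals tod (seconds past midnight)
.next_tod <- function(from, tod, config) {
  cur <- .tod_of(from, config)
  from + ((tod - cur) %% 86400L)
}

#' Fixed-width analysis windows aligned to the lighting schedule
#'
#' Windows of `bin_hours` are laid end to end from an anchor inside the
#' session. When the session starts exactly at lights-on or lights-off the
#' anchor is the session start (the standard protocol introduces animals at
#' lights-on); otherwise the anchor is moved to the first lights-on at or
#' after the session start and a warning is emitted. The final window is
#' truncated at session end if the session length is not a multiple of the
#' bin width.
#'
#' @param config A [session_config()].
#' @param bin_hours Window width in hours (2 for activity/CCR time courses,
#'   12 for light/dark totals).
#' @return A `data.table` with columns `window_id`, `start_sec`,
#'   `end_sec` (exclusive), `T` (number of one-second samples), `phase`
#'   (`"light"`, `"dark"`, or `"mixed"` when the window straddles a lighting
#'   transition), `start_time` (POSIXct) and `label` (e.g. `"day1 08:00"`).
#' @examples
#' w <- make_windows(session_config(), bin_hours = 2)
#' nrow(w)  # 36 windows in 72 h
#' @export
make_windows <- function(config, bin_hours = 2) {
  stopifnot(inherits(config, "session_config"), bin_hours > 0)
  anchor <- config$start_sec
  tod <- .tod_of(anchor, config)
  if (tod != config$lights_on_sec && tod != config$lights_off_sec) {
    anchor <- .next_tod(config$start_sec, config$lights_on_sec, config)
    warning(sprintf(
      "session does not start at a lighting-phase boundary; windows anchored to first lights-on at %s",
      format(.sec_to_time(anchor, config), "%Y-%m-%d %H:%M:%S")))
  }
  bin <- as.integer(round(bin_hours * 3600))
  starts <- seq.int(anchor, config$end_sec - 1L, by = bin)
  ends <- pmin(starts + bin, config$end_sec)
  ph_start <- phase_at(starts, config)
  ph_end <- phase_at(ends - 1L, config)
  # a window is pure if no lighting transition falls strictly inside it
  pure <- ph_start == ph_end &
    (ends - starts) <= .seconds_to_next_transition(starts, config)
  st <- .sec_to_time(starts, config)
  day <- floor((starts - starts[1]) / 86400) + 1L
  data.table::data.table(
    window_id = seq_along(starts),
    start_sec = as.integer(starts),
    end_sec = as.integer(ends),
    T = as.integer(ends - starts),
    phase = ifelse(pure, ph_start, "mixed"),
    start_time = st,
    label = sprintf("day%d %s", day, format(st, "%H:%M"))
  )
}

# seconds from each start to the next lights-on/off transition (exclusive)
.seconds_to_next_transition <- function(starts, config) {
  tod <- .tod_of(starts, config)
  d_on <- (config$lights_on_sec - tod) %% 86400L
  d_off <- (config$lights_off_sec - tod) %% 86400L
  d_on[d_on == 0L] <- 86400L
  d_off[d_off == 0L] <- 86400L
  pmin(d_on, d_off)
}

.sec_to_time <- function(sec, config) {
  as.POSIXct(as.numeric(sec), origin = "1970-01-01", tz = config$tz)
}

#' Successive light/dark intervals of a session
#'
#' Splits the session into its alternating lighting phases (12-h half-days
#' under the default 12:12 cycle), labeled `"day 1 light"`, `"day 1 dark"`,
#' and so on; the day counter increments at each return to the phase the
#' session started in.
#'
#' @inheritParams make_windows
#' @return A `data.table` in the same layout as [make_windows()].
#' @examples
#' phase_windows(session_config())$label  # 6 half-days over 72 h
#' @export
phase_windows <- function(config) {
  stopifnot(inherits(config, "session_config"))
  anchor <- config$start_sec
  tod <- .tod_of(anchor, config)
  if (tod != config$lights_on_sec && tod != config$lights_off_sec) {
    anchor <- .next_tod(config$start_sec, config$lights_on_sec, config)
    warning(sprintf(
      "session does not start at a lighting-phase boundary; intervals anchored to first lights-on at %s",
      format(.sec_to_time(anchor, config), "%Y-%m-%d %H:%M:%S")))
  }
  starts <- integer(0)
  cur <- anchor
  while (cur < config$end_sec) {
    starts <- c(starts, cur)
    cur <- cur + .seconds_to_next_transition(cur, config)
  }
  ends <- pmin(c(starts[-1], config$end_sec), config$end_sec)
  ph <- phase_at(starts, config)
  day <- cumsum(ph == ph[1])
  data.table::data.table(
    window_id = seq_along(starts),
    start_sec = as.integer(starts),
    end_sec = as.integer(ends),
    T = as.integer(ends - starts),
    phase = ph,
    start_time = .sec_to_time(starts, config),
    label = sprintf("day %d %s", day, ph)
  )
}
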