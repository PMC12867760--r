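#' Parse a raw RFID floor-plate log
#'
#' Reads a plain-text detection log, one sensor event per line:
#' an ISO-8601 local timestamp (optionally with fractional seconds, and
#' either `"YYYY-MM-DD HH:MM:SS.ff"` or `"YYYY-MM-DDTHH:MM:SS.ff"`), an
#' integer antenna ID and a transponder (tag) ID, separated by tabs or
#' whitespace. Lines starting with `#` and blank lines are ignored.
#' Malformed lines (unparseable timestamp, non-integer or out-of-range
#' antenna ID, missing tag) are rejected and counted; `strict = TRUE` turns
#' the first malformed line into an error naming its line number.
#'
#' Timestamps are assumed to be monotone wall-clock time; if they are not,
#' a warning is emitted and detections are stably sorted by
#' `(timestamp, line_no)`.
#'
#' @param path Path to the log file.
#' @param strict If `TRUE`, abort on the first malformed line.
#' @param geom A [grid_geometry()]; antenna IDs outside
#'   `[1, geom$n_antennas]` are rejected.
#' @param tz Time zone for timestamp interpretation. Default `"UTC"`.
#' @return A `data.table` of detections with columns `line_no` (integer,
#'   source-line ordinal), `timestamp` (POSIXct, fractional seconds
#'   preserved), `antenna_id` (integer), `tag_id` (character), in file
#'   order. The number of rejected lines is attached as attribute
#'   `n_rejected`.
#' @export
parse_raw_log <- function(path, strict = FALSE, geom = grid_geometry(),
                          tz = "UTC") {
  if (!file.exists(path)) stop("cannot read raw log: ", path)
  fast <- .parse_fast_tsv(path, geom, tz)
  if (!is.null(fast)) return(fast)
  lines <- readLines(path, warn = FALSE)
  empty <- data.table::data.table(
    line_no = integer(0),
    timestamp = as.POSIXct(numeric(0), origin = "1970-01-01", tz = tz),
    antenna_id = integer(0), tag_id = character(0))
  data.table::setattr(empty, "n_rejected", 0L)
  if (length(lines) == 0L) return(empty)

  line_no <- seq_along(lines)
  keep <- !grepl("^[ \t]*(#|$)", lines)
  if (!any(keep)) return(empty)
  lines <- lines[keep]; line_no <- line_no[keep]

  toks <- strsplit(trimws(gsub("\t", " ", lines, fixed = TRUE)),
                   " +", perl = TRUE)
  nf <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  first <- cumsum(c(1L, nf[-length(nf)]))

  ts_str <- rep(NA_character_, length(lines))
  ant_str <- rep(NA_character_, length(lines))
  tag <- rep(NA_character_, length(lines))
  i3 <- which(nf == 3L)                 # timestamp has no internal space
  if (length(i3)) {
    ts_str[i3] <- flat[first[i3]]
    ant_str[i3] <- flat[first[i3] + 1L]
    tag[i3] <- flat[first[i3] + 2L]
  }
  i4 <- which(nf == 4L)                 # "date time antenna tag"
  if (length(i4)) {
    ts_str[i4] <- paste(flat[first[i4]], flat[first[i4] + 1L])
    ant_str[i4] <- flat[first[i4] + 2L]
    tag[i4] <- flat[first[i4] + 3L]
  }

  ts <- suppressWarnings(lubridate::ymd_hms(ts_str, tz = tz, quiet = TRUE))
  ant <- suppressWarnings(as.integer(ant_str))
  bad_range <- !is.na(ant) & (ant < 1L | ant > geom$n_antennas)
  bad <- is.na(ts) | is.na(ant) | bad_range | is.na(tag) | tag == ""
  if (any(bad)) {
    if (strict) {
      stop(sprintf("malformed line %d in %s: '%s'",
                   line_no[which(bad)[1]], path, lines[which(bad)[1]]))
    }
    reasons <- ifelse(is.na(ts), "unparseable timestamp",
               ifelse(bad_range,
                      sprintf("antenna ID outside 1-%d", geom$n_antennas),
                      "unparseable fields"))
    message(sprintf("parse_raw_log: rejected %d malformed line(s) (e.g. line %d: %s)",
                    sum(bad), line_no[which(bad)[1]], reasons[which(bad)[1]]))
  }
  det <- data.table::data.table(
    line_no = line_no[!bad], timestamp = ts[!bad],
    antenna_id = ant[!bad], tag_id = tag[!bad])
  if (is.unsorted(as.numeric(det$timestamp))) {
    warning("non-monotonic timestamps in raw log; stably sorting by (timestamp, line_no)")
    data.table::setorder(det, timestamp, line_no)
  }
  data.table::setattr(det, "n_rejected", sum(bad))
  det[]
}

# Fast path for clean machine-written logs: strictly tab-delimited, three
# fields per line, no comments, every line well-formed. Returns NULL on any
# irregularity so the caller falls back to the tolerant line-by-line parser
# (which preserves true line numbers for diagnostics).
.parse_fast_tsv <- function(path, geom, tz) {
  dt <- tryCatch(
    suppressWarnings(data.table::fread(
      path, header = FALSE, sep = "\t", quote = "", fill = TRUE,
      colClasses = "character", strip.white = TRUE,
      blank.lines.skip = FALSE)),
    error = function(e) NULL)
  if (is.null(dt) || ncol(dt) != 3L || nrow(dt) == 0L) return(NULL)
  if (anyNA(dt$V3) || any(dt$V3 == "") || any(startsWith(dt$V1, "#"))) {
    return(NULL)
  }
  ts <- suppressWarnings(lubridate::ymd_hms(dt$V1, tz = tz, quiet = TRUE))
  ant <- suppressWarnings(as.integer(dt$V2))
  if (anyNA(ts) || anyNA(ant) || any(ant < 1L | ant > geom$n_antennas)) {
    return(NULL)
  }
  det <- data.table::data.table(line_no = seq_len(nrow(dt)), timestamp = ts,
                                antenna_id = ant, tag_id = dt$V3)
  if (is.unsorted(as.numeric(det$timestamp))) {
    warning("non-monotonic timestamps in raw log; stably sorting by (timestamp, line_no)")
    data.table::setorder(det, timestamp, line_no)
  }
  data.table::setattr(det, "n_rejected", 0L)
  det[]
}

#' Truncate detection timestamps to whole seconds
#'
#' Drops fractional seconds by floor truncation (removal of the decimal
#' part, not rounding) and adds an integer epoch-second column `second`.
#' Order is preserved and the operation is idempotent.
#'
#' @param detections A detection table from [parse_raw_log()] (or any table
#'   with `timestamp`, `antenna_id`, `tag_id`, `line_no`).
#' @return A copy with `second` (integer epoch seconds) and `timestamp`
#'   truncated to the whole second.
#' @export
truncate_to_seconds <- function(detections) {
  det <- data.table::as.data.table(detections)
  sec <- floor(as.numeric(det$timestamp))
  det[, `:=`(second = as.integer(sec),
             timestamp = as.POSIXct(sec, origin = "1970-01-01",
                                    tz = attr(detections$timestamp, "tzone") %||% "UTC"))]
  det[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep the first detection per animal per second
#'
#' When an animal is detected more than once within one second, only the
#' first detection (earliest by source line) is retained; detections of
#' different animals in the same second are all kept, one row each.
#' Idempotent.
#'
#' @param detections A truncated detection table (see
#'   [truncate_to_seconds()]); must have columns `tag_id`, `second`,
#'   `line_no`.
#' @return The deduplicated table, ordered by `line_no`.
#' @export
dedupe_first_wins <- function(detections) {
  det <- data.table::as.data.table(detections)
  stopifnot(all(c("tag_id", "second", "line_no") %in% names(det)))
  det <- det[order(line_no)]
  unique(det, by = c("tag_id", "second"))
}

#' Forward-fill per-second trajectories
#'
#' Builds the per-second trajectory table: for each animal, every second
#' from its first detection to the fill horizon gets a position; seconds
#' with no detection carry the most recent observed position forward
#' (`observed = FALSE`). Seconds before an animal's first detection are
#' absent — there is no preceding value to carry, so no back-fill.
#'
#' @param deduped Deduplicated detections (one row per animal-second, see
#'   [dedupe_first_wins()]).
#' @param config A [session_config()]; tags listed in
#'   `config$expected_tags` but never detected trigger a warning and are
#'   omitted.
#' @param geom A [grid_geometry()] for the antenna-to-coordinate mapping.
#' @param fill_to `"session"` (default) fills each animal through the last
#'   second of the configured session; `"last"` fills only to the animal's
#'   last detection.
#' @param max_fill_gap Maximum gap, in seconds, that forward fill may
#'   bridge (default `Inf`, unlimited). Seconds further than this from the
#'   last detection are left absent — used to stop a detached tag's final
#'   position from being carried for days.
#' @param drop_tags Character vector of tag IDs to exclude entirely (e.g.
#'   an animal whose tag detached mid-experiment).
#' @return A keyed `data.table` — the trajectory table — with columns
#'   `tag_id`, `second` (integer epoch), `antenna_id`, `x`, `y`,
#'   `observed` (logical), one row per animal-second.
#' @export
forward_fill <- function(deduped, config, geom = grid_geometry(),
                         fill_to = c("session", "last"),
                         max_fill_gap = Inf, drop_tags = NULL) {
  fill_to <- match.arg(fill_to)
  stopifnot(inherits(config, "session_config"))
  det <- data.table::as.data.table(deduped)
  if (length(drop_tags)) det <- det[!tag_id %in% drop_tags]
  if (!is.null(config$expected_tags)) {
    missing_tags <- setdiff(setdiff(config$expected_tags, drop_tags),
                            unique(det$tag_id))
    if (length(missing_tags)) {
      warning("expected tag(s) never detected, omitted: ",
              paste(missing_tags, collapse = ", "))
    }
  }
  if (nrow(det) == 0L) {
    return(data.table::data.table(tag_id = character(0), second = integer(0),
                                  antenna_id = integer(0), x = integer(0),
                                  y = integer(0), observed = logical(0)))
  }
  xy <- antenna_to_xy(det$antenna_id, geom)
  obs <- data.table::data.table(tag_id = det$tag_id, second = det$second,
                                antenna_id = as.integer(det$antenna_id),
                                x = xy$x, y = xy$y, obs_second = det$second)
  data.table::setkey(obs, tag_id, second)

  span <- obs[, .(first = min(second),
                  last = if (fill_to == "session") config$end_sec - 1L
                         else max(second)), by = tag_id]
  grid <- span[, .(second = seq.int(first, last)), by = tag_id]
  roll <- if (is.finite(max_fill_gap)) as.numeric(max_fill_gap) else Inf
  traj <- obs[grid, on = c("tag_id", "second"), roll = roll]
  traj <- traj[!is.na(x)]
  traj[, observed := obs_second == second]
  traj[, obs_second := NULL]
  data.table::setkey(traj, tag_id, second)
  traj[]
}

#' One-shot preprocessing: raw log to trajectory table
#'
#' Convenience wrapper chaining [parse_raw_log()] (skipped when `x` is
#' already a detection table), [truncate_to_seconds()],
#' [dedupe_first_wins()] and [forward_fill()].
#'
#' @param x Path to a raw log file, or a detection table with columns
#'   `timestamp`, `antenna_id`, `tag_id`, `line_no`.
#' @inheritParams forward_fill
#' @inheritParams parse_raw_log
#' @return A trajectory table (see [forward_fill()]).
#' @export
preprocess <- function(x, config, geom = grid_geometry(), strict = FALSE,
                       fill_to = c("session", "last"), max_fill_gap = Inf,
                       drop_tags = NULL) {
  det <- if (is.character(x)) {
    parse_raw_log(x, strict = strict, geom = geom, tz = config$tz)
  } else {
    data.table::as.data.table(x)
  }
  det <- truncate_to_seconds(det)
  det <- dedupe_first_wins(det)
  forward_fill(det, config, geom, fill_to = match.arg(fill_to),
               max_fill_gap = max_fill_gap, drop_tags = drop_tags)
}

#' Write / read a processed trajectory table
#'
#' CSV dialect with header `tag_id,second,antenna_id,x,y,observed`.
#' `time_format = "epoch"` writes `second` as integer epoch seconds
#' (lossless round trip); `"iso"` writes an ISO-8601 timestamp instead.
#'
#' @param traj A trajectory table from [forward_fill()].
#' @param path Output (input) CSV path.
#' @param time_format `"epoch"` or `"iso"`.
#' @param tz Time zone used for `"iso"` formatting/parsing.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the trajectory table.
#' @export
write_trajectory <- function(traj, path, time_format = c("epoch", "iso"),
                             tz = "UTC") {
  time_format <- match.arg(time_format)
  out <- data.table::as.data.table(traj)
  if (time_format == "iso") {
    out <- data.table::copy(out)
    out[, second := format(as.POSIXct(second, origin = "1970-01-01", tz = tz),
                           "%Y-%m-%dT%H:%M:%S")]
  }
  data.table::fwrite(out[, .(tag_id, second, antenna_id, x, y, observed)],
                     path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, tz = "UTC") {
  traj <- data.table::fread(path, colClasses = list(
    character = "tag_id", logical = "observed"))
  if (is.character(traj$second)) {
    traj[, second := as.integer(floor(as.numeric(
      lubridate::ymd_hms(second, tz = tz))))]
  }
  traj[, `:=`(second = as.integer(second), antenna_id = as.integer(antenna_id),
              x = as.integer(x), y = as.integer(y))]
  data.table::setkey(traj, tag_id, second)
  traj[]
}
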