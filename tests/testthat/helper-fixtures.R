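library(data.table)

# epoch second of the default session start (lights-on 08:00)
default_config <- function(hours = 72, ...) {
  session_config(session_hours = hours, ...)
}
T0 <- default_config()$start_sec

# detection table from offsets relative to the default session start;
# frac gives sub-second timing, line order follows row order
make_detections <- function(tag, sec_offset, antenna, frac = 0) {
  n <- max(length(tag), length(sec_offset), length(antenna))
  data.table(
    line_no = seq_len(n),
    timestamp = as.POSIXct(T0 + sec_offset + frac,
                           origin = "1970-01-01", tz = "UTC"),
    antenna_id = as.integer(antenna),
    tag_id = tag)
}

# trajectory table straight from positions (already per-second, observed)
make_traj <- function(tag, sec_offset, x, y, geom = grid_geometry()) {
  dt <- data.table(tag_id = tag, second = as.integer(T0 + sec_offset),
                   x = as.integer(x), y = as.integer(y))
  dt[, antenna_id := xy_to_antenna(x, y, geom)]
  dt[, observed := TRUE]
  setcolorder(dt, c("tag_id", "second", "antenna_id", "x", "y", "observed"))
  setkey(dt, tag_id, second)
  dt[]
}

write_log_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent Chebyshev ring rule used as classification oracle
ring_oracle <- function(dx, dy) {
  ring <- pmax(abs(dx), abs(dy))
  ifelse(ring == 0, "Same",
         ifelse(ring == 1, "Close",
                ifelse(ring == 2, "Intermediate", "Away")))
}
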