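#' Per-second step distances
#'
#' For each animal, the Euclidean distance in cm between consecutive
#' per-second positions: `D[t+1] = pitch_cm * sqrt(dx^2 + dy^2)`. The step
#' is attributed to its arrival second; the first second of each animal has
#' no step (`NA`). Forward-filled spans contribute zero by construction
#' (position constant).
#'
#' @param traj A trajectory table from [forward_fill()] — contiguous
#'   seconds per animal are required and enforced.
#' @param geom A [grid_geometry()].
#' @return A `data.table` with one row per trajectory row: `tag_id`,
#'   `second`, `dist_cm` (`NA` on each animal's first second).
#' @export
step_distances <- function(traj, geom = grid_geometry()) {
  dt <- data.table::as.data.table(traj)
  data.table::setorder(dt, tag_id, second)
  gap <- dt[, .(ok = all(diff(second) == 1L) || .N == 1L), by = tag_id]
  if (!all(gap$ok)) {
    stop("non-contiguous seconds for tag(s): ",
         paste(gap$tag_id[!gap$ok], collapse = ", "),
         " (trajectory must be forward-filled)")
  }
  dt[, dist_cm := {
    dx <- x - data.table::shift(x)
    dy <- y - data.table::shift(y)
    geom$pitch_cm * sqrt(dx^2 + dy^2)
  }, by = tag_id]
  dt[, .(tag_id, second, dist_cm)]
}

#' Travel distance per animal per window
#'
#' Sums step distances whose arrival second falls inside each window
#' (total distance = sum over t of D[t+1], with T-1 steps in an isolated
#' window of T samples). Windows with no trajectory rows for an animal get
#' distance 0 and coverage 0.
#'
#' @param steps Step-distance table from [step_distances()].
#' @param windows A window table from [make_windows()] or
#'   [phase_windows()].
#' @return A `data.table` with one row per animal per window: `tag_id`,
#'   `window_id`, `start_sec`, `start_time`, `label`, `phase`, `T`,
#'   `distance_cm` and `coverage` (fraction of window seconds on which the
#'   animal has a trajectory row).
#' @export
windowed_distance <- function(steps, windows) {
  st <- data.table::as.data.table(steps)
  win <- data.table::as.data.table(windows)
  idx <- findInterval(st$second, win$start_sec)
  ok <- idx >= 1L & st$second < win$end_sec[pmax(idx, 1L)]
  agg <- st[ok][, window_id := win$window_id[idx[ok]]][
    , .(distance_cm = sum(dist_cm, na.rm = TRUE), n_sec = .N),
    by = .(tag_id, window_id)]
  full <- data.table::CJ(tag_id = unique(st$tag_id),
                         window_id = win$window_id)
  out <- agg[full, on = c("tag_id", "window_id")]
  out[is.na(distance_cm), `:=`(distance_cm = 0, n_sec = 0L)]
  out <- win[, .(window_id, start_sec, start_time, label, phase, T)][
    out, on = "window_id"]
  out[, coverage := n_sec / T][, n_sec := NULL]
  data.table::setorder(out, tag_id, window_id)
  out[]
}

#' Normalize windowed activity to each animal's maximum
#'
#' Adds `relative_activity`: each window's distance as a percentage of that
#' animal's maximum windowed distance over the whole recording, so every
#' moving animal has at least one window at 100. An animal that never moved
#' gets 0 everywhere, with a warning.
#'
#' @param activity A windowed-distance table from [windowed_distance()].
#' @return The table with a `relative_activity` column in `[0, 100]`.
#' @export
normalize_activity <- function(activity) {
  act <- data.table::as.data.table(activity)
  act[, relative_activity := {
    m <- max(distance_cm)
    if (m > 0) 100 * distance_cm / m else rep(0, .N)
  }, by = tag_id]
  still <- act[, .(m = max(distance_cm)), by = tag_id][m == 0, tag_id]
  if (length(still)) {
    warning("animal(s) with zero total movement, relative_activity set to 0: ",
            paste(still, collapse = ", "))
  }
  act[]
}

#' Travel distance per light/dark half-day
#'
#' Totals over the session's successive 12-h lighting phases, labeled
#' `"day 1 light"`, `"day 1 dark"`, and so on.
#'
#' @param steps Step-distance table from [step_distances()].
#' @param config A [session_config()].
#' @return A windowed-distance table (see [windowed_distance()]) over
#'   [phase_windows()].
#' @export
light_dark_totals <- function(steps, config) {
  windowed_distance(steps, phase_windows(config))
}

#' Relative-activity heatmap matrix
#'
#' Dense animals-by-windows matrix of `relative_activity`, the numeric
#' content of the time-course heatmaps. Windows an animal does not cover
#' are `NA`.
#'
#' @param activity A normalized activity table (see [normalize_activity()]).
#' @param tag_order Optional character vector fixing row order; defaults to
#'   sorted tag IDs.
#' @return A numeric matrix, rows = animals, columns = windows (named by
#'   window label).
#' @export
activity_heatmap_matrix <- function(activity, tag_order = NULL) {
  act <- data.table::as.data.table(activity)
  stopifnot("relative_activity" %in% names(act))
  act <- data.table::copy(act)
  act[coverage == 0, relative_activity := NA_real_]
  wide <- data.table::dcast(act, tag_id ~ window_id,
                            value.var = "relative_activity")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$tag_id
  labs <- unique(act[, .(window_id, label)])
  colnames(m) <- labs$label[match(as.integer(colnames(m)), labs$window_id)]
  if (!is.null(tag_order)) {
    stopifnot(all(rownames(m) %in% tag_order))
    m <- m[tag_order[tag_order %in% rownames(m)], , drop = FALSE]
  }
  m
}
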