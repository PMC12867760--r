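#' Home-cage simulation parameters
#'
#' Parameter bundle for the synthetic home-cage generator. Defaults model
#' the standard recording regime: a 72-h session of 8 tagged mice on the
#' 12 x 8 board under a 12:12 light-dark cycle, with nocturnal movement
#' (per-second movement probability 0.2 in the light phase, 0.8 in the
#' dark — the 4:1 contrast typical of mouse circadian activity), moderate
#' social attraction, and mild sensor noise (5% per-second detection
#' dropout, 1% spurious same-second duplicate detections).
#'
#' @param n_mice Number of animals. Default 8.
#' @param hours Session length in hours. Default 72.
#' @param p_move_light,p_move_dark Per-second probability of attempting a
#'   move during the light / dark phase. A scalar applies to every animal;
#'   a length-`n_mice` vector gives each animal its own rate, modeling
#'   individual variation within a cohort.
#' @param p_social Probability that an attempted move is a social step —
#'   one Chebyshev-reducing step toward the nearest conspecific — instead
#'   of a uniform 8-neighbor step. Scalar or length-`n_mice`.
#' @param p_miss Per-second probability that a detection is dropped.
#' @param p_dup Per-detection probability of an extra same-second spurious
#'   detection at an adjacent cell.
#' @param tag_loss Optional `data.frame(tag_id, from_sec)`: tags that stop
#'   emitting from the given second (offset from session start), emulating
#'   a detached transponder.
#' @param tags Optional character vector of tag IDs (default
#'   `"TAG_01"`...).
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given the seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_mice = 8L, hours = 72,
                       p_move_light = 0.2, p_move_dark = 0.8,
                       p_social = 0.3, p_miss = 0.05, p_dup = 0.01,
                       tag_loss = NULL, tags = NULL, seed = 1L) {
  n_mice <- as.integer(n_mice)
  per_mouse <- function(p) {
    stopifnot(length(p) %in% c(1L, n_mice), all(p >= 0), all(p <= 1))
    rep(as.numeric(p), length.out = n_mice)
  }
  p_move_light <- per_mouse(p_move_light)
  p_move_dark <- per_mouse(p_move_dark)
  p_social <- per_mouse(p_social)
  stopifnot(n_mice >= 1L, hours > 0,
            p_miss >= 0, p_miss <= 1, p_dup >= 0, p_dup <= 1)
  if (is.null(tags)) tags <- sprintf("TAG_%02d", seq_len(n_mice))
  stopifnot(length(tags) == n_mice, !anyDuplicated(tags))
  if (!is.null(tag_loss)) {
    stopifnot(is.data.frame(tag_loss),
              all(c("tag_id", "from_sec") %in% names(tag_loss)),
              all(tag_loss$tag_id %in% tags))
  }
  structure(list(n_mice = n_mice, hours = as.numeric(hours),
                 p_move_light = p_move_light, p_move_dark = p_move_dark,
                 p_social = p_social, p_miss = p_miss, p_dup = p_dup,
                 tag_loss = tag_loss, tags = tags, seed = as.integer(seed)),
            class = "sim_params")
}

#' Named simulation scenario presets
#'
#' Parameter bundles mirroring the recording cohorts the pipeline is built
#' for: `"small-group"` (4 mice), `"large-group"` (16 mice),
#' `"nocturnal"` (strong light/dark movement contrast), `"asocial"`
#' (no social attraction), and `"tag-loss"` (16 mice, one tag silenced
#' from hour 24, reproducing the dropped-animal analysis path).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [sim_params()].
#' @return A [sim_params()] object.
#' @export
scenario_presets <- function(name, ...) {
  presets <- list(
    "small-group" = function(...) sim_params(n_mice = 4L, ...),
    "large-group" = function(...) sim_params(n_mice = 16L, ...),
    "nocturnal" = function(...) sim_params(p_move_light = 0.1,
                                           p_move_dark = 0.8, ...),
    "asocial" = function(...) sim_params(p_social = 0, ...),
    "tag-loss" = function(...) sim_params(
      n_mice = 16L,
      tag_loss = data.frame(tag_id = "TAG_16", from_sec = 24L * 3600L), ...)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]](...)
}

#' Simulate a home-cage cohort and its raw RFID log
#'
#' Generates per-second ground-truth positions for a group of mice (seeded
#' circadian random walk with social attraction, see [sim_params()]), then
#' passes them through a noisy detection channel: per-second dropouts,
#' spurious same-second duplicate detections at an adjacent cell, and
#' optional mid-session tag loss. Detections carry fractional-second
#' timestamps (the true detection earlier within the second than any
#' duplicate, so first-wins deduplication recovers the true position).
#'
#' @param params A [sim_params()] object.
#' @param config A [session_config()]; defaults to a session of
#'   `params$hours` starting at lights-on. When supplied, its span defines
#'   the simulated duration.
#' @param geom A [grid_geometry()].
#' @param log_path If non-`NULL`, the raw log is written there
#'   (tab-delimited `timestamp  antenna_id  tag_id` lines).
#' @return A list with `detections` (a detection table with `line_no`,
#'   `timestamp`, `antenna_id`, `tag_id` — directly consumable by
#'   [preprocess()]), `truth` (the ground-truth trajectory table, same
#'   layout as [forward_fill()] output with `observed = TRUE`), `config`,
#'   `params` and `log_path`.
#' @examples
#' sim <- simulate_cohort(sim_params(n_mice = 4, hours = 1, seed = 42))
#' traj <- preprocess(sim$detections, sim$config)
#' @export
simulate_cohort <- function(params, config = NULL, geom = grid_geometry(),
                            log_path = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(config)) {
    config <- session_config(session_hours = params$hours)
  }
  n_sec <- config$end_sec - config$start_sec
  n <- params$n_mice
  secs <- config$start_sec + seq_len(n_sec) - 1L
  set.seed(params$seed)

  is_light <- phase_at(secs, config) == "light"
  x0 <- sample.int(geom$n_x, n, replace = TRUE)
  y0 <- sample.int(geom$n_y, n, replace = TRUE)
  walk <- walk_cohort_cpp(n_sec, geom$n_x, geom$n_y, is_light,
                          params$p_move_light, params$p_move_dark,
                          params$p_social, x0, y0)

  truth <- data.table::data.table(
    tag_id = rep(params$tags, each = n_sec),
    second = rep(secs, n),
    x = as.integer(walk$x), y = as.integer(walk$y))
  truth[, antenna_id := xy_to_antenna(x, y, geom)]
  truth[, observed := TRUE]
  data.table::setcolorder(truth, c("tag_id", "second", "antenna_id",
                                   "x", "y", "observed"))
  data.table::setkey(truth, tag_id, second)

  det <- truth[, .(tag_id, second, antenna_id, x, y)]
  # detection channel: dropout, then tag loss, then duplicates
  det <- det[stats::runif(nrow(det)) >= params$p_miss]
  if (!is.null(params$tag_loss)) {
    loss <- data.table::as.data.table(params$tag_loss)
    loss[, cutoff := config$start_sec + as.integer(from_sec)]
    det <- det[!loss, on = .(tag_id, second >= cutoff)]
  }
  det[, frac := stats::runif(.N) * 0.5]
  dup <- det[stats::runif(.N) < params$p_dup]
  if (nrow(dup)) {
    # spurious read at a uniformly chosen in-bounds neighbor, later within
    # the same second than the true read
    dup[, `:=`(
      x = pmin(pmax(x + sample(c(-1L, 0L, 1L), .N, replace = TRUE), 1L),
               geom$n_x),
      y = pmin(pmax(y + sample(c(-1L, 0L, 1L), .N, replace = TRUE), 1L),
               geom$n_y),
      frac = 0.5 + stats::runif(.N) * 0.5)]
    dup[, antenna_id := xy_to_antenna(x, y, geom)]
    det <- data.table::rbindlist(list(det, dup))
  }
  data.table::setorder(det, second, frac, tag_id)
  det[, line_no := seq_len(.N)]
  det[, timestamp := as.POSIXct(second + frac, origin = "1970-01-01",
                                tz = config$tz)]
  detections <- det[, .(line_no, timestamp, antenna_id, tag_id)]

  if (!is.null(log_path)) {
    base <- format(.sec_to_time(seq.int(config$start_sec, config$end_sec - 1L),
                                config), "%Y-%m-%d %H:%M:%S")
    lines <- sprintf("%s.%02d\t%d\t%s",
                     base[det$second - config$start_sec + 1L],
                     pmin(as.integer(floor(det$frac * 100)), 99L),
                     det$antenna_id, det$tag_id)
    con <- file(log_path, "w")
    writeLines(lines, con)
    close(con)
  }
  list(detections = detections, truth = truth, config = config,
       params = params, log_path = log_path)
}
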