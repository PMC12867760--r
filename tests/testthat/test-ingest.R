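test_that("raw log lines map to detections; malformed lines are rejected or abort", {
  path <- write_log_lines(c(
    "# logger header",
    "2023-01-10 08:00:00.41\t13\tTAG_A",
    "2023-01-10T08:00:01.99 14 TAG_A",        # ISO-T, space-delimited
    "",
    "2023-01-10 08:00:02.10\t97\tTAG_A",      # antenna out of range
    "garbage line"))
  det <- suppressMessages(parse_raw_log(path))
  expect_equal(nrow(det), 2L)
  expect_equal(attr(det, "n_rejected"), 2L)
  expect_equal(det$antenna_id, c(13L, 14L))
  expect_equal(det$tag_id, c("TAG_A", "TAG_A"))
  # fractional timestamp preserved before truncation
  expect_equal(as.numeric(det$timestamp[1]) %% 1, 0.41, tolerance = 1e-6)
  expect_error(parse_raw_log(path, strict = TRUE), "line 5")
  expect_error(parse_raw_log(file.path(tempdir(), "nope.txt")), "cannot read")
})

test_that("an empty log parses to an empty detection table", {
  path <- write_log_lines(character(0))
  det <- parse_raw_log(path)
  expect_equal(nrow(det), 0L)
  expect_equal(attr(det, "n_rejected"), 0L)
})

test_that("non-monotonic timestamps are stably re-sorted with a warning", {
  path <- write_log_lines(c(
    "2023-01-10 08:00:05\t2\tTAG_A",
    "2023-01-10 08:00:01\t3\tTAG_A"))
  expect_warning(det <- parse_raw_log(path), "non-monotonic")
  expect_equal(det$antenna_id, c(3L, 2L))
})

test_that("timestamp truncation floors fractional seconds and is idempotent", {
  det <- make_detections("A", c(0, 0, 1), c(1, 2, 3), frac = c(0.41, 0.99, 0))
  tr <- truncate_to_seconds(det)
  expect_equal(tr$second, as.integer(T0 + c(0, 0, 1)))
  expect_true(all(as.numeric(tr$timestamp) %% 1 == 0))
  expect_equal(truncate_to_seconds(tr)$second, tr$second)
})

test_that("first detection wins within each animal-second; other animals keep theirs", {
  det <- truncate_to_seconds(make_detections(
    c("A", "A", "B", "A"), c(100, 100, 100, 101), c(13, 14, 14, 15),
    frac = c(0.1, 0.6, 0.3, 0)))
  dd <- dedupe_first_wins(det)
  expect_equal(nrow(dd), 3L)
  expect_equal(dd[tag_id == "A" & second == T0 + 100, antenna_id], 13L)
  expect_equal(dd[tag_id == "B", antenna_id], 14L)
  # idempotent, and identity when there are no duplicates
  expect_identical(dedupe_first_wins(dd), dd)
})

test_that("forward fill carries the preceding position across gaps, no back-fill", {
  cfg <- default_config(hours = 1)
  det <- dedupe_first_wins(truncate_to_seconds(make_detections(
    c("A", "A"), c(100, 103), c(1, 2))))   # (1,1) then (2,1)
  traj <- forward_fill(det, cfg, fill_to = "last")
  expect_equal(nrow(traj), 4L)
  expect_equal(traj$x, c(1L, 1L, 1L, 2L))
  expect_equal(traj$observed, c(TRUE, FALSE, FALSE, TRUE))
  # filled rows repeat the last observed position exactly
  expect_true(all(traj[observed == FALSE, x] == 1L))
  expect_false(any(traj$second < T0 + 100))
})

test_that("fill horizon extends to session end and matches a scalar LOCF oracle", {
  cfg <- session_config(session_hours = 106 / 3600)  # session ends at sec 106
  det <- dedupe_first_wins(truncate_to_seconds(
    make_detections("A", 100, 37)))
  traj <- forward_fill(det, cfg, fill_to = "session")
  # oracle: carry the single observation over the remaining range by hand
  expect_equal(traj$second, as.integer(T0 + 100:105))
  expect_true(all(traj$antenna_id == 37L))
  expect_equal(traj$observed, c(TRUE, rep(FALSE, 5)))

  # independent last-observation-carried-forward oracle on a random series
  set.seed(21)
  obs_sec <- sort(sample(0:59, 20))
  ants <- sample(96, 20, replace = TRUE)
  det2 <- dedupe_first_wins(truncate_to_seconds(
    make_detections("B", obs_sec, ants)))
  cfg2 <- session_config(session_hours = 60 / 3600)
  traj2 <- forward_fill(det2, cfg2, fill_to = "session")
  locf <- sapply(min(obs_sec):59, function(s) ants[max(which(obs_sec <= s))])
  expect_equal(traj2$antenna_id, as.integer(locf))
})

test_that("row count per tag equals last - first + 1 over the observed span", {
  set.seed(4)
  det <- dedupe_first_wins(truncate_to_seconds(make_detections(
    rep(c("A", "B"), each = 30), c(sample(0:200, 30), sample(50:300, 30)),
    sample(96, 60, replace = TRUE))))
  traj <- forward_fill(det, default_config(), fill_to = "last")
  spans <- traj[, .(n = .N, span = max(second) - min(second) + 1L), by = tag_id]
  expect_equal(spans$n, spans$span)
})

test_that("forward fill is idempotent on its own output", {
  cfg <- default_config(hours = 1)
  det <- dedupe_first_wins(truncate_to_seconds(make_detections(
    c("A", "A", "A"), c(0, 5, 9), c(1, 50, 96))))
  traj <- forward_fill(det, cfg, fill_to = "last")
  as_det <- traj[, .(tag_id, second, antenna_id, line_no = seq_len(.N),
                     timestamp = as.POSIXct(second, origin = "1970-01-01",
                                            tz = "UTC"))]
  again <- forward_fill(dedupe_first_wins(truncate_to_seconds(as_det)),
                        cfg, fill_to = "last")
  expect_equal(again[, .(tag_id, second, antenna_id, x, y)],
               traj[, .(tag_id, second, antenna_id, x, y)])
})

test_that("max_fill_gap caps bridging and drop_tags excludes animals", {
  cfg <- default_config(hours = 1)
  det <- dedupe_first_wins(truncate_to_seconds(make_detections(
    c("A", "A", "B"), c(0, 100, 0), c(1, 2, 3))))
  traj <- forward_fill(det, cfg, fill_to = "last", max_fill_gap = 10)
  expect_equal(nrow(traj[tag_id == "A"]), 12L)  # 0-10 filled, then 100
  expect_false(any(traj$second %in% (T0 + 11:99) & traj$tag_id == "A"))
  dropped <- forward_fill(det, cfg, fill_to = "last", drop_tags = "B")
  expect_false("B" %in% dropped$tag_id)
})

test_that("expected tags never detected trigger a warning and are omitted", {
  cfg <- session_config(session_hours = 1, expected_tags = c("A", "GHOST"))
  det <- dedupe_first_wins(truncate_to_seconds(make_detections("A", 0:2, 1:3)))
  expect_warning(traj <- forward_fill(det, cfg, fill_to = "last"), "GHOST")
  expect_equal(unique(traj$tag_id), "A")
})

test_that("processed-CSV round trip reproduces the trajectory exactly", {
  set.seed(9)
  det <- dedupe_first_wins(truncate_to_seconds(make_detections(
    rep(c("A", "B"), 15), sample(0:100, 30), sample(96, 30, replace = TRUE))))
  traj <- forward_fill(det, default_config(), fill_to = "last")
  for (fmt in c("epoch", "iso")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_trajectory(traj, path, time_format = fmt)
    back <- read_trajectory(path)
    expect_equal(as.data.frame(back), as.data.frame(traj), ignore_attr = TRUE)
  }
})

test_that("interleaving lines across tags does not change the trajectory", {
  set.seed(13)
  detA <- make_detections(rep("A", 40), sort(sample(0:120, 40)),
                          sample(96, 40, replace = TRUE),
                          frac = runif(40, 0, 0.9))
  detB <- make_detections(rep("B", 40), sort(sample(0:120, 40)),
                          sample(96, 40, replace = TRUE),
                          frac = runif(40, 0, 0.9))
  both <- rbind(detA, detB)
  # shuffle rows, preserving each tag's internal order via a stable sort key
  perm <- order(rep(seq_len(40), 2) + runif(80, 0, 0.4))
  shuffled <- both[perm]
  shuffled[, line_no := .I]
  both[, line_no := .I]
  cfg <- default_config()
  t1 <- forward_fill(dedupe_first_wins(truncate_to_seconds(both)),
                     cfg, fill_to = "last")
  t2 <- forward_fill(dedupe_first_wins(truncate_to_seconds(shuffled)),
                     cfg, fill_to = "last")
  expect_equal(as.data.frame(t1), as.data.frame(t2), ignore_attr = TRUE)
})
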