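test_that("pair enumeration yields one series per unordered pair", {
  set.seed(37)
  traj <- data.table::rbindlist(lapply(sprintf("M%d", 1:4), function(tg)
    make_traj(tg, 0:9, sample(12, 10, TRUE), sample(8, 10, TRUE))))
  ps <- pair_series(traj)
  expect_equal(nrow(unique(ps[, .(tag_i, tag_j)])), 6L)  # C(4,2)
  expect_true(all(ps$tag_i < ps$tag_j))
  expect_error(pair_series(make_traj("A", 0:9, 1L, 1L)), "at least 2")
})

test_that("two animals sharing every cell give an all-Same series and CCR 100", {
  traj <- rbind(make_traj("A", 0:99, rep(c(1L, 5L), 50), rep(c(1L, 4L), 50)),
                make_traj("B", 0:99, rep(c(1L, 5L), 50), rep(c(1L, 4L), 50)))
  ps <- pair_series(traj)
  expect_true(all(ps$category == "Same"))
  expect_true(all(ps$L_cm == 0))
  win <- list(start_sec = T0, end_sec = T0 + 100L, T = 100L)
  expect_equal(ccr(ps, win)$ccr_pct, 100)
  # constant offset (3,0) is always Away: CCR 0
  traj2 <- rbind(make_traj("A", 0:99, 1L, 1L), make_traj("B", 0:99, 4L, 1L))
  expect_equal(ccr(pair_series(traj2), win)$ccr_pct, 0)
})

test_that("category proportions come from direct second counting", {
  # 1800 s Same + 5400 s Close in a 7200-s window
  xsB <- c(rep(1L, 1800), rep(2L, 5400))
  traj <- rbind(make_traj("A", 0:7199, 1L, 1L),
                make_traj("B", 0:7199, xsB, 1L))
  w <- make_windows(default_config(hours = 2), 2)
  st <- pair_window_stats(traj, w)
  expect_equal(st$n_same, 1800L)
  expect_equal(st$n_close, 5400L)
  expect_equal(unlist(st[, .(p_same, p_close, p_intermediate, p_away)]),
               c(p_same = 0.25, p_close = 0.75, p_intermediate = 0, p_away = 0))
  expect_equal(st$ccr_pct, 100)

  # 1800 of 7200 s at Chebyshev <= 1: CCR 25%, against a brute-force count
  xsB2 <- c(rep(2L, 1800), rep(8L, 5400))
  traj2 <- rbind(make_traj("A", 0:7199, 1L, 1L),
                 make_traj("B", 0:7199, xsB2, 1L))
  st2 <- pair_window_stats(traj2, w)
  brute <- sum(abs(xsB2 - 1L) <= 1L)  # Chebyshev distance, y offset is 0
  expect_equal(st2$ccr_pct, 100 * brute / 7200)
  expect_equal(st2$ccr_pct, 25)

  # all-Away window
  xsB3 <- rep(12L, 7200)
  st3 <- pair_window_stats(rbind(make_traj("A", 0:7199, 1L, 1L),
                                 make_traj("B", 0:7199, xsB3, 1L)), w)
  expect_equal(unlist(st3[, .(p_same, p_close, p_intermediate, p_away)]),
               c(p_same = 0, p_close = 0, p_intermediate = 0, p_away = 1))
})

test_that("proportions sum to 1 and CCR equals 100*(p_same + p_close) on simulated data", {
  sim <- simulate_cohort(sim_params(n_mice = 5, hours = 4, seed = 41))
  traj <- preprocess(sim$detections, sim$config)
  st <- pair_window_stats(traj, make_windows(sim$config, 2))
  covered <- st[covered > 0]
  expect_equal(covered[, p_same + p_close + p_intermediate + p_away],
               rep(1, nrow(covered)), tolerance = 1e-9)
  expect_equal(covered$ccr_pct, 100 * (covered$p_same + covered$p_close))
})

test_that("pair series matches positions recomputed by direct join", {
  sim <- simulate_cohort(sim_params(n_mice = 3, hours = 0.25, seed = 43,
                                    p_miss = 0, p_dup = 0))
  ps <- pair_series(sim$truth)
  # independent oracle: merge positions per pair and compute L directly
  tr <- as.data.frame(sim$truth)
  for (pr in list(c("TAG_01", "TAG_02"), c("TAG_02", "TAG_03"))) {
    a <- tr[tr$tag_id == pr[1], ]; b <- tr[tr$tag_id == pr[2], ]
    mrg <- merge(a, b, by = "second")
    L <- 5 * sqrt((mrg$x.x - mrg$x.y)^2 + (mrg$y.x - mrg$y.y)^2)
    got <- ps[tag_i == pr[1] & tag_j == pr[2]][order(second)]
    expect_equal(got$L_cm, L[order(mrg$second)])
  }
})

test_that("group proportions pool seconds across pairs (convex combination)", {
  # pair coverage differs: C present only half the window
  traj <- rbind(make_traj("A", 0:99, 1L, 1L),
                make_traj("B", 0:99, 2L, 1L),
                make_traj("C", 0:49, 12L, 8L))
  w <- data.table::data.table(window_id = 1L, start_sec = T0,
                              end_sec = T0 + 100L, T = 100L,
                              phase = "light", label = "w1",
                              start_time = as.POSIXct(T0, origin = "1970-01-01"))
  st <- pair_window_stats(traj, w)
  g <- category_proportions(st, by = "group")
  # pooled = count-weighted mean of pair proportions
  manual <- st[, sum(n_away)] / st[, sum(covered)]
  expect_equal(g$p_away, manual)
  expect_gte(g$p_away, st[, min(p_away)])
  expect_lte(g$p_away, st[, max(p_away)])
  # per-pair proportions pass through unchanged
  pp <- category_proportions(st, by = "pair")
  expect_equal(pp$p_away, st$p_away)
})

test_that("CCR matrix is symmetric with NA diagonal and missing pairs NA", {
  tags <- sprintf("M%02d", 1:8)
  set.seed(47)
  traj <- data.table::rbindlist(lapply(tags, function(tg)
    make_traj(tg, 0:199, sample(12, 200, TRUE), sample(8, 200, TRUE))))
  w <- make_windows(default_config(hours = 200 / 3600), 200 / 3600)
  st <- pair_window_stats(traj, w)
  m <- ccr_matrix(st, window_id = 1L)
  expect_equal(dim(m), c(8L, 8L))
  expect_identical(m, t(m))
  expect_true(all(is.na(diag(m))))
  expect_equal(sum(!is.na(m[upper.tri(m)])), 28L)  # C(8,2)

  # a pair with no shared seconds is NA
  traj2 <- rbind(make_traj("A", 0:9, 1L, 1L), make_traj("B", 20:29, 1L, 1L),
                 make_traj("C", 0:29, 2L, 2L))
  w2 <- make_windows(default_config(hours = 30 / 3600), 30 / 3600)
  m2 <- ccr_matrix(pair_window_stats(traj2, w2), 1L)
  expect_true(is.na(m2["A", "B"]))
  expect_false(is.na(m2["A", "C"]))
})

test_that("per-animal sociability is the partner mean and handles edge cases", {
  m <- matrix(NA_real_, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  m["a", "b"] <- m["b", "a"] <- 10
  m["a", "c"] <- m["c", "a"] <- 20
  m["a", "d"] <- m["d", "a"] <- 30
  expect_equal(unname(per_animal_ccr(m)["a"]), 20)  # mean of {10, 20, 30}
  m2 <- matrix(NA_real_, 2, 2, dimnames = rep(list(c("a", "b")), 2))
  expect_true(is.na(per_animal_ccr(m2)["a"]))
  m2["a", "b"] <- m2["b", "a"] <- 37
  expect_equal(unname(per_animal_ccr(m2)), c(37, 37))  # two-animal group
})

test_that("CCR is invariant under relabeling of animals", {
  sim <- simulate_cohort(sim_params(n_mice = 4, hours = 0.5, seed = 53))
  traj <- preprocess(sim$detections, sim$config)
  w <- make_windows(sim$config, 0.5)
  st1 <- pair_window_stats(traj, w)
  relab <- data.table::copy(traj)
  map <- c(TAG_01 = "Z", TAG_02 = "Y", TAG_03 = "X", TAG_04 = "W")
  relab[, tag_id := unname(map[tag_id])]
  st2 <- pair_window_stats(relab, w)
  expect_equal(sort(st1$ccr_pct), sort(st2$ccr_pct))
  expect_true(all(st1$ccr_pct >= 0 & st1$ccr_pct <= 100, na.rm = TRUE))
})

test_that("partial coverage divides by covered seconds, zero coverage is NA", {
  traj <- rbind(make_traj("A", 0:99, 1L, 1L),
                make_traj("B", 0:49, 1L, 1L))     # B leaves halfway
  w <- data.table::data.table(window_id = 1L, start_sec = T0,
                              end_sec = T0 + 100L, T = 100L, phase = "light",
                              label = "w1",
                              start_time = as.POSIXct(T0, origin = "1970-01-01"))
  st <- pair_window_stats(traj, w)
  expect_equal(st$coverage, 0.5)
  expect_equal(st$ccr_pct, 100)  # all covered seconds were Same
  w2 <- data.table::copy(w)[, `:=`(start_sec = T0 + 200L, end_sec = T0 + 300L,
                                   window_id = 1L)]
  st2 <- pair_window_stats(traj, w2)
  expect_true(is.na(st2$ccr_pct))
  expect_equal(st2$coverage, 0)
})
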