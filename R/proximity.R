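# Position matrices (seconds x animals) for fast pairwise work.
# Returns list(X, Y, secs, tags); NA where an animal has no trajectory row.
.position_matrices <- function(traj, tag_order = NULL) {
  dt <- data.table::as.data.table(traj)
  tags <- tag_order %||% sort(unique(dt$tag_id))
  stopifnot(all(dt$tag_id %in% tags))
  smin <- min(dt$second); smax <- max(dt$second)
  n <- smax - smin + 1L
  X <- matrix(NA_integer_, n, length(tags))
  Y <- matrix(NA_integer_, n, length(tags))
  i <- cbind(dt$second - smin + 1L, match(dt$tag_id, tags))
  X[i] <- dt$x
  Y[i] <- dt$y
  list(X = X, Y = Y, secs = seq.int(smin, smax), tags = tags)
}

#' Per-second proximity series for all animal pairs
#'
#' For every unordered pair (i < j in `tag_order`), the interindividual
#' Euclidean distance `L` and proximity category at each second on which
#' both animals have trajectory rows. This is the explicit long form
#' (N*(N-1)/2 pairs x seconds); for long recordings of large groups prefer
#' [pair_window_stats()], which aggregates without materializing it.
#'
#' @param traj A trajectory table from [forward_fill()].
#' @param geom A [grid_geometry()].
#' @param tag_order Optional character vector fixing the animal ordering
#'   used to normalize pairs; defaults to sorted tag IDs.
#' @return A `data.table` with columns `tag_i`, `tag_j`, `second`, `L_cm`
#'   and `category` (factor, see [proximity_categories()]).
#' @export
pair_series <- function(traj, geom = grid_geometry(), tag_order = NULL) {
  pm <- .position_matrices(traj, tag_order)
  nt <- length(pm$tags)
  if (nt < 2L) stop("pair analysis requires at least 2 animals")
  out <- vector("list", nt * (nt - 1L) / 2L)
  k <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in seq.int(i + 1L, nt)) {
      d2 <- (pm$X[, i] - pm$X[, j])^2 + (pm$Y[, i] - pm$Y[, j])^2
      ok <- which(!is.na(d2))
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        tag_i = pm$tags[i], tag_j = pm$tags[j],
        second = pm$secs[ok],
        L_cm = geom$pitch_cm * sqrt(d2[ok]),
        category = factor(proximity_categories()[.classify_d2(d2[ok])],
                          levels = proximity_categories()))
    }
  }
  data.table::rbindlist(out)
}

#' Windowed proximity-category counts for all pairs
#'
#' The workhorse behind category proportions, CCR and the network layer:
#' for every unordered pair and every analysis window, the number of
#' covered seconds (both animals present) spent in each proximity
#' category, plus the derived proportions and CCR. Computed pair by pair
#' on position matrices, so a 72-h, 16-animal session stays fast and
#' memory-light.
#'
#' The CCR (close contact ratio) of a pair over a window is the percentage
#' of time spent at `Same` or `Close` proximity, i.e. at Euclidean
#' distance `L <= 5*sqrt(2)` cm (Chebyshev distance <= 1 tile):
#' `CCR = 100/T * sum_t delta(L_t <= 5*sqrt(2))`. The divisor is the
#' window length `T` for fully covered windows and the covered-second
#' count otherwise (coverage is always reported).
#'
#' @inheritParams pair_series
#' @param windows A window table from [make_windows()] or
#'   [phase_windows()].
#' @return A `data.table` with one row per pair per window: `tag_i`,
#'   `tag_j`, `window_id`, `label`, `phase`, `T`, counts `n_same`,
#'   `n_close`, `n_intermediate`, `n_away`, `covered`, `coverage`,
#'   proportions `p_same` ... `p_away` (NA when coverage is 0) and
#'   `ccr_pct` in `[0, 100]`.
#' @export
pair_window_stats <- function(traj, windows, geom = grid_geometry(),
                              tag_order = NULL) {
  pm <- .position_matrices(traj, tag_order)
  nt <- length(pm$tags)
  if (nt < 2L) stop("pair analysis requires at least 2 animals")
  win <- data.table::as.data.table(windows)
  nw <- nrow(win)
  widx <- findInterval(pm$secs, win$start_sec)
  widx[widx < 1L | pm$secs >= win$end_sec[pmax(widx, 1L)]] <- NA_integer_

  npair <- nt * (nt - 1L) / 2L
  counts <- matrix(0L, npair, 4L * nw)
  ti <- character(npair); tj <- character(npair)
  k <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in seq.int(i + 1L, nt)) {
      k <- k + 1L
      ti[k] <- pm$tags[i]; tj[k] <- pm$tags[j]
      d2 <- (pm$X[, i] - pm$X[, j])^2 + (pm$Y[, i] - pm$Y[, j])^2
      code <- .classify_d2(d2) + 4L * (widx - 1L)
      code <- code[!is.na(d2) & !is.na(widx)]
      counts[k, ] <- tabulate(code, nbins = 4L * nw)
    }
  }
  out <- data.table::data.table(
    tag_i = rep(ti, each = nw), tag_j = rep(tj, each = nw),
    window_id = rep(win$window_id, npair),
    n_same = as.integer(t(counts[, seq.int(1L, 4L * nw, 4L), drop = FALSE])),
    n_close = as.integer(t(counts[, seq.int(2L, 4L * nw, 4L), drop = FALSE])),
    n_intermediate = as.integer(t(counts[, seq.int(3L, 4L * nw, 4L), drop = FALSE])),
    n_away = as.integer(t(counts[, seq.int(4L, 4L * nw, 4L), drop = FALSE])))
  out <- win[, .(window_id, label, phase, T)][out, on = "window_id"]
  out[, covered := n_same + n_close + n_intermediate + n_away]
  out[, coverage := covered / T]
  out[, `:=`(p_same = ifelse(covered > 0, n_same / covered, NA_real_),
             p_close = ifelse(covered > 0, n_close / covered, NA_real_),
             p_intermediate = ifelse(covered > 0, n_intermediate / covered, NA_real_),
             p_away = ifelse(covered > 0, n_away / covered, NA_real_))]
  out[, ccr_pct := ifelse(covered > 0,
                          100 * (n_same + n_close) / covered, NA_real_)]
  data.table::setcolorder(out, c("tag_i", "tag_j", "window_id"))
  data.table::setorder(out, tag_i, tag_j, window_id)
  out[]
}

#' Proximity-category proportions per window
#'
#' Per-pair proportions are taken directly from [pair_window_stats()];
#' group-level proportions pool category-seconds across all pairs in each
#' window (pooled counts, not a mean of per-pair ratios — the two differ
#' only under unequal coverage). Pooled counts are also the input to the
#' light/dark chi-square test.
#'
#' @param stats A table from [pair_window_stats()].
#' @param by `"pair"` (default) or `"group"`.
#' @return For `by = "pair"`, the stats table's proportion columns; for
#'   `by = "group"`, one row per window with pooled counts and
#'   proportions.
#' @export
category_proportions <- function(stats, by = c("pair", "group")) {
  by <- match.arg(by)
  st <- data.table::as.data.table(stats)
  if (by == "pair") {
    return(st[, .(tag_i, tag_j, window_id, label, phase, coverage,
                  p_same, p_close, p_intermediate, p_away)])
  }
  g <- st[, .(n_same = sum(n_same), n_close = sum(n_close),
              n_intermediate = sum(n_intermediate), n_away = sum(n_away)),
          by = .(window_id, label, phase)]
  g[, covered := n_same + n_close + n_intermediate + n_away]
  g[, `:=`(p_same = ifelse(covered > 0, n_same / covered, NA_real_),
           p_close = ifelse(covered > 0, n_close / covered, NA_real_),
           p_intermediate = ifelse(covered > 0, n_intermediate / covered, NA_real_),
           p_away = ifelse(covered > 0, n_away / covered, NA_real_))]
  g[]
}

#' CCR of one pair series over one window
#'
#' Direct form of the close contact ratio for a single
#' [pair_series()] pair: the percentage of covered window seconds at
#' distance `L <= 5*sqrt(2)` cm. See [pair_window_stats()] for the
#' windowed all-pairs version.
#'
#' @param series A [pair_series()] table restricted to one pair.
#' @param window One row of a window table (`start_sec`, `end_sec`, `T`).
#' @param geom A [grid_geometry()].
#' @return A list with `ccr_pct` (NA when no covered seconds) and
#'   `coverage`.
#' @export
ccr <- function(series, window, geom = grid_geometry()) {
  s <- data.table::as.data.table(series)
  stopifnot(nrow(unique(s[, .(tag_i, tag_j)])) <= 1L)
  s <- s[second >= window$start_sec & second < window$end_sec]
  covered <- nrow(s)
  if (covered == 0L) return(list(ccr_pct = NA_real_, coverage = 0))
  close <- sum(s$L_cm <= geom$pitch_cm * sqrt(2) + 1e-9)
  list(ccr_pct = 100 * close / covered, coverage = covered / window$T)
}

#' Symmetric animals-by-animals CCR matrix for one window
#'
#' @param stats A table from [pair_window_stats()].
#' @param window_id Which window to extract.
#' @param tags Optional tag ordering for rows/columns; defaults to all
#'   tags in `stats`, sorted.
#' @return A symmetric numeric matrix of `ccr_pct` with `NA` diagonal;
#'   pairs with no coverage in the window are `NA`.
#' @export
ccr_matrix <- function(stats, window_id, tags = NULL) {
  st <- data.table::as.data.table(stats)
  st <- st[st$window_id == window_id]
  tags <- tags %||% sort(unique(c(st$tag_i, st$tag_j)))
  m <- matrix(NA_real_, length(tags), length(tags),
              dimnames = list(tags, tags))
  i <- match(st$tag_i, tags); j <- match(st$tag_j, tags)
  m[cbind(i, j)] <- st$ccr_pct
  m[cbind(j, i)] <- st$ccr_pct
  m
}

#' Per-animal sociability score
#'
#' An animal's sociability in a window is the mean of its pairwise CCR
#' values over all partners (missing pairs ignored); the per-animal
#' quantity shown in CCR heatmaps and used as the SL/SD phenotype
#' features.
#'
#' @param mat A CCR matrix from [ccr_matrix()].
#' @return Named numeric vector, one score per animal (`NA` when all of an
#'   animal's pairs are missing).
#' @export
per_animal_ccr <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  res <- rowMeans(mat, na.rm = TRUE)
  res[rowSums(!is.na(mat)) == 0L] <- NA_real_
  res
}

#' Per-animal CCR table over all windows
#'
#' @param stats A table from [pair_window_stats()].
#' @return A `data.table` with `tag_id`, `window_id`, `label`, `phase`,
#'   `ccr_pct` (mean over partners).
#' @export
per_animal_ccr_table <- function(stats) {
  st <- data.table::as.data.table(stats)
  long <- data.table::rbindlist(list(
    st[, .(tag_id = tag_i, window_id, label, phase, ccr_pct)],
    st[, .(tag_id = tag_j, window_id, label, phase, ccr_pct)]))
  long[, .(ccr_pct = if (all(is.na(ccr_pct))) NA_real_
           else mean(ccr_pct, na.rm = TRUE)),
       by = .(tag_id, window_id, label, phase)]
}
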