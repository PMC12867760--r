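#' Per-animal behavioral feature vector (AL, AD, SL, SD)
#'
#' The four phenotyping features: normalized locomotor activity averaged
#' over the light (`AL`) and dark (`AD`) periods, and sociability —
#' per-animal CCR — over the pooled light (`SL`) and dark (`SD`) seconds.
#' Activity values at each time point (bin time-of-day) are first averaged
#' across recording days, then averaged over the time points of each
#' phase; CCR is pooled at the count level across each phase's windows
#' before the per-animal partner mean is taken.
#'
#' @param activity A normalized activity table from [normalize_activity()]
#'   (bins from [make_windows()], typically 2-h).
#' @param stats A [pair_window_stats()] table whose windows carry
#'   light/dark phase labels (e.g. over [phase_windows()]).
#' @param config The [session_config()] (for the lighting schedule).
#' @return A `data.table` with one row per animal: `tag_id`, `AL`, `AD`,
#'   `SL`, `SD`, all in `[0, 100]`. Animals missing an entire phase get
#'   `NA` for that feature, with a warning.
#' @export
extract_features <- function(activity, stats, config) {
  act <- data.table::as.data.table(activity)
  stopifnot("relative_activity" %in% names(act))
  act <- act[phase %in% c("light", "dark") & coverage > 0]
  act[, tod := .tod_of(start_sec, config)]
  day_avg <- act[, .(v = mean(relative_activity)),
                 by = .(tag_id, phase, tod)]
  feat_a <- day_avg[, .(value = mean(v)), by = .(tag_id, phase)]
  wide_a <- data.table::dcast(feat_a, tag_id ~ phase, value.var = "value")
  data.table::setnames(wide_a, c("light", "dark"), c("AL", "AD"),
                       skip_absent = TRUE)

  st <- data.table::as.data.table(stats)
  pool <- st[phase %in% c("light", "dark"),
             .(n_cc = sum(n_same + n_close), cov = sum(covered)),
             by = .(tag_i, tag_j, phase)]
  pool[, ccr_pct := ifelse(cov > 0, 100 * n_cc / cov, NA_real_)]
  long <- data.table::rbindlist(list(
    pool[, .(tag_id = tag_i, phase, ccr_pct)],
    pool[, .(tag_id = tag_j, phase, ccr_pct)]))
  feat_s <- long[, .(value = if (all(is.na(ccr_pct))) NA_real_
                     else mean(ccr_pct, na.rm = TRUE)),
                 by = .(tag_id, phase)]
  wide_s <- data.table::dcast(feat_s, tag_id ~ phase, value.var = "value")
  data.table::setnames(wide_s, c("light", "dark"), c("SL", "SD"),
                       skip_absent = TRUE)

  feats <- merge(wide_a, wide_s, by = "tag_id", all = TRUE)
  for (col in c("AL", "AD", "SL", "SD")) {
    if (!col %in% names(feats)) feats[, (col) := NA_real_]
  }
  feats <- feats[, .(tag_id, AL, AD, SL, SD)]
  incomplete <- feats[!stats::complete.cases(feats), tag_id]
  if (length(incomplete)) {
    warning("animal(s) missing a full phase, feature(s) NA: ",
            paste(incomplete, collapse = ", "))
  }
  feats[]
}

#' PCA embedding of behavioral features
#'
#' Principal components of the per-animal feature matrix. Features are
#' centered and, by default, z-scored (AL/AD and SL/SD share a 0-100 scale,
#' so scaling mainly rebalances loading magnitudes). Component signs are
#' fixed deterministically: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param features A feature table from [extract_features()] (or any table
#'   with `tag_id` plus numeric feature columns). Animals with missing
#'   features are excluded with a warning.
#' @param n_components Number of components to keep. Default 2.
#' @param scale Z-score features before PCA? Default `TRUE`.
#' @param feature_cols Feature column names. Default
#'   `c("AL", "AD", "SL", "SD")`.
#' @return A list of class `pca_embedding`: `scores` (animals x
#'   components, zero column means), `loadings` (features x components,
#'   orthonormal), `sdev`, `var_explained` (fractions over all feature
#'   dimensions), `center`, `scale`, `tags`.
#' @export
pca_embed <- function(features, n_components = 2L, scale = TRUE,
                      feature_cols = c("AL", "AD", "SL", "SD")) {
  ft <- data.table::as.data.table(features)
  stopifnot(all(feature_cols %in% names(ft)))
  X <- as.matrix(ft[, feature_cols, with = FALSE])
  rownames(X) <- ft$tag_id
  ok <- stats::complete.cases(X)
  if (!all(ok)) {
    warning("excluding animal(s) with missing features from PCA: ",
            paste(rownames(X)[!ok], collapse = ", "))
    X <- X[ok, , drop = FALSE]
  }
  if (nrow(X) < 3L) stop("PCA requires at least 3 animals with complete features")
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance feature(s): ",
         paste(feature_cols[v == 0], collapse = ", "))
  }
  n_components <- min(as.integer(n_components), ncol(X))
  pr <- stats::prcomp(X, center = TRUE, scale. = scale)
  for (k in seq_len(ncol(pr$rotation))) {
    lk <- pr$rotation[, k]
    if (lk[which.max(abs(lk))] < 0) {
      pr$rotation[, k] <- -lk
      pr$x[, k] <- -pr$x[, k]
    }
  }
  keep <- seq_len(n_components)
  structure(list(
    scores = pr$x[, keep, drop = FALSE],
    loadings = pr$rotation[, keep, drop = FALSE],
    sdev = pr$sdev,
    var_explained = pr$sdev^2 / sum(pr$sdev^2),
    center = pr$center,
    scale = if (isFALSE(pr$scale)) NULL else pr$scale,
    tags = rownames(X)), class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf("<pca_embedding> %d animals, %d components; variance explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(ncol(x$scores))]),
                    collapse = ", ")))
  invisible(x)
}

#' Cluster-count selection by silhouette, with the inertia (elbow) curve
#'
#' Runs k-means (multiple restarts, fixed seed) on the PCA scores for each
#' candidate `k`, recording total within-cluster inertia (the elbow curve)
#' and mean silhouette width. The chosen `k` maximizes mean silhouette —
#' a deterministic automation of the usual elbow-plus-silhouette
#' inspection; the inertia curve is returned for manual elbow reading.
#'
#' @inheritParams pca_embed
#' @param k_range Candidate cluster counts, clipped to `[2, n - 1]`.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of random restarts per `k`. Default 50.
#' @param n_components PCA components to cluster on. Default 2.
#' @return A list of class `clustering_report`: chosen `k`, `k_range`,
#'   `inertia` and `silhouette` (named by k), `labels` (named integer
#'   vector in `1..k`), plus the `pca_embedding` used (`embedding`).
#' @export
select_k <- function(features, k_range = 2:6, seed = 1L, nstart = 50L,
                     n_components = 2L, scale = TRUE,
                     feature_cols = c("AL", "AD", "SL", "SD")) {
  emb <- pca_embed(features, n_components = n_components, scale = scale,
                   feature_cols = feature_cols)
  sc <- emb$scores
  n <- nrow(sc)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) stop("no admissible k in k_range for n = ", n, " animals")
  d <- stats::dist(sc)
  if (all(d == 0)) stop("degenerate input: all points identical, clustering undefined")
  inertia <- silh <- stats::setNames(numeric(length(k_range)),
                                     as.character(k_range))
  labels_by_k <- vector("list", length(k_range))
  set.seed(seed)
  for (i in seq_along(k_range)) {
    km <- stats::kmeans(sc, centers = k_range[i], nstart = nstart,
                        iter.max = 100L)
    inertia[i] <- km$tot.withinss
    silh[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    labels_by_k[[i]] <- stats::setNames(km$cluster, emb$tags)
  }
  best <- which.max(silh)
  structure(list(k = k_range[best], k_range = k_range,
                 inertia = inertia, silhouette = silh,
                 labels = labels_by_k[[best]],
                 labels_by_k = stats::setNames(labels_by_k, as.character(k_range)),
                 embedding = emb, seed = seed),
            class = "clustering_report")
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf("<clustering_report> chosen k = %d (max mean silhouette %.3f)\n",
              x$k, max(x$silhouette)))
  cat("  k:          ", paste(x$k_range, collapse = "  "), "\n")
  cat("  silhouette: ", paste(sprintf("%.3f", x$silhouette), collapse = "  "), "\n")
  cat("  inertia:    ", paste(sprintf("%.2f", x$inertia), collapse = "  "), "\n")
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean;
#' dimensionless, scale-invariant for positive rescaling. Used to compare
#' behavioral variability (travel distance, CCR) across groups.
#'
#' @param values Numeric vector of per-animal (or per-pair) measurements.
#' @return A single CV value; `NA` with a warning when the mean is zero.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) {
    warning("zero mean: coefficient of variation undefined")
    return(NA_real_)
  }
  stats::sd(values) / m
}

#' Chi-square test on proximity-category count tables
#'
#' Pearson chi-square on a contingency table of pooled category-seconds —
#' rows are conditions (light vs dark periods, or group sizes), columns
#' the proximity categories (Same, Close, Intermediate, Away; df = 3 for
#' the 2 x 4 light/dark layout). Any zero row or column margin is an
#' error.
#'
#' @param counts Numeric matrix of counts (conditions x categories).
#' @return A list with `statistic`, `df`, `p_value` and the `expected`
#'   count matrix.
#' @export
chi_square_light_dark <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), nrow(counts) >= 2L, ncol(counts) >= 2L,
            all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Step-down Sidak adjustment of a family of p-values: sort ascending,
#' set `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforce monotone
#' non-decrease along the sorted order, cap at 1 and return in input
#' order. Applied to per-comparison p-values (e.g. from a two-way ANOVA
#' run in standard software).
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
holm_sidak_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax(1 - (1 - p[o])^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}
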