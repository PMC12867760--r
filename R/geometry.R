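#' Floor-plate grid geometry
#'
#' Describes the antenna board: a rectangular grid of square antenna tiles.
#' The default matches the commercial 96-tile board: 12 columns by 8 rows of
#' 5 cm x 5 cm tiles, antenna IDs 1--96.
#'
#' @param n_x Number of grid columns (antennas per row). Default 12.
#' @param n_y Number of grid rows. Default 8.
#' @param pitch_cm Tile edge length in cm (grid spacing). Default 5.
#' @return An object of class `grid_geometry` with fields `n_x`, `n_y`,
#'   `pitch_cm` and `n_antennas = n_x * n_y`.
#' @examples
#' geom <- grid_geometry()
#' geom$n_antennas  # 96
#' @export
grid_geometry <- function(n_x = 12L, n_y = 8L, pitch_cm = 5) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  stopifnot(n_x >= 1L, n_y >= 1L, is.numeric(pitch_cm), pitch_cm > 0)
  structure(
    list(n_x = n_x, n_y = n_y, pitch_cm = as.numeric(pitch_cm),
         n_antennas = n_x * n_y),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d tiles (%.3g cm pitch), antenna IDs 1-%d\n",
              x$n_x, x$n_y, x$pitch_cm, x$n_antennas))
  invisible(x)
}

#' Convert antenna IDs to grid coordinates
#'
#' Antennas are numbered row-major with the column index varying fastest:
#' antenna 1 is at (x = 1, y = 1), antenna `n_x` at (n_x, 1), antenna
#' `n_x + 1` at (1, 2), and so on. This convention is isolated here and in
#' [xy_to_antenna()] so an alternative board numbering is a one-line change.
#'
#' @param antenna_id Integer vector of antenna IDs in `[1, n_antennas]`.
#' @param geom A [grid_geometry()].
#' @return A data.frame with integer columns `x` (column, 1-based) and `y`
#'   (row, 1-based), one row per input ID.
#' @examples
#' antenna_to_xy(c(1, 13, 96), grid_geometry())
#' @export
antenna_to_xy <- function(antenna_id, geom = grid_geometry()) {
  id <- as.integer(antenna_id)
  bad <- is.na(id) | id < 1L | id > geom$n_antennas
  if (any(bad)) {
    stop(sprintf("antenna_id out of range: valid IDs are 1-%d (got %s)",
                 geom$n_antennas,
                 paste(utils::head(antenna_id[bad], 3L), collapse = ", ")))
  }
  data.frame(x = (id - 1L) %% geom$n_x + 1L,
             y = (id - 1L) %/% geom$n_x + 1L)
}

#' Convert grid coordinates to antenna IDs
#'
#' Inverse of [antenna_to_xy()] under the row-major numbering convention.
#'
#' @param x,y Integer vectors of column and row indices (1-based).
#' @inheritParams antenna_to_xy
#' @return Integer vector of antenna IDs.
#' @export
xy_to_antenna <- function(x, y, geom = grid_geometry()) {
  x <- as.integer(x); y <- as.integer(y)
  bad <- is.na(x) | is.na(y) | x < 1L | x > geom$n_x | y < 1L | y > geom$n_y
  if (any(bad)) {
    stop(sprintf("coordinates out of bounds: x in [1,%d], y in [1,%d]",
                 geom$n_x, geom$n_y))
  }
  (y - 1L) * geom$n_x + x
}

#' Physical distance between two grid positions
#'
#' Euclidean distance in cm between tile centers:
#' `pitch_cm * sqrt((ax-bx)^2 + (ay-by)^2)`.
#'
#' @param ax,ay,bx,by Integer vectors of grid coordinates (recycled).
#' @inheritParams antenna_to_xy
#' @return Numeric vector of distances in cm.
#' @examples
#' pair_distance_cm(1, 1, 2, 2)  # 5 * sqrt(2)
#' pair_distance_cm(1, 1, 4, 5)  # 25 (3-4-5 triangle)
#' @export
pair_distance_cm <- function(ax, ay, bx, by, geom = grid_geometry()) {
  geom$pitch_cm * sqrt((as.numeric(ax) - bx)^2 + (as.numeric(ay) - by)^2)
}

#' Proximity category labels
#'
#' The four concentric spatial-relationship categories for an animal pair,
#' in increasing distance order.
#'
#' @return Character vector `c("Same", "Close", "Intermediate", "Away")`.
#' @export
proximity_categories <- function() c("Same", "Close", "Intermediate", "Away")

# Category from squared grid-index distance. Integer comparisons, so the
# cm thresholds (0; 5, 5*sqrt(2); 10, 5*sqrt(5), 10*sqrt(2); beyond) are
# exact: d2 = 0 -> Same; {1,2} -> Close; {4,5,8} -> Intermediate; >8 -> Away.
# Equivalently Chebyshev rings 0 / 1 / 2 / >=3.
.classify_d2 <- function(d2) {
  out <- integer(length(d2))
  out[d2 == 0L] <- 1L
  out[d2 >= 1L & d2 <= 2L] <- 2L
  out[d2 >= 3L & d2 <= 8L] <- 3L
  out[d2 > 8L] <- 4L
  out
}

#' Classify the spatial relationship of two grid positions
#'
#' Pairs are assigned one of four categories by the Euclidean distance `L`
#' between their tiles: `Same` (`L = 0`), `Close` (adjacent tiles,
#' `L` = 5 or 5*sqrt(2) cm at 5 cm pitch), `Intermediate` (second ring,
#' `L` = 10, 5*sqrt(5) or 10*sqrt(2) cm) and `Away` (`L` > 10*sqrt(2) cm).
#' On the integer grid these rings coincide with Chebyshev distance
#' 0 / 1 / 2 / >= 3, and classification is computed on squared grid-index
#' distance so the boundaries are exact.
#'
#' @inheritParams pair_distance_cm
#' @return Factor vector with levels [proximity_categories()].
#' @examples
#' classify_proximity(1, 1, 1, 1)  # Same
#' classify_proximity(1, 1, 3, 2)  # Intermediate (L = 5*sqrt(5))
#' classify_proximity(1, 1, 4, 1)  # Away (L = 15 cm)
#' @export
classify_proximity <- function(ax, ay, bx, by, geom = grid_geometry()) {
  d2 <- (as.integer(ax) - as.integer(bx))^2 + (as.integer(ay) - as.integer(by))^2
  factor(proximity_categories()[.classify_d2(as.integer(d2))],
         levels = proximity_categories())
}
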