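# Voxel index key for a cubic grid of side r anchored at `origin`.
# Points on the upper grid boundary are clamped into the last voxel so that
# the binning covers the closed bounding cube.
voxel_keys <- function(pts, r, origin, n_cells) {
  ix <- floor((pts[, 1L] - origin[1L]) / r)
  iy <- floor((pts[, 2L] - origin[2L]) / r)
  iz <- floor((pts[, 3L] - origin[3L]) / r)
  ix <- pmin(pmax(ix, 0), n_cells - 1)
  iy <- pmin(pmax(iy, 0), n_cells - 1)
  iz <- pmin(pmax(iz, 0), n_cells - 1)
  (ix * n_cells + iy) * n_cells + iz
}

#' Voxel occupancy counts under recursive halving
#'
#' Overlays the cloud with a cubic grid whose side length starts at the
#' largest bounding-box extent and halves at every step; at each scale the
#' number of voxels containing at least one point is recorded. Scales
#' smaller than \code{min_voxel} are excluded: the minimum voxel size acts
#' as a guard against occlusion and sampling-density artefacts at fine
#' scales. The grid is anchored at the cloud's minimum corner, which makes
#' the counts exactly translation-invariant.
#'
#' @param cloud a \code{point_cloud}.
#' @param min_voxel smallest voxel side length in meters (default 0.5).
#' @return An object of class \code{box_count_series}: a data frame with
#'   columns \code{r} (voxel side, meters) and \code{n_occupied}, plus
#'   attributes \code{initial_extent} and \code{min_voxel}.
#' @export
voxel_occupancy_counts <- function(cloud, min_voxel = 0.5) {
  stopifnot(inherits(cloud, "point_cloud"), min_voxel > 0)
  bb <- bounding_box(cloud)
  r0 <- max(bb$extents)
  if (r0 <= 0) {
    stop("degenerate extent: all points coincide, box counting undefined")
  }
  n_scales <- floor(log2(r0 / min_voxel)) + 1L
  if (n_scales < 3L) {
    stop("insufficient scales: fewer than 3 voxel sizes >= min_voxel (",
         format(min_voxel), " m) fit the cloud extent ", format(r0), " m")
  }
  pts <- cloud$points
  origin <- bb$min_corner
  rs <- r0 / 2^(seq_len(n_scales) - 1L)
  counts <- vapply(seq_along(rs), function(k) {
    n_cells <- 2^(k - 1L)
    length(unique(voxel_keys(pts, rs[k], origin, n_cells)))
  }, numeric(1L))
  out <- data.frame(r = rs, n_occupied = counts)
  attr(out, "initial_extent") <- r0
  attr(out, "min_voxel") <- min_voxel
  class(out) <- c("box_count_series", "data.frame")
  out
}

#' Fit the box dimension from a box-count series
#'
#' Ordinary least squares of ln N on ln(1/r), excluding the first (coarsest)
#' scale, whose single occupied voxel pins the regression at the origin and
#' carries no information about scaling. The slope is the box dimension.
#'
#' @param series a \code{box_count_series} (or data frame with columns
#'   \code{r}, \code{n_occupied}) with at least 4 entries.
#' @return An object of class \code{db_result}: list with \code{db} (slope),
#'   \code{intercept}, \code{r_squared}, \code{series}, \code{n_fit_points}.
#' @export
fit_box_dimension <- function(series) {
  if (nrow(series) < 4L) {
    stop("insufficient scales: need >= 4 box-count entries (>= 3 after ",
         "dropping the first scale), got ", nrow(series))
  }
  use <- series[-1L, , drop = FALSE]
  lx <- log(1 / use$r)
  ly <- log(use$n_occupied)
  fit <- stats::lm(ly ~ lx)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(
    db = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    series = series,
    n_fit_points = nrow(use)
  ), class = "db_result")
}

#' Box dimension (Db) of a point cloud
#'
#' The fractal box-counting dimension: voxel occupancy counts under
#' recursive halving of the voxel side (down to \code{min_voxel}), followed
#' by a log-log regression of occupied-voxel count against inverse voxel
#' side. Db lies in [0, 3] for any 3D point cloud: roughly 1 for lines,
#' 2 for planes and surfaces, approaching 3 for space-filling clouds.
#'
#' @inheritParams voxel_occupancy_counts
#' @return a \code{db_result}; see \code{\link{fit_box_dimension}}.
#' @examples
#' db <- box_dimension(generate_plane(15, 0.25))
#' db$db  # close to 2
#' @export
box_dimension <- function(cloud, min_voxel = 0.5) {
  fit_box_dimension(voxel_occupancy_counts(cloud, min_voxel))
}

#' @export
print.db_result <- function(x, ...) {
  cat(sprintf("Box dimension Db = %.4f  (intercept %.3f, R^2 %.4f, %d scales fit)\n",
              x$db, x$intercept, x$r_squared, x$n_fit_points))
  invisible(x)
}
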