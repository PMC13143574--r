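#' Per-layer nearest-neighbour profile of a cloud
#'
#' Splits the cloud into horizontal layers of fixed thickness starting at
#' the minimum height (the top point falls into the last layer) and, within
#' each layer, averages the 3D Euclidean distance from every point to its
#' nearest other point in the same layer. The resulting height-ordered
#' sequence of mean distances is the input of the sampling-density-bias
#' trend test: in a scan whose density thins with height the sequence
#' rises monotonically.
#'
#' @param cloud a \code{point_cloud}.
#' @param layer_width layer thickness in meters (default 1).
#' @return An object of class \code{layer_profile}: data frame with columns
#'   \code{layer_floor} (m), \code{n_points}, \code{mean_nn_distance}
#'   (NA for layers with fewer than 2 points).
#' @export
layer_profile <- function(cloud, layer_width = 1.0) {
  stopifnot(inherits(cloud, "point_cloud"), layer_width > 0)
  pts <- cloud$points
  if (nrow(pts) < 2L) stop("insufficient points: need >= 2 for a layer profile")
  z0 <- min(pts[, 3L])
  idx <- floor((pts[, 3L] - z0) / layer_width)
  top <- max(idx)
  # the single topmost point(s) exactly at z_max join the layer below
  if (top > 0 && sum(idx == top) > 0 &&
      max(pts[, 3L]) == z0 + top * layer_width) {
    idx[idx == top & pts[, 3L] == z0 + top * layer_width] <- top - 1
    top <- max(idx)
  }
  layers <- sort(unique(idx))
  nnd <- rep(NA_real_, length(layers))
  npts <- integer(length(layers))
  for (k in seq_along(layers)) {
    sel <- which(idx == layers[k])
    npts[k] <- length(sel)
    if (npts[k] >= 2L) {
      nnd[k] <- mean(nn_distances_cpp(pts[sel, , drop = FALSE]))
    }
  }
  structure(data.frame(layer_floor = z0 + layers * layer_width,
                       n_points = npts, mean_nn_distance = nnd),
            class = c("layer_profile", "data.frame"))
}

#' Mann-Kendall trend test with Hamed-Rao variance correction
#'
#' Nonparametric monotone-trend test on an ordered sequence: the S
#' statistic counts concordant minus discordant pairs; its variance uses
#' the tie correction and, following Hamed and Rao (1998), is inflated by
#' an effective-sample-size factor built from the significant lag
#' autocorrelations of the ranks of the Sen-detrended sequence. The z
#' score applies the usual continuity correction and the p value is
#' two-sided normal. Sequences shorter than 4 are declared untestable and
#' returned with \code{trend_detected = FALSE}, \code{p_value = 1}: with
#' so few layers the test has no power either way.
#'
#' @param sequence numeric vector, ordered (here: by layer height).
#' @param alpha significance level for trend detection (default 0.05).
#' @return An object of class \code{mk_test}: list with \code{s_statistic},
#'   \code{variance}, \code{z_score}, \code{p_value}, \code{trend_detected},
#'   \code{n}, \code{correction_factor}.
#' @export
mk_trend_test <- function(sequence, alpha = 0.05) {
  x <- as.numeric(sequence)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) {
    return(structure(list(s_statistic = NA_real_, variance = NA_real_,
                          z_score = NA_real_, p_value = 1,
                          trend_detected = FALSE, n = n,
                          correction_factor = NA_real_),
                     class = "mk_test"))
  }
  s <- 0
  for (i in seq_len(n - 1L)) {
    s <- s + sum(sign(x[(i + 1L):n] - x[i]))
  }
  # tie-corrected variance of S
  tie_counts <- table(x)
  tie_counts <- tie_counts[tie_counts > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(tie_counts * (tie_counts - 1) * (2 * tie_counts + 5))) / 18
  # Hamed-Rao effective-sample-size correction from significant rank
  # autocorrelations of the Sen-detrended series
  cf <- hamed_rao_factor(x)
  var_s <- var_s * cf
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(s_statistic = s, variance = var_s, z_score = z,
                 p_value = p, trend_detected = p < alpha, n = n,
                 correction_factor = cf),
            class = "mk_test")
}

# n/n* variance inflation factor of Hamed & Rao (1998): detrend with the
# Sen slope, rank, and accumulate the lag autocorrelations that are
# individually significant at the 5% level.
hamed_rao_factor <- function(x) {
  n <- length(x)
  if (n < 10L) return(1)  # acf estimates are meaningless on shorter series
  t_idx <- seq_len(n)
  slopes <- outer(x, x, `-`) / outer(t_idx, t_idx, `-`)
  sen <- stats::median(slopes[lower.tri(slopes)])
  detr <- x - sen * t_idx
  rk <- rank(detr)
  max_lag <- n - 3L
  ac <- stats::acf(rk, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1L]
  crit <- stats::qnorm(0.975) / sqrt(n)
  sig <- which(abs(ac) > crit)
  if (!length(sig)) return(1)
  i <- sig
  cf <- 1 + 2 / (n * (n - 1) * (n - 2)) *
    sum((n - i) * (n - i - 1) * (n - i - 2) * ac[i])
  # the correction addresses variance inflation under positive serial
  # correlation; deflating the variance from noisy negative acf estimates
  # on short profiles would wreck the test's type-I calibration
  max(cf, 1)
}

#' @export
print.mk_test <- function(x, ...) {
  if (is.na(x$s_statistic)) {
    cat("Mann-Kendall test: sequence too short (n =", x$n, "), no test\n")
  } else {
    cat(sprintf("Mann-Kendall (Hamed-Rao): S = %d, z = %.3f, p = %.4g%s\n",
                as.integer(x$s_statistic), x$z_score, x$p_value,
                if (x$trend_detected) "  ** trend detected" else ""))
  }
  invisible(x)
}

#' Voxel-centre resampling of a cloud
#'
#' Replaces all points falling in each occupied cubic voxel by the voxel's
#' geometric centre, equalizing point density at the voxel scale. The grid
#' is anchored at the cloud's minimum corner.
#'
#' @param cloud a \code{point_cloud}.
#' @param voxel_size voxel side length in meters (> 0).
#' @return a \code{point_cloud} with one point per occupied voxel.
#' @export
voxel_center_resample <- function(cloud, voxel_size) {
  stopifnot(inherits(cloud, "point_cloud"), voxel_size > 0)
  pts <- cloud$points
  origin <- c(min(pts[, 1L]), min(pts[, 2L]), min(pts[, 3L]))
  ix <- floor((pts[, 1L] - origin[1L]) / voxel_size)
  iy <- floor((pts[, 2L] - origin[2L]) / voxel_size)
  iz <- floor((pts[, 3L] - origin[3L]) / voxel_size)
  ky <- max(iy) + 1; kz <- max(iz) + 1
  key <- unique((ix * ky + iy) * kz + iz)
  iz_u <- key %% kz
  iy_u <- ((key - iz_u) / kz) %% ky
  ix_u <- (key - iz_u - iy_u * kz) / (ky * kz)
  centers <- cbind((ix_u + 0.5) * voxel_size + origin[1L],
                   (iy_u + 0.5) * voxel_size + origin[2L],
                   (iz_u + 0.5) * voxel_size + origin[3L])
  point_cloud(centers, cloud$source_id)
}

#' Detect and correct vertical sampling-density bias
#'
#' Mobile and terrestrial laser scans represent near objects with more
#' returns than far ones, so point density typically decays with height.
#' This routine tests the height-ordered layer nearest-neighbour profile
#' for a monotone trend (Mann-Kendall, Hamed-Rao variance). If a trend is
#' evident (p < alpha) the cloud is voxel-centre resampled, starting at a
#' voxel size equal to the largest layer mean nearest-neighbour distance
#' and growing by the factor \code{growth} each iteration, until the
#' resampled cloud's profile shows no evident trend.
#'
#' Each iteration resamples the original cloud (not the previous
#' iteration's output), so the final cloud is exactly the original cloud
#' voxelized once at the final voxel size.
#'
#' @param cloud a \code{point_cloud}.
#' @param layer_width layer thickness in meters (default 1).
#' @param alpha Mann-Kendall significance level (default 0.05).
#' @param growth multiplicative voxel-size growth per iteration
#'   (default 1.10, i.e. +10\% steps).
#' @param max_iter iteration cap; exceeding it raises an error carrying the
#'   report in its \code{report} field.
#' @return list with \code{cloud} (possibly resampled) and \code{report},
#'   an object of class \code{sdb_report}: \code{initial_profile},
#'   \code{tests} (list of \code{mk_test}, one per iteration including the
#'   initial test), \code{voxel_sizes}, \code{iterations},
#'   \code{biased_initially}, \code{final_voxel_size} (NA when unbiased).
#' @export
correct_sdb <- function(cloud, layer_width = 1.0, alpha = 0.05,
                        growth = 1.10, max_iter = 50L) {
  stopifnot(inherits(cloud, "point_cloud"), alpha > 0, alpha < 1, growth > 1)
  profile0 <- if (nrow(cloud$points) >= 2L) layer_profile(cloud, layer_width) else NULL
  seq0 <- if (is.null(profile0)) numeric(0) else
    profile0$mean_nn_distance[!is.na(profile0$mean_nn_distance)]
  test0 <- mk_trend_test(seq0, alpha)
  tests <- list(test0)
  voxel_sizes <- numeric(0)
  if (!isTRUE(test0$trend_detected)) {
    report <- structure(list(initial_profile = profile0, tests = tests,
                             voxel_sizes = voxel_sizes, iterations = 0L,
                             biased_initially = FALSE,
                             final_voxel_size = NA_real_),
                        class = "sdb_report")
    return(list(cloud = cloud, report = report))
  }
  v <- max(seq0)
  for (iter in seq_len(max_iter)) {
    resampled <- voxel_center_resample(cloud, v)
    prof <- if (nrow(resampled$points) >= 2L) layer_profile(resampled, layer_width) else NULL
    s <- if (is.null(prof)) numeric(0) else
      prof$mean_nn_distance[!is.na(prof$mean_nn_distance)]
    tst <- mk_trend_test(s, alpha)
    tests[[iter + 1L]] <- tst
    voxel_sizes[iter] <- v
    if (!isTRUE(tst$trend_detected)) {
      report <- structure(list(initial_profile = profile0, tests = tests,
                               voxel_sizes = voxel_sizes, iterations = iter,
                               biased_initially = TRUE, final_voxel_size = v),
                          class = "sdb_report")
      return(list(cloud = resampled, report = report))
    }
    v <- v * growth
  }
  report <- structure(list(initial_profile = profile0, tests = tests,
                           voxel_sizes = voxel_sizes, iterations = max_iter,
                           biased_initially = TRUE, final_voxel_size = NA_real_),
                      class = "sdb_report")
  cond <- simpleError(paste0("sampling-density-bias correction did not ",
                             "converge in ", max_iter, " iterations"))
  cond$report <- report
  stop(cond)
}

#' @export
print.sdb_report <- function(x, ...) {
  if (!x$biased_initially) {
    cat("No vertical sampling-density bias detected (p =",
        format(x$tests[[1L]]$p_value, digits = 3), ")\n")
  } else {
    cat(sprintf("Sampling-density bias corrected in %d iteration(s); final voxel %.3f m\n",
                x$iterations, x$final_voxel_size))
  }
  invisible(x)
}

#' Differential entropy of a 2D point projection via Gaussian KDE
#'
#' Estimates the density of the projected points with an equal-weight
#' isotropic Gaussian kernel of the given bandwidth, evaluated on a
#' regular grid covering the bounding box padded by 5 bandwidths per side
#' (so that less than 1e-6 of the kernel mass falls off the grid). The
#' evaluation linear-bins the points onto the grid and smooths with the
#' full (untruncated, within the grid) Gaussian kernel; the grid density
#' is renormalized to integrate to 1 and the Riemann-sum plug-in entropy
#' -sum p ln(p) dA is returned. Cells with density below 1e-300
#' contribute zero. The renormalization factor is attached as attribute
#' \code{"normalization"}.
#'
#' @param points2d two-column numeric matrix of (u, v) coordinates, meters.
#' @param bandwidth Gaussian kernel standard deviation in meters
#'   (default 0.2).
#' @param grid_step target grid spacing in meters (default 0.1,
#'   bandwidth/2); must not exceed the bandwidth.
#' @return the entropy estimate (dimensionless; natural log of m^2).
#' @export
plane_entropy <- function(points2d, bandwidth = 0.2, grid_step = 0.1) {
  pts <- as.matrix(points2d)
  stopifnot(ncol(pts) == 2L, nrow(pts) >= 1L, bandwidth > 0,
            grid_step > 0, grid_step <= bandwidth)
  pad <- 5 * bandwidth
  gx <- entropy_grid(range(pts[, 1L]), pad, grid_step)
  gy <- entropy_grid(range(pts[, 2L]), pad, grid_step)
  # points are mass-preservingly binned on a 4x finer internal grid, so
  # the binning resolution error is negligible against the quadrature step
  bin_step <- grid_step / 4
  bx <- entropy_grid(range(pts[, 1L]), pad, bin_step)
  by <- entropy_grid(range(pts[, 2L]), pad, bin_step)
  D <- bin_linear_2d(pts, bx, by, bin_step)
  # separable Gaussian smoothing: full kernel support within the grid
  Kx <- stats::dnorm(outer(gx, bx, `-`), sd = bandwidth)
  Ky <- stats::dnorm(outer(gy, by, `-`), sd = bandwidth)
  p <- (Kx %*% D %*% t(Ky)) / nrow(pts)
  dA <- grid_step^2
  norm <- sum(p) * dA
  p <- p / norm
  out <- -sum(ifelse(p > 1e-300, p * log(p), 0)) * dA
  attr(out, "normalization") <- norm
  out
}

entropy_grid <- function(rng, pad, step) {
  lo <- rng[1L] - pad
  n <- max(7L, as.integer(ceiling((diff(rng) + 2 * pad) / step)))
  lo + (0:n) * step
}

# Distribute unit mass per point over the 4 surrounding grid nodes with
# bilinear weights; returns the Gx x Gy mass matrix.
bin_linear_2d <- function(pts, gx, gy, step) {
  nx <- length(gx); ny <- length(gy)
  fx <- (pts[, 1L] - gx[1L]) / step
  fy <- (pts[, 2L] - gy[1L]) / step
  ix <- pmin(floor(fx), nx - 2); wx <- fx - ix
  iy <- pmin(floor(fy), ny - 2); wy <- fy - iy
  idx <- c(ix + nx * iy, (ix + 1) + nx * iy,
           ix + nx * (iy + 1), (ix + 1) + nx * (iy + 1)) + 1
  w <- c((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy)
  mass <- numeric(nx * ny)
  acc <- rowsum(w, idx)
  mass[as.integer(rownames(acc))] <- acc[, 1L]
  matrix(mass, nx, ny)
}

#' Canopy entropy (CE) of a point cloud
#'
#' An entropy-based index of how homogeneously biomass fills the plot:
#' after sampling-density-bias correction (\code{\link{correct_sdb}}), the
#' cloud is projected onto the xy, xz and yz planes, the differential
#' entropy of each projected density is estimated by Gaussian KDE
#' (\code{\link{plane_entropy}}), and the three plane entropies are
#' combined by the Pythagorean formula
#' \code{ce = sqrt(ce_xy^2 + ce_xz^2 + ce_yz^2)}.
#'
#' CE grows with plot extent (a density spread over a larger area has a
#' larger differential entropy), so values are only comparable across
#' clouds of identical footprint and height range.
#'
#' @param cloud a \code{point_cloud}.
#' @param bandwidth KDE bandwidth in meters (default 0.2).
#' @param layer_width SDB layer thickness in meters (default 1).
#' @param alpha SDB trend-test significance level (default 0.05).
#' @param grid_step KDE evaluation grid step in meters (default 0.1).
#' @param growth SDB voxel growth factor per iteration (default 1.10).
#' @return An object of class \code{ce_result}: list with \code{ce},
#'   \code{ce_xy}, \code{ce_xz}, \code{ce_yz}, \code{sdb}
#'   (\code{sdb_report}), \code{n_points_used}.
#' @examples
#' ce <- canopy_entropy(generate_uniform_cube(5, 2000, seed = 1))
#' ce$ce
#' @export
canopy_entropy <- function(cloud, bandwidth = 0.2, layer_width = 1.0,
                           alpha = 0.05, grid_step = 0.1, growth = 1.10) {
  stopifnot(inherits(cloud, "point_cloud"))
  corrected <- correct_sdb(cloud, layer_width = layer_width, alpha = alpha,
                           growth = growth)
  pts <- corrected$cloud$points
  ce_xy <- as.numeric(plane_entropy(pts[, c(1L, 2L), drop = FALSE], bandwidth, grid_step))
  ce_xz <- as.numeric(plane_entropy(pts[, c(1L, 3L), drop = FALSE], bandwidth, grid_step))
  ce_yz <- as.numeric(plane_entropy(pts[, c(2L, 3L), drop = FALSE], bandwidth, grid_step))
  structure(list(ce = sqrt(ce_xy^2 + ce_xz^2 + ce_yz^2),
                 ce_xy = ce_xy, ce_xz = ce_xz, ce_yz = ce_yz,
                 sdb = corrected$report, n_points_used = nrow(pts)),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Canopy entropy CE = %.4f  (xy %.3f, xz %.3f, yz %.3f; %d points used)\n",
              x$ce, x$ce_xy, x$ce_xz, x$ce_yz, x$n_points_used))
  invisible(x)
}
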