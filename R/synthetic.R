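# Synthetic point clouds with known structure: analytic fractals anchor the
# box dimension at 1, 2, ln20/ln3 and 3; uniform bodies give closed-form
# entropy limits; the biased canopy exercises the sampling-density-bias
# machinery; the paired-index generator feeds the regression recovery tests.

#' Regular planar grid of points
#'
#' A horizontal square grid at constant height; its box dimension is 2.
#'
#' @param side square side in meters.
#' @param spacing grid spacing in meters (< side).
#' @param z constant height in meters.
#' @return a \code{point_cloud} of \code{(floor(side/spacing)+1)^2} points.
#' @export
generate_plane <- function(side, spacing, z = 0) {
  stopifnot(spacing > 0, spacing < side)
  g <- seq(0, side, by = spacing)
  pts <- cbind(rep(g, times = length(g)), rep(g, each = length(g)), z)
  point_cloud(pts, sprintf("plane_%gm", side))
}

#' Collinear points along the x axis
#'
#' A regularly spaced line segment; its box dimension is 1.
#'
#' @param length segment length in meters.
#' @param spacing point spacing in meters (< length).
#' @return a \code{point_cloud}.
#' @export
generate_line <- function(length, spacing) {
  stopifnot(spacing > 0, spacing < length)
  g <- seq(0, length, by = spacing)
  point_cloud(cbind(g, 0, 0), sprintf("line_%gm", length))
}

#' Uniform random points in a cube
#'
#' I.i.d. uniform points in \code{[0, side]^3}; the space-filling anchor
#' (box dimension approaches 3 with density, never exceeding it) and the
#' analytic canopy-entropy limit \code{sqrt(3) * ln(side^2)}.
#'
#' @param side cube side in meters.
#' @param n_points number of points.
#' @param seed RNG seed (the global RNG state is left untouched).
#' @return a \code{point_cloud}.
#' @export
generate_uniform_cube <- function(side, n_points, seed = 1L) {
  stopifnot(side > 0, n_points >= 1L)
  pts <- with_seed(seed, matrix(stats::runif(3L * n_points, 0, side),
                                ncol = 3L))
  point_cloud(pts, sprintf("cube_%gm_n%d", side, n_points))
}

#' Menger-sponge point lattice
#'
#' Recursive 3x3x3 subdivision of the unit cube keeping the 20 sub-cubes
#' that are neither face centres nor the body centre; emits the centres of
#' the 20^level final-level cubes, scaled to \code{[0, side]^3}. The
#' construction's Hausdorff dimension is ln(20)/ln(3) = 2.7268..., the
#' theoretical upper limit of tree structural complexity.
#'
#' @param level recursion depth, 1 to 5.
#' @param side cube side in meters.
#' @return a \code{point_cloud} of \code{20^level} points; every coordinate
#'   is \code{(k + 0.5)/3^level * side} for integer k.
#' @export
generate_menger_sponge <- function(level, side = 15) {
  if (!(is.numeric(level) && length(level) == 1L && level == round(level) &&
        level >= 1 && level <= 5)) {
    stop("menger sponge level must be an integer in 1..5")
  }
  level <- as.integer(level)
  # sub-cube offsets kept at each subdivision: at most one middle coordinate
  keep <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  keep <- keep[rowSums(keep == 1L) <= 1L, , drop = FALSE]  # 20 of 27
  idx <- matrix(0, nrow = 1L, ncol = 3L)
  for (l in seq_len(level)) {
    n <- nrow(idx)
    idx <- idx[rep(seq_len(n), each = nrow(keep)), , drop = FALSE] * 3 +
      keep[rep(seq_len(nrow(keep)), times = n), , drop = FALSE]
  }
  pts <- (idx + 0.5) / 3^level * side
  point_cloud(pts, sprintf("menger_l%d_%gm", level, side))
}

#' Parameters of the biased synthetic canopy
#'
#' @param side horizontal plot side in meters (default 15, the study's
#'   plot footprint).
#' @param height canopy height in meters.
#' @param n_points number of points.
#' @param density_decay exponential density decay rate per meter of
#'   height (>= 0); point density is proportional to
#'   \code{exp(-density_decay * z)}, emulating a ground-based scanner that
#'   samples the upper canopy more sparsely.
#' @param seed RNG seed.
#' @return list of class \code{canopy_params}.
#' @export
canopy_params <- function(side = 15, height = 20, n_points = 2e5,
                          density_decay = 0.3, seed = 1L) {
  stopifnot(side > 0, height > 0, n_points > 0, density_decay >= 0)
  structure(list(side = side, height = height, n_points = as.integer(n_points),
                 density_decay = density_decay, seed = as.integer(seed)),
            class = "canopy_params")
}

#' Synthetic canopy with vertical sampling-density bias
#'
#' Points uniform in xy over \code{[0, side]^2}; heights drawn from a
#' truncated exponential on \code{[0, height]} with rate
#' \code{density_decay}, so the expected per-layer point count decays as
#' \code{exp(-rate * z)} and the per-layer nearest-neighbour distance
#' grows with height — the monotone profile that the Mann-Kendall-based
#' bias test targets. With \code{density_decay = 0} the cloud reduces to a
#' uniform (bias-free) slab.
#'
#' @param params a \code{\link{canopy_params}} object.
#' @return a \code{point_cloud}.
#' @export
generate_biased_canopy <- function(params = canopy_params()) {
  stopifnot(inherits(params, "canopy_params"))
  pts <- with_seed(params$seed, {
    n <- params$n_points
    u <- stats::runif(n)
    z <- if (params$density_decay > 0) {
      rate <- params$density_decay
      # inverse-CDF of the exponential truncated to [0, height]
      -log(1 - u * (1 - exp(-rate * params$height))) / rate
    } else {
      u * params$height
    }
    cbind(stats::runif(n, 0, params$side), stats::runif(n, 0, params$side), z)
  })
  point_cloud(pts, sprintf("canopy_r%g_n%d", params$density_decay,
                           params$n_points))
}

#' Simulated paired index table for regression recovery
#'
#' Draws a latent structural gradient uniform over \code{db_range},
#' observes db with x-noise and ce on the line
#' \code{slope * latent + intercept} with y-noise, and assigns site labels
#' round-robin. The defaults emulate the study's fitted relationship
#' (slope 4.75, intercept -1.07, error-SD ratio 0.245 over a Db range of
#' 1.99, with the noise magnitude set so the population correlation is
#' about 0.82).
#'
#' @param n number of rows (>= 3).
#' @param slope,intercept true linear relationship of ce on db.
#' @param noise_sd_x,noise_sd_y measurement-error SDs of db and ce.
#' @param sites number of site labels.
#' @param seed RNG seed.
#' @param db_range range of the latent db gradient (length 2).
#' @return data frame with columns \code{source_id}, \code{site},
#'   \code{db}, \code{ce}, \code{n_points}, \code{t_db}, \code{t_ce}.
#' @export
generate_paired_indices <- function(n = 170L, slope = 4.75, intercept = -1.07,
                                    noise_sd_x = 0.2818, noise_sd_y = 1.15,
                                    sites = 4L, seed = 1L,
                                    db_range = c(1.2, 3.19)) {
  stopifnot(n >= 3L, sites >= 1L)
  with_seed(seed, {
    latent <- stats::runif(n, db_range[1L], db_range[2L])
    db <- latent + stats::rnorm(n, 0, noise_sd_x)
    ce <- slope * latent + intercept + stats::rnorm(n, 0, noise_sd_y)
    npts <- round(stats::runif(n, 2e5, 4e6))
    data.frame(
      source_id = sprintf("plot%03d", seq_len(n)),
      site = sprintf("site%d", (seq_len(n) - 1L) %% sites + 1L),
      db = db, ce = ce, n_points = npts,
      t_db = 1.8e-6 * npts^0.91, t_ce = 3.2e-5 * npts^0.96
    )
  })
}

# Evaluate `expr` under a local, restorable RNG state so generators are
# reproducible without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
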