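test_that("cube-corner cloud produces the expected halving series", {
  pts <- as.matrix(expand.grid(c(0, 4), c(0, 4), c(0, 4)))
  s <- voxel_occupancy_counts(point_cloud(pts), min_voxel = 0.5)
  expect_equal(s$r, c(4, 2, 1, 0.5))
  expect_equal(s$n_occupied, c(1, 8, 8, 8))
})

test_that("voxel counts match the brute-force scan on varied clouds", {
  clouds <- list(
    generate_uniform_cube(10, 3000, seed = 1),
    generate_plane(16, 0.5),
    generate_line(12, 0.1),
    generate_menger_sponge(2, 9),
    generate_biased_canopy(canopy_params(n_points = 3000, seed = 5))
  )
  for (cl in clouds) {
    s <- voxel_occupancy_counts(cl, min_voxel = 0.5)
    origin <- bounding_box(cl)$min_corner
    for (i in seq_len(nrow(s))) {
      expect_equal(s$n_occupied[i],
                   brute_voxel_count(cl$points, s$r[i], origin),
                   info = sprintf("%s at r=%g", cl$source_id, s$r[i]))
    }
  }
})

test_that("a dense single-plane grid quadruples occupancy per halving", {
  s <- voxel_occupancy_counts(generate_plane(16, 0.05), min_voxel = 0.5)
  expect_equal(s$n_occupied, c(1, 4^(1:5)))
})

test_that("box-count series obey the occupancy invariants", {
  for (seed in 1:5) {
    cl <- generate_uniform_cube(8, 500 * seed, seed = seed)
    s <- voxel_occupancy_counts(cl, min_voxel = 0.25)
    expect_true(all(diff(s$n_occupied) >= 0))
    ratio <- s$n_occupied[-1] / s$n_occupied[-nrow(s)]
    expect_true(all(ratio <= 8 + 1e-12))
    expect_true(all(s$n_occupied >= 1 & s$n_occupied <= n_points(cl)))
    expect_equal(s$r[-nrow(s)] / s$r[-1], rep(2, nrow(s) - 1))
  }
})

test_that("log-log fit reproduces hand-computed slopes", {
  cubic <- data.frame(r = c(4, 2, 1, 0.5), n_occupied = c(1, 8, 64, 512))
  fit <- fit_box_dimension(cubic)
  expect_equal(fit$db, 3, tolerance = 1e-12)
  expect_equal(fit$n_fit_points, 3L)

  flat <- data.frame(r = c(4, 2, 1, 0.5), n_occupied = c(1, 8, 8, 8))
  expect_equal(fit_box_dimension(flat)$db, 0, tolerance = 1e-12)

  set.seed(77)
  for (i in 1:20) {
    k <- sample(4:8, 1)
    r <- 16 / 2^(0:(k - 1))
    n <- cumprod(c(1, sample(1:8, k - 1, replace = TRUE)))
    fit <- fit_box_dimension(data.frame(r = r, n_occupied = n))
    expect_equal(fit$db, brute_ols_slope(log(1 / r[-1]), log(n[-1])),
                 tolerance = 1e-12)
  }
  expect_error(fit_box_dimension(cubic[1:3, ]), "insufficient scales")
})

test_that("analytic shapes recover their known dimensions", {
  expect_lt(abs(box_dimension(generate_plane(15, 0.05))$db - 2), 0.05)
  expect_lt(abs(box_dimension(generate_line(16, 0.05))$db - 1), 0.05)
  # fractal lattice validated over its self-similar scale range: from the
  # extent down to the construction pitch side/3^level
  menger <- generate_menger_sponge(4, 15)
  db <- box_dimension(menger, min_voxel = 15 / 81)$db
  expect_lt(abs(db - log(20) / log(3)), 0.1)
})

test_that("the estimate stays within [0, 3] across generators", {
  clouds <- list(
    generate_plane(15, 0.2), generate_line(15, 0.05),
    generate_uniform_cube(15, 20000, seed = 4),
    generate_menger_sponge(3, 15),
    generate_biased_canopy(canopy_params(n_points = 20000, seed = 2))
  )
  for (cl in clouds) {
    db <- box_dimension(cl)$db
    expect_gte(db, 0)
    expect_lte(db, 3 + 1e-9)
  }
})

test_that("the series is exactly translation- and scale-invariant", {
  cl <- generate_uniform_cube(10, 2000, seed = 6)
  s0 <- voxel_occupancy_counts(cl, 0.5)
  shifted <- point_cloud(sweep(cl$points, 2, c(103.7, -55.1, 12.9), `+`))
  s1 <- voxel_occupancy_counts(shifted, 0.5)
  expect_equal(s1$n_occupied, s0$n_occupied)
  expect_equal(s1$r, s0$r)

  scaled <- point_cloud(cl$points * 3.7)
  fit0 <- box_dimension(cl, 0.5)
  fit1 <- box_dimension(scaled, 0.5 * 3.7)
  expect_equal(fit1$db, fit0$db, tolerance = 1e-12)
})

test_that("widening a flat plot damps the estimated dimension", {
  mk_slab <- function(side, dens = 40) {
    n <- round(dens * side^2)
    set.seed(11)
    point_cloud(cbind(stats::runif(n, 0, side), stats::runif(n, 0, side),
                      stats::runif(n, 0, 2)))
  }
  expect_lt(box_dimension(mk_slab(60))$db, box_dimension(mk_slab(15))$db)
})

test_that("degenerate inputs are rejected", {
  same <- point_cloud(matrix(1, nrow = 5, ncol = 3))
  expect_error(voxel_occupancy_counts(same), "degenerate extent")
  tiny <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(voxel_occupancy_counts(tiny, min_voxel = 0.5), "insufficient scales")
})
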