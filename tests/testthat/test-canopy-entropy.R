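test_that("layer profile handles the two-point and lattice cases", {
  cl <- point_cloud(rbind(c(0, 0, 0.2), c(1, 0, 0.4)))
  prof <- layer_profile(cl)
  expect_equal(nrow(prof), 1L)
  # full 3D distance within the layer: sqrt(1^2 + 0.2^2)
  expect_equal(prof$mean_nn_distance, sqrt(1.04))
  expect_equal(prof$n_points, 2L)

  g <- seq(0, 2, by = 0.1)
  lattice <- point_cloud(cbind(rep(g, each = length(g)),
                               rep(g, times = length(g)), 0.5))
  m <- layer_profile(lattice)$mean_nn_distance
  expect_equal(m, 0.1, tolerance = 0.02)
})

test_that("per-layer means equal the all-pairs brute-force computation", {
  for (seed in c(3, 14)) {
    cl <- generate_biased_canopy(canopy_params(n_points = 2000,
                                               density_decay = 0.25,
                                               height = 8, seed = seed))
    prof <- layer_profile(cl)
    oracle <- brute_layer_means(cl$points)
    expect_equal(prof$mean_nn_distance, oracle, tolerance = 1e-9)
  }
})

test_that("Mann-Kendall statistics match enumeration and reference formulas", {
  expect_equal(mk_trend_test(1:10)$s_statistic, 45)
  expect_equal(mk_trend_test(1:10)$s_statistic, brute_mk_s(1:10))

  const <- mk_trend_test(rep(2.5, 10))
  expect_equal(const$s_statistic, 0)
  expect_equal(const$p_value, 1)
  expect_false(const$trend_detected)

  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(12)
    tt <- mk_trend_test(x)
    expect_equal(tt$s_statistic, brute_mk_s(x))
    # reversal negates S
    expect_equal(mk_trend_test(rev(x))$s_statistic, -tt$s_statistic)
    # cross-check S against the Kendall concordance count of cor.test
    ct <- suppressWarnings(stats::cor.test(x, seq_along(x), method = "kendall"))
    expect_equal(tt$s_statistic, unname(2 * ct$statistic - 12 * 11 / 2))
  }

  short <- mk_trend_test(c(1, 2, 3))
  expect_false(short$trend_detected)
  expect_equal(short$p_value, 1)
})

test_that("Mann-Kendall null rejection rate is near nominal", {
  set.seed(100)
  vals <- rnorm(12)
  rej <- mean(replicate(200, mk_trend_test(sample(vals))$trend_detected))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)
})

test_that("voxel-centre resampling emits one centre per occupied voxel", {
  cl <- point_cloud(rbind(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2)))
  r <- voxel_center_resample(cl, 1)
  expect_equal(unname(r$points), rbind(c(0.6, 0.6, 0.6)))

  corners <- point_cloud(as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2))))
  expect_equal(n_points(voxel_center_resample(corners, 1)), 8L)

  cl2 <- generate_uniform_cube(4, 3000, seed = 9)
  rs <- voxel_center_resample(cl2, 0.37)
  # one centre per brute-force occupied voxel
  origin <- bounding_box(cl2)$min_corner
  expect_equal(n_points(rs), brute_voxel_count(cl2$points, 0.37, origin))
  # distinct centres at least one voxel apart along some axis
  d <- as.matrix(stats::dist(rs$points, method = "maximum"))
  diag(d) <- Inf
  expect_gte(min(d), 0.37 * (1 - 1e-9))
  # every centre lies in a voxel that contains at least one input point
  key <- function(m) {
    i <- floor(sweep(m, 2, origin) / 0.37)
    paste(i[, 1], i[, 2], i[, 3])
  }
  expect_true(all(key(rs$points) %in% key(cl2$points)))
})

test_that("bias correction flags the decaying canopy and de-trends it", {
  cl <- generate_biased_canopy(canopy_params(side = 15, height = 20,
                                             n_points = 5e4,
                                             density_decay = 0.3, seed = 3))
  res <- correct_sdb(cl)
  rep <- res$report
  expect_true(rep$biased_initially)
  expect_gt(rep$iterations, 0)
  expect_true(is.finite(rep$final_voxel_size))
  expect_true(all(diff(rep$voxel_sizes) > 0))
  # last test clean
  last <- rep$tests[[length(rep$tests)]]
  expect_false(last$trend_detected)
  # correction reduces the trend z-score magnitude
  expect_lt(abs(last$z_score), abs(rep$tests[[1]]$z_score))
  expect_lte(n_points(res$cloud), n_points(cl))
})

test_that("bias-free slabs are usually left untouched", {
  flags <- vapply(1:10, function(s) {
    cl <- generate_biased_canopy(canopy_params(n_points = 1e4,
                                               density_decay = 0, seed = s))
    correct_sdb(cl)$report$biased_initially
  }, logical(1))
  expect_lte(mean(flags), 0.1)
  # an unbiased cloud comes back unchanged
  cl <- generate_biased_canopy(canopy_params(n_points = 1e4,
                                             density_decay = 0, seed = 1))
  res <- correct_sdb(cl)
  expect_identical(res$cloud$points, cl$points)
})

test_that("clouds with too few layers are declared untestable, not biased", {
  cl <- generate_uniform_cube(2.5, 500, seed = 6)  # under 4 one-metre layers
  res <- correct_sdb(cl)
  expect_false(res$report$biased_initially)
  expect_identical(res$cloud$points, cl$points)
})

test_that("plane entropy matches closed forms and the exact-mixture oracle", {
  h <- 0.2
  e1 <- plane_entropy(matrix(c(3.17, -0.42), 1, 2))
  expect_lt(abs(c(e1) - log(2 * pi * exp(1) * h^2)), 1e-3)

  set.seed(1)
  sq <- matrix(stats::runif(2e4, 0, 15), ncol = 2)
  e2 <- plane_entropy(sq)
  expect_lt(abs(c(e2) - log(225)) / log(225), 0.02)
  expect_lt(abs(attr(e2, "normalization") - 1), 0.01)
  # quadrature refinement stability
  e2h <- plane_entropy(sq, grid_step = 0.05)
  expect_lt(abs(c(e2) - c(e2h)), 1e-3)

  # exact Gaussian-mixture oracle on a matching grid
  set.seed(2)
  pts <- matrix(stats::runif(600, 0, 3), ncol = 2)
  step <- 0.1; pad <- 5 * h
  gx <- min(pts[, 1]) - pad + (0:ceiling((diff(range(pts[, 1])) + 2 * pad) / step)) * step
  gy <- min(pts[, 2]) - pad + (0:ceiling((diff(range(pts[, 2])) + 2 * pad) / step)) * step
  oracle <- brute_plane_entropy(pts, gx, gy, h)
  expect_equal(c(plane_entropy(pts)), oracle, tolerance = 1e-3)
})

test_that("canopy entropy combines plane entropies pythagoreanly", {
  cl <- generate_uniform_cube(6, 4000, seed = 12)
  ce <- canopy_entropy(cl)
  expect_equal(ce$ce, sqrt(ce$ce_xy^2 + ce$ce_xz^2 + ce$ce_yz^2))
  expect_gte(ce$ce, abs(ce$ce_xy))
  expect_gte(ce$ce, 0)
})

test_that("dense uniform cubes reach the analytic entropy limit", {
  cl <- generate_uniform_cube(15, 1e5, seed = 5)
  ce <- canopy_entropy(cl)
  expect_equal(ce$ce, sqrt(3) * log(225), tolerance = 0.02)
})

test_that("entropy respects translation and scaling identities", {
  cl <- generate_uniform_cube(5, 3000, seed = 21)
  ce0 <- canopy_entropy(cl)
  shifted <- point_cloud(sweep(cl$points, 2, c(40.5, -12.25, 7.75), `+`))
  ce1 <- suppressWarnings(canopy_entropy(shifted))
  expect_equal(ce1$ce, ce0$ce, tolerance = 1e-9)

  # doubling coordinates, bandwidth and grid step adds exactly 2 ln 2
  # to each plane entropy
  doubled <- point_cloud(cl$points * 2)
  e0 <- plane_entropy(cl$points[, 1:2])
  e2 <- plane_entropy(doubled$points[, 1:2], bandwidth = 0.4, grid_step = 0.2)
  expect_equal(c(e2) - c(e0), 2 * log(2), tolerance = 1e-9)
})

test_that("canopy entropy grows with plot size for uniform clouds", {
  ces <- vapply(c(5, 10, 15), function(side) {
    canopy_entropy(generate_uniform_cube(side, 2e4, seed = 30))$ce
  }, numeric(1))
  expect_true(all(diff(ces) > 0))
})
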