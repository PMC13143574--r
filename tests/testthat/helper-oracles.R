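# Independent brute-force reference implementations used as oracles.
# These deliberately take the slow, obvious route and share no code with
# the package internals they check.

# Occupied-voxel count by collecting per-point index triples as strings.
brute_voxel_count <- function(pts, r, origin = apply(pts, 2, min)) {
  r0 <- max(apply(pts, 2, max) - origin)
  k <- ceiling(r0 / r)
  ijk <- sapply(1:3, function(d) {
    i <- floor((pts[, d] - origin[d]) / r)
    pmin(pmax(i, 0), k - 1)
  })
  length(unique(paste(ijk[, 1], ijk[, 2], ijk[, 3])))
}

# All-pairs nearest-neighbour distances.
brute_nn <- function(pts) {
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  apply(D, 1, min)
}

# Per-layer mean NN distance with half-open 1 m layers anchored at min z,
# the top point folded into the layer below when it sits on a boundary.
brute_layer_means <- function(pts, width = 1) {
  z0 <- min(pts[, 3])
  idx <- floor((pts[, 3] - z0) / width)
  top <- max(idx)
  if (top > 0 && max(pts[, 3]) == z0 + top * width) {
    idx[idx == top] <- top - 1
  }
  sapply(sort(unique(idx)), function(k) {
    sel <- idx == k
    if (sum(sel) < 2) NA_real_ else mean(brute_nn(pts[sel, , drop = FALSE]))
  })
}

# Exact Gaussian-mixture entropy on a caller-supplied grid.
brute_plane_entropy <- function(pts, gx, gy, h) {
  P <- matrix(0, length(gx), length(gy))
  for (i in seq_len(nrow(pts))) {
    P <- P + outer(stats::dnorm(gx, pts[i, 1], h), stats::dnorm(gy, pts[i, 2], h))
  }
  P <- P / nrow(pts)
  dA <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  P <- P / (sum(P) * dA)
  -sum(P * log(P)) * dA
}

# Closed-form simple-regression slope.
brute_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Deming fit by direct numerical minimisation of the errors-in-variables
# loss: profile out the latent xi, leaving sum (y - a - b x)^2 / (b^2 + lambda)
# with lambda the y:x error variance ratio.
brute_deming_slope <- function(x, y, delta) {
  lambda <- 1 / delta^2
  loss <- function(par) {
    sum((y - par[1] - par[2] * x)^2) / (par[2]^2 + lambda)
  }
  init <- c(mean(y) - brute_ols_slope(x, y) * mean(x), brute_ols_slope(x, y))
  stats::optim(init, loss, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$par[2]
}

# Mann-Kendall S by direct pair enumeration.
brute_mk_s <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  s
}

tmp_path <- function(ext) tempfile(fileext = ext)
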