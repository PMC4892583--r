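# Covariance PCA, mode-PC overlap, DCCM, ensemble merging

# trajectory oscillating along a given unit-MRMS real-space direction
osc_traj <- function(base, u, amps, noise_sd = 0, seed = 1) {
  set.seed(seed)
  frames <- lapply(amps, function(a) {
    X <- base + a * u
    if (noise_sd > 0)
      X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X), 3)
    X
  })
  toy_trajectory(frames, topology = toy_model(base))
}

internal_direction <- function() {
  # an internal ENM mode: orthogonal to rigid translations/rotations, so
  # superposition does not absorb it
  if (is.null(.fx$u7)) {
    ms <- fx_modes()
    .fx$u7 <- armflex:::.mode_direction_unit_mrms(ms, 7L)
  }
  .fx$u7
}

test_that("single-direction motion gives a rank-1 PCA", {
  sol <- fx_solenoid()
  u <- internal_direction()
  amps <- 1.5 * sin(2 * pi * (0:19) / 10)
  tr <- osc_traj(sol$structure$coords, u, amps)
  pca <- compute_pca(tr)
  expect_equal(pca$var_explained[1], 1, tolerance = 1e-9)
  expect_gt(mode_overlap(pca$vectors[, 1], u), 1 - 1e-6)
  expect_error(compute_pca(toy_trajectory(list(u))), "2 frames")
})

test_that("PCA eigenvalue sum equals the total fitted variance", {
  sol <- fx_small_solenoid()
  set.seed(20)
  frames <- lapply(1:12, function(i)
    sol$structure$coords + matrix(rnorm(3 * n_atoms(sol$structure),
                                        sd = 0.4), ncol = 3))
  tr <- toy_trajectory(frames, topology = sol$structure)
  pca <- compute_pca(tr)
  expect_equal(sum(pca$eigenvalues), pca$total_variance,
               tolerance = 1e-9 * pca$total_variance)
})

test_that("isotropic noise gives no dominant component", {
  set.seed(21)
  base <- matrix(rnorm(15, sd = 10), 5, 3)
  frames <- lapply(1:2000, function(i) base + matrix(rnorm(15, sd = 1),
                                                     5, 3))
  pca <- compute_pca(toy_trajectory(frames))
  expect_lt(pca$eigenvalues[1] / pca$eigenvalues[3], 2)
})

test_that("PCA matches a direct covariance oracle on a small toy", {
  set.seed(22)
  base <- matrix(rnorm(15, sd = 5), 5, 3)
  frames <- lapply(1:10, function(i) base + matrix(rnorm(15, sd = 1), 5, 3))
  tr <- toy_trajectory(frames)
  pca <- compute_pca(tr, fit = FALSE)
  # oracle: flatten (x1,y1,z1,...), covariance, eigen — written afresh
  M <- t(vapply(frames, function(F) as.vector(t(F)), numeric(15)))
  Mc <- sweep(M, 2, colMeans(M))
  C <- t(Mc) %*% Mc / nrow(M)
  eo <- eigen(C, symmetric = TRUE)
  expect_equal(pca$eigenvalues, pmax(eo$values, 0), tolerance = 1e-12)
  for (k in 1:3)
    expect_gt(abs(sum(pca$vectors[, k] * eo$vectors[, k])), 1 - 1e-9)
})

test_that("mode overlap extremes and recovery from noisy motion", {
  v <- rnorm(30)
  expect_equal(mode_overlap(v, v), 1, tolerance = 1e-12)
  expect_equal(mode_overlap(v, -v), 1, tolerance = 1e-12)  # sign-blind
  w <- c(v[-1], 0); w <- w - v * sum(w * v) / sum(v^2)
  expect_equal(mode_overlap(v, w), 0, tolerance = 1e-9)
  expect_error(mode_overlap(v, numeric(30)), "zero")
  expect_error(mode_overlap(v, rnorm(9)), "dimension")

  sol <- fx_solenoid()
  ms <- fx_modes()
  u <- internal_direction()
  amps <- 2 * sin(2 * pi * (0:49) / 25)
  overlaps <- vapply(c(0.4, 0.1, 0.02), function(ns) {
    tr <- osc_traj(sol$structure$coords, u, amps, noise_sd = ns, seed = 23)
    mode_overlap(ms$vectors[, 7], compute_pca(tr)$vectors[, 1])
  }, 0)
  expect_true(all(diff(overlaps) > 0))       # overlap -> 1 as noise -> 0
  expect_gt(overlaps[3], 0.99)
})

test_that("DCCM closed forms: in-phase +1, anti-phase -1", {
  base <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  shift <- c(1, 0, 0)
  inphase <- toy_trajectory(list(base,
                                 sweep(base, 2, shift, "+"),
                                 base,
                                 sweep(base, 2, shift, "+")))
  C <- dccm(inphase, fit = FALSE)$matrix
  expect_equal(unname(C[1, 2]), 1, tolerance = 1e-12)

  anti <- lapply(1:4, function(t) {
    X <- base
    X[1, 1] <- X[1, 1] + (-1)^t
    X[2, 1] <- X[2, 1] - (-1)^t
    X
  })
  C2 <- dccm(toy_trajectory(anti), fit = FALSE)$matrix
  expect_equal(unname(C2[1, 2]), -1, tolerance = 1e-12)
})

test_that("DCCM matches the brute-force formula elementwise", {
  set.seed(24)
  base <- matrix(rnorm(15, sd = 5), 5, 3)
  frames <- lapply(1:8, function(i) base + matrix(rnorm(15, sd = .7), 5, 3))
  tr <- toy_trajectory(frames)
  C <- dccm(tr, fit = FALSE)$matrix
  # oracle straight from the definition
  X <- simplify2array(frames)                       # 5 x 3 x 8
  mu <- apply(X, c(1, 2), mean)
  for (i in 1:5) for (j in 1:5) {
    di <- t(X[i, , ]) - matrix(mu[i, ], 8, 3, byrow = TRUE)
    dj <- t(X[j, , ]) - matrix(mu[j, ], 8, 3, byrow = TRUE)
    cij <- mean(rowSums(di * dj)) /
      sqrt(mean(rowSums(di^2)) * mean(rowSums(dj^2)))
    expect_equal(unname(C[i, j]), cij, tolerance = 1e-12)
  }
  expect_equal(C, t(C), tolerance = 1e-12)
  expect_equal(unname(diag(C)), rep(1, 5))
  expect_true(all(C >= -1 & C <= 1))
})

test_that("DCCM flags zero-variance atoms and survives rigid transforms", {
  set.seed(25)
  base <- matrix(rnorm(12, sd = 4), 4, 3)
  frames <- lapply(1:6, function(i) {
    X <- base + matrix(rnorm(12, sd = .5), 4, 3)
    X[4, ] <- base[4, ]                         # frozen atom
    X
  })
  expect_warning(m <- dccm(toy_trajectory(frames), fit = FALSE),
                 "zero displacement variance")
  expect_equal(unname(m$matrix[4, 1:3]), c(0, 0, 0))
  expect_equal(unname(m$matrix[4, 4]), 1)

  # fitted DCCM invariant under per-frame global rigid transforms
  sol <- fx_small_solenoid()
  frames2 <- lapply(1:6, function(i)
    sol$structure$coords + matrix(rnorm(3 * n_atoms(sol$structure),
                                        sd = .3), ncol = 3))
  tr <- toy_trajectory(frames2, topology = sol$structure)
  C0 <- dccm(tr)$matrix
  set.seed(26)
  moved <- lapply(frames2, function(F)
    apply_transform(F, random_rotation(), rnorm(3, sd = 20)))
  C1 <- dccm(toy_trajectory(moved, topology = sol$structure))$matrix
  expect_equal(C1, C0, tolerance = 1e-6)
})

test_that("merge_ensemble concatenates and preserves DCCM idempotence", {
  sol <- fx_small_solenoid()
  set.seed(27)
  frames <- lapply(1:5, function(i)
    sol$structure$coords + matrix(rnorm(3 * n_atoms(sol$structure),
                                        sd = .3), ncol = 3))
  tr <- toy_trajectory(frames, topology = sol$structure)
  m3 <- merge_ensemble(list(tr, tr, tr))
  expect_equal(n_frames(m3), 15L)
  expect_equal(attr(m3, "frame_sources"),
               rep(tr$source_id, 15))
  expect_equal(dccm(m3)$matrix, dccm(tr)$matrix, tolerance = 1e-9)

  # displacement series merge: 61 conformers per mode
  ms <- fx_modes()
  big <- fx_solenoid()
  dss <- lapply(7:9, function(k)
    displace_along_mode(big$structure, ms, k, hessian = fx_hessian()))
  merged <- merge_ensemble(dss)
  expect_equal(n_frames(merged), 183L)
  other <- fx_small_solenoid()
  expect_error(merge_ensemble(list(tr, dss[[1]])), "mismatch")
})
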