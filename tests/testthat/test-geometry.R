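# Bend/twist geometry: radius of curvature, helix vectors, angle series

test_that("radius of curvature closed forms", {
  expect_equal(radius_of_curvature(c(-1, 0, 0), c(0, 1, 0), c(1, 0, 0)), 1,
               tolerance = 1e-12)                    # unit circle
  # d = 5, m = 4 -> R = 25/6
  expect_equal(radius_of_curvature(c(-4, 0, 0), c(0, 3, 0), c(4, 0, 0)),
               25 / 6, tolerance = 1e-12)
  expect_error(radius_of_curvature(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
  expect_error(radius_of_curvature(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincident")
})

test_that("random triples match the general circumradius oracle", {
  set.seed(30)
  n_ok <- 0
  while (n_ok < 20) {
    p <- lapply(1:3, function(i) rnorm(3, sd = 10))
    # keep only clearly non-collinear, near-isoceles-agnostic triples with
    # d > m (the formula's domain)
    d1 <- sqrt(sum((p[[1]] - p[[2]])^2)); d2 <- sqrt(sum((p[[3]] - p[[2]])^2))
    m <- sqrt(sum((p[[1]] - p[[3]])^2)) / 2
    if (abs(d1 - d2) > 1e-6 * (d1 + d2)) {
      # symmetrize: reflect to an isoceles triple so both definitions agree
      mid <- (p[[1]] + p[[3]]) / 2
      u <- (p[[1]] - p[[3]]) / sqrt(sum((p[[1]] - p[[3]])^2))
      w <- p[[2]] - mid; w <- w - sum(w * u) * u
      if (sqrt(sum(w^2)) < 1e-3) next
      p[[2]] <- mid + w                       # apex over the base midpoint
      d1 <- sqrt(sum((p[[1]] - p[[2]])^2))
    }
    if (d1 <= m * 1.001) next
    got <- radius_of_curvature(p[[1]], p[[2]], p[[3]])
    expect_equal(got, oracle_circumradius(p[[1]], p[[2]], p[[3]]),
                 tolerance = 1e-9)
    n_ok <- n_ok + 1
  }
})

test_that("helix vector fitting: ideal, equivariant, noise-tolerant", {
  # 18 residues x 100 degrees = 5 full turns: phases tile the circle, so
  # the principal axis coincides with the helix axis exactly
  z_helix <- function(n = 18, rise = 1.5, radius = 2.3) {
    t <- (seq_len(n) - 1) * 100 * pi / 180
    cbind(radius * cos(t), radius * sin(t), (seq_len(n) - 1) * rise)
  }
  m <- toy_model(z_helix())
  hv <- fit_helix_vector(m, 1:18)
  expect_equal(abs(hv$vector[3]), 1, tolerance = 1e-6)
  expect_gt(hv$vector[3], 0)                     # oriented N -> C (+z)

  R <- oracle_rotation(c(1, 1, 0), 63)
  m2 <- toy_model(z_helix() %*% t(R))
  hv2 <- fit_helix_vector(m2, 1:18)
  expect_equal(hv2$vector, as.vector(R %*% hv$vector), tolerance = 1e-6)

  set.seed(31)
  noisy <- toy_model(z_helix() + matrix(rnorm(54, sd = 0.2), 18, 3))
  hv3 <- fit_helix_vector(noisy, 1:18)
  ang <- acos(min(1, hv3$vector[3])) * 180 / pi
  expect_lt(ang, 3)

  expect_error(fit_helix_vector(m, 1:3), ">= 4")
})

test_that("inter-repeat angles: parallel 0, orthogonal 90, twist ~ 25", {
  two_helix_model <- function(dir2) {
    t <- (0:17) * 100 * pi / 180        # 5 full turns: exact axis
    h1 <- cbind(2.3 * cos(t), 2.3 * sin(t), (0:17) * 1.5)
    R <- diag(3)
    if (dir2 == "x")
      R <- oracle_rotation(c(0, 1, 0), 90)
    h2 <- sweep(h1 %*% t(R), 2, c(40, 0, 0), "+")
    toy_model(rbind(h1, h2))
  }
  ann2 <- structure(list(repeats = list(list(H3 = c(1L, 18L)),
                                        list(H3 = c(19L, 36L))),
                         n_repeats = 2L, residues_per_helix = 18L,
                         helices_per_repeat = 1L), class = "ArmAnnotation")
  a_par <- inter_repeat_angles(two_helix_model("z"), ann2)
  expect_equal(a_par$angle, 0, tolerance = 1e-6)
  a_perp <- inter_repeat_angles(two_helix_model("x"), ann2)
  expect_equal(a_perp$angle, 90, tolerance = 1e-6)
  expect_error(inter_repeat_angles(two_helix_model("z"),
                                   structure(list(repeats = list(list(
                                     H1 = c(1L, 6L))), n_repeats = 1L),
                                     class = "ArmAnnotation"), "H3"),
               "no H3")

  # uniform 25-degree repeat twist shows up in all nine neighbour angles
  sol <- fx_solenoid()
  a <- inter_repeat_angles(sol$structure, sol$annotation)
  expect_equal(a$angle, rep(25, 9), tolerance = 1)
  # torsions are uniform by construction (screw symmetry)
  expect_lt(diff(range(a$torsion)), 1e-6)
})

test_that("geometry is invariant under rigid transforms", {
  sol <- fx_solenoid()
  anch <- default_anchors(sol$structure, sol$annotation)
  g0 <- geometry_series(trajectory(sol$structure,
                                   array(sol$structure$coords,
                                         c(1, 360, 3))),
                        anch, sol$annotation)
  set.seed(32)
  R <- random_rotation(); tv <- rnorm(3, sd = 30)
  moved <- sol$structure
  moved$coords <- apply_transform(moved$coords, R, tv)
  g1 <- geometry_series(trajectory(moved, array(moved$coords,
                                                c(1, 360, 3))),
                        anch, sol$annotation)
  expect_equal(g1$R, g0$R, tolerance = 1e-9)
  expect_equal(unlist(g1[grep("^angle_", names(g1))]),
               unlist(g0[grep("^angle_", names(g0))]), tolerance = 1e-9)
})

test_that("static trajectories give constant geometry rows", {
  sol <- fx_small_solenoid()
  anch <- default_anchors(sol$structure, sol$annotation)
  tr <- trajectory(sol$structure,
                   array(rep(sol$structure$coords, each = 3),
                         c(3, n_atoms(sol$structure), 3)))
  g <- geometry_series(tr, anch, sol$annotation)
  expect_equal(g$R, rep(g$R[1], 3), tolerance = 1e-12)
  expect_equal(g$mean_angle, rep(g$mean_angle[1], 3), tolerance = 1e-12)
})

test_that("bend and twist are geometrically decoupled", {
  sol <- fx_solenoid()
  ann <- sol$annotation
  anch <- default_anchors(sol$structure, ann)

  bend <- simulate_trajectory(sol$structure, ann,
                              motion_spec(bend_amplitude = 8,
                                          twist_amplitude = 0,
                                          noise_sd = 0, n_frames = 40,
                                          period = 40))
  gb <- geometry_series(bend, anch, ann)
  # hinge-adjacent pairs move; all other pairs stay fixed
  angs <- as.matrix(gb[, grep("^angle_", names(gb))])
  ptp <- apply(angs, 2, function(x) diff(range(x)))
  mid <- ceiling(ann$n_repeats / 2)
  straddle <- c(mid - 1L, mid)
  expect_lt(max(ptp[-straddle]), 1e-6)
  expect_gt(max(ptp[straddle]), 1)
  expect_gt(diff(range(gb$R)) / mean(gb$R), 0.05)   # R moves a lot

  twist <- simulate_trajectory(sol$structure, ann,
                               motion_spec(bend_amplitude = 0,
                                           twist_amplitude = 4,
                                           noise_sd = 0, n_frames = 40,
                                           period = 40))
  gt <- geometry_series(twist, anch, ann)
  expect_lt(diff(range(gt$R)) / mean(gt$R), 0.01)   # R ~ constant
  angs_t <- as.matrix(gt[, grep("^angle_", names(gt))])
  ptp_t <- apply(angs_t, 2, function(x) diff(range(x)))
  expect_equal(unname(ptp_t), rep(2 * 4, 9), tolerance = 0.5)
})

test_that("recovered bend ranges order with the generator amplitude", {
  sol <- fx_solenoid()
  ann <- sol$annotation
  anch <- default_anchors(sol$structure, ann)
  ranges <- vapply(c(4, 10), function(A) {
    tr <- simulate_trajectory(sol$structure, ann,
                              motion_spec(bend_amplitude = A,
                                          twist_amplitude = 0,
                                          noise_sd = 0, n_frames = 20,
                                          period = 20))
    diff(range(geometry_series(tr, anch, ann)$R))
  }, 0)
  expect_gt(ranges[2], ranges[1])      # apo-style larger amplitude
})
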