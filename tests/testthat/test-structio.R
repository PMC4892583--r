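# Structure model, PDB round-trips, superposition, RMSD/RMSF

test_that("structure_model enforces its invariants", {
  xyz <- matrix(rnorm(9), 3, 3)
  m <- toy_model(xyz)
  expect_s3_class(m, "StructureModel")
  expect_equal(n_atoms(m), 3L)

  bad <- m$atoms; bad$residue_number <- c(1L, 1L, 2L)
  expect_error(structure_model(bad, xyz), "duplicate")
  expect_error(toy_model(matrix(c(0, 0, NA, 1, 1, 1), 2, 3)), "finite")
  badm <- m$atoms; badm$mass[2] <- 0
  expect_error(structure_model(badm, xyz), "positive")
  expect_error(element_mass("XX"), "unknown element")
})

test_that("trajectory enforces atom count and time ordering", {
  m <- toy_model(matrix(rnorm(12), 4, 3))
  coords <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  tr <- trajectory(m, coords)
  expect_equal(n_frames(tr), 2L)
  expect_error(trajectory(m, array(0, c(2, 5, 3))), "atom count")
  expect_error(trajectory(m, coords, times = c(10, 10)),
               "strictly increasing")
})

test_that("PDB write/read round-trips a model and a trajectory", {
  set.seed(1)
  coords <- round(matrix(rnorm(30, sd = 20), 10, 3), 3)
  atoms <- data.frame(
    serial = 1:10,
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "NZ", "OE1", "H"),
    residue_name = c(rep("LYS", 5), rep("LEU", 5)),
    residue_number = c(rep(7L, 5), rep(8L, 5)),
    chain_id = "A",
    element = c("N", "C", "C", "O", "C", "C", "C", "N", "O", "H"),
    stringsAsFactors = FALSE)
  atoms$mass <- element_mass(atoms$element)
  m <- structure_model(atoms, coords)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, p)
  m2 <- read_pdb(p)
  expect_identical(m2$atoms[, names(atoms)], atoms)
  expect_equal(m2$coords, m$coords, tolerance = 1e-12)  # already 3-dec

  tr <- toy_trajectory(list(coords, coords + 1, coords - 2), topology = m)
  write_pdb(tr, p)
  expect_identical(sum(grepl("^MODEL", readLines(p))), 3L)
  tr2 <- read_pdb(p)
  expect_equal(n_frames(tr2), 3L)
  expect_equal(tr2$coords, tr$coords, tolerance = 5e-4)  # fixed width
})

test_that("PDB parser reports malformed and inconsistent input", {
  p <- withr::local_tempfile(fileext = ".pdb")
  m <- toy_model(matrix(rnorm(9), 3, 3))
  tr <- toy_trajectory(list(m$coords, m$coords), topology = m)
  write_pdb(tr, p)
  lines <- readLines(p)
  # drop one atom from MODEL 2 -> topology error
  writeLines(lines[-8], p)
  expect_error(read_pdb(p), "inconsistent atom count")
  # corrupt a coordinate field -> parse error with line number
  lines2 <- readLines(p)
  atom_line <- grep("^ATOM", lines2)[1]
  substr(lines2[atom_line], 31, 38) <- "   abc  "
  writeLines(lines2, p)
  expect_error(read_pdb(p), "line")
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("write_pdb rejects coordinates too wide for the format", {
  m <- toy_model(matrix(c(99999, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE))
  expect_error(write_pdb(m, withr::local_tempfile()), "10000")
})

test_that("superpose recovers rigid transforms and is idempotent", {
  set.seed(2)
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  m <- toy_model(P)
  expect_equal(superpose(m, m)$rmsd, 0, tolerance = 1e-12)

  R <- oracle_rotation(c(0, 0, 1), 90)
  rot <- toy_model(P %*% t(R) + 3)
  fit <- superpose(rot, m)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # idempotence: re-fitting an already-fitted mobile barely moves
  refit <- superpose(fit$transformed, m)
  expect_lt(abs(refit$rmsd - fit$rmsd), 1e-9)

  # collinear selection is rejected
  line <- toy_model(cbind(1:5, 0, 0))
  expect_error(superpose(line, line), "collinear")
})

test_that("superpose matches a brute-force rotation-search oracle", {
  set.seed(3)
  Q <- matrix(rnorm(12, sd = 3), 4, 3)
  P <- Q
  P[4, ] <- P[4, ] + c(1, 0, 0)     # one point offset by 1 A
  R <- random_rotation()
  P <- P %*% t(R) + 5
  got <- superpose(toy_model(P), toy_model(Q))$rmsd
  expect_equal(got, oracle_fit_rmsd(P, Q), tolerance = 1e-3)
})

test_that("RMSD is invariant under common rigid transforms", {
  set.seed(4)
  for (k in 1:5) {
    A <- toy_model(matrix(rnorm(24, sd = 4), 8, 3))
    B <- toy_model(A$coords + matrix(rnorm(24, sd = 1), 8, 3))
    base <- rmsd(A, B)
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    A2 <- toy_model(apply_transform(A$coords, R, t))
    B2 <- toy_model(apply_transform(B$coords, R, t))
    expect_equal(rmsd(A2, B2), base, tolerance = 1e-6)
    # unfitted RMSD is invariant too when both move together
    expect_equal(rmsd(A2, B2, fit = FALSE), rmsd(A, B, fit = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("rmsd_series handles fitting and matches the direct formula", {
  set.seed(5)
  ref <- toy_model(matrix(rnorm(15, sd = 3), 5, 3))
  same <- toy_trajectory(list(ref$coords, ref$coords, ref$coords),
                         topology = ref)
  expect_equal(rmsd_series(same, ref), c(0, 0, 0), tolerance = 1e-12)

  shifted <- toy_trajectory(list(sweep(ref$coords, 2, c(-3, 0, 0))),
                            topology = ref)
  expect_equal(rmsd_series(shifted, ref, fit = TRUE), 0, tolerance = 1e-9)
  expect_equal(rmsd_series(shifted, ref, fit = FALSE), 3, tolerance = 1e-12)

  frames <- lapply(1:5, function(i) ref$coords + matrix(rnorm(15), 5, 3))
  tr <- toy_trajectory(frames, topology = ref)
  direct <- vapply(frames, function(F)
    sqrt(mean(rowSums((F - ref$coords)^2))), 0)
  expect_equal(rmsd_series(tr, ref, fit = FALSE), direct, tolerance = 1e-12)
  expect_error(rmsd_series(tr, ref, sel = atom_selection(chain = "Z")),
               "empty")
})

test_that("rmsf closed forms, oracle and scaling property", {
  set.seed(6)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  const <- toy_trajectory(list(base, base, base))
  expect_equal(rmsf(const), rep(0, 10), tolerance = 1e-9)
  expect_error(rmsf(toy_trajectory(list(base))), "2 frames")

  # one atom alternating +-1 A on x, others fixed (pre-aligned frames)
  up <- base; up[1, 1] <- up[1, 1] + 1
  dn <- base; dn[1, 1] <- dn[1, 1] - 1
  r <- rmsf(toy_trajectory(list(up, dn, up, dn)), fit = FALSE)
  expect_equal(r, c(1, rep(0, 9)), tolerance = 1e-12)

  # brute-force definition oracle on a random 10-frame toy
  frames <- lapply(1:10, function(i) base + matrix(rnorm(30, sd = .5), 10, 3))
  tr <- toy_trajectory(frames)
  X <- simplify2array(frames)                    # 10 x 3 x nf
  mu <- apply(X, c(1, 2), mean)
  oracle <- sqrt(sapply(1:10, function(j)
    mean(colSums((X[j, , ] - mu[j, ])^2))))
  expect_equal(rmsf(tr, fit = FALSE), oracle, tolerance = 1e-12)

  # rmsf >= 0 and |c|-scaling of displacements
  dev <- lapply(frames, function(F) F - base)
  sc <- toy_trajectory(lapply(dev, function(D) base - 2.5 * D))
  expect_true(all(rmsf(tr, fit = FALSE) >= 0))
  expect_equal(rmsf(sc, fit = FALSE), 2.5 * rmsf(tr, fit = FALSE),
               tolerance = 1e-9)

  # fitted RMSF is invariant under per-frame rigid shuffling
  shuf <- toy_trajectory(lapply(frames, function(F) {
    apply_transform(F, random_rotation(), rnorm(3, sd = 8))
  }))
  expect_equal(rmsf(shuf), rmsf(tr), tolerance = 1e-6)
})

test_that("selection strings resolve to sorted unique indices", {
  sol <- fx_small_solenoid()
  idx <- resolve_selection(sol$structure, "A:1-10:CA")
  expect_identical(idx, 1:10)
  expect_identical(resolve_selection(sol$structure, "A:*:CA"),
                   seq_len(n_atoms(sol$structure)))
  two <- resolve_selection(sol$structure, "A:3:CA,A:1:CA")
  expect_identical(two, c(1L, 3L))
  expect_error(parse_selection("A:1"), "triplet")
})
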