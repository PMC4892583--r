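# Shared fixtures (built once per test run) and independent oracles.
# Oracle code deliberately avoids the package's own implementations.

.fx <- new.env(parent = emptyenv())

fx_solenoid <- function() {
  if (is.null(.fx$sol)) .fx$sol <- build_solenoid(solenoid_spec())
  .fx$sol
}

fx_small_solenoid <- function() {
  if (is.null(.fx$small))
    .fx$small <- build_solenoid(solenoid_spec(n_repeats = 4,
                                              residues_per_helix = 6))
  .fx$small
}

fx_modes <- function() {
  if (is.null(.fx$modes)) {
    sol <- fx_solenoid()
    .fx$hessian <- build_hessian(sol$structure, enm_params())
    .fx$modes <- compute_modes(.fx$hessian, n_requested = 20L)
  }
  .fx$modes
}

fx_hessian <- function() { fx_modes(); .fx$hessian }

# quick Calpha-only model from a coordinate matrix
toy_model <- function(coords, chain = "A", element = "C",
                      atom_name = "CA", resname = "GLY") {
  n <- nrow(coords)
  structure_model(data.frame(
    serial = seq_len(n), atom_name = atom_name, residue_name = resname,
    residue_number = seq_len(n), chain_id = chain, element = element,
    mass = element_mass(rep(element, n)), stringsAsFactors = FALSE),
    coords)
}

toy_trajectory <- function(frames, topology = NULL, ...) {
  # frames: list of n x 3 matrices
  n <- nrow(frames[[1]])
  if (is.null(topology)) topology <- toy_model(frames[[1]])
  coords <- array(0, dim = c(length(frames), n, 3L))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  trajectory(topology, coords, ...)
}

# --- independent rotation oracle (quaternion construction, not Rodrigues)
oracle_rotation <- function(axis, angle_deg) {
  th <- angle_deg * pi / 360            # half angle, radians
  u <- axis / sqrt(sum(axis^2))
  w <- cos(th); x <- sin(th) * u[1]; y <- sin(th) * u[2]; z <- sin(th) * u[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  oracle_rotation(ax, stats::runif(1, 0, 360))
}

# --- brute-force rigid-fit RMSD oracle: Euler-angle optimisation with
# multi-start Nelder-Mead over centered coordinates (no SVD/Kabsch)
oracle_fit_rmsd <- function(P, Q, n_starts = 40) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(a) mean(rowSums((Pc %*% t(euler(a)) - Qc)^2))
  best <- Inf
  for (s in seq_len(n_starts)) {
    a0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(a0, f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# --- circumradius of a triangle from side lengths: |a||b||c| / (4 * area)
oracle_circumradius <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  c <- sqrt(sum((p1 - p2)^2))
  s <- (a + b + c) / 2
  area <- sqrt(s * (s - a) * (s - b) * (s - c))
  a * b * c / (4 * area)
}

# --- direct collectivity formula oracle
oracle_collectivity <- function(v3n) {
  n <- length(v3n) / 3
  u2 <- colSums(matrix(v3n, 3, n)^2)  # v3n as (x1,y1,z1,x2,...)
  alpha <- 1 / sum(u2)
  p <- alpha * u2
  p <- p[p > 0]
  exp(-sum(p * log(p))) / n
}

# hinge oracle: radius-of-curvature extrema of a pure bend of half-angle
# amplitude A about the anchor-plane normal through the middle anchor
oracle_bend_R <- function(anchors_xyz, A_deg, phase) {
  pN <- anchors_xyz[1, ]; pM <- anchors_xyz[2, ]; pC <- anchors_xyz[3, ]
  ax <- pracma_cross_test(pN - pM, pC - pM)
  ax <- ax / sqrt(sum(ax^2))
  RN <- oracle_rotation(ax, -A_deg * phase)
  RC <- oracle_rotation(ax, A_deg * phase)
  qN <- as.vector(RN %*% (pN - pM)) + pM
  qC <- as.vector(RC %*% (pC - pM)) + pM
  oracle_circumradius(qN, pM, qC)
}

# minimal hydrogen-bond frame: donor D at origin, hydrogen H, acceptor A
# placed at the requested donor-acceptor distance and D-H-A deviation
hb_frame <- function(da_dist, dev_deg) {
  D <- c(0, 0, 0)
  H <- c(1, 0, 0)
  th <- (180 - dev_deg) * pi / 180
  v <- c(cos(pi - th), sin(pi - th), 0)  # H -> A direction
  w <- H - D
  b <- 2 * sum(w * v); cc <- sum(w^2) - da_dist^2
  t <- (-b + sqrt(b^2 - 4 * cc)) / 2
  A <- H + t * v
  atoms <- data.frame(
    serial = 1:3, atom_name = c("N", "H", "O"),
    residue_name = c("GLY", "GLY", "ALA"),
    residue_number = c(1L, 1L, 2L), chain_id = c("A", "A", "B"),
    element = c("N", "H", "O"), stringsAsFactors = FALSE)
  atoms$mass <- element_mass(atoms$element)
  structure_model(atoms, rbind(D, H, A))
}

hb_cand <- data.frame(donor = 1L, hydrogen = 2L, acceptor = 3L)

pracma_cross_test <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
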