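## Calpha anisotropic elastic-network normal modes: a desk-scale stand-in
## for all-atom vibrational analysis. Hookean springs connect Calpha pairs
## within a cutoff; the 3N x 3N Hessian's low-frequency eigenvectors are
## the collective motions, numbered 1-based with modes 1-6 the rigid-body
## modes, so "mode 7" is the first internal mode (the convention used when
## relating bending to NM7 and twisting to NM9). Each mode carries a
## degree of collectivity; conformers are generated along a mode on a
## mass-weighted RMS (MRMS) displacement grid and screened by their
## elastic (restraint) energy.

#' Elastic-network parameters
#'
#' @param cutoff spring inclusion radius in Angstrom (default 10, matching
#'   the conventional nonbonded cutoff; not claimed equivalent to an
#'   all-atom force field).
#' @param gamma uniform spring constant (arbitrary energy/A^2 unit).
#' @param mass_weighting build the mass-weighted Hessian
#'   `M^-1/2 H M^-1/2` (default TRUE; immaterial for an equal-mass
#'   Calpha trace up to a uniform eigenvalue scale).
#' @return object of class `EnmParams`.
#' @export
enm_params <- function(cutoff = 10, gamma = 1, mass_weighting = TRUE) {
  stopifnot(cutoff > 0, gamma > 0)
  structure(list(cutoff = cutoff, gamma = gamma,
                 mass_weighting = mass_weighting), class = "EnmParams")
}

# connected components of the spring network (adjacency list BFS)
.network_components <- function(pairs, n) {
  comp <- integer(n)
  adj <- vector("list", n)
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Build the elastic-network Hessian
#'
#' Anisotropic network model: for each atom pair within `cutoff`, the
#' off-diagonal 3x3 superblock is `-gamma * r_hat %*% t(r_hat)`; diagonal
#' superblocks make every superblock row sum to zero (translational
#' invariance). With `mass_weighting` the result is `M^-1/2 H M^-1/2`.
#' A disconnected network is allowed with a warning (it contributes
#' `6 * components` zero modes).
#'
#' @param structure a `StructureModel` (>= 2 atoms).
#' @param params an [enm_params()].
#' @return 3N x 3N symmetric matrix with attributes `masses`,
#'   `mass_weighted`, `gamma` and `n_components`.
#' @export
build_hessian <- function(structure, params = enm_params()) {
  X <- structure$coords
  n <- nrow(X)
  if (n < 2L) stop("elastic network needs >= 2 atoms")
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  within <- d2 <= params$cutoff^2 & upper.tri(d2)
  pairs <- which(within, arr.ind = TRUE)
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    r <- X[j, ] - X[i, ]
    r <- r / sqrt(sum(r^2))
    blk <- -params$gamma * tcrossprod(r)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk; H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  comp <- .network_components(pairs, n)
  ncomp <- max(comp)
  if (ncomp > 1L)
    warning("elastic network is disconnected: ", ncomp, " components (",
            6L * ncomp, " zero modes expected)")
  masses <- structure$atoms$mass
  if (params$mass_weighting) {
    w <- 1 / sqrt(rep(masses, each = 3L))
    H <- H * tcrossprod(w)
  }
  attr(H, "masses") <- masses
  attr(H, "mass_weighted") <- params$mass_weighting
  attr(H, "gamma") <- params$gamma
  attr(H, "n_components") <- ncomp
  H
}

#' Degree of collectivity of a displacement vector
#'
#' Entropy-based measure of how many atoms participate in a motion:
#' `kappa = N^-1 * exp(-sum_i alpha*u_i^2 * log(alpha*u_i^2))`, where
#' `u_i^2` is the squared displacement magnitude of atom i and `alpha`
#' normalizes `sum_i alpha*u_i^2 = 1`. Ranges over (0, 1]: 1 when every
#' atom moves with the same amplitude, 1/N when a single atom moves.
#' Invariant under rigid rotation of the structure, mode sign flip and
#' overall scaling.
#'
#' @param mode numeric displacement vector of length 3N (or an N x 3
#'   matrix), nonzero.
#' @param masses optional per-atom masses; when given, `u` is first
#'   un-mass-weighted (`u_i / sqrt(m_i)`) so that collectivity refers to
#'   real-space displacements of a mass-weighted eigenvector.
#' @return collectivity in (0, 1].
#' @export
collectivity <- function(mode, masses = NULL) {
  if (is.matrix(mode)) mode <- as.vector(t(mode))
  if (length(mode) %% 3L != 0L) stop("mode length must be a multiple of 3")
  n <- length(mode) %/% 3L
  u2 <- rowSums(matrix(mode, n, 3L, byrow = TRUE)^2)
  if (!is.null(masses)) {
    stopifnot(length(masses) == n)
    u2 <- u2 / masses
  }
  s <- sum(u2)
  if (s <= 0) stop("zero displacement vector")
  p <- u2 / s
  nz <- p > 0
  exp(-sum(p[nz] * log(p[nz]))) / n
}

#' Compute the lowest-frequency normal modes
#'
#' Eigen-decomposition of the (mass-weighted) Hessian, returning the
#' lowest `n_requested + 6` eigenpairs in ascending eigenvalue order.
#' Modes are numbered 1-based; for a connected network modes 1-6 are the
#' rigid-body modes, so mode 7 is the first internal mode. Collectivity
#' is computed per non-rigid mode (NA for rigid modes).
#'
#' @param hessian matrix from [build_hessian()].
#' @param n_requested number of non-rigid modes wanted (default 87, the
#'   number of low-frequency modes analysed per reference structure).
#' @return object of class `ModeSet`: `eigenvalues`, `vectors` (3N x k,
#'   orthonormal columns), `mode_id`, `rigid` (logical), `collectivity`,
#'   `n_rigid`, `masses`, `mass_weighted`.
#' @export
compute_modes <- function(hessian, n_requested = 87L) {
  n3 <- nrow(hessian)
  n_zero_expected <- 6L * max(1L, attr(hessian, "n_components") %||% 1L)
  k <- n_requested + n_zero_expected
  if (k > n3)
    stop("n_requested + ", n_zero_expected, " rigid modes exceeds 3N = ", n3)
  e <- eigen(hessian, symmetric = TRUE)
  ord <- rev(seq_len(n3))                       # ascending eigenvalues
  vals <- e$values[ord][seq_len(k)]
  vecs <- e$vectors[, ord, drop = FALSE][, seq_len(k), drop = FALSE]
  if (any(vals < -1e-8 * max(abs(e$values))))
    warning("negative eigenvalue(s) beyond the numerical floor")
  tol <- 1e-8 * max(abs(e$values))
  rigid <- vals < tol
  masses <- attr(hessian, "masses")
  coll <- rep(NA_real_, k)
  for (i in which(!rigid))
    coll[i] <- collectivity(vecs[, i],
                            if (isTRUE(attr(hessian, "mass_weighted")))
                              masses else NULL)
  structure(list(eigenvalues = vals, vectors = vecs,
                 mode_id = seq_len(k), rigid = rigid, collectivity = coll,
                 n_rigid = sum(rigid), masses = masses,
                 mass_weighted = isTRUE(attr(hessian, "mass_weighted"))),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat("ModeSet:", length(x$eigenvalues), "modes (", x$n_rigid,
      "rigid );  first internal mode:", which(!x$rigid)[1], "\n")
  invisible(x)
}

#' Summary table of a mode set
#' @param object a `ModeSet`.
#' @param ... unused.
#' @return data.frame: mode, eigenvalue, rigid flag, collectivity.
#' @export
summary.ModeSet <- function(object, ...) {
  data.frame(mode = object$mode_id, eigenvalue = object$eigenvalues,
             rigid = object$rigid, collectivity = object$collectivity)
}

# real-space displacement direction of mode i, scaled to unit MRMS
# (mass-weighted RMS displacement = sqrt(sum m_i |dx_i|^2 / sum m_i) = 1)
.mode_direction_unit_mrms <- function(modes, i) {
  v <- modes$vectors[, i]
  n <- length(v) %/% 3L
  m <- modes$masses
  dx <- matrix(v, n, 3L, byrow = TRUE)
  if (modes$mass_weighted) dx <- dx / sqrt(m)
  mrms <- sqrt(sum(m * rowSums(dx^2)) / sum(m))
  dx / mrms
}

#' Generate conformers along a normal mode
#'
#' Displaces the structure along one internal mode on a symmetric MRMS
#' grid `-max_range .. +max_range` in steps of `step` (defaults 3.0 and
#' 0.1 Angstrom: 61 conformers). The realized mass-weighted RMS
#' displacement of each conformer equals its grid value. Each conformer's
#' restraint energy is its harmonic network energy relative to the input,
#' normalized by total mass so that a pure-mode displacement satisfies
#' `E = 1/2 * lambda * MRMS^2` exactly; conformers above the 90th energy
#' percentile are flagged unfavorable.
#'
#' @param structure the `StructureModel` the modes were computed on.
#' @param modes a `ModeSet`.
#' @param mode_id 1-based mode number (must be non-rigid).
#' @param max_range maximum MRMS displacement per direction (A).
#' @param step grid step (A), in (0, max_range].
#' @param hessian optional Hessian for the energy (rebuilt if omitted);
#'   pass the one the modes came from.
#' @param params used to rebuild the Hessian when `hessian` is missing.
#' @return object of class `DisplacementSeries`: `mode_id`, `mrms_grid`,
#'   `coords` (n_grid x N x 3), `restraint_energy`, `unfavorable`
#'   (logical), `topology`.
#' @export
displace_along_mode <- function(structure, modes, mode_id,
                                max_range = 3.0, step = 0.1,
                                hessian = NULL, params = enm_params()) {
  if (step <= 0 || step > max_range)
    stop("step must be in (0, max_range]")
  i <- match(mode_id, modes$mode_id)
  if (is.na(i)) stop("mode ", mode_id, " not in ModeSet")
  if (modes$rigid[i]) stop("mode ", mode_id, " is a rigid-body mode")
  if (is.null(hessian)) hessian <- build_hessian(structure, params)

  nsteps <- round(max_range / step)
  grid <- seq(-nsteps, nsteps) * step            # symmetric, includes 0
  u <- .mode_direction_unit_mrms(modes, i)       # unit-MRMS direction
  n <- nrow(u)
  m <- modes$masses
  total_mass <- sum(m)

  # energy of displacement dx: 1/2 dx' H dx (un-mass-weighted H), per amu
  Hplain <- hessian
  if (isTRUE(attr(hessian, "mass_weighted"))) {
    w <- sqrt(rep(m, each = 3L))
    Hplain <- hessian * tcrossprod(w)
  }
  uvec <- as.vector(t(u))
  e_unit <- 0.5 * sum(uvec * (Hplain %*% uvec)) / total_mass

  coords <- array(0, dim = c(length(grid), n, 3L))
  for (g in seq_along(grid)) coords[g, , ] <- structure$coords + grid[g] * u
  energy <- e_unit * grid^2
  structure(list(mode_id = mode_id, mrms_grid = grid, coords = coords,
                 restraint_energy = energy,
                 unfavorable = energy > stats::quantile(energy, 0.9),
                 topology = structure),
            class = "DisplacementSeries")
}

#' Convert a displacement series to a trajectory
#' @param series a `DisplacementSeries`.
#' @return a `Trajectory` whose frames are the grid conformers in order.
#' @export
as_trajectory <- function(series) {
  stopifnot(inherits(series, "DisplacementSeries"))
  trajectory(series$topology, series$coords,
             times = seq_along(series$mrms_grid) - 1,
             source_id = paste0("mode", series$mode_id))
}

#' Restraint-energy map over a range of modes
#'
#' One row per internal mode, one column per MRMS grid point: the
#' harmonic restraint energy of the conformer displaced to that MRMS
#' along that mode. Rows are minimal at MRMS 0 and, for a harmonic
#' network, non-decreasing in |MRMS|; lower-eigenvalue modes bound
#' higher-eigenvalue modes from below at every grid point.
#'
#' @param structure the `StructureModel` the modes were computed on.
#' @param modes a `ModeSet`.
#' @param mode_ids internal mode numbers (default: all non-rigid modes).
#' @param max_range,step grid as in [displace_along_mode()].
#' @param params used to build the Hessian once for all modes.
#' @return numeric matrix (modes x grid) with dimnames, plus attribute
#'   `mrms_grid`.
#' @export
restraint_energy_map <- function(structure, modes, mode_ids = NULL,
                                 max_range = 3.0, step = 0.1,
                                 params = enm_params()) {
  if (is.null(mode_ids)) mode_ids <- modes$mode_id[!modes$rigid]
  if (length(mode_ids) < 1L) stop("need at least one non-rigid mode")
  H <- build_hessian(structure, params)
  rows <- lapply(mode_ids, function(k)
    displace_along_mode(structure, modes, k, max_range, step,
                        hessian = H)$restraint_energy)
  out <- do.call(rbind, rows)
  grid <- displace_along_mode(structure, modes, mode_ids[1], max_range,
                              step, hessian = H)$mrms_grid
  dimnames(out) <- list(paste0("mode", mode_ids),
                        sprintf("%.1f", grid))
  attr(out, "mrms_grid") <- grid
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
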