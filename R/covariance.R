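## PCA of Calpha displacement covariance, normal-mode / principal-component
## overlap, and residue-residue dynamic cross-correlation maps (DCCM).

#' Principal component analysis of a trajectory
#'
#' Frames are superposed on their ensemble mean over the selection (fit
#' to frame 1, then one re-fit to the running mean), the 3N x 3N
#' covariance matrix of atomic displacements is formed, and its
#' eigenpairs are returned in descending variance order (PC numbering is
#' 1-based: PC1 carries the most variance).
#'
#' @param traj a `Trajectory` with >= 2 frames.
#' @param sel atom selection (default all; pass a Calpha selection for
#'   the conventional analysis).
#' @param n_components number of components to keep (default all).
#' @param fit superpose frames on their mean first (default TRUE);
#'   disable for pre-aligned ensembles.
#' @return object of class `PcaResult`: `eigenvalues` (variances, A^2,
#'   descending), `vectors` (3N x k orthonormal), `mode_id`,
#'   `var_explained`, `total_variance`, `mean_coords`, `sel_idx`.
#' @export
compute_pca <- function(traj, sel = NULL, n_components = NULL, fit = TRUE) {
  if (n_frames(traj) < 2L) stop("PCA needs at least 2 frames")
  idx <- resolve_selection(traj, sel)
  X <- .fitted_frames(traj, idx, fit = fit)      # nf x n x 3
  nf <- dim(X)[1]; n <- dim(X)[2]
  flat <- matrix(X, nf, 3L * n)                  # column-major: atom-major
  # reorder to (x1,y1,z1,x2,...) for interoperability with mode vectors
  perm <- as.vector(t(matrix(seq_len(3L * n), n, 3L)))
  flat <- flat[, perm, drop = FALSE]
  mu <- colMeans(flat)
  D <- sweep(flat, 2L, mu)
  C <- crossprod(D) / nf
  e <- eigen(C, symmetric = TRUE)                # descending
  k <- if (is.null(n_components)) length(e$values) else
    min(n_components, length(e$values))
  vals <- pmax(e$values[seq_len(k)], 0)
  mean_coords <- matrix(mu, n, 3L, byrow = TRUE)
  structure(list(eigenvalues = vals,
                 vectors = e$vectors[, seq_len(k), drop = FALSE],
                 mode_id = seq_len(k),
                 var_explained = vals / sum(pmax(e$values, 0)),
                 total_variance = sum(pmax(e$values, 0)),
                 mean_coords = mean_coords, sel_idx = idx),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult:", length(x$eigenvalues), "components; PC1-3 explain",
      sprintf("%.1f%%", 100 * sum(x$var_explained[1:min(3,
              length(x$var_explained))])), "of the variance\n")
  invisible(x)
}

#' Overlap between two displacement directions
#'
#' Absolute normalized dot product between, e.g., a normal-mode
#' eigenvector and a principal component — 1 for identical directions,
#' 0 for orthogonal ones. Both vectors must use the same atom ordering
#' and the `(x1, y1, z1, x2, ...)` component layout.
#'
#' @param a,b numeric vectors of equal length (or N x 3 matrices),
#'   nonzero.
#' @return overlap in \[0, 1\].
#' @export
mode_overlap <- function(a, b) {
  if (is.matrix(a)) a <- as.vector(t(a))
  if (is.matrix(b)) b <- as.vector(t(b))
  if (length(a) != length(b)) stop("vectors must have equal dimension")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector")
  abs(sum(a * b)) / (na * nb)
}

#' Dynamic cross-correlation map
#'
#' After superposing all frames on their mean, computes per residue pair
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2> <dr_j^2>)` from the Calpha (or
#' selected-atom) displacement vectors. Entries lie in \[-1, 1\], the
#' diagonal is 1. Atoms with displacement variance below `zero_var_tol`
#' get zero off-diagonal entries and are flagged.
#'
#' @param traj a `Trajectory` with >= 2 frames.
#' @param sel atom selection (one atom per residue; default all atoms).
#' @param zero_var_tol variance floor in A^2 (default 1e-12).
#' @param fit superpose frames on their mean first (default TRUE);
#'   disable for pre-aligned ensembles.
#' @return object of class `CorrelationMap`: `matrix` (with residue
#'   labels), `labels`, `zero_variance` (logical per atom).
#' @export
dccm <- function(traj, sel = NULL, zero_var_tol = 1e-12, fit = TRUE) {
  if (n_frames(traj) < 2L) stop("DCCM needs at least 2 frames")
  idx <- resolve_selection(traj, sel)
  X <- .fitted_frames(traj, idx, fit = fit)
  nf <- dim(X)[1]; n <- dim(X)[2]
  mu <- apply(X, c(2, 3), mean)
  # inner products <dr_i . dr_j> accumulated over the three components
  G <- matrix(0, n, n)
  for (c3 in 1:3) {
    Dc <- X[, , c3] - matrix(mu[, c3], nf, n, byrow = TRUE)
    G <- G + crossprod(Dc) / nf
  }
  v <- diag(G)
  dead <- v < zero_var_tol
  denom <- sqrt(outer(pmax(v, zero_var_tol), pmax(v, zero_var_tol)))
  C <- G / denom
  C[dead, ] <- 0; C[, dead] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  at <- traj$topology$atoms[idx, ]
  labels <- paste0(at$chain_id, at$residue_number)
  dimnames(C) <- list(labels, labels)
  if (any(dead))
    warning(sum(dead), " atom(s) with zero displacement variance; their ",
            "off-diagonal correlations are set to 0")
  structure(list(matrix = C, labels = labels, zero_variance = dead),
            class = "CorrelationMap")
}

#' @export
print.CorrelationMap <- function(x, ...) {
  cat("CorrelationMap:", nrow(x$matrix), "x", ncol(x$matrix),
      "; range", sprintf("[%.2f, %.2f]\n",
                         min(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Merge trajectories or displacement series into one pseudo-trajectory
#'
#' Concatenates frames in the given order over a shared topology,
#' recording the originating `source_id` per frame — the ensemble used
#' for cross-correlation and occupancy analysis (all MD runs into one
#' pseudo-trajectory; all mode-displacement conformers into another).
#'
#' @param xs list of `Trajectory` and/or `DisplacementSeries` objects.
#' @param source_id label of the merged ensemble.
#' @return a `Trajectory` with attribute `frame_sources`.
#' @export
merge_ensemble <- function(xs, source_id = "ensemble") {
  if (inherits(xs, c("Trajectory", "DisplacementSeries"))) xs <- list(xs)
  xs <- lapply(xs, function(x)
    if (inherits(x, "DisplacementSeries")) as_trajectory(x) else x)
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "Trajectory")))
  na <- vapply(xs, n_atoms, 1L)
  if (length(unique(na)) != 1L)
    stop("topology mismatch: atom counts ", paste(na, collapse = ", "))
  nf <- vapply(xs, n_frames, 1L)
  coords <- array(0, dim = c(sum(nf), na[1], 3L))
  srcs <- character(sum(nf))
  at <- 0L
  for (x in xs) {
    k <- n_frames(x)
    coords[at + seq_len(k), , ] <- x$coords
    srcs[at + seq_len(k)] <- x$source_id
    at <- at + k
  }
  out <- trajectory(xs[[1]]$topology, coords,
                    times = (seq_len(sum(nf)) - 1) * 10,
                    source_id = source_id)
  attr(out, "frame_sources") <- srcs
  out
}

#' Write a correlation map as CSV
#' @param map a `CorrelationMap`.
#' @param path output CSV path (residue labels as header and first column).
#' @return `path`, invisibly.
#' @export
write_dccm_csv <- function(map, path) {
  df <- data.frame(residue = map$labels, map$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
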