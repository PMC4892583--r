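## Reference-structure clustering (Lyman-Zuckerman) of merged trajectories
## and the per-trajectory convergence check: sample a random remaining
## frame as a reference, remove everything within an RMSD cutoff d of it,
## repeat until no frames remain; then assign every frame to its nearest
## reference and tabulate per-run cluster frequencies. Convergence is
## assessed by how equally each reference is represented in each run.

#' Clustering parameters
#'
#' @param d_cutoff RMSD cutoff d in Angstrom (default 2.5, the value used
#'   to keep the reference count feasible for subsequent normal-mode
#'   analysis of importin-alpha).
#' @param selection atom selection for the RMSD (default all atoms; use
#'   `"A:*:CA"` or [atom_selection()] with `atoms = "CA"` for a Calpha
#'   RMSD, the quantity the procedure was defined on).
#' @param fit_before_rmsd superpose each frame pair before the RMSD
#'   (default TRUE; unfitted RMSD would conflate rigid drift with
#'   conformational change).
#' @param seed RNG seed for the uniform random reference sampling.
#' @return object of class `ClusterParams`.
#' @export
cluster_params <- function(d_cutoff = 2.5, selection = NULL,
                           fit_before_rmsd = TRUE, seed = 1L) {
  stopifnot(d_cutoff > 0)
  structure(list(d_cutoff = d_cutoff, selection = selection,
                 fit_before_rmsd = fit_before_rmsd, seed = as.integer(seed)),
            class = "ClusterParams")
}

# frame coordinates over the selection as a list of n x 3 matrices
.frame_mats <- function(traj, idx) {
  lapply(seq_len(n_frames(traj)), function(i) {
    P <- traj$coords[i, idx, , drop = TRUE]
    dim(P) <- c(length(idx), 3L)
    P
  })
}

.pair_rmsd <- function(P, Q, fit) {
  if (fit) .kabsch(P, Q)$rmsd else sqrt(mean(rowSums((P - Q)^2)))
}

#' Reference-structure clustering of one or more trajectories
#'
#' Merges the trajectories, then repeatedly: samples one remaining frame
#' uniformly at random (seeded) as a reference, and removes all frames
#' (including the reference) whose RMSD to it is below `d_cutoff`. When
#' no frames remain, every original frame is assigned to its nearest
#' reference (ties broken by lowest reference index) and per-source
#' cluster frequencies are tabulated.
#'
#' @param trajs a `Trajectory` or list of them sharing one topology.
#' @param params a [cluster_params()].
#' @return object of class `ClusterResult`: `references` (data.frame of
#'   source/frame/time per reference plus `structures`, a list of
#'   `StructureModel`s), `assignment` (per merged frame: reference index),
#'   `frame_sources`, `frequencies` (source x reference matrix of
#'   fractions summing to 1 per row), and `params`.
#' @export
lz_cluster <- function(trajs, params = cluster_params()) {
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  na <- vapply(trajs, n_atoms, 1L)
  if (length(unique(na)) != 1L)
    stop("topology mismatch across trajectories: atom counts ",
         paste(na, collapse = ", "))
  nm0 <- trajs[[1]]$topology$atoms$atom_name
  for (tr in trajs[-1])
    if (!identical(tr$topology$atoms$atom_name, nm0))
      stop("topology mismatch across trajectories: atom names differ")

  idx <- resolve_selection(trajs[[1]], params$selection)
  mats <- list(); src <- character(0); frame_no <- integer(0); tms <- numeric(0)
  for (tr in trajs) {
    mats <- c(mats, .frame_mats(tr, idx))
    src <- c(src, rep(tr$source_id, n_frames(tr)))
    frame_no <- c(frame_no, seq_len(n_frames(tr)))
    tms <- c(tms, tr$times)
  }
  n <- length(mats)

  set.seed(params$seed)
  remaining <- seq_len(n)
  refs <- integer(0)
  while (length(remaining) > 0L) {
    pick <- remaining[sample.int(length(remaining), 1L)]
    refs <- c(refs, pick)
    d <- vapply(remaining, function(i)
      .pair_rmsd(mats[[i]], mats[[pick]], params$fit_before_rmsd), 0)
    remaining <- remaining[d >= params$d_cutoff]
  }

  dist_to_ref <- vapply(refs, function(r) vapply(seq_len(n), function(i)
    .pair_rmsd(mats[[i]], mats[[r]], params$fit_before_rmsd), 0),
    numeric(n))
  dim(dist_to_ref) <- c(n, length(refs))
  assignment <- apply(dist_to_ref, 1L, which.min)  # ties -> lowest index

  sources <- unique(src)
  freq <- matrix(0, length(sources), length(refs),
                 dimnames = list(sources, paste0("ref", seq_along(refs))))
  for (s in sources) {
    a <- assignment[src == s]
    freq[s, ] <- tabulate(a, nbins = length(refs)) / length(a)
  }

  ref_structs <- lapply(refs, function(r) {
    tr <- trajs[[match(src[r], vapply(trajs, `[[`, "", "source_id"))]]
    get_frame(tr, frame_no[r])
  })
  references <- data.frame(reference = seq_along(refs),
                           source_id = src[refs], frame = frame_no[refs],
                           time_ps = tms[refs], stringsAsFactors = FALSE)
  structure(list(references = references, structures = ref_structs,
                 assignment = assignment, frame_sources = src,
                 frequencies = freq, params = params),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult:", nrow(x$references), "reference(s),",
      length(x$assignment), "frames,",
      nrow(x$frequencies), "source(s); d =", x$params$d_cutoff, "A\n")
  invisible(x)
}

#' Per-trajectory cluster-frequency table and convergence spread
#'
#' Convergence of independent runs is assessed by how equally each
#' reference structure is represented in each run: the spread is the
#' maximum, over references, of (max - min) frequency across sources.
#'
#' @param result a `ClusterResult` with at least 2 sources (a single
#'   source gives `spread = NA` with a warning).
#' @return list with `table` (source x reference frequency matrix, rows
#'   summing to 1) and `spread`.
#' @export
convergence_table <- function(result) {
  f <- result$frequencies
  if (nrow(f) < 2L) {
    warning("convergence spread needs >= 2 sources; returning NA")
    return(list(table = f, spread = NA_real_))
  }
  spread <- max(apply(f, 2L, function(col) max(col) - min(col)))
  list(table = f, spread = spread)
}
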