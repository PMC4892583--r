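## Bend/twist quantification of a solenoid: radius of curvature from three
## anchor atoms (two distal tips and a middle vertex) and inter-repeat H3
## helix-axis angles/torsions, per structure or per frame.
##
## The curvature convention: d is the distance from a distal vertex to the
## middle vertex (the two are averaged for asymmetric inputs), m is half
## the distance between the two distal vertices, and
## R = d^2 / (2 * sqrt(d^2 - m^2)), the circumradius of the isoceles
## vertex triangle. Larger R = flatter (more open) solenoid.

#' Radius of curvature from three anchor points
#'
#' @param pN,pM,pC numeric 3-vectors: distal N-side anchor, middle anchor,
#'   distal C-side anchor (e.g. the Calpha of residues 117, 313, 486 of
#'   importin-alpha).
#' @param tol collinearity tolerance on `d - m` (A).
#' @return radius of curvature R in Angstrom.
#' @export
radius_of_curvature <- function(pN, pM, pC, tol = 1e-9) {
  stopifnot(length(pN) == 3L, length(pM) == 3L, length(pC) == 3L)
  dN <- sqrt(sum((pN - pM)^2))
  dC <- sqrt(sum((pC - pM)^2))
  if (dN < tol || dC < tol || sqrt(sum((pN - pC)^2)) < tol)
    stop("degenerate anchors: coincident points")
  d <- (dN + dC) / 2                 # near-isoceles: average the two legs
  m <- sqrt(sum((pN - pC)^2)) / 2
  if (d - m < tol)
    stop("collinear anchors: radius of curvature is infinite (d <= m)")
  d^2 / (2 * sqrt(d^2 - m^2))
}

#' Fit a helix axis vector
#'
#' Axis vector along the Calpha atoms of a residue range, oriented from
#' the N-terminal toward the C-terminal end. The default `"bisector"`
#' method uses the local second differences `r[i-1] + r[i+1] - 2 r[i]`,
#' which for a helix point radially at the axis; cross products of
#' consecutive bisectors are parallel to the axis, and their average is
#' exact for an ideal helix (a plain principal-axis fit is biased by a
#' couple of degrees on a finite helix because the phase-height cross
#' terms of the covariance do not cancel). `method = "pca"` gives the
#' dominant principal direction of the centered coordinates instead.
#'
#' @param structure a `StructureModel`.
#' @param residues integer residue numbers of the helix (>= 4 Calpha).
#' @param chain chain id (default first chain present).
#' @param method `"bisector"` (default) or `"pca"`.
#' @return object of class `HelixVector`: `vector` (unit 3-vector),
#'   `centroid`, `residues`.
#' @export
fit_helix_vector <- function(structure, residues, chain = NULL,
                             method = c("bisector", "pca")) {
  method <- match.arg(method)
  a <- structure$atoms
  if (is.null(chain)) chain <- a$chain_id[1]
  idx <- which(a$chain_id == chain & a$residue_number %in% residues &
                 a$atom_name == "CA")
  idx <- idx[order(a$residue_number[idx])]
  if (length(idx) < 4L)
    stop("helix fit needs >= 4 Calpha atoms, got ", length(idx))
  X <- structure$coords[idx, , drop = FALSE]
  ctr <- colMeans(X)
  n <- nrow(X)
  if (method == "pca") {
    sv <- svd(sweep(X, 2, ctr))
    if (sv$d[1] < 1e-9) stop("degenerate helix: all points coincident")
    v <- sv$v[, 1]
  } else {
    # bisectors point from each interior Calpha toward the axis
    B <- X[1:(n - 2), , drop = FALSE] + X[3:n, , drop = FALSE] -
      2 * X[2:(n - 1), , drop = FALSE]
    v <- c(0, 0, 0)
    for (i in seq_len(nrow(B) - 1L)) {
      h <- pracma_cross(B[i, ], B[i + 1, ])
      nh <- sqrt(sum(h^2))
      if (nh > 1e-12) v <- v + h / nh
    }
    if (sqrt(sum(v^2)) < 1e-9)
      stop("degenerate helix: no curvature (collinear or coincident ",
           "points)")
  }
  v <- v / sqrt(sum(v^2))
  # orient N -> C: along increasing residue index
  if (sum((X[n, ] - X[1, ]) * v) < 0) v <- -v
  structure(list(vector = v, centroid = ctr,
                 residues = range(residues)), class = "HelixVector")
}

.angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# signed torsion of vector v2 relative to v1 about axis a, in (-180, 180]
.torsion_deg <- function(v1, v2, a) {
  a <- .unit(a)
  p1 <- v1 - sum(v1 * a) * a
  p2 <- v2 - sum(v2 * a) * a
  if (sqrt(sum(p1^2)) < 1e-12 || sqrt(sum(p2^2)) < 1e-12) return(NA_real_)
  x <- sum(p1 * p2)
  y <- sum(pracma_cross(p1, p2) * a)
  atan2(y, x) * 180 / pi
}

#' Inter-repeat H3 helix angles (and torsions)
#'
#' Fits an axis vector to the H3 helix of every repeat and returns, for
#' each neighbouring repeat pair (r, r+1), the unsigned inter-vector
#' angle in \[0, 180\] degrees and (optionally) the signed torsion of the
#' two vectors about the axis connecting their centroids.
#'
#' @param structure a `StructureModel`.
#' @param annotation an `ArmAnnotation` providing H3 for every repeat.
#' @param helix which helix to use (default `"H3"`).
#' @param torsion also compute signed torsions (default TRUE).
#' @return data.frame: `pair` ("r-r+1"), `angle`, and `torsion` when
#'   requested.
#' @export
inter_repeat_angles <- function(structure, annotation, helix = "H3",
                                torsion = TRUE) {
  nr <- annotation$n_repeats
  hv <- lapply(seq_len(nr), function(r)
    fit_helix_vector(structure, helix_range(annotation, r, helix)))
  out <- data.frame(
    pair = paste0(seq_len(nr - 1), "-", 2:nr),
    angle = vapply(seq_len(nr - 1), function(r)
      .angle_deg(hv[[r]]$vector, hv[[r + 1]]$vector), 0),
    stringsAsFactors = FALSE)
  if (torsion)
    out$torsion <- vapply(seq_len(nr - 1), function(r)
      .torsion_deg(hv[[r]]$vector, hv[[r + 1]]$vector,
                   hv[[r + 1]]$centroid - hv[[r]]$centroid), 0)
  out
}

#' Per-frame bend/twist geometry of a trajectory
#'
#' One row per frame: radius of curvature from the three anchors, every
#' neighbouring-pair H3 angle, their arithmetic mean, and the signed
#' torsions.
#'
#' @param frames a `Trajectory` or `DisplacementSeries`.
#' @param anchors length-3 atom index vector `(distal_N, middle,
#'   distal_C)`, e.g. from [default_anchors()].
#' @param annotation an `ArmAnnotation`.
#' @return data.frame: `frame`, `R`, `angle_1..angle_{n-1}`, `mean_angle`,
#'   `torsion_1..torsion_{n-1}`.
#' @export
geometry_series <- function(frames, anchors, annotation) {
  if (inherits(frames, "DisplacementSeries")) frames <- as_trajectory(frames)
  stopifnot(inherits(frames, "Trajectory"), length(anchors) == 3L)
  nf <- n_frames(frames)
  np <- annotation$n_repeats - 1L
  out <- matrix(NA_real_, nf, 2L + 2L * np)
  for (t in seq_len(nf)) {
    fr <- get_frame(frames, t)
    R <- tryCatch(
      radius_of_curvature(fr$coords[anchors[1], ], fr$coords[anchors[2], ],
                          fr$coords[anchors[3], ]),
      error = function(e) stop("frame ", t, ": ", conditionMessage(e),
                               call. = FALSE))
    ang <- inter_repeat_angles(fr, annotation)
    out[t, ] <- c(R, ang$angle, mean(ang$angle), ang$torsion)
  }
  df <- as.data.frame(out)
  names(df) <- c("R", paste0("angle_", seq_len(np)), "mean_angle",
                 paste0("torsion_", seq_len(np)))
  cbind(data.frame(frame = seq_len(nf)), df)
}
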