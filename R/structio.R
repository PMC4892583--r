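## Structure / trajectory data model, PDB I/O, superposition, RMSD/RMSF.
## All coordinates are in Angstrom, masses in amu, times in picoseconds.

# Atomic masses for the elements that occur in Calpha traces and the
# pseudo-atoms of the synthetic complex. Unknown elements are an error
# rather than a silent default.
.ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  `NA` = 22.990, K = 39.098, CA = 40.078, CL = 35.45
)

#' Look up atomic masses by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @keywords internal
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .ELEMENT_MASSES[key]
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "),
         " (no mass available)", call. = FALSE)
  }
  unname(m)
}

#' Construct a StructureModel
#'
#' A `StructureModel` is one conformation: an atom table plus an
#' `n_atoms x 3` coordinate matrix in Angstrom.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`,
#'   `residue_name`, `residue_number`, `chain_id`, `element`, `mass`.
#' @param coords numeric matrix, `nrow(atoms) x 3`, Angstrom.
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(atoms) < 1L) stop("a StructureModel needs at least one atom")
  if (!identical(dim(coords), c(nrow(atoms), 3L)) &&
      !(nrow(coords) == nrow(atoms) && ncol(coords) == 3L))
    stop("coords must be an n_atoms x 3 matrix")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (any(atoms$mass <= 0)) stop("masses must be strictly positive")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_number, atom_name): ",
         key[duplicated(key)][1L])
  rownames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords), class = "StructureModel")
}

#' Number of atoms in a structure or trajectory topology
#' @param x a `StructureModel` or `Trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Construct a Trajectory
#'
#' Ordered frames over a fixed topology. `coords` is an
#' `n_frames x n_atoms x 3` array; `times` are in ps and must be strictly
#' increasing. `source_id` labels independent runs for the clustering
#' convergence table.
#'
#' @param topology a `StructureModel`.
#' @param coords numeric array `n_frames x n_atoms x 3`.
#' @param times numeric vector of frame times (ps); default `0, 10, 20, ...`
#'   mirroring a 10 ps sampling interval.
#' @param source_id character label for this run.
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, source_id = "run1") {
  stopifnot(inherits(topology, "StructureModel"))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[2] != n_atoms(topology))
    stop("every frame must have exactly the topology's atom count (",
         n_atoms(topology), "), got ", dim(coords)[2])
  nf <- dim(coords)[1]
  if (nf < 1L) stop("trajectory needs at least one frame")
  if (is.null(times)) times <- (seq_len(nf) - 1) * 10
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), source_id = source_id),
            class = "Trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory as a StructureModel
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return `StructureModel` with the topology's atom table.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  m <- traj$topology
  m$coords <- traj$coords[i, , , drop = TRUE]
  dim(m$coords) <- c(n_atoms(traj), 3L)
  m
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain_id)), "chain(s)\n")
  invisible(x)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", n_atoms(x), "atoms",
      sprintf("(source '%s')\n", x$source_id))
  invisible(x)
}

## ---------------------------------------------------------------- selections

#' Define an atom selection
#'
#' A predicate over (chain_id, residue_number, atom_name); `NULL` fields
#' match everything. Resolve against a model with [resolve_selection()].
#'
#' @param chain character vector of chain ids, or NULL.
#' @param residues integer vector of residue numbers, or NULL.
#' @param atoms character vector of atom names (e.g. `"CA"`), or NULL.
#' @return object of class `AtomSelection`.
#' @export
atom_selection <- function(chain = NULL, residues = NULL, atoms = NULL) {
  structure(list(chain = chain, residues = residues, atoms = atoms),
            class = "AtomSelection")
}

#' Parse a selection string
#'
#' Accepts comma-separated `chain:residue_range:atom_name` triplets, e.g.
#' `"A:1-360:CA"` or `"A:117:CA,A:313:CA"`. `*` matches everything in a
#' field; a residue range is `lo-hi` or a single number.
#'
#' @param s selection string.
#' @return list of `AtomSelection` objects (one per triplet).
#' @export
parse_selection <- function(s) {
  parts <- strsplit(trimws(strsplit(s, ",")[[1]]), ":", fixed = TRUE)
  lapply(parts, function(p) {
    if (length(p) != 3L)
      stop("selection triplet must be chain:residues:atom, got: ",
           paste(p, collapse = ":"))
    chain <- if (p[1] == "*") NULL else p[1]
    res <- if (p[2] == "*") NULL else {
      rr <- as.integer(strsplit(p[2], "-", fixed = TRUE)[[1]])
      if (length(rr) == 2L) seq.int(rr[1], rr[2]) else rr
    }
    atoms <- if (p[3] == "*") NULL else p[3]
    atom_selection(chain, res, atoms)
  })
}

#' Resolve a selection to atom indices
#'
#' @param model a `StructureModel`.
#' @param sel an `AtomSelection`, a list of them (union), a selection
#'   string, an integer index vector (validated), or NULL (all atoms).
#' @return sorted unique integer indices into the model's atom table.
#' @export
resolve_selection <- function(model, sel = NULL) {
  if (inherits(model, "Trajectory")) model <- model$topology
  a <- model$atoms
  if (is.null(sel)) return(seq_len(nrow(a)))
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (anyDuplicated(idx) || any(idx < 1L | idx > nrow(a)))
      stop("invalid atom index selection")
    return(sort(idx))
  }
  if (is.character(sel)) sel <- parse_selection(sel)
  if (inherits(sel, "AtomSelection")) sel <- list(sel)
  hit <- rep(FALSE, nrow(a))
  for (s in sel) {
    keep <- rep(TRUE, nrow(a))
    if (!is.null(s$chain)) keep <- keep & a$chain_id %in% s$chain
    if (!is.null(s$residues)) keep <- keep & a$residue_number %in% s$residues
    if (!is.null(s$atoms)) keep <- keep & a$atom_name %in% s$atoms
    hit <- hit | keep
  }
  which(hit)
}

## --------------------------------------------------------------------- PDB

.guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  if (nchar(nm) == 0L) stop("cannot infer element from atom name '",
                            atom_name, "'")
  # Calpha traces: names like CA/CB/CD1 are carbon; single leading letter.
  substr(nm, 1L, 1L)
}

#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records; MODEL/ENDMDL delimit frames.
#' A single-model file yields a [structure_model()], a multi-model file a
#' [trajectory()] (frame times `0, 10, 20, ...` ps unless stated by the
#' caller afterwards). The first alternate location is kept; insertion
#' codes are rejected. Chain and residue numbering follow the file verbatim.
#'
#' @param path path to a PDB file.
#' @param source_id source label for a multi-model file.
#' @return `StructureModel` or `Trajectory`.
#' @export
read_pdb <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- rec == "MODEL "
  model_no <- cumsum(is_model)
  multi <- any(is_model)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  parse_block <- function(idx) {
    ln <- lines[idx]
    altloc <- substr(ln, 17, 17)
    keep_alt <- altloc %in% c(" ", "", "A", "1")
    if (!all(keep_alt)) { ln <- ln[keep_alt]; idx <- idx[keep_alt] }
    icode <- trimws(substr(ln, 27, 27))
    if (any(icode != ""))
      stop("insertion codes are not supported (line ",
           idx[which(icode != "")[1]], ")")
    xyz <- cbind(
      suppressWarnings(as.numeric(substr(ln, 31, 38))),
      suppressWarnings(as.numeric(substr(ln, 39, 46))),
      suppressWarnings(as.numeric(substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed coordinate field at line ",
           idx[which(is.na(rowSums(xyz)))[1]])
    serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
    resnum <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (anyNA(serial) || anyNA(resnum))
      stop("malformed serial/residue-number field at line ",
           idx[which(is.na(serial) | is.na(resnum))[1]])
    elem <- trimws(substr(ln, 77, 78))
    name <- trimws(substr(ln, 13, 16))
    elem[elem == ""] <- vapply(name[elem == ""], .guess_element, "")
    atoms <- data.frame(
      serial = serial,
      atom_name = name,
      residue_name = trimws(substr(ln, 18, 20)),
      residue_number = resnum,
      chain_id = substr(ln, 22, 22),
      element = elem,
      mass = element_mass(elem),
      stringsAsFactors = FALSE)
    structure_model(atoms, xyz)
  }

  if (!multi) return(parse_block(which(is_atom)))

  ids <- sort(unique(model_no[is_atom]))
  models <- lapply(ids, function(k) parse_block(which(is_atom & model_no == k)))
  counts <- vapply(models, n_atoms, 1L)
  if (length(unique(counts)) != 1L)
    stop("inconsistent atom count across models: ",
         paste(counts, collapse = ", "))
  coords <- array(0, dim = c(length(models), counts[1], 3L))
  for (i in seq_along(models)) coords[i, , ] <- models[[i]]$coords
  trajectory(models[[1]], coords, source_id = source_id)
}

.format_atom_line <- function(a, xyz) {
  if (any(abs(xyz) >= 10000 - 0.0005))
    stop("coordinate magnitude >= 10000 Angstrom does not fit the ",
         "fixed-width PDB coordinate field")
  nm <- a$atom_name
  nm <- ifelse(nchar(nm) < 4L, paste0(" ", formatC(nm, width = -3)), nm)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000L, nm, a$residue_name, a$chain_id,
          a$residue_number, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          toupper(a$element))
}

#' Write a PDB file
#'
#' A `StructureModel` is written as a single model, a `Trajectory` as one
#' MODEL/ENDMDL block per frame. Round-trips through [read_pdb()] preserve
#' atom identities exactly and coordinates to 3 decimals (PDB fixed width).
#'
#' @param x `StructureModel` or `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "StructureModel")) {
    writeLines(.format_atom_line(x$atoms, x$coords), con)
    writeLines("END", con)
  } else if (inherits(x, "Trajectory")) {
    for (i in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL %8d", i), con)
      xyz <- x$coords[i, , , drop = TRUE]
      dim(xyz) <- c(n_atoms(x), 3L)
      writeLines(.format_atom_line(x$topology$atoms, xyz), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else stop("x must be a StructureModel or Trajectory")
  invisible(path)
}

## ------------------------------------------------------------- superposition

# Kabsch: optimal rotation/translation of P (mobile, n x 3) onto Q (ref).
# Returns rotation (det +1), translation, rmsd and transformed coords.
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Pt <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pt - Qc)^2)))
  list(rotation = R, translation = cq - as.vector(R %*% cp), rmsd = rmsd,
       transformed = sweep(Pt, 2, cq, "+"))
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param rotation 3x3 rotation matrix (applied as `R %*% x`).
#' @param translation length-3 vector added after rotation.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, rotation, translation = c(0, 0, 0)) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

#' Least-squares superposition of two structures
#'
#' Kabsch superposition of `mobile` onto `reference` over a common atom
#' selection; the returned rotation has determinant +1.
#'
#' @param mobile,reference `StructureModel`s.
#' @param sel selection (see [resolve_selection()]) resolving to the same
#'   number (>= 3, non-collinear) of atoms in both.
#' @return list with `rotation`, `translation`, `rmsd` (post-fit, over the
#'   selection) and `transformed` (the full mobile model, moved).
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  im <- resolve_selection(mobile, sel)
  ir <- resolve_selection(reference, sel)
  if (length(im) != length(ir))
    stop("selection resolves to ", length(im), " atoms in mobile but ",
         length(ir), " in reference")
  if (length(im) < 3L) stop("need at least 3 atoms to superpose")
  P <- mobile$coords[im, , drop = FALSE]
  Q <- reference$coords[ir, , drop = FALSE]
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) selection: superposition is not unique")
  k <- .kabsch(P, Q)
  out <- mobile
  out$coords <- apply_transform(mobile$coords, k$rotation, k$translation)
  list(rotation = k$rotation, translation = k$translation, rmsd = k$rmsd,
       transformed = out)
}

#' RMSD between two structures over a selection
#'
#' @param a,b `StructureModel`s with a common selection.
#' @param sel selection; default all atoms.
#' @param fit superpose `a` onto `b` first (default TRUE).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, sel = NULL, fit = TRUE) {
  ia <- resolve_selection(a, sel); ib <- resolve_selection(b, sel)
  if (length(ia) != length(ib)) stop("selection size mismatch")
  P <- a$coords[ia, , drop = FALSE]; Q <- b$coords[ib, , drop = FALSE]
  if (fit) .kabsch(P, Q)$rmsd else sqrt(mean(rowSums((P - Q)^2)))
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' @param traj a `Trajectory`.
#' @param reference a `StructureModel` (defaults to frame 1).
#' @param sel selection used both for fitting and for the RMSD.
#' @param fit superpose each frame on the reference first (default TRUE).
#' @return numeric vector, one Angstrom value per frame.
#' @export
rmsd_series <- function(traj, reference = NULL, sel = NULL, fit = TRUE) {
  if (is.null(reference)) reference <- get_frame(traj, 1L)
  it <- resolve_selection(traj, sel)
  ir <- resolve_selection(reference, sel)
  if (length(it) == 0L) stop("empty selection")
  if (length(it) != length(ir)) stop("selection size mismatch")
  Q <- reference$coords[ir, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(i) {
    P <- traj$coords[i, it, , drop = TRUE]
    dim(P) <- c(length(it), 3L)
    if (fit) .kabsch(P, Q)$rmsd else sqrt(mean(rowSums((P - Q)^2)))
  }, 0)
}

# Fit all frames over selection `idx`; returns n_frames x n x 3 array.
# Two-pass: fit to frame 1, average, re-fit every frame to the average.
.fitted_frames <- function(traj, idx, fit = TRUE) {
  nf <- n_frames(traj); n <- length(idx)
  X <- array(0, dim = c(nf, n, 3L))
  for (i in seq_len(nf)) {
    P <- traj$coords[i, idx, , drop = TRUE]; dim(P) <- c(n, 3L)
    X[i, , ] <- P
  }
  if (!fit) return(X)
  ref <- X[1, , ]; dim(ref) <- c(n, 3L)
  for (pass in 1:2) {
    for (i in seq_len(nf)) {
      P <- X[i, , ]; dim(P) <- c(n, 3L)
      X[i, , ] <- .kabsch(P, ref)$transformed
    }
    ref <- apply(X, c(2, 3), mean)
  }
  X
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed on the time-averaged structure (fit to frame 1,
#' then one re-fit to the running mean) before computing, per selected
#' atom, the RMS deviation from its mean position.
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param sel selection; default all atoms.
#' @param fit superpose frames before measuring (default TRUE); disable
#'   for pre-aligned ensembles.
#' @return numeric vector of Angstrom values, one per selected atom.
#' @export
rmsf <- function(traj, sel = NULL, fit = TRUE) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  idx <- resolve_selection(traj, sel)
  X <- .fitted_frames(traj, idx, fit = fit)
  mu <- apply(X, c(2, 3), mean)
  d2 <- sapply(seq_along(idx), function(j) {
    dx <- sweep(X[, j, , drop = TRUE], 2, mu[j, ])
    mean(rowSums(dx^2))
  })
  sqrt(d2)
}
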