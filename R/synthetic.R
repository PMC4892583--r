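## Synthetic ARM-solenoid generator: idealized repeat architecture, motion
## trajectories with analytically known bend/twist amplitudes, and a bound
## extended peptide whose interface contacts follow an exact schedule.
## This is the ground-truth stand-in for an importin-alpha / bipartite-NLS
## system: 10 tandem repeats of 3 alpha-helices on a superhelix, a bending
## motion (opening/closing of the concave face), a per-repeat twisting
## motion, Gaussian thermal noise, and scheduled salt bridges / hydrogen
## bonds / hydrophobic contacts.

#' Specification of an idealized alpha-solenoid
#'
#' Geometry of a Calpha-trace solenoid: `n_repeats` tandem repeats of
#' `helices_per_repeat` ideal alpha-helices, laid on a superhelix around
#' the z axis. Successive repeats are related by a fixed screw transform:
#' rotation by `repeat_twist` degrees about z plus a rise of `repeat_rise`
#' Angstrom.
#'
#' @param n_repeats number of tandem repeats (>= 2; default 10).
#' @param helices_per_repeat helices per repeat (default 3; the third is
#'   the "H3" used for inter-repeat twist angles).
#' @param residues_per_helix residues per helix (>= 4; default 12).
#' @param helix_rise rise per residue along the helix axis (A; default 1.5).
#' @param helix_radius helix backbone radius (A; default 2.3).
#' @param helix_spacing radial spacing between helices of a repeat (A).
#' @param helix_stagger axial (z) stagger between helices of a repeat (A).
#' @param superhelix_radius radius of the superhelical path (A; default 15).
#' @param repeat_rise z rise per repeat (A; default 8).
#' @param repeat_twist rotation per repeat about the superhelical axis
#'   (degrees; default 25).
#' @param seed integer seed (construction is deterministic; kept for API
#'   symmetry with the stochastic generators).
#' @return object of class `SolenoidSpec`.
#' @export
solenoid_spec <- function(n_repeats = 10L, helices_per_repeat = 3L,
                          residues_per_helix = 12L, helix_rise = 1.5,
                          helix_radius = 2.3, helix_spacing = 5.0,
                          helix_stagger = 2.0, superhelix_radius = 15,
                          repeat_rise = 8, repeat_twist = 25, seed = 1L) {
  stopifnot(n_repeats >= 2L, residues_per_helix >= 4L,
            helices_per_repeat >= 1L,
            helix_rise > 0, helix_radius > 0, helix_spacing > 0,
            superhelix_radius > 0, repeat_rise > 0)
  structure(as.list(environment()), class = "SolenoidSpec")
}

# Rotation matrix about a unit axis by an angle in degrees (Rodrigues).
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Build an idealized solenoid Calpha trace
#'
#' One Calpha pseudo-atom per residue, chain "A", residues numbered 1..N
#' consecutively over repeats and helices. Helices within a repeat run
#' tangentially (along the local y axis), antiparallel in alternation,
#' offset radially by `helix_spacing` and axially by `helix_stagger`;
#' repeat r is repeat 1 rotated by `(r-1) * repeat_twist` about z and
#' raised by `(r-1) * repeat_rise`.
#'
#' @param spec a [solenoid_spec()].
#' @return list with `structure` (`StructureModel`) and `annotation`
#'   (`ArmAnnotation`: per-repeat H1/H2/H3 residue ranges).
#' @export
build_solenoid <- function(spec = solenoid_spec()) {
  stopifnot(inherits(spec, "SolenoidSpec"))
  nh <- spec$helices_per_repeat
  m <- spec$residues_per_helix
  per_repeat <- nh * m
  n_res <- spec$n_repeats * per_repeat

  # repeat 1, local frame: x radial, y tangential, z superhelical axis
  local <- matrix(0, per_repeat, 3)
  for (h in seq_len(nh)) {
    dir <- if (h %% 2 == 1L) 1 else -1          # antiparallel packing
    cx <- spec$superhelix_radius + (h - (nh + 1) / 2) * spec$helix_spacing
    cz <- (h - 1) * spec$helix_stagger
    for (i in seq_len(m)) {
      t <- (i - 1) * 100 * pi / 180              # ~3.6 residues per turn
      along <- (i - (m + 1) / 2) * spec$helix_rise * dir
      local[(h - 1) * m + i, ] <- c(
        cx + spec$helix_radius * cos(t),
        along,
        cz + spec$helix_radius * sin(t))
    }
  }

  coords <- matrix(0, n_res, 3)
  for (r in seq_len(spec$n_repeats)) {
    R <- rotation_about_axis(c(0, 0, 1), (r - 1) * spec$repeat_twist)
    block <- sweep(local %*% t(R), 2, c(0, 0, (r - 1) * spec$repeat_rise), "+")
    coords[((r - 1) * per_repeat + 1):(r * per_repeat), ] <- block
  }

  # self-intersection guard: min Calpha distance between distinct repeats
  rep_of <- rep(seq_len(spec$n_repeats), each = per_repeat)
  dmin <- Inf
  for (r in seq_len(spec$n_repeats - 1L)) {
    a <- coords[rep_of == r, , drop = FALSE]
    for (q in (r + 1L):spec$n_repeats) {
      b <- coords[rep_of == q, , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
      dmin <- min(dmin, sqrt(max(0, min(d2))))
    }
  }
  if (dmin < 1)
    stop("geometry error: solenoid self-intersects (minimum inter-repeat ",
         "Calpha distance ", round(dmin, 3), " A < 1 A)")

  atoms <- data.frame(
    serial = seq_len(n_res), atom_name = "CA", residue_name = "ALA",
    residue_number = seq_len(n_res), chain_id = "A", element = "C",
    mass = element_mass(rep("C", n_res)), stringsAsFactors = FALSE)

  repeats <- lapply(seq_len(spec$n_repeats), function(r) {
    base <- (r - 1) * per_repeat
    stats::setNames(lapply(seq_len(nh), function(h)
      as.integer(c(base + (h - 1) * m + 1L, base + h * m))),
      paste0("H", seq_len(nh)))
  })
  annotation <- structure(
    list(repeats = repeats, n_repeats = spec$n_repeats,
         residues_per_helix = m, helices_per_repeat = nh),
    class = "ArmAnnotation")

  list(structure = structure_model(atoms, coords), annotation = annotation)
}

#' Tabulate annotation ranges
#' @param annotation an `ArmAnnotation`.
#' @return data.frame with columns `repeat_index`, `helix`, `start`, `end`.
#' @export
annotation_ranges <- function(annotation) {
  do.call(rbind, lapply(seq_along(annotation$repeats), function(r) {
    rr <- annotation$repeats[[r]]
    data.frame(repeat_index = r, helix = names(rr),
               start = vapply(rr, `[`, 1L, 1L),
               end = vapply(rr, `[`, 1L, 2L), row.names = NULL)
  }))
}

#' Residue range of helix H3 (or another helix) of one repeat
#' @param annotation an `ArmAnnotation`.
#' @param r repeat index.
#' @param helix helix name, default `"H3"`.
#' @return integer residue index vector `start:end`.
#' @export
helix_range <- function(annotation, r, helix = "H3") {
  rr <- annotation$repeats[[r]][[helix]]
  if (is.null(rr)) stop("repeat ", r, " has no ", helix, " annotation")
  seq.int(rr[1], rr[2])
}

# Index of the Calpha nearest each repeat's centroid ("pivot" atom).
# Pivots anchor the per-repeat twist axes and the curvature anchors.
repeat_pivots <- function(structure, annotation) {
  vapply(seq_len(annotation$n_repeats), function(r) {
    idx <- seq.int(annotation$repeats[[r]][[1]][1],
                   annotation$repeats[[r]][[annotation$helices_per_repeat]][2])
    X <- structure$coords[idx, , drop = FALSE]
    ctr <- colMeans(X)
    idx[which.min(rowSums(sweep(X, 2, ctr)^2))]
  }, 1L)
}

#' Default curvature anchors for a solenoid
#'
#' Three anchor atoms for the radius-of-curvature triangle: the pivot
#' Calpha (atom nearest the repeat centroid) of the first, middle and last
#' repeat — two distal tips plus the middle point, matching the vertex
#' scheme used for importin-alpha (residues R117 / A313 / K486).
#'
#' @param structure solenoid `StructureModel`.
#' @param annotation its `ArmAnnotation`.
#' @return named integer vector `c(distal_N, middle, distal_C)` of atom
#'   indices.
#' @export
default_anchors <- function(structure, annotation) {
  piv <- repeat_pivots(structure, annotation)
  mid <- ceiling(annotation$n_repeats / 2)
  c(distal_N = piv[1], middle = piv[mid], distal_C = piv[annotation$n_repeats])
}

#' Specification of a synthetic bend/twist motion
#'
#' Frame t (t = 0, 1, ...) applies, with phase `sin(2*pi*t/period)`:
#' a hinge rotation of `bend_amplitude * phase` degrees of each half of
#' the solenoid (opposite signs) about an axis through the middle repeat,
#' then a cumulative per-repeat twist of `twist_amplitude * phase` degrees
#' between neighbouring repeats about axes parallel to the superhelical
#' axis, then isotropic Gaussian noise of `noise_sd` Angstrom per atom.
#'
#' @param bend_amplitude hinge half-angle (degrees; each half rotates by
#'   this much at peak phase, so the total opening is twice it).
#' @param twist_amplitude per-repeat relative rotation (degrees).
#' @param period motion period in frames.
#' @param noise_sd isotropic Gaussian noise per coordinate (A).
#' @param n_frames number of frames (>= 2).
#' @param seed integer RNG seed (noise only).
#' @return object of class `MotionSpec`.
#' @export
motion_spec <- function(bend_amplitude = 10, twist_amplitude = 5,
                        period = 100L, noise_sd = 0.3, n_frames = 100L,
                        seed = 1L) {
  stopifnot(bend_amplitude >= 0, twist_amplitude >= 0, noise_sd >= 0,
            n_frames >= 2L, period > 0)
  structure(as.list(environment()), class = "MotionSpec")
}

#' Simulate a bend/twist trajectory of a solenoid
#'
#' Repeats move as rigid bodies. The twist rotates repeat r by
#' `(r - mid) * twist_amplitude * phase` degrees about the axis parallel
#' to z through that repeat's pivot atom, so every neighbouring pair
#' changes by exactly `twist_amplitude * phase` degrees and the three
#' curvature anchors stay fixed (pure twist leaves the radius of
#' curvature constant by construction). The bend then rotates the
#' N-terminal half by `-bend_amplitude * phase` and the C-terminal half
#' by `+bend_amplitude * phase` about the normal of the anchor plane
#' through the middle pivot. Frame times are 10 ps apart.
#'
#' @param structure solenoid `StructureModel` from [build_solenoid()].
#' @param annotation matching `ArmAnnotation`.
#' @param motion a [motion_spec()].
#' @param source_id run label recorded on the trajectory.
#' @return a `Trajectory` with `n_frames` frames.
#' @export
simulate_trajectory <- function(structure, annotation,
                                motion = motion_spec(),
                                source_id = "run1") {
  stopifnot(inherits(motion, "MotionSpec"))
  nr <- annotation$n_repeats
  mid <- ceiling(nr / 2)
  piv <- repeat_pivots(structure, annotation)
  anchors <- structure$coords[c(piv[1], piv[mid], piv[nr]), , drop = FALSE]
  hinge_axis <- .unit(pracma_cross(anchors[1, ] - anchors[2, ],
                                   anchors[3, ] - anchors[2, ]))
  hinge_origin <- anchors[2, ]

  per_repeat <- annotation$helices_per_repeat * annotation$residues_per_helix
  rep_of <- rep(seq_len(nr), each = per_repeat)
  n <- n_atoms(structure)
  nf <- motion$n_frames
  coords <- array(0, dim = c(nf, n, 3L))

  set.seed(motion$seed)
  for (t in seq_len(nf)) {
    phase <- sin(2 * pi * (t - 1) / motion$period)
    X <- structure$coords
    if (motion$twist_amplitude > 0 && phase != 0) {
      for (r in seq_len(nr)) {
        ang <- (r - mid) * motion$twist_amplitude * phase
        if (ang == 0) next
        R <- rotation_about_axis(c(0, 0, 1), ang)
        o <- structure$coords[piv[r], ]
        sel <- rep_of == r
        X[sel, ] <- sweep(sweep(X[sel, , drop = FALSE], 2, o) %*% t(R),
                          2, o, "+")
      }
    }
    if (motion$bend_amplitude > 0 && phase != 0) {
      for (side in c(-1, 1)) {
        sel <- if (side < 0) rep_of < mid else rep_of > mid
        R <- rotation_about_axis(hinge_axis,
                                 side * motion$bend_amplitude * phase)
        X[sel, ] <- sweep(sweep(X[sel, , drop = FALSE], 2, hinge_origin) %*%
                            t(R), 2, hinge_origin, "+")
      }
    }
    if (motion$noise_sd > 0)
      X <- X + matrix(stats::rnorm(3 * n, sd = motion$noise_sd), n, 3)
    coords[t, , ] <- X
  }
  trajectory(structure, coords, times = (seq_len(nf) - 1) * 10,
             source_id = source_id)
}

# cross product (avoid pulling in a package for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## ------------------------------------------------------------------ peptide

#' Specification of a bipartite basic peptide
#'
#' Default sequence emulates a bipartite nuclear-localization sequence:
#' a minor basic cluster (positions P1'-P2'), a >= 10 residue linker, and
#' a major basic cluster (P2-P5), numbered 151-172 on chain "B".
#'
#' @param sequence one-letter amino-acid sequence (length >= 14).
#' @param start_resnum first residue number.
#' @param chain chain id.
#' @return object of class `PeptideSpec`.
#' @export
peptide_spec <- function(sequence = "GSAVKRPAATKKAGQAKKKKLD",
                         start_resnum = 151L, chain = "B") {
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) < 14L)
    stop("peptide must have >= 14 residues (two basic clusters plus a ",
         ">= 10 residue linker)")
  basic <- which(aa %in% c("K", "R"))
  if (length(basic) < 2L) stop("peptide needs two basic clusters")
  # clusters = maximal runs of basic residues; linker = gap between the
  # end of the first cluster and the start of the last cluster
  runs <- split(basic, cumsum(c(1, diff(basic) != 1)))
  if (length(runs) < 2L) stop("peptide needs two separated basic clusters")
  first_end <- max(runs[[1]])
  last_start <- min(runs[[length(runs)]])
  if (last_start - first_end - 1L < 10L)
    stop("linker between the basic clusters must be >= 10 residues, got ",
         last_start - first_end - 1L)
  structure(list(sequence = aa, start_resnum = as.integer(start_resnum),
                 chain = chain, linker = c(first_end + 1L, last_start - 1L)),
            class = "PeptideSpec")
}

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

#' Default contact table for the synthetic complex
#'
#' Six typed interface contacts spanning both binding sites with target
#' occupancies straddling the 50% reporting filter (including the exact
#' boundary). `peptide_pos` indexes into the peptide sequence.
#'
#' @return data.frame with columns `contact_id`, `type`, `peptide_pos`,
#'   `peptide_atom`, `receptor_atom`, `receptor_resname`, `occupancy`.
#' @export
default_contacts <- function() {
  data.frame(
    contact_id = c("sb_major_1", "sb_minor_1", "hb_linker_1", "hb_major_1",
                   "hp_linker_1", "hp_minor_1"),
    type = c("salt_bridge", "salt_bridge", "hbond", "hbond",
             "hydrophobic", "hydrophobic"),
    peptide_pos = c(17L, 5L, 10L, 21L, 13L, 3L),
    peptide_atom = c("NZ", "NZ", "N", "N", "CB", "CB"),
    receptor_atom = c("OE1", "OD1", "O", "O", "CD1", "CD1"),
    receptor_resname = c("GLU", "ASP", "ALA", "ALA", "LEU", "LEU"),
    occupancy = c(1.0, 0.8, 0.5, 0.5, 0.3, 0.0),
    stringsAsFactors = FALSE)
}

# distances used to realize contacts: "on" satisfies the criterion with
# margin; "off" violates the distance criterion by >= 1 A
.CONTACT_GEOM <- list(
  salt_bridge = c(on = 3.0, off = 5.0),   # threshold 3.5
  hbond       = c(on = 3.0, off = 5.0),   # threshold 3.5
  hydrophobic = c(on = 3.6, off = 5.5))   # threshold 4.0

#' Build a solenoid-peptide complex with a known contact schedule
#'
#' Places an extended peptide antiparallel along the concave face of the
#' solenoid and adds the designated pseudo-atoms (charged-group nitrogens
#' and oxygens, backbone donor N/H and acceptor O, hydrophobic side-chain
#' carbons) so that each scheduled contact satisfies its geometric
#' criterion exactly in its formed frames and violates the distance
#' criterion by at least 1 Angstrom otherwise. `formed_frames` are drawn
#' (seeded) so that each contact's occupancy equals its target exactly.
#'
#' @param structure solenoid `StructureModel`.
#' @param annotation its `ArmAnnotation`.
#' @param peptide a [peptide_spec()].
#' @param contacts contact table as from [default_contacts()].
#' @param n_frames frames in the schedule; each `occupancy * n_frames`
#'   must be an integer.
#' @param seed RNG seed for drawing formed frames.
#' @return list with `complex` (`StructureModel`) and `schedule`
#'   (`ContactSchedule`).
#' @export
build_complex <- function(structure, annotation, peptide = peptide_spec(),
                          contacts = default_contacts(), n_frames = 60L,
                          seed = 1L) {
  stopifnot(inherits(peptide, "PeptideSpec"))
  nr <- annotation$n_repeats
  L <- length(peptide$sequence)

  # peptide backbone: screw path at reduced radius, antiparallel (descends
  # the superhelix as the receptor ascends)
  # the receptor path is estimated from the repeat pivots so non-default
  # solenoids still get a sensible concave-face path
  piv <- repeat_pivots(structure, annotation)
  pc <- structure$coords[piv, , drop = FALSE]
  rad <- mean(sqrt(pc[, 1]^2 + pc[, 2]^2))
  zr <- range(pc[, 3])
  phis <- atan2(pc[, 2], pc[, 1])
  phis <- phis + c(0, cumsum(round(diff(phis) / (2 * pi)) * -2 * pi))
  rad_p <- max(rad - 9, 3)
  u <- seq(1, 0, length.out = L)                 # 1 = top (receptor C side)
  phi_p <- phis[1] + u * (phis[nr] - phis[1])
  z_p <- zr[1] + u * (zr[2] - zr[1])
  pep_ca <- cbind(rad_p * cos(phi_p), rad_p * sin(phi_p), z_p)

  atoms <- structure$atoms
  coords <- structure$coords
  resname <- .AA3[peptide$sequence]
  pep_atoms <- data.frame(
    serial = max(atoms$serial) + seq_len(L), atom_name = "CA",
    residue_name = unname(resname),
    residue_number = peptide$start_resnum + seq_len(L) - 1L,
    chain_id = peptide$chain, element = "C",
    mass = element_mass(rep("C", L)), stringsAsFactors = FALSE)
  atoms <- rbind(atoms, pep_atoms)
  coords <- rbind(coords, pep_ca)

  add_atom <- function(name, resrow, element, xyz) {
    atoms <<- rbind(atoms, data.frame(
      serial = max(atoms$serial) + 1L, atom_name = name,
      residue_name = resrow$residue_name,
      residue_number = resrow$residue_number, chain_id = resrow$chain_id,
      element = element, mass = element_mass(element),
      stringsAsFactors = FALSE))
    coords <<- rbind(coords, matrix(xyz, 1, 3))
    nrow(atoms)
  }

  set.seed(seed)
  sched <- vector("list", nrow(contacts))
  used_receptor <- integer(0)
  for (k in seq_len(nrow(contacts))) {
    ct <- contacts[k, ]
    if (ct$peptide_pos < 1L || ct$peptide_pos > L)
      stop("contact ", ct$contact_id, ": peptide_pos out of range")
    occ_frames <- ct$occupancy * n_frames
    if (abs(occ_frames - round(occ_frames)) > 1e-9)
      stop("contact ", ct$contact_id, ": occupancy * n_frames must be an ",
           "integer (got ", occ_frames, ")")
    occ_frames <- as.integer(round(occ_frames))

    p_ca <- pep_ca[ct$peptide_pos, ]
    # nearest receptor Calpha not already used by another contact
    d2 <- rowSums(sweep(structure$coords, 2, p_ca)^2)
    d2[used_receptor] <- Inf
    ri <- which.min(d2)
    used_receptor <- c(used_receptor, ri)
    r_ca <- structure$coords[ri, ]
    dir <- .unit(p_ca - r_ca)

    # receptor-side contact atom 1.5 A out of the Calpha toward the peptide
    rrow <- atoms[ri, ]
    rrow$residue_name <- ct$receptor_resname
    atoms$residue_name[ri] <- ct$receptor_resname
    elem_r <- substr(ct$receptor_atom, 1, 1)
    x_r <- r_ca + 1.5 * dir
    i_r <- add_atom(ct$receptor_atom, rrow, elem_r, x_r)

    geom <- .CONTACT_GEOM[[ct$type]]
    prow <- pep_atoms[ct$peptide_pos, ]
    elem_p <- substr(ct$peptide_atom, 1, 1)
    on_pos <- x_r + geom["on"] * dir
    off_pos <- x_r + geom["off"] * dir
    i_p <- add_atom(ct$peptide_atom, prow, elem_p, on_pos)
    i_h <- NA_integer_
    h_on <- h_off <- NULL
    if (ct$type == "hbond") {
      # linear D-H...A: H 1.0 A from the donor toward the acceptor
      h_on <- on_pos - 1.0 * dir
      h_off <- off_pos - 1.0 * dir
      i_h <- add_atom("H", prow, "H", h_on)
    }
    formed <- sort(sample.int(n_frames, occ_frames))
    sched[[k]] <- list(
      contact_id = ct$contact_id, type = ct$type,
      peptide_atom = i_p, hydrogen_atom = i_h, receptor_atom = i_r,
      peptide_label = sprintf("%s:%d:%s", prow$chain_id,
                              prow$residue_number, ct$peptide_atom),
      receptor_label = sprintf("%s:%d:%s", rrow$chain_id,
                               rrow$residue_number, ct$receptor_atom),
      target_occupancy = ct$occupancy, formed_frames = formed,
      on_pos = on_pos, off_pos = off_pos, h_on = h_on, h_off = h_off)
  }

  schedule <- structure(list(contacts = sched, n_frames = as.integer(n_frames),
                             seed = seed),
                        class = "ContactSchedule")
  list(complex = structure_model(atoms, coords), schedule = schedule)
}

#' Tabulate a contact schedule
#' @param schedule a `ContactSchedule`.
#' @return data.frame with one row per contact: id, type, partner labels,
#'   target occupancy and formed-frame count.
#' @export
schedule_table <- function(schedule) {
  do.call(rbind, lapply(schedule$contacts, function(ct)
    data.frame(contact_id = ct$contact_id, type = ct$type,
               peptide = ct$peptide_label, receptor = ct$receptor_label,
               target_occupancy = ct$target_occupancy,
               n_formed = length(ct$formed_frames),
               stringsAsFactors = FALSE)))
}

#' Realize a contact schedule as a trajectory
#'
#' Every frame starts from the complex coordinates; each contact's mobile
#' peptide atom (and its hydrogen, for hydrogen bonds) is placed at the
#' formed position in that contact's `formed_frames` and at the broken
#' position (distance criterion violated by >= 1 A) otherwise. Optional
#' Gaussian noise is applied to all atoms not involved in any contact so
#' the realized occupancies stay exact.
#'
#' @param complex `StructureModel` from [build_complex()].
#' @param schedule matching `ContactSchedule`.
#' @param noise_sd Gaussian noise (A) on non-contact atoms; default 0.
#' @param seed RNG seed for the noise.
#' @param source_id run label.
#' @return a `Trajectory` with `schedule$n_frames` frames.
#' @export
simulate_complex_trajectory <- function(complex, schedule, noise_sd = 0,
                                        seed = 1L, source_id = "complex") {
  nf <- schedule$n_frames
  n <- n_atoms(complex)
  fixed <- unlist(lapply(schedule$contacts, function(ct)
    c(ct$peptide_atom, ct$hydrogen_atom, ct$receptor_atom)))
  fixed <- fixed[!is.na(fixed)]
  coords <- array(0, dim = c(nf, n, 3L))
  set.seed(seed)
  for (t in seq_len(nf)) {
    X <- complex$coords
    if (noise_sd > 0) {
      noise <- matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
      noise[fixed, ] <- 0
      X <- X + noise
    }
    for (ct in schedule$contacts) {
      on <- t %in% ct$formed_frames
      X[ct$peptide_atom, ] <- if (on) ct$on_pos else ct$off_pos
      if (!is.na(ct$hydrogen_atom))
        X[ct$hydrogen_atom, ] <- if (on) ct$h_on else ct$h_off
    }
    coords[t, , ] <- X
  }
  trajectory(complex, coords, times = (seq_len(nf) - 1) * 10,
             source_id = source_id)
}

#' Write a synthetic fixture set to a directory
#'
#' Generates the solenoid, `n_runs` independent motion trajectories and
#' the peptide complex ensemble, writing multi-model PDB files plus a
#' JSON ground-truth sidecar (amplitudes, schedule, seeds).
#'
#' @param dir output directory (created if needed).
#' @param spec a [solenoid_spec()].
#' @param motion a [motion_spec()]; run k uses `seed + k - 1`.
#' @param n_runs number of independent trajectories.
#' @param contacts contact table for the complex.
#' @param n_contact_frames frames in the complex ensemble.
#' @return invisibly, the list of generated objects.
#' @export
write_fixture_set <- function(dir, spec = solenoid_spec(),
                              motion = motion_spec(), n_runs = 3L,
                              contacts = default_contacts(),
                              n_contact_frames = 60L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sol <- build_solenoid(spec)
  write_pdb(sol$structure, file.path(dir, "solenoid.pdb"))
  runs <- lapply(seq_len(n_runs), function(k) {
    mk <- motion; mk$seed <- motion$seed + k - 1L
    tr <- simulate_trajectory(sol$structure, sol$annotation, mk,
                              source_id = paste0("run", k))
    write_pdb(tr, file.path(dir, paste0("traj_run", k, ".pdb")))
    tr
  })
  cx <- build_complex(sol$structure, sol$annotation,
                      contacts = contacts, n_frames = n_contact_frames,
                      seed = spec$seed)
  write_pdb(cx$complex, file.path(dir, "complex.pdb"))
  ens <- simulate_complex_trajectory(cx$complex, cx$schedule)
  write_pdb(ens, file.path(dir, "complex_ensemble.pdb"))
  truth <- list(
    solenoid = spec[setdiff(names(spec), "")],
    motion = motion[setdiff(names(motion), "")],
    n_runs = n_runs,
    annotation = annotation_ranges(sol$annotation),
    anchors = as.list(default_anchors(sol$structure, sol$annotation)),
    schedule = schedule_table(cx$schedule),
    formed_frames = lapply(cx$schedule$contacts, `[[`, "formed_frames"))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(solenoid = sol, runs = runs, complex = cx, ensemble = ens))
}
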