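## Interface contact detection and occupancy: salt bridges, hydrogen bonds
## and hydrophobic contacts between a receptor and a peptide, evaluated
## per frame over an ensemble. Criteria (all inclusive at the boundary):
## donor-acceptor distance <= 3.5 A for salt bridges and hydrogen bonds,
## donor-hydrogen-acceptor angle deviation from linear <= 60 degrees for
## hydrogen bonds, and closest side-chain carbon-carbon distance <= 4 A
## for hydrophobic contacts. Contacts are reported with their occupancy
## (fraction of frames present); the headline report keeps occupancy >= 50%.

#' Interaction detection criteria
#'
#' @param hbond_dist_max donor-acceptor distance cutoff (A, default 3.5).
#' @param hbond_angle_dev_max D-H-A deviation from 180 degrees (default 60).
#' @param saltbridge_dist_max N-O distance cutoff (A, default 3.5).
#' @param hydrophobic_dist_max closest C-C distance cutoff (A, default 4).
#' @param report_min_occupancy occupancy filter for the headline report
#'   (default 0.5).
#' @return object of class `InteractionCriteria`.
#' @export
interaction_criteria <- function(hbond_dist_max = 3.5,
                                 hbond_angle_dev_max = 60,
                                 saltbridge_dist_max = 3.5,
                                 hydrophobic_dist_max = 4.0,
                                 report_min_occupancy = 0.5) {
  stopifnot(hbond_dist_max > 0, hbond_angle_dev_max > 0,
            saltbridge_dist_max > 0, hydrophobic_dist_max > 0,
            report_min_occupancy >= 0, report_min_occupancy <= 1)
  structure(as.list(environment()), class = "InteractionCriteria")
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# inclusive thresholds, robust to floating-point representation of
# geometrically exact boundary cases
.EPS_CONTACT <- 1e-9

#' Detect hydrogen bonds in one frame
#'
#' A donor-acceptor pair is present iff distance(D, A) <= `hbond_dist_max`
#' and the D-H-A angle deviates from linear by at most
#' `hbond_angle_dev_max` degrees (boundaries inclusive). Donors without
#' an explicit hydrogen are skipped with a warning unless
#' `distance_only_fallback` is set.
#'
#' @param frame a `StructureModel`.
#' @param candidates data.frame with integer atom-index columns `donor`,
#'   `hydrogen` (NA when missing) and `acceptor`.
#' @param criteria an [interaction_criteria()].
#' @param distance_only_fallback judge hydrogen-less donors by distance
#'   alone (default FALSE).
#' @return logical vector, one per candidate row.
#' @export
detect_hbonds <- function(frame, candidates,
                          criteria = interaction_criteria(),
                          distance_only_fallback = FALSE) {
  X <- frame$coords
  vapply(seq_len(nrow(candidates)), function(k) {
    d <- candidates$donor[k]; h <- candidates$hydrogen[k]
    a <- candidates$acceptor[k]
    if (.dist3(X[d, ], X[a, ]) > criteria$hbond_dist_max + .EPS_CONTACT)
      return(FALSE)
    if (is.na(h)) {
      if (!distance_only_fallback) {
        warning("donor atom ", d, " has no explicit hydrogen; skipped")
        return(FALSE)
      }
      return(TRUE)
    }
    v1 <- X[d, ] - X[h, ]; v2 <- X[a, ] - X[h, ]
    dev <- 180 - .angle_deg(v1, v2)
    dev <= criteria$hbond_angle_dev_max + .EPS_CONTACT
  }, TRUE)
}

#' Detect salt bridges in one frame
#'
#' A basic/acidic group pair is present iff the minimum nitrogen-oxygen
#' distance over the groups' atoms is `<= saltbridge_dist_max`
#' (inclusive).
#'
#' @param frame a `StructureModel`.
#' @param basic list of integer atom-index vectors, one per basic
#'   charged group (side-chain N of Lys/Arg/His or designated atoms).
#' @param acidic list of index vectors, one per acidic group (side-chain
#'   O of Asp/Glu or designated atoms).
#' @param criteria an [interaction_criteria()].
#' @return logical matrix `length(basic) x length(acidic)`.
#' @export
detect_salt_bridges <- function(frame, basic, acidic,
                                criteria = interaction_criteria()) {
  if (length(basic) == 0L || length(acidic) == 0L)
    stop("empty charged-group list")
  X <- frame$coords
  out <- matrix(FALSE, length(basic), length(acidic))
  for (i in seq_along(basic)) for (j in seq_along(acidic)) {
    A <- X[basic[[i]], , drop = FALSE]; B <- X[acidic[[j]], , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    out[i, j] <- sqrt(max(0, min(d2))) <=
      criteria$saltbridge_dist_max + .EPS_CONTACT
  }
  out
}

#' Detect hydrophobic contacts in one frame
#'
#' A residue pair is present iff the closest distance between the two
#' residues' designated side-chain carbons is `<= hydrophobic_dist_max`
#' (inclusive). Residues with no designated carbons are skipped with a
#' warning.
#'
#' @param frame a `StructureModel`.
#' @param carbons_a,carbons_b lists of integer atom-index vectors, one
#'   per residue on each side of the interface.
#' @param criteria an [interaction_criteria()].
#' @return logical matrix `length(carbons_a) x length(carbons_b)`.
#' @export
detect_hydrophobic <- function(frame, carbons_a, carbons_b,
                               criteria = interaction_criteria()) {
  empty_a <- lengths(carbons_a) == 0L
  empty_b <- lengths(carbons_b) == 0L
  if (any(empty_a) || any(empty_b))
    warning("residue(s) with no designated side-chain carbons skipped")
  X <- frame$coords
  out <- matrix(FALSE, length(carbons_a), length(carbons_b))
  for (i in which(!empty_a)) for (j in which(!empty_b)) {
    A <- X[carbons_a[[i]], , drop = FALSE]
    B <- X[carbons_b[[j]], , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    out[i, j] <- sqrt(max(0, min(d2))) <=
      criteria$hydrophobic_dist_max + .EPS_CONTACT
  }
  out
}

# residues whose side-chain carbons count as hydrophobic (documented
# default; overridable via the hydrophobic_resnames argument)
.HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")
.BASIC_N <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2")
.ACIDIC_O <- c("OD1", "OD2", "OE1", "OE2")
.BACKBONE <- c("N", "CA", "C", "O", "H", "HA")

#' Enumerate interface contact candidates
#'
#' Internal candidate generation (replacing an external contact-list
#' program): across the two selections it pairs every hydrogen-bond donor
#' (N with an attached explicit H, backbone or side chain) with every
#' acceptor O; every basic charged group (side-chain N of Lys/Arg/His)
#' with every acidic group (side-chain O of Asp/Glu); and every
#' hydrophobic residue's side-chain carbons with those across the
#' interface. Only pairs crossing the interface are produced.
#'
#' @param model topology `StructureModel`.
#' @param sel_a,sel_b the two sides of the interface (selections).
#' @param hydrophobic_resnames residues whose side-chain carbons count
#'   as hydrophobic.
#' @param h_max_dist donor-hydrogen attachment distance (A, default 1.3).
#' @return list with `hbonds` (data.frame donor/hydrogen/acceptor),
#'   `salt` (data.frame + index lists), `hydrophobic` (data.frame +
#'   index lists).
#' @export
enumerate_candidates <- function(model, sel_a, sel_b,
                                 hydrophobic_resnames = .HYDROPHOBIC_RES,
                                 h_max_dist = 1.3) {
  a <- model$atoms
  ia <- resolve_selection(model, sel_a)
  ib <- resolve_selection(model, sel_b)
  if (length(intersect(ia, ib)) > 0)
    stop("interface selections overlap")
  reskey <- paste0(a$chain_id, ":", a$residue_number)

  side <- function(idx) {
    don <- idx[a$element[idx] == "N"]
    don_h <- lapply(don, function(d) {
      same <- idx[reskey[idx] == reskey[d] & a$element[idx] == "H"]
      if (length(same) == 0L) return(NA_integer_)
      dd <- sqrt(rowSums(sweep(model$coords[same, , drop = FALSE], 2,
                               model$coords[d, ])^2))
      if (min(dd) > h_max_dist) NA_integer_ else same[which.min(dd)]
    })
    acc <- idx[a$element[idx] == "O"]
    basic_res <- unique(reskey[idx][a$atom_name[idx] %in% .BASIC_N &
                                      a$residue_name[idx] %in%
                                      c("LYS", "ARG", "HIS")])
    basic <- lapply(basic_res, function(r)
      idx[reskey[idx] == r & a$atom_name[idx] %in% .BASIC_N])
    acidic_res <- unique(reskey[idx][a$atom_name[idx] %in% .ACIDIC_O &
                                       a$residue_name[idx] %in%
                                       c("ASP", "GLU")])
    acidic <- lapply(acidic_res, function(r)
      idx[reskey[idx] == r & a$atom_name[idx] %in% .ACIDIC_O])
    hydro_res <- unique(reskey[idx][a$residue_name[idx] %in%
                                      hydrophobic_resnames])
    hydro <- lapply(hydro_res, function(r)
      idx[reskey[idx] == r & a$element[idx] == "C" &
            !(a$atom_name[idx] %in% .BACKBONE)])
    keep <- lengths(hydro) > 0L
    list(donors = don, hydrogens = unlist(don_h), acceptors = acc,
         basic = basic, basic_res = basic_res,
         acidic = acidic, acidic_res = acidic_res,
         hydro = hydro[keep], hydro_res = hydro_res[keep])
  }
  A <- side(ia); B <- side(ib)

  cross_hb <- function(S1, S2) {
    if (length(S1$donors) == 0L || length(S2$acceptors) == 0L)
      return(NULL)
    g <- expand.grid(di = seq_along(S1$donors),
                     acceptor = S2$acceptors)
    data.frame(donor = S1$donors[g$di], hydrogen = S1$hydrogens[g$di],
               acceptor = g$acceptor)
  }
  hb <- rbind(cross_hb(A, B), cross_hb(B, A))

  salt <- list(basic = c(A$basic, B$basic),
               basic_res = c(A$basic_res, B$basic_res),
               acidic = c(A$acidic, B$acidic),
               acidic_res = c(A$acidic_res, B$acidic_res),
               basic_side = rep(c("A", "B"), c(length(A$basic),
                                               length(B$basic))),
               acidic_side = rep(c("A", "B"), c(length(A$acidic),
                                                length(B$acidic))))
  hydro <- list(a = A$hydro, a_res = A$hydro_res,
                b = B$hydro, b_res = B$hydro_res)
  list(hbonds = hb, salt = salt, hydrophobic = hydro)
}

.atom_label <- function(model, i) {
  a <- model$atoms
  sprintf("%s:%d:%s", a$chain_id[i], a$residue_number[i], a$atom_name[i])
}

#' Per-contact occupancy over an ensemble
#'
#' Enumerates candidate interface contacts (see [enumerate_candidates()]),
#' evaluates every candidate in every frame, and reports one
#' `InteractionRecord` row per candidate with `frames_present` and
#' `occupancy = frames_present / n_frames`. `records` holds all
#' candidates; `filtered` keeps those with occupancy at or above
#' `report_min_occupancy` (the >= 50% headline filter by default).
#'
#' @param ensemble a `Trajectory` (e.g. from [merge_ensemble()]).
#' @param sel_a,sel_b the two sides of the interface.
#' @param criteria an [interaction_criteria()].
#' @param drop_never drop candidates never present from `records`
#'   (default FALSE; they are kept with occupancy 0).
#' @return list with data.frames `records` and `filtered` (columns:
#'   `type`, `partner_a`, `partner_b`, `frames_present`, `total_frames`,
#'   `occupancy`, `passes_filter`).
#' @export
occupancy_report <- function(ensemble, sel_a, sel_b,
                             criteria = interaction_criteria(),
                             drop_never = FALSE) {
  nf <- n_frames(ensemble)
  if (nf == 0L) stop("ensemble has zero frames")
  cand <- enumerate_candidates(ensemble$topology, sel_a, sel_b)
  if (!is.null(cand$hbonds) && anyNA(cand$hbonds$hydrogen)) {
    warning(sum(is.na(cand$hbonds$hydrogen)), " donor(s) without an ",
            "explicit hydrogen skipped as hydrogen-bond candidates")
    cand$hbonds <- cand$hbonds[!is.na(cand$hbonds$hydrogen), , drop = FALSE]
  }
  n_hb <- if (is.null(cand$hbonds)) 0L else nrow(cand$hbonds)
  n_sb <- length(cand$salt$basic) * length(cand$salt$acidic)
  n_hp <- length(cand$hydrophobic$a) * length(cand$hydrophobic$b)
  counts_hb <- integer(n_hb)
  counts_sb <- matrix(0L, length(cand$salt$basic), length(cand$salt$acidic))
  counts_hp <- matrix(0L, length(cand$hydrophobic$a),
                      length(cand$hydrophobic$b))
  for (t in seq_len(nf)) {
    fr <- get_frame(ensemble, t)
    if (n_hb > 0)
      counts_hb <- counts_hb + detect_hbonds(fr, cand$hbonds, criteria)
    if (n_sb > 0)
      counts_sb <- counts_sb +
        detect_salt_bridges(fr, cand$salt$basic, cand$salt$acidic, criteria)
    if (n_hp > 0)
      counts_hp <- counts_hp +
        suppressWarnings(detect_hydrophobic(fr, cand$hydrophobic$a,
                                            cand$hydrophobic$b, criteria))
  }
  topo <- ensemble$topology
  rec <- list()
  if (n_hb > 0)
    rec$hb <- data.frame(
      type = "hbond",
      partner_a = vapply(cand$hbonds$donor, .atom_label, "", model = topo),
      partner_b = vapply(cand$hbonds$acceptor, .atom_label, "",
                         model = topo),
      frames_present = as.integer(counts_hb), stringsAsFactors = FALSE)
  if (n_sb > 0) {
    g <- expand.grid(i = seq_along(cand$salt$basic),
                     j = seq_along(cand$salt$acidic))
    # only cross-interface group pairs
    keep <- cand$salt$basic_side[g$i] != cand$salt$acidic_side[g$j]
    g <- g[keep, , drop = FALSE]
    if (nrow(g) > 0)
      rec$sb <- data.frame(
        type = "salt_bridge",
        partner_a = cand$salt$basic_res[g$i],
        partner_b = cand$salt$acidic_res[g$j],
        frames_present = as.integer(counts_sb[cbind(g$i, g$j)]),
        stringsAsFactors = FALSE)
  }
  if (n_hp > 0) {
    g <- expand.grid(i = seq_along(cand$hydrophobic$a),
                     j = seq_along(cand$hydrophobic$b))
    rec$hp <- data.frame(
      type = "hydrophobic",
      partner_a = cand$hydrophobic$a_res[g$i],
      partner_b = cand$hydrophobic$b_res[g$j],
      frames_present = as.integer(counts_hp[cbind(g$i, g$j)]),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  if (is.null(records) || nrow(records) == 0L)
    return(list(records = data.frame(), filtered = data.frame()))
  rownames(records) <- NULL
  records$total_frames <- nf
  records$occupancy <- records$frames_present / nf
  records$passes_filter <- records$occupancy >= criteria$report_min_occupancy
  if (drop_never) records <- records[records$frames_present > 0L, ]
  list(records = records,
       filtered = records[records$passes_filter, , drop = FALSE])
}
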