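# Structure-derived per-residue descriptors: relative solvent accessibility
# (sphere-sampling ASA / published max-ASA), residue depth (distance to the
# sampled molecular surface), 3-state secondary structure via the
# Kabsch-Sander hydrogen-bond energy criterion, and backbone torsions.

PROBE_RADIUS <- 1.4

# deterministic golden-spiral unit sphere points
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(atoms) {
  r <- VDW_RADII[atoms$element]
  r[is.na(r)] <- 1.7
  unname(r)
}

# Per-atom solvent-accessible surface area (Shrake-Rupley sphere sampling)
# and, as a by-product, the exposed sampling directions used to build the
# molecular-surface point cloud for residue depth.
sasa_detail <- function(atoms, n_points = 100) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- atom_radii(atoms)
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  surface <- vector("list", n)
  ext <- radii + PROBE_RADIUS
  for (i in seq_len(n)) {
    probe_pts <- sweep(pts * ext[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    cand <- which(sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2)) < ext[i] + ext)
    for (j in setdiff(cand, i)) {
      dj2 <- rowSums(sweep(probe_pts, 2, xyz[j, ])^2)
      exposed <- exposed & dj2 > ext[j]^2
      if (!any(exposed)) break
    }
    frac <- mean(exposed)
    area[i] <- 4 * pi * ext[i]^2 * frac
    if (any(exposed)) {
      # map exposed directions back to the van der Waals (contact) surface
      surface[[i]] <- sweep(pts[exposed, , drop = FALSE] * radii[i],
                            2, xyz[i, ], "+")
    }
  }
  list(area = area, surface = do.call(rbind, surface))
}

#' Relative solvent accessibility of one residue
#'
#' Accessible surface area of the residue (sphere-sampling with a 1.4 A
#' probe, deterministic golden-spiral directions) divided by the residue
#' type's theoretical maximum ASA (Tien et al. 2013 table, bundled).
#' Values can slightly exceed 1 for highly exposed residues.
#'
#' @param protein a [protein_record()].
#' @param position residue index.
#' @param n_points sampling density per atom sphere.
#' @return RSA fraction (>= 0).
#' @export
compute_rsa <- function(protein, position, n_points = 100) {
  rsa_all(protein, n_points)[as.character(position)]
}

rsa_all <- function(protein, n_points = 100) {
  det <- sasa_detail(protein$atoms, n_points)
  resis <- modeled_positions(protein)
  out <- vapply(resis, function(ri) {
    sel <- protein$atoms$resi == ri
    if (residue_letter(protein, ri) != "G" &&
        all(protein$atoms$atom[sel] %in% c("N", "CA", "C", "O"))) {
      warning("residue ", ri, " has only backbone atoms; RSA computed anyway")
    }
    sum(det$area[sel]) / MAX_ASA[[residue_letter(protein, ri)]]
  }, numeric(1))
  stats::setNames(out, resis)
}

#' Residue depth
#'
#' Mean distance of the residue's atoms to the sampled molecular surface
#' (the van der Waals surface of solvent-exposed atoms, probe 1.4 A).
#' Surface-lying atoms have depths near their own atomic radius; deeply
#' buried atoms have depths approaching the cluster radius.
#'
#' @inheritParams compute_rsa
#' @return depth in Angstroms (>= 0).
#' @export
compute_depth <- function(protein, position, n_points = 100) {
  depth_all(protein, n_points)[as.character(position)]
}

depth_all <- function(protein, n_points = 100) {
  if (nrow(protein$atoms) < 4L) {
    stop("degenerate structure: fewer than 4 atoms")
  }
  det <- sasa_detail(protein$atoms, n_points)
  if (is.null(det$surface)) stop("structure has no solvent-exposed surface")
  xyz <- as.matrix(protein$atoms[, c("x", "y", "z")])
  surf <- det$surface
  mind <- vapply(seq_len(nrow(xyz)), function(i) {
    sqrt(min(rowSums(sweep(surf, 2, xyz[i, ])^2)))
  }, numeric(1))
  resis <- modeled_positions(protein)
  out <- vapply(resis, function(ri) mean(mind[protein$atoms$resi == ri]),
                numeric(1))
  stats::setNames(out, resis)
}

# ---------------------------------------------------------------------------
# Kabsch-Sander secondary structure, collapsed to 3 states:
# (H, G, I) -> "H", (E, B) -> "E", everything else -> "C".

backbone_coords <- function(protein) {
  resis <- modeled_positions(protein)
  get <- function(name) {
    m <- matrix(NA_real_, length(resis), 3)
    for (k in seq_along(resis)) {
      sel <- protein$atoms$resi == resis[k] & protein$atoms$atom == name
      if (any(sel)) m[k, ] <- as.numeric(protein$atoms[which(sel)[1],
                                                       c("x", "y", "z")])
    }
    m
  }
  list(resis = resis, N = get("N"), CA = get("CA"), C = get("C"),
       O = get("O"))
}

# Kabsch-Sander electrostatic hydrogen-bond energy (kcal/mol) between the
# CO of residue j (acceptor) and the NH of residue i (donor); bond if
# E < -0.5. Amide H inferred 1.0 A from N opposite the preceding carbonyl.
ks_hbond_matrix <- function(bb, sequence) {
  n <- length(bb$resis)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    co <- bb$C[i - 1, ] - bb$O[i - 1, ]
    if (all(is.finite(co)) && all(is.finite(bb$N[i, ]))) {
      H[i, ] <- bb$N[i, ] + co / vnorm(co)
    }
  }
  q1q2f <- 0.084 * 332
  hb <- matrix(FALSE, n, n)  # hb[i, j]: N-H(i) donates to C=O(j)
  for (i in 2:n) {
    letter <- substr(sequence, bb$resis[i], bb$resis[i])
    if (letter == "P") next  # proline has no amide hydrogen
    if (!all(is.finite(H[i, ])) || !all(is.finite(bb$N[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      if (!all(is.finite(bb$C[j, ])) || !all(is.finite(bb$O[j, ]))) next
      dON <- vnorm(bb$O[j, ] - bb$N[i, ])
      dCH <- vnorm(bb$C[j, ] - H[i, ])
      dOH <- vnorm(bb$O[j, ] - H[i, ])
      dCN <- vnorm(bb$C[j, ] - bb$N[i, ])
      if (dON < 0.5 || dCH < 0.5 || dOH < 0.5 || dCN < 0.5) next
      e <- q1q2f * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
      hb[i, j] <- e < -0.5
    }
  }
  hb
}

#' Assign 3-state secondary structure (Kabsch-Sander criterion)
#'
#' Re-implementation of the hydrogen-bond-pattern assignment: backbone
#' amide hydrogens are inferred from geometry, the Kabsch-Sander
#' electrostatic energy defines hydrogen bonds (E < -0.5 kcal/mol), n-turn
#' patterns define helices (two consecutive i -> i+n turns, n = 3, 4, 5)
#' and bridge patterns define strands. The 8-state alphabet is collapsed to
#' H (all helix classes), E (strand/bridge) and C (other). Residues with a
#' missing backbone atom are forced to C with a warning.
#'
#' @param protein a [protein_record()].
#' @return named character vector over modeled residues with values
#'   `"H"`, `"E"` or `"C"`.
#' @export
assign_secondary_structure <- function(protein) {
  bb <- backbone_coords(protein)
  n <- length(bb$resis)
  ss <- rep("C", n)
  incomplete <- !stats::complete.cases(cbind(bb$N, bb$CA, bb$C, bb$O))
  if (any(incomplete)) {
    warning("missing backbone atoms at residue(s) ",
            paste(bb$resis[incomplete], collapse = ", "),
            "; forced to coil")
  }
  if (n >= 5) {
    hb <- ks_hbond_matrix(bb, protein$sequence)
    # turns[nt][i]: hydrogen bond CO(i) -> NH(i + nt)
    turn <- function(nt) {
      v <- rep(FALSE, n)
      idx <- seq_len(n - nt)
      v[idx] <- hb[cbind(idx + nt, idx)]
      v
    }
    t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
    helix <- function(tn, nt) {
      mark <- rep(FALSE, n)
      for (i in 2:(n - nt)) {
        if (tn[i - 1] && tn[i]) mark[i:(i + nt - 1)] <- TRUE
      }
      mark
    }
    h4 <- helix(t4, 4)
    h3 <- helix(t3, 3)
    h5 <- helix(t5, 5)
    # bridges (parallel or antiparallel) -> strand
    bridge <- rep(FALSE, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (abs(i - j) < 3) next
        par <- (hb[i, j - 1] && hb[j + 1, i]) || (hb[j, i - 1] && hb[i + 1, j])
        anti <- (hb[j, i] && hb[i, j]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
        if (par || anti) bridge[i] <- TRUE
      }
    }
    ss[h3 | h5] <- "H"
    ss[bridge] <- "E"
    ss[h4] <- "H"
  }
  ss[incomplete] <- "C"
  stats::setNames(ss, bb$resis)
}

#' Backbone torsion angles at one residue
#'
#' Phi and psi dihedrals in degrees, in (-180, 180]. Phi is undefined (NA)
#' for the first modeled residue and psi for the last; a chain break
#' (consecutive CA-CA distance > 4.5 A) also leaves the affected angle
#' undefined, with a warning.
#'
#' @param protein a [protein_record()].
#' @param position residue index.
#' @return named numeric vector `c(phi = ..., psi = ...)`.
#' @export
compute_torsions <- function(protein, position) {
  bb <- backbone_coords(protein)
  k <- match(position, bb$resis)
  if (is.na(k)) stop("residue ", position, " is not modeled")
  n <- length(bb$resis)
  phi <- NA_real_
  psi <- NA_real_
  chain_ok <- function(k1, k2) {
    if (!all(is.finite(bb$CA[k1, ])) || !all(is.finite(bb$CA[k2, ]))) {
      return(FALSE)
    }
    d <- vnorm(bb$CA[k1, ] - bb$CA[k2, ])
    if (d > 4.5) {
      warning("chain break between residues ", bb$resis[k1], " and ",
              bb$resis[k2], " (CA-CA ", round(d, 1), " A)")
      return(FALSE)
    }
    TRUE
  }
  if (k > 1 && chain_ok(k - 1, k)) {
    phi <- dihedral_angle(bb$C[k - 1, ], bb$N[k, ], bb$CA[k, ], bb$C[k, ])
  }
  if (k < n && chain_ok(k, k + 1)) {
    psi <- dihedral_angle(bb$N[k, ], bb$CA[k, ], bb$C[k, ], bb$N[k + 1, ])
  }
  c(phi = phi, psi = psi)
}

#' Per-residue structural descriptor table
#'
#' Convenience wrapper computing RSA, depth, secondary structure, torsions
#' and pLDDT for every modeled residue in one pass.
#'
#' @param protein a [protein_record()].
#' @param n_points sphere-sampling density.
#' @return data.frame with one row per modeled residue.
#' @export
structural_descriptors <- function(protein, n_points = 100) {
  resis <- modeled_positions(protein)
  rsa <- rsa_all(protein, n_points)
  depth <- depth_all(protein, n_points)
  ss <- assign_secondary_structure(protein)
  tors <- t(vapply(resis, function(ri) {
    suppressWarnings(compute_torsions(protein, ri))
  }, numeric(2)))
  data.frame(resi = resis, rsa = unname(rsa), depth = unname(depth),
             ss = unname(ss), phi = tors[, 1], psi = tors[, 2],
             plddt = unname(protein$plddt), stringsAsFactors = FALSE)
}
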