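# Interaction-contact typing at the mutation site, mutant-vs-WT contact
# deltas, and cumulative pharmacophore graph-based signatures. Includes the
# simplified mutant-structure builder (idealized side-chain swap).
#
# All contact operators share one exclusion rule: atoms of the site residue
# itself and of its backbone-bonded neighbours (|delta position| <= 1) are
# never counted as contacts -- covalent geometry is not an interaction.

PHARMACOPHORE_CLASSES <- c("Hydrophobic", "Aromatic", "PositiveIonizable",
                           "NegativeIonizable", "HydrogenDonor",
                           "HydrogenAcceptor", "Sulfur", "Neutral")

PHARMACOPHORE_ABBREV <- c(Hydrophobic = "Hyd", Aromatic = "Aro",
                          PositiveIonizable = "Pos",
                          NegativeIonizable = "Neg",
                          HydrogenDonor = "Don", HydrogenAcceptor = "Acc",
                          Sulfur = "Sul", Neutral = "Neu")

INTERACTION_TYPES <- c("HydrogenBond", "Polar", "WeakPolar", "Hydrophobic",
                       "Aromatic", "Ionic")

# Geometric contact thresholds (Angstrom / degrees). The upstream tools the
# profile emulates publish no numbers; these defaults are configuration,
# pinned by the test suite.
DEFAULT_CONTACT_THRESHOLDS <- list(
  hbond_dist = 3.5, hbond_angle = 90, polar_dist = 4.0,
  weak_polar_dist = 4.0, hydrophobic_dist = 4.5, aromatic_dist = 6.0,
  ionic_dist = 4.0
)

#' Load a pharmacophore assignment map
#'
#' Reads a `residue,atom,classes` TSV mapping every heavy atom of the 20
#' canonical residues to one or more of the eight pharmacophore classes
#' (`;`-separated). Rows with residue `*` define backbone defaults which
#' specific residue rows may override (e.g. proline's amide nitrogen).
#'
#' @param path TSV file; defaults to the bundled map.
#' @return object of class `pharmacophore_map` (nested named list).
#' @export
load_pharmacophore_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- pkg_extdata("pharmacophores.tsv")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  map <- list(defaults = list(), residues = list())
  for (i in seq_len(nrow(tab))) {
    classes <- strsplit(tab$classes[i], ";")[[1]]
    bad <- setdiff(classes, PHARMACOPHORE_CLASSES)
    if (length(bad) > 0) {
      stop("unknown pharmacophore class(es): ", paste(bad, collapse = ", "))
    }
    if (tab$residue[i] == "*") {
      map$defaults[[tab$atom[i]]] <- classes
    } else {
      map$residues[[tab$residue[i]]][[tab$atom[i]]] <- classes
    }
  }
  structure(map, class = "pharmacophore_map")
}

atom_classes <- function(resn, atom, map) {
  cls <- map$residues[[resn]][[atom]]
  if (is.null(cls)) cls <- map$defaults[[atom]]
  cls
}

# per-atom class list for a whole structure; unknown atoms yield NULL and a
# single warning
structure_classes <- function(protein, map) {
  out <- vector("list", nrow(protein$atoms))
  unknown <- character(0)
  for (i in seq_len(nrow(protein$atoms))) {
    cls <- atom_classes(protein$atoms$resn[i], protein$atoms$atom[i], map)
    if (is.null(cls)) {
      unknown <- c(unknown, paste0(protein$atoms$resn[i], ":",
                                   protein$atoms$atom[i]))
    } else {
      out[[i]] <- cls
    }
  }
  if (length(unknown) > 0) {
    warning("atoms without pharmacophore assignment skipped: ",
            paste(unique(unknown), collapse = ", "))
  }
  out
}

# ---------------------------------------------------------------------------

#' Build a simplified mutant structure (idealized side-chain swap)
#'
#' Replaces the side chain of the mutated residue with the mutant residue's
#' idealized side-chain template placed from the existing N-CA-C backbone
#' frame (no refinement); backbone coordinates and every other residue are
#' untouched. If an externally modeled mutant structure is supplied it is
#' validated and returned instead, taking precedence over the swap.
#'
#' @param protein a [protein_record()].
#' @param mutation a [mutation_record()] mapping onto `protein`.
#' @param mutant_structure optional externally modeled [protein_record()]
#'   of the mutant (takes precedence).
#' @return a [protein_record()] of the mutant.
#' @export
build_mutant_model <- function(protein, mutation, mutant_structure = NULL) {
  if (!check_mutation_maps(mutation, protein)) {
    stop("mutation ", mutation_key(mutation),
         " does not map onto the canonical sequence")
  }
  if (!is.null(mutant_structure)) {
    resn <- unique(mutant_structure$atoms$resn[
      mutant_structure$atoms$resi == mutation$position])
    if (!identical(resn, AA_THREE[[mutation$mt]])) {
      stop("supplied mutant structure does not carry ", mutation$mt,
           " at position ", mutation$position)
    }
    return(mutant_structure)
  }
  pos <- mutation$position
  atoms <- protein$atoms
  sel <- atoms$resi == pos
  backbone <- atoms[sel & atoms$atom %in% c("N", "CA", "C", "O", "OXT"), ]
  if (!all(c("N", "CA", "C") %in% backbone$atom)) {
    stop("backbone atoms missing at residue ", pos)
  }
  mt3 <- AA_THREE[[mutation$mt]]
  get <- function(name) {
    as.numeric(backbone[backbone$atom == name, c("x", "y", "z")][1, ])
  }
  sc <- build_sidechain(mt3, get("N"), get("CA"), get("C"))
  backbone$resn <- mt3
  new_res <- backbone
  if (nrow(sc) > 0) {
    new_res <- rbind(backbone, data.frame(
      atom = sc$atom, element = atom_element(sc$atom), resi = pos,
      resn = mt3, x = sc$x, y = sc$y, z = sc$z, stringsAsFactors = FALSE))
  }
  before <- atoms[atoms$resi < pos, ]
  after <- atoms[atoms$resi > pos, ]
  new_atoms <- rbind(before, new_res, after)
  rownames(new_atoms) <- NULL
  seq_chars <- strsplit(protein$sequence, "")[[1]]
  seq_chars[pos] <- mutation$mt
  protein_record(protein$protein_id, paste(seq_chars, collapse = ""),
                 new_atoms, unname(protein$plddt))
}

# ---------------------------------------------------------------------------

ring_centroids <- function(protein, positions = NULL) {
  atoms <- protein$atoms
  if (!is.null(positions)) atoms <- atoms[atoms$resi %in% positions, ]
  out <- list()
  for (ri in unique(atoms$resi)) {
    resn <- atoms$resn[atoms$resi == ri][1]
    rings <- AROMATIC_RINGS[[resn]]
    if (is.null(rings)) next
    for (ring in rings) {
      sel <- atoms$resi == ri & atoms$atom %in% ring
      if (sum(sel) == length(ring)) {
        out[[length(out) + 1L]] <- list(
          resi = ri, centroid = colMeans(atoms[sel, c("x", "y", "z")]))
      }
    }
  }
  out
}

#' Type interaction contacts at one residue
#'
#' Counts, for the residue at `position`, atom-pair contacts of six types
#' against the rest of the structure using explicit geometric criteria:
#' hydrogen bond (donor-acceptor heavy atoms <= 3.5 A with the angle at the
#' donor, measured from its covalent antecedent, >= 90 deg), polar
#' (donor/acceptor pair <= 4.0 A), weak polar (carbon C-H donor to acceptor
#' <= 4.0 A), hydrophobic (two hydrophobic-class atoms <= 4.5 A), aromatic
#' (ring-centroid pair <= 6.0 A) and ionic (oppositely ionizable classes
#' <= 4.0 A). Atoms of the site residue and its sequence neighbours
#' (|delta| <= 1) are excluded as contact partners.
#'
#' @param protein a [protein_record()].
#' @param position residue index.
#' @param map a [load_pharmacophore_map()] result.
#' @param thresholds named list overriding the default geometric cutoffs.
#' @return object of class `interaction_profile`: named integer vector over
#'   the six interaction types.
#' @export
type_contacts <- function(protein, position,
                          map = load_pharmacophore_map(),
                          thresholds = DEFAULT_CONTACT_THRESHOLDS) {
  th <- utils::modifyList(DEFAULT_CONTACT_THRESHOLDS, thresholds)
  atoms <- protein$atoms
  cls <- structure_classes(protein, map)
  site_idx <- which(atoms$resi == position)
  if (length(site_idx) == 0) stop("residue ", position, " is not modeled")
  other_idx <- which(abs(atoms$resi - position) > 1)
  counts <- stats::setNames(integer(length(INTERACTION_TYPES)),
                            INTERACTION_TYPES)
  if (length(other_idx) > 0) {
    sx <- as.matrix(atoms[site_idx, c("x", "y", "z")])
    ox <- as.matrix(atoms[other_idx, c("x", "y", "z")])
    dmat <- sqrt(outer(rowSums(sx^2), rep(1, nrow(ox))) +
                   outer(rep(1, nrow(sx)), rowSums(ox^2)) -
                   2 * sx %*% t(ox))
    antecedent <- function(i) {
      same <- which(atoms$resi == atoms$resi[i])
      same <- setdiff(same, i)
      if (length(same) == 0) return(NULL)
      p <- as.numeric(atoms[i, c("x", "y", "z")])
      d <- vapply(same, function(j) {
        vnorm(p - as.numeric(atoms[j, c("x", "y", "z")]))
      }, numeric(1))
      if (min(d) > 2.0) return(NULL)
      as.numeric(atoms[same[which.min(d)], c("x", "y", "z")])
    }
    hbond_geometry_ok <- function(donor_i, acceptor_i) {
      ante <- antecedent(donor_i)
      if (is.null(ante)) return(TRUE)
      dpos <- as.numeric(atoms[donor_i, c("x", "y", "z")])
      apos <- as.numeric(atoms[acceptor_i, c("x", "y", "z")])
      bond_angle(ante, dpos, apos) >= th$hbond_angle
    }
    for (a in seq_along(site_idx)) {
      i <- site_idx[a]
      ci <- cls[[i]]
      if (is.null(ci)) next
      for (b in seq_along(other_idx)) {
        j <- other_idx[b]
        cj <- cls[[j]]
        if (is.null(cj)) next
        d <- dmat[a, b]
        if (d > max(th$hydrophobic_dist, th$polar_dist,
                    th$weak_polar_dist, th$ionic_dist, th$hbond_dist)) next
        don_i <- "HydrogenDonor" %in% ci; acc_i <- "HydrogenAcceptor" %in% ci
        don_j <- "HydrogenDonor" %in% cj; acc_j <- "HydrogenAcceptor" %in% cj
        if (d <= th$hbond_dist &&
            ((don_i && acc_j && hbond_geometry_ok(i, j)) ||
             (don_j && acc_i && hbond_geometry_ok(j, i)))) {
          counts["HydrogenBond"] <- counts["HydrogenBond"] + 1L
        }
        if (d <= th$polar_dist && ((don_i && acc_j) || (don_j && acc_i))) {
          counts["Polar"] <- counts["Polar"] + 1L
        }
        if (d <= th$weak_polar_dist &&
            ((atoms$element[i] == "C" && acc_j) ||
             (atoms$element[j] == "C" && acc_i))) {
          counts["WeakPolar"] <- counts["WeakPolar"] + 1L
        }
        if (d <= th$hydrophobic_dist && "Hydrophobic" %in% ci &&
            "Hydrophobic" %in% cj) {
          counts["Hydrophobic"] <- counts["Hydrophobic"] + 1L
        }
        if (d <= th$ionic_dist &&
            (("PositiveIonizable" %in% ci && "NegativeIonizable" %in% cj) ||
             ("NegativeIonizable" %in% ci && "PositiveIonizable" %in% cj))) {
          counts["Ionic"] <- counts["Ionic"] + 1L
        }
      }
    }
  }
  site_rings <- ring_centroids(protein, position)
  if (length(site_rings) > 0) {
    other_rings <- Filter(function(r) abs(r$resi - position) > 1,
                          ring_centroids(protein))
    for (r1 in site_rings) {
      for (r2 in other_rings) {
        if (vnorm(r1$centroid - r2$centroid) <= th$aromatic_dist) {
          counts["Aromatic"] <- counts["Aromatic"] + 1L
        }
      }
    }
  }
  structure(counts, class = "interaction_profile")
}

#' Contact delta between WT and mutant profiles
#'
#' Per-type mutant minus wild-type counts. In feature matrices the WT
#' profile is exported as `IT<Type>` and the delta as `ITd_<Type>`.
#'
#' @param wt,mut [type_contacts()] profiles computed at the same site.
#' @return named integer vector over the six interaction types.
#' @export
contact_delta <- function(wt, mut) {
  stopifnot(identical(names(wt), INTERACTION_TYPES),
            identical(names(mut), INTERACTION_TYPES))
  stats::setNames(as.integer(unclass(mut) - unclass(wt)),
                  INTERACTION_TYPES)
}

contact_feature_vector <- function(wt, mut) {
  c(stats::setNames(as.numeric(unclass(wt)),
                    paste0("IT", INTERACTION_TYPES)),
    stats::setNames(as.numeric(contact_delta(wt, mut)),
                    paste0("ITd_", INTERACTION_TYPES)))
}

# ---------------------------------------------------------------------------

signature_pair_names <- function(cutoffs) {
  ab <- sort(unname(PHARMACOPHORE_ABBREV))
  pairs <- character(0)
  for (i in seq_along(ab)) {
    for (j in i:length(ab)) {
      pairs <- c(pairs, paste0(ab[i], ":", ab[j]))
    }
  }
  as.vector(t(outer(pairs, sprintf("%.2f", cutoffs), paste, sep = "-")))
}

#' Cumulative pharmacophore graph-based signature at one site
#'
#' Models atoms as pharmacophore-class nodes and counts, for every
#' unordered class pair and every cutoff of a distance grid, the atom pairs
#' (one atom in the site residue, one elsewhere, same exclusion rule as
#' [type_contacts()]) within that cutoff. Counts are cumulative in the
#' cutoff. Component names follow `<ClassA>:<ClassB>-<cutoff>` with
#' two-decimal cutoffs (e.g. `Aro:Sul-11.00`). When a `mutation` is given,
#' eight pharmacophore-change components are appended (class abbreviation
#' alone, e.g. `Neg`): the WT-to-mutant change in the residue's atom count
#' of that class, from the idealized mutant model.
#'
#' @param protein a [protein_record()].
#' @param position residue index.
#' @param map a [load_pharmacophore_map()] result.
#' @param cutoffs increasing distance grid in Angstroms.
#' @param mutation optional [mutation_record()] for the change components.
#' @return named numeric vector (class `signature_vector`).
#' @export
graph_signature <- function(protein, position,
                            map = load_pharmacophore_map(),
                            cutoffs = seq(1, 11, by = 0.5),
                            mutation = NULL) {
  atoms <- protein$atoms
  cls <- structure_classes(protein, map)
  site_idx <- which(atoms$resi == position)
  if (length(site_idx) == 0) stop("residue ", position, " is not modeled")
  other_idx <- which(abs(atoms$resi - position) > 1)
  names_out <- signature_pair_names(cutoffs)
  sig <- stats::setNames(numeric(length(names_out)), names_out)
  if (length(other_idx) > 0) {
    sx <- as.matrix(atoms[site_idx, c("x", "y", "z")])
    ox <- as.matrix(atoms[other_idx, c("x", "y", "z")])
    d2 <- outer(rowSums(sx^2), rep(1, nrow(ox))) +
      outer(rep(1, nrow(sx)), rowSums(ox^2)) - 2 * sx %*% t(ox)
    d2[d2 < 0] <- 0
    dmat <- sqrt(d2)
    maxcut <- max(cutoffs)
    hits <- which(dmat <= maxcut, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      i <- site_idx[hits[h, 1]]
      j <- other_idx[hits[h, 2]]
      ci <- cls[[i]]; cj <- cls[[j]]
      if (is.null(ci) || is.null(cj)) next
      d <- dmat[hits[h, 1], hits[h, 2]]
      cut_sel <- cutoffs >= d
      for (a in PHARMACOPHORE_ABBREV[ci]) {
        for (b in PHARMACOPHORE_ABBREV[cj]) {
          pr <- paste(sort(c(a, b)), collapse = ":")
          keys <- paste0(pr, "-", sprintf("%.2f", cutoffs[cut_sel]))
          sig[keys] <- sig[keys] + 1
        }
      }
    }
  }
  if (!is.null(mutation)) {
    sig <- c(sig, pharmacophore_change(protein, mutation, map))
  }
  structure(sig, class = c("signature_vector", class(sig)))
}

#' WT-to-mutant pharmacophore count change at the mutated residue
#' @keywords internal
pharmacophore_change <- function(protein, mutation,
                                 map = load_pharmacophore_map()) {
  count_classes <- function(prot) {
    sel <- prot$atoms$resi == mutation$position
    counts <- stats::setNames(numeric(8), unname(PHARMACOPHORE_ABBREV))
    for (i in which(sel)) {
      cl <- atom_classes(prot$atoms$resn[i], prot$atoms$atom[i], map)
      for (cc in cl) {
        ab <- PHARMACOPHORE_ABBREV[[cc]]
        counts[ab] <- counts[ab] + 1
      }
    }
    counts
  }
  mut <- build_mutant_model(protein, mutation)
  count_classes(mut) - count_classes(protein)
}
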