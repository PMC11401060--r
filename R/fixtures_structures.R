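# Synthetic structure fixtures: ideal backbones built from standard bond
# lengths/angles with requested torsions, plus idealized side chains.
# These stand in for predicted monomer models so that every structural
# operation is testable offline.

BACKBONE_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, omega = 180
)

#' Build an ideal polypeptide with uniform backbone torsions
#'
#' Constructs a single-chain all-heavy-atom model of `sequence` with every
#' residue at the requested (phi, psi), using standard backbone bond
#' lengths and angles and idealized side-chain templates. The default
#' torsions give an alpha-helix; `phi = psi = 180` gives a fully extended
#' chain. B-factors (pLDDT) are settable per residue.
#'
#' @param sequence amino-acid string (length >= 4 for a meaningful helix;
#'   >= 2 accepted).
#' @param phi,psi backbone torsions in degrees (finite).
#' @param plddt scalar or per-residue vector of confidence values.
#' @param protein_id symbol for the resulting record.
#' @return a [protein_record()].
#' @export
build_ideal_helix <- function(sequence, phi = -57, psi = -47, plddt = 90,
                              protein_id = "FIXTURE") {
  if (!is.finite(phi) || !is.finite(psi)) stop("torsions must be finite")
  letters1 <- strsplit(sequence, "")[[1]]
  stop_if_not_canonical(letters1, "sequence")
  n_res <- length(letters1)
  if (n_res < 2L) stop("sequence too short for a backbone")
  g <- BACKBONE_GEOM
  N <- vector("list", n_res); CA <- vector("list", n_res)
  C <- vector("list", n_res)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  C[[1]] <- CA[[1]] + g$ca_c * c(cos(pi - g$ang_n_ca_c * pi / 180),
                                 sin(pi - g$ang_n_ca_c * pi / 180), 0)
  for (i in seq_len(n_res)[-1]) {
    N[[i]]  <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                          g$c_n, g$ang_ca_c_n, psi)
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          g$n_ca, g$ang_c_n_ca, g$omega)
    C[[i]]  <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                          g$ca_c, g$ang_n_ca_c, phi)
  }
  rows <- list()
  add_atom <- function(resi, resn, atom, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom = atom, element = atom_element(atom), resi = resi, resn = resn,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    resn <- AA_THREE[[letters1[i]]]
    add_atom(i, resn, "N", N[[i]])
    add_atom(i, resn, "CA", CA[[i]])
    add_atom(i, resn, "C", C[[i]])
    # O dihedral N-CA-C-O = psi + 180 (trans to the next amide nitrogen)
    add_atom(i, resn, "O",
             place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o,
                        psi + 180))
    sc <- build_sidechain(resn, N[[i]], CA[[i]], C[[i]])
    for (j in seq_len(nrow(sc))) {
      add_atom(i, resn, sc$atom[j], c(sc$x[j], sc$y[j], sc$z[j]))
    }
  }
  atoms <- do.call(rbind, rows)
  if (length(plddt) == 1L) plddt <- rep(plddt, n_res)
  protein_record(protein_id, sequence, atoms, plddt)
}

#' Build a packed two-helix bundle fixture
#'
#' Two ideal helices of equal length joined as one chain (with a chain
#' break between them), the second translated sideways by `separation`
#' Angstroms. Interface residues are buried; outward-facing residues are
#' solvent exposed, which gives the burial contrast needed by surface and
#' depth tests.
#'
#' @param seq1,seq2 amino-acid strings of the two helices.
#' @param separation center-to-center distance between helix axes (A).
#' @param plddt scalar or per-residue confidence values.
#' @param protein_id symbol for the record.
#' @return a [protein_record()].
#' @export
build_helix_bundle <- function(seq1, seq2, separation = 10, plddt = 90,
                               protein_id = "BUNDLE") {
  h1 <- build_ideal_helix(seq1, protein_id = protein_id, plddt = 50)
  h2 <- build_ideal_helix(seq2, protein_id = protein_id, plddt = 50)
  ca1 <- h1$atoms[h1$atoms$atom == "CA", c("x", "y", "z")]
  axis <- unit(as.numeric(ca1[nrow(ca1), ]) - as.numeric(ca1[1, ]))
  # any vector perpendicular to the helix axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- unit(pracma_cross(axis, ref))
  a2 <- h2$atoms
  a2$x <- a2$x + separation * perp[1]
  a2$y <- a2$y + separation * perp[2]
  a2$z <- a2$z + separation * perp[3]
  a2$resi <- a2$resi + nchar(seq1)
  atoms <- rbind(h1$atoms, a2)
  n_res <- nchar(seq1) + nchar(seq2)
  if (length(plddt) == 1L) plddt <- rep(plddt, n_res)
  protein_record(protein_id, paste0(seq1, seq2), atoms, plddt)
}
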