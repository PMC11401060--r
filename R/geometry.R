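# Internal-coordinate geometry: dihedrals and NeRF atom placement used by
# the fixture builders and the idealized side-chain swap.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vnorm(v)

#' @keywords internal
bond_angle <- function(a, b, c) {
  v1 <- unit(a - b)
  v2 <- unit(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Dihedral angle of four points
#'
#' Signed dihedral a-b-c-d in degrees, in (-180, 180].
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Natural extension reference frame (NeRF) placement
#'
#' Places atom D bonded to `c` such that |c-D| = `bond`, angle(b, c, D) =
#' `angle` (degrees) and dihedral(a, b, c, D) = `torsion` (degrees).
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # sign flip matches dihedral_angle() convention
  d2 <- c(bond * cos(pi - ang),
          bond * sin(pi - ang) * cos(tor),
          bond * sin(pi - ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d2 + c)
}

# Side-chain z-matrices. Each row: atom placed from reference atoms
# (a, b, c) with bond length (to c), angle (b-c-atom) and torsion
# (a-b-c-atom), all within one residue (backbone N/CA/C already placed).
# CB uses the L-chirality improper torsion C-N-CA-CB = +122.6 deg.
zrow <- function(atom, a, b, c, bond, angle, torsion) {
  list(atom = atom, a = a, b = b, c = c,
       bond = bond, angle = angle, torsion = torsion)
}

CB_ROW <- zrow("CB", "C", "N", "CA", 1.53, 110.5, 122.6)

SIDECHAIN_ZMAT <- list(
  GLY = list(),
  ALA = list(CB_ROW),
  SER = list(CB_ROW, zrow("OG",  "N", "CA", "CB", 1.42, 110.5, -65)),
  CYS = list(CB_ROW, zrow("SG",  "N", "CA", "CB", 1.81, 114.0, -65)),
  THR = list(CB_ROW,
             zrow("OG1", "N", "CA", "CB", 1.43, 109.5, -65),
             zrow("CG2", "N", "CA", "CB", 1.52, 111.0, 173)),
  VAL = list(CB_ROW,
             zrow("CG1", "N", "CA", "CB", 1.53, 111.0, -65),
             zrow("CG2", "N", "CA", "CB", 1.53, 111.0, 173)),
  LEU = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB", 1.53, 116.0, -65),
             zrow("CD1", "CA", "CB", "CG", 1.53, 111.0, 180),
             zrow("CD2", "CA", "CB", "CG", 1.53, 111.0, 60)),
  ILE = list(CB_ROW,
             zrow("CG1", "N",  "CA", "CB",  1.53, 111.0, -65),
             zrow("CG2", "N",  "CA", "CB",  1.53, 111.0, 173),
             zrow("CD1", "CA", "CB", "CG1", 1.53, 111.0, 180)),
  MET = list(CB_ROW,
             zrow("CG", "N",  "CA", "CB", 1.53, 114.0, -65),
             zrow("SD", "CA", "CB", "CG", 1.81, 112.7, 180),
             zrow("CE", "CB", "CG", "SD", 1.79, 100.2, 180)),
  PRO = list(CB_ROW,
             zrow("CG", "N",  "CA", "CB", 1.50, 104.0, 30),
             zrow("CD", "CA", "CB", "CG", 1.51, 105.0, -35)),
  ASP = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB", 1.52, 112.6, -65),
             zrow("OD1", "CA", "CB", "CG", 1.25, 118.5, -20),
             zrow("OD2", "CA", "CB", "CG", 1.25, 118.5, 160)),
  ASN = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB", 1.52, 112.6, -65),
             zrow("OD1", "CA", "CB", "CG", 1.23, 120.8, -20),
             zrow("ND2", "CA", "CB", "CG", 1.33, 116.4, 160)),
  GLU = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB", 1.53, 114.0, -65),
             zrow("CD",  "CA", "CB", "CG", 1.52, 112.6, 180),
             zrow("OE1", "CB", "CG", "CD", 1.25, 118.5, 0),
             zrow("OE2", "CB", "CG", "CD", 1.25, 118.5, 180)),
  GLN = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB", 1.53, 114.0, -65),
             zrow("CD",  "CA", "CB", "CG", 1.52, 112.6, 180),
             zrow("OE1", "CB", "CG", "CD", 1.23, 120.8, 0),
             zrow("NE2", "CB", "CG", "CD", 1.33, 116.4, 180)),
  LYS = list(CB_ROW,
             zrow("CG", "N",  "CA", "CB", 1.53, 114.0, -65),
             zrow("CD", "CA", "CB", "CG", 1.53, 111.0, 180),
             zrow("CE", "CB", "CG", "CD", 1.53, 111.0, 180),
             zrow("NZ", "CG", "CD", "CE", 1.49, 111.0, 180)),
  ARG = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB", 1.53, 114.0, -65),
             zrow("CD",  "CA", "CB", "CG", 1.53, 111.0, 180),
             zrow("NE",  "CB", "CG", "CD", 1.46, 111.8, 180),
             zrow("CZ",  "CG", "CD", "NE", 1.33, 124.4, 180),
             zrow("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
             zrow("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)),
  HIS = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB",  1.49, 113.8, -65),
             zrow("ND1", "CA", "CB", "CG",  1.38, 122.7, 90),
             zrow("CD2", "CA", "CB", "CG",  1.36, 129.1, -90),
             zrow("CE1", "CB", "CG", "ND1", 1.32, 109.0, 180),
             zrow("NE2", "CG", "ND1", "CE1", 1.31, 111.0, 0)),
  PHE = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB",  1.50, 113.8, -65),
             zrow("CD1", "CA", "CB", "CG",  1.39, 120.0, 90),
             zrow("CD2", "CA", "CB", "CG",  1.39, 120.0, -90),
             zrow("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             zrow("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             zrow("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  TYR = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB",  1.50, 113.8, -65),
             zrow("CD1", "CA", "CB", "CG",  1.39, 120.0, 90),
             zrow("CD2", "CA", "CB", "CG",  1.39, 120.0, -90),
             zrow("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             zrow("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             zrow("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0),
             zrow("OH",  "CD1", "CE1", "CZ", 1.38, 120.0, 180)),
  TRP = list(CB_ROW,
             zrow("CG",  "N",  "CA", "CB",  1.50, 113.8, -65),
             zrow("CD1", "CA", "CB", "CG",  1.37, 127.0, 90),
             zrow("CD2", "CA", "CB", "CG",  1.43, 126.6, -90),
             zrow("NE1", "CB", "CG", "CD1", 1.38, 110.2, 180),
             zrow("CE2", "CB", "CG", "CD2", 1.41, 107.2, 180),
             zrow("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0),
             zrow("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180),
             zrow("CZ3", "CG", "CD2", "CE3", 1.39, 118.7, 180),
             zrow("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0)
  )
)

#' Build idealized side-chain coordinates for one residue
#'
#' Given backbone N/CA/C coordinates, returns the heavy side-chain atoms
#' (including CB) of `res3` placed from internal-coordinate templates.
#'
#' @param res3 three-letter residue name.
#' @param n,ca,c numeric xyz vectors of the backbone atoms.
#' @return data.frame with columns `atom`, `x`, `y`, `z` (0 rows for GLY).
#' @keywords internal
build_sidechain <- function(res3, n, ca, c) {
  zmat <- SIDECHAIN_ZMAT[[res3]]
  if (is.null(zmat)) stop("no side-chain template for residue ", res3)
  coords <- list(N = n, CA = ca, C = c)
  out <- data.frame(atom = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), stringsAsFactors = FALSE)
  for (row in zmat) {
    p <- place_atom(coords[[row$a]], coords[[row$b]], coords[[row$c]],
                    row$bond, row$angle, row$torsion)
    coords[[row$atom]] <- p
    out <- rbind(out, data.frame(atom = row$atom, x = p[1], y = p[2],
                                 z = p[3], stringsAsFactors = FALSE))
  }
  out
}
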