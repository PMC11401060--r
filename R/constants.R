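# Canonical amino-acid tables and residue-group schemes shared across modules.

#' @keywords internal
AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @keywords internal
AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' @keywords internal
AA_FROM_THREE <- stats::setNames(names(AA_THREE), AA_THREE)

is_canonical_aa <- function(x) {
  is.character(x) & x %in% AA_ONE
}

stop_if_not_canonical <- function(x, what = "residue") {
  bad <- x[!is_canonical_aa(x)]
  if (length(bad) > 0) {
    stop(sprintf("non-canonical %s letter(s): %s", what,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Five-group biochemical classification of the 20 amino acids.
FIVE_GROUPS <- list(
  hydrophobic = c("A", "F", "I", "L", "M", "V", "W", "Y"),
  polar       = c("N", "Q", "S", "T"),
  negative    = c("D", "E"),
  positive    = c("H", "K", "R"),
  special     = c("C", "G", "P")
)

# Seven-group classification used for the neighboring-residue frequency.
SEVEN_GROUPS <- list(
  hydrophobic           = c("A", "L", "M"),
  aliphatic             = c("I", "V"),
  aromatic              = c("F", "Y", "W"),
  long_polar            = c("E", "Q", "K", "R"),
  short_polar           = c("H", "S", "T", "C"),
  short_charged_polar   = c("D", "N"),
  structure_breaking    = c("G", "P")
)

scheme_assignment <- function(groups) {
  out <- character(0)
  for (g in names(groups)) {
    out[groups[[g]]] <- g
  }
  out[AA_ONE]
}

#' Residue group schemes
#'
#' Returns one of the two built-in residue classification schemes: the
#' five-group biochemical scheme (hydrophobic / polar / negative / positive /
#' special) used for wild-type and mutant indicator features, or the
#' seven-group scheme (hydrophobic / aliphatic / aromatic / long_polar /
#' short_polar / short_charged_polar / structure_breaking) used by the
#' neighboring amino-acid frequency.
#'
#' @param name `"five"` or `"seven"`.
#' @return An object of class `group_scheme`: a list with `name` and
#'   `assignment` (named character vector over the 20 canonical letters).
#' @export
group_scheme <- function(name = c("five", "seven")) {
  name <- match.arg(name)
  groups <- if (name == "five") FIVE_GROUPS else SEVEN_GROUPS
  structure(list(name = name, assignment = scheme_assignment(groups)),
            class = "group_scheme")
}

# Theoretical maximum accessible surface area per residue type (Angstrom^2),
# Tien et al. (2013) theoretical values; used to normalise ASA into RSA.
MAX_ASA <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
             Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
             L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
             S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# Van der Waals radii by element (Angstrom) for surface calculations.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "pathomiss")
  if (nzchar(p)) return(p)
  local <- file.path("inst", "extdata", file)  # sourced-from-tree fallback
  if (file.exists(local)) return(local)
  stop("bundled data file not found: ", file)
}

atom_element <- function(atom_names) {
  # PDB convention: element is the first alphabetic character for C/N/O/S
  # heavy atoms (no two-letter elements occur in canonical residues).
  substr(gsub("[^A-Z]", "", toupper(atom_names)), 1L, 1L)
}

# Aromatic ring memberships used for ring-centroid contact typing.
AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)
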