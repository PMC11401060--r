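# Reading and validation of sequences, structures and mutation tables.
# Conventions established here and used everywhere else:
#   * residue numbering is 1-based and equals the canonical-sequence position
#     (predicted-monomer convention: structures arrive renumbered);
#   * only the 20 canonical residues are supported;
#   * per-residue model confidence (pLDDT, 0-100) is read from the
#     alpha-carbon B-factor.

#' Construct a ProteinRecord
#'
#' Container for one protein: canonical sequence, heavy-atom coordinates of a
#' single-chain monomer model, and per-residue confidence (pLDDT) taken from
#' the structure's B-factor column.
#'
#' @param protein_id short gene-style symbol.
#' @param sequence amino-acid string over the 20 canonical letters.
#' @param atoms data.frame with columns `atom`, `element`, `resi` (1-based
#'   residue index), `resn` (three-letter residue name), `x`, `y`, `z`.
#' @param plddt numeric vector, one confidence value in \[0, 100\] per
#'   modeled residue, named by residue index.
#' @return object of class `protein_record`.
#' @export
protein_record <- function(protein_id, sequence, atoms, plddt) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  letters1 <- strsplit(sequence, "")[[1]]
  stop_if_not_canonical(letters1, "sequence")
  resis <- sort(unique(atoms$resi))
  if (length(resis) == 0) stop("structure contains no residues")
  if (!all(diff(resis) == 1L)) {
    stop("residue indices are not contiguous over the modeled range")
  }
  if (min(resis) < 1L || max(resis) > length(letters1)) {
    stop("residue indices fall outside the canonical sequence (1..",
         length(letters1), ")")
  }
  for (ri in resis) {
    resn <- unique(atoms$resn[atoms$resi == ri])
    if (length(resn) != 1L) {
      stop("conflicting residue names at residue index ", ri)
    }
    expected <- AA_THREE[[letters1[ri]]]
    if (resn != expected) {
      stop(sprintf(
        "sequence/structure mismatch at residue index %d: sequence %s (%s), structure %s",
        ri, letters1[ri], expected, resn))
    }
  }
  if (length(plddt) != length(resis)) {
    stop("plddt must hold exactly one value per modeled residue (",
         length(resis), " residues, ", length(plddt), " values)")
  }
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100)) {
    stop("plddt values must be finite and within [0, 100]")
  }
  names(plddt) <- resis
  structure(list(protein_id = protein_id, sequence = sequence,
                 atoms = atoms, plddt = plddt),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record %s: %d residues, %d atoms, mean pLDDT %.1f>\n",
              x$protein_id, nchar(x$sequence), nrow(x$atoms),
              mean(x$plddt)))
  invisible(x)
}

modeled_positions <- function(protein) {
  sort(unique(protein$atoms$resi))
}

residue_letter <- function(protein, position) {
  substr(protein$sequence, position, position)
}

#' Construct a MutationRecord
#'
#' One missense variant: protein symbol, 1-based canonical-sequence
#' position, wild-type and mutant residues, and a phenotype label.
#'
#' @param protein_id protein symbol.
#' @param position 1-based position.
#' @param wt,mt canonical one-letter residues, `wt != mt`.
#' @param label `"Disease-causing"`, `"Neutral"` or `"Unlabeled"`.
#' @return object of class `mutation_record`.
#' @export
mutation_record <- function(protein_id, position, wt, mt,
                            label = "Unlabeled") {
  stop_if_not_canonical(c(wt, mt))
  if (wt == mt) stop("synonymous substitution (wt == mt): not a missense mutation")
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stop("position must be a 1-based integer")
  label <- normalize_label(label)
  structure(list(protein_id = protein_id, position = position,
                 wt = wt, mt = mt, label = label),
            class = "mutation_record")
}

#' @export
print.mutation_record <- function(x, ...) {
  cat(sprintf("<mutation %s %s%d%s [%s]>\n", x$protein_id, x$wt, x$position,
              x$mt, x$label))
  invisible(x)
}

mutation_key <- function(m) {
  sprintf("%s_%s%d%s", m$protein_id, m$wt, m$position, m$mt)
}

normalize_label <- function(label) {
  lab <- tolower(trimws(label))
  if (lab %in% c("disease-causing", "disease causing", "pathogenic", "disease")) {
    return("Disease-causing")
  }
  if (lab %in% c("neutral", "benign", "non-disease")) return("Neutral")
  if (lab %in% c("", "unlabeled", "unlabelled", "na", "unknown")) {
    return("Unlabeled")
  }
  stop("unrecognized phenotype label: ", label)
}

# ---------------------------------------------------------------------------
# PDB parsing / writing (single chain, ATOM records, fixed-width columns).

parse_pdb_atoms <- function(lines) {
  atom_lines <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom_lines) == 0) stop("no ATOM records in structure file")
  data.frame(
    atom = trimws(substr(atom_lines, 13, 16)),
    resn = trimws(substr(atom_lines, 18, 20)),
    chain = substr(atom_lines, 22, 22),
    resi = as.integer(substr(atom_lines, 23, 26)),
    x = as.numeric(substr(atom_lines, 31, 38)),
    y = as.numeric(substr(atom_lines, 39, 46)),
    z = as.numeric(substr(atom_lines, 47, 54)),
    bfactor = as.numeric(substr(atom_lines, 61, 66)),
    stringsAsFactors = FALSE
  )
}

#' Load a protein (FASTA sequence + single-chain PDB model)
#'
#' Reads the canonical sequence from a single-record FASTA file and the
#' monomer model from a PDB file whose B-factor column carries per-residue
#' confidence (pLDDT), as written by structure-prediction pipelines. The
#' model must be a single chain, renumbered so residue indices equal
#' canonical-sequence positions, and every residue must have an
#' alpha-carbon (whose B-factor is taken as the residue pLDDT).
#'
#' @param fasta_path path to a FASTA file holding exactly one record.
#' @param structure_path path to a single-chain PDB file.
#' @param protein_id optional symbol; defaults to the FASTA record name.
#' @return a [protein_record()].
#' @export
load_protein <- function(fasta_path, structure_path, protein_id = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("FASTA file must hold exactly one record, found ", length(seqs))
  }
  sequence <- as.character(seqs[[1]])
  if (is.null(protein_id)) {
    protein_id <- strsplit(names(seqs)[1], "\\s+")[[1]][1]
  }
  lines <- readLines(structure_path)
  atoms <- parse_pdb_atoms(lines)
  chains <- unique(atoms$chain)
  if (length(chains) > 1L) {
    stop("multi-chain structure not supported; chains found: ",
         paste(chains, collapse = ", "))
  }
  plddt <- vapply(sort(unique(atoms$resi)), function(ri) {
    ca <- atoms$bfactor[atoms$resi == ri & atoms$atom == "CA"]
    if (length(ca) == 0) {
      stop("missing alpha-carbon at residue index ", ri)
    }
    ca[1]
  }, numeric(1))
  atoms$element <- atom_element(atoms$atom)
  atoms$chain <- NULL
  atoms$bfactor <- NULL
  protein_record(protein_id, sequence, atoms, plddt)
}

#' Write a ProteinRecord to a PDB file
#'
#' Emits standard fixed-width ATOM records (chain A), with the B-factor
#' column set per-residue from `bfactor` (default: the record's pLDDT).
#' Round-trips through [load_protein()] to format precision.
#'
#' @param protein a [protein_record()].
#' @param path output file.
#' @param bfactor per-residue values for the B-factor column, aligned with
#'   the modeled residues; defaults to `protein$plddt`.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(protein, path, bfactor = NULL) {
  atoms <- protein$atoms
  resis <- modeled_positions(protein)
  if (is.null(bfactor)) bfactor <- protein$plddt
  if (length(bfactor) != length(resis)) {
    stop("bfactor must hold one value per modeled residue")
  }
  bmap <- stats::setNames(bfactor, resis)
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    name4 <- if (nchar(a$atom) < 4L) sprintf(" %-3s", a$atom) else a$atom
    lines[i] <- sprintf(
      "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name4, a$resn, a$resi, a$x, a$y, a$z, 1.0,
      bmap[[as.character(a$resi)]], a$element)
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Write a one-record FASTA file
#' @keywords internal
write_fasta <- function(protein, path) {
  writeLines(c(paste0(">", protein$protein_id), protein$sequence), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Mutation tables.

#' Parse a mutation CSV table
#'
#' Expects header columns `protein,position,wt,mt,label`. Rows that are
#' synonymous (`wt == mt`), carry non-canonical letters (B, Z, X, U, ...)
#' or have a malformed position are rejected, not errors: the function is a
#' filter whose accepted + rejected rows account for every input row.
#'
#' @param csv_path path to the CSV file.
#' @return list with `records` (list of [mutation_record()]) and `rejected`
#'   (data.frame of offending rows with a `reason` column).
#' @export
parse_mutation_table <- function(csv_path) {
  raw <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("protein", "position", "wt", "mt", "label")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("mutation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- list()
  rejected <- data.frame(row = integer(0), protein = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  reject <- function(i, reason) {
    rejected <<- rbind(rejected, data.frame(
      row = i, protein = raw$protein[i], reason = reason,
      stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(raw))) {
    wt <- toupper(trimws(raw$wt[i]))
    mt <- toupper(trimws(raw$mt[i]))
    pos <- suppressWarnings(as.integer(trimws(raw$position[i])))
    if (!is_canonical_aa(wt) || !is_canonical_aa(mt)) {
      reject(i, "non-canonical residue")
      next
    }
    if (wt == mt) {
      reject(i, "synonymous")
      next
    }
    if (is.na(pos) || pos < 1L) {
      reject(i, "malformed position")
      next
    }
    lab <- tryCatch(normalize_label(raw$label[i]), error = function(e) NA)
    if (is.na(lab)) {
      reject(i, "unrecognized label")
      next
    }
    records[[length(records) + 1L]] <- mutation_record(
      trimws(raw$protein[i]), pos, wt, mt, lab)
  }
  list(records = records, rejected = rejected)
}

#' Does a mutation map onto a protein's canonical sequence?
#'
#' TRUE iff the position lies within the sequence and the sequence letter at
#' that position equals the mutation's wild-type residue.
#'
#' @param mutation a [mutation_record()].
#' @param protein a [protein_record()] with matching `protein_id`.
#' @return logical scalar.
#' @export
check_mutation_maps <- function(mutation, protein) {
  if (mutation$protein_id != protein$protein_id) {
    stop("protein_id mismatch: mutation is on ", mutation$protein_id,
         ", record is ", protein$protein_id)
  }
  mutation$position <= nchar(protein$sequence) &&
    residue_letter(protein, mutation$position) == mutation$wt
}
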