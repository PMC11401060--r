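# Sequence-derived feature generators: residue-group classification,
# neighboring amino-acid frequency over a 15-residue window, AAindex
# property lookups with sliding-window deltas, and substitution-matrix
# scores. Property and matrix tables are parsed from AAindex flat files.

#' Construct a PropertyTable
#'
#' A named per-residue numeric property (an AAindex-1 style scale).
#'
#' @param table_id short unique identifier (e.g. an AAindex accession).
#' @param values numeric vector of exactly 20 values named by the canonical
#'   one-letter codes.
#' @return object of class `property_table`.
#' @export
property_table <- function(table_id, values) {
  if (length(values) != 20L || !setequal(names(values), AA_ONE)) {
    stop("property table must hold exactly one value per canonical residue")
  }
  structure(list(table_id = table_id, values = values[AA_ONE]),
            class = "property_table")
}

#' Construct a SubstitutionTable
#'
#' A residue-pair score table (an AAindex-2/3 style matrix). Symmetric
#' tables may be stored as a triangle; lookups then treat (a, b) and (b, a)
#' identically.
#'
#' @param table_id short unique identifier.
#' @param scores 20 x 20 numeric matrix with dimnames over the canonical
#'   letters; `NA` marks absent pairs.
#' @param symmetric logical.
#' @return object of class `substitution_table`.
#' @export
substitution_table <- function(table_id, scores, symmetric = TRUE) {
  stopifnot(is.matrix(scores), nrow(scores) == 20L, ncol(scores) == 20L)
  if (!setequal(rownames(scores), AA_ONE) ||
      !setequal(colnames(scores), AA_ONE)) {
    stop("substitution table dimnames must be the 20 canonical letters")
  }
  scores <- scores[AA_ONE, AA_ONE]
  if (symmetric) {
    # fill each triangle from the other where absent
    for (i in seq_len(20L)) {
      for (j in seq_len(20L)) {
        if (is.na(scores[i, j]) && !is.na(scores[j, i])) {
          scores[i, j] <- scores[j, i]
        }
      }
    }
    filled <- !is.na(scores) & !is.na(t(scores))
    if (any(scores[filled] != t(scores)[filled])) {
      stop("table declared symmetric but score(a,b) != score(b,a)")
    }
  }
  structure(list(table_id = table_id, scores = scores,
                 symmetric = symmetric),
            class = "substitution_table")
}

# ---------------------------------------------------------------------------
# AAindex flat-file parsing. Entries are keyed by an `H` accession line;
# `I` blocks hold 20 per-residue values (two rows of ten, residue order
# A R N D C Q E G H I / L K M F P S T W Y V); `M` blocks hold pair matrices
# (lower-triangular for symmetric tables or full 20 x 20).

AAINDEX_ROW1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
AAINDEX_ROW2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse an AAindex flat file
#'
#' Reads every parseable entry from an AAindex-format file and returns
#' [property_table()] objects for `I`-block entries and
#' [substitution_table()] objects for `M`-block entries.
#'
#' @param path file path.
#' @return named list of tables keyed by accession.
#' @export
parse_aaindex <- function(path) {
  lines <- readLines(path)
  entries <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "H ")) {
      i <- i + 1L
      next
    }
    acc <- trimws(sub("^H ", "", lines[i]))
    j <- i + 1L
    block <- character(0)
    while (j <= length(lines) && !startsWith(lines[j], "//")) {
      block <- c(block, lines[j])
      j <- j + 1L
    }
    tab <- tryCatch(parse_aaindex_entry(acc, block),
                    error = function(e) NULL)
    if (!is.null(tab)) entries[[acc]] <- tab
    i <- j + 1L
  }
  entries
}

parse_aaindex_entry <- function(acc, block) {
  i_idx <- which(startsWith(block, "I "))
  m_idx <- which(startsWith(block, "M "))
  if (length(i_idx) == 1L) {
    vals <- as.numeric(unlist(strsplit(trimws(block[c(i_idx + 1L, i_idx + 2L)]),
                                       "\\s+")))
    if (length(vals) != 20L || any(is.na(vals))) {
      stop("unparseable I block in ", acc)
    }
    return(property_table(acc, stats::setNames(vals,
                                               c(AAINDEX_ROW1, AAINDEX_ROW2))))
  }
  if (length(m_idx) == 1L) {
    header <- block[m_idx]
    rows_str <- sub(".*rows = ([A-Z]+).*", "\\1", header)
    cols_str <- sub(".*cols = ([A-Z]+).*", "\\1", header)
    row_letters <- strsplit(rows_str, "")[[1]]
    col_letters <- strsplit(cols_str, "")[[1]]
    data_lines <- block[seq(m_idx + 1L, length(block))]
    data_lines <- data_lines[!startsWith(data_lines, "C ") &
                               nzchar(trimws(data_lines))]
    data_lines <- data_lines[seq_len(length(row_letters))]
    scores <- matrix(NA_real_, 20, 20, dimnames = list(AA_ONE, AA_ONE))
    symmetric <- FALSE
    for (r in seq_along(row_letters)) {
      vals <- suppressWarnings(
        as.numeric(unlist(strsplit(trimws(data_lines[r]), "\\s+"))))
      if (length(vals) == length(col_letters)) {
        scores[row_letters[r], col_letters] <- vals
      } else if (length(vals) == r) {
        symmetric <- TRUE
        scores[row_letters[r], col_letters[seq_len(r)]] <- vals
      } else {
        stop("unparseable M block row in ", acc)
      }
    }
    keep <- intersect(AA_ONE, row_letters)
    if (length(keep) < 20L) stop("matrix does not cover the 20 residues")
    return(substitution_table(acc, scores, symmetric = symmetric))
  }
  stop("entry ", acc, " has neither I nor M block")
}

the_catalog_env <- new.env(parent = emptyenv())

#' Built-in property-table catalog
#'
#' The bundled AAindex-1 style scales plus the three basic physicochemical
#' tables (isoelectric point `pI`, molecular weight `MW`, molecular volume
#' `MV`). Three accessions named by the final feature set (MEIH800101,
#' VASM830102, CHAM830107) ship as documented synthetic stand-in values
#' because the reference database is not redistributable here; see the
#' bundled data file's D lines.
#'
#' @return named list of [property_table()]s.
#' @export
builtin_property_catalog <- function() {
  if (!is.null(the_catalog_env$props)) return(the_catalog_env$props)
  path <- pkg_extdata("aaindex1_builtin.txt")
  props <- parse_aaindex(path)
  the_catalog_env$props <- props
  props
}

#' Built-in substitution-table catalog
#'
#' Currently BLOSUM62 (accession-style id `HENS920102`), sourced from the
#' Biostrings package's published matrix and restricted to the 20 canonical
#' residues.
#'
#' @return named list of [substitution_table()]s.
#' @export
builtin_substitution_catalog <- function() {
  if (!is.null(the_catalog_env$subs)) return(the_catalog_env$subs)
  b62 <- get_blosum62()
  subs <- list(HENS920102 = substitution_table("HENS920102", b62,
                                               symmetric = TRUE))
  the_catalog_env$subs <- subs
  subs
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ONE, AA_ONE]
  storage.mode(m) <- "double"
  m
}

# ---------------------------------------------------------------------------
# Operations.

#' Assign a residue to a biochemical group
#'
#' @param residue canonical one-letter code.
#' @param scheme a [group_scheme()].
#' @return group label (character scalar).
#' @export
assign_group <- function(residue, scheme) {
  stopifnot(inherits(scheme, "group_scheme"))
  stop_if_not_canonical(residue)
  unname(scheme$assignment[residue])
}

#' Neighboring amino-acid frequency (seven-group, 15-residue window)
#'
#' Counts, for each of the seven residue groups, the group members among
#' the seven residues before and seven after `position` (the site itself
#' excluded; the window is truncated at sequence ends) and normalizes each
#' count by the full sequence length. Note the deliberate coupling of a
#' local window count to global protein length: the normalizer is the whole
#' sequence length, not the window size.
#'
#' @param sequence amino-acid string.
#' @param position 1-based site.
#' @return named numeric vector `<group>_freq` over the seven groups.
#' @export
neighbor_frequency <- function(sequence, position) {
  len <- nchar(sequence)
  if (len == 0L) stop("empty sequence")
  if (position < 1L || position > len) stop("position out of range")
  idx <- setdiff(max(1L, position - 7L):min(len, position + 7L), position)
  letters1 <- strsplit(sequence, "")[[1]][idx]
  scheme <- group_scheme("seven")
  counts <- table(factor(scheme$assignment[letters1],
                         levels = names(SEVEN_GROUPS)))
  out <- as.numeric(counts) / len
  stats::setNames(out, paste0(names(SEVEN_GROUPS), "_freq"))
}

#' Sliding-window property delta
#'
#' The wild-type property is averaged over the residues at positions
#' `position - k` to `position + k` (clipped to the sequence); the mutant
#' property is the raw table value of `mt`. The feature is the WT window
#' mean minus the mutant value, optionally divided by the sequence length.
#' Half-widths k = 0, 1, 2, 3 correspond to window sizes 1, 3, 5 and 7.
#'
#' @param sequence amino-acid string.
#' @param position 1-based site.
#' @param mt mutant residue letter.
#' @param table a [property_table()].
#' @param k half-width in `0:3`.
#' @param normalized divide by sequence length?
#' @return numeric scalar.
#' @export
window_delta <- function(sequence, position, mt, table, k = 0,
                         normalized = FALSE) {
  stopifnot(inherits(table, "property_table"), k %in% 0:3)
  stop_if_not_canonical(mt, "mutant")
  len <- nchar(sequence)
  if (position < 1L || position > len) stop("position out of range")
  idx <- max(1L, position - k):min(len, position + k)
  letters1 <- strsplit(sequence, "")[[1]][idx]
  stop_if_not_canonical(letters1, "sequence")
  delta <- mean(table$values[letters1]) - table$values[[mt]]
  if (normalized) delta <- delta / len
  delta
}

#' Substitution-matrix score for a residue pair
#'
#' @param wt,mt canonical one-letter codes.
#' @param table a [substitution_table()].
#' @return the stored score; for symmetric tables (a, b) and (b, a) agree.
#' @export
substitution_score <- function(wt, mt, table) {
  stopifnot(inherits(table, "substitution_table"))
  stop_if_not_canonical(c(wt, mt))
  s <- table$scores[wt, mt]
  if (is.na(s) && table$symmetric) s <- table$scores[mt, wt]
  if (is.na(s)) {
    stop(sprintf("pair (%s, %s) absent from table %s", wt, mt,
                 table$table_id))
  }
  unname(s)
}
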