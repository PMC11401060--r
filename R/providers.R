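# Adapters for externally computed per-mutation scores consumed as
# features: four stability predictors (ddG, kcal/mol), SIFT, SNAP2, PSSM
# and disorder (IUPred-style short/long) scores. Scores arrive as TSV
# tables keyed by (protein, position, wt, mt); no provider algorithm is
# re-implemented here.

PROVIDER_SCHEMA <- list(
  ddg_mcsm      = c(-Inf, Inf),
  ddg_saafecseq = c(-Inf, Inf),
  ddg_ddmut     = c(-Inf, Inf),
  ddg_dynamut2  = c(-Inf, Inf),
  sift_score    = c(0, 1),
  snap2_score   = c(-100, 100),
  pssm_score    = c(-Inf, Inf),
  iupred_short  = c(0, 1),
  iupred_long   = c(0, 1)
)

provider_key <- function(df) {
  sprintf("%s_%s%d%s", df$protein, df$wt, as.integer(df$position), df$mt)
}

#' Load a provider score table
#'
#' Reads a TSV with columns `protein`, `position`, `wt`, `mt` plus any
#' subset of the known score columns. Duplicate mutation keys, scores
#' outside their documented ranges and unknown columns are errors. When
#' `mutations` is supplied a coverage report (fraction of requested
#' mutations present, plus the missing keys) is attached.
#'
#' @param tsv_path path to the TSV file.
#' @param schema character vector of expected score columns; defaults to
#'   whatever known columns the file carries.
#' @param mutations optional list of [mutation_record()] to compute
#'   coverage against.
#' @return object of class `provider_scores`: list with `table` (data.frame
#'   keyed by mutation), `schema`, `coverage`, `missing`.
#' @export
load_provider_table <- function(tsv_path, schema = NULL, mutations = NULL) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  key_cols <- c("protein", "position", "wt", "mt")
  if (!all(key_cols %in% names(tab))) {
    stop("provider table must carry columns ",
         paste(key_cols, collapse = ", "))
  }
  score_cols <- setdiff(names(tab), key_cols)
  unknown <- setdiff(score_cols, names(PROVIDER_SCHEMA))
  if (length(unknown) > 0) {
    stop("unknown provider column(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(schema)) {
    missing_cols <- setdiff(schema, score_cols)
    if (length(missing_cols) > 0) {
      stop("declared schema column(s) absent from table: ",
           paste(missing_cols, collapse = ", "))
    }
    score_cols <- schema
  }
  keys <- provider_key(tab)
  dup <- keys[duplicated(keys)]
  if (length(dup) > 0) {
    stop("duplicate mutation key(s) in provider table: ",
         paste(unique(dup), collapse = ", "))
  }
  for (col in score_cols) {
    rng <- PROVIDER_SCHEMA[[col]]
    vals <- tab[[col]]
    bad <- which(is.finite(vals) & (vals < rng[1] | vals > rng[2]))
    if (length(bad) > 0) {
      stop(sprintf("%s out of range [%g, %g] at row %d (value %g)",
                   col, rng[1], rng[2], bad[1], vals[bad[1]]))
    }
  }
  rownames(tab) <- keys
  coverage <- NA_real_
  missing <- character(0)
  if (!is.null(mutations)) {
    wanted <- vapply(mutations, mutation_key, character(1))
    missing <- setdiff(wanted, keys)
    coverage <- 1 - length(missing) / length(wanted)
  }
  structure(list(table = tab, schema = score_cols, coverage = coverage,
                 missing = missing),
            class = "provider_scores")
}

#' Look up provider scores for one mutation
#' @param scores a [load_provider_table()] result.
#' @param mutation a [mutation_record()].
#' @return named numeric vector over the schema columns (NA when the
#'   mutation is absent from the table).
#' @export
provider_lookup <- function(scores, mutation) {
  key <- mutation_key(mutation)
  out <- stats::setNames(rep(NA_real_, length(scores$schema)),
                         scores$schema)
  if (key %in% rownames(scores$table)) {
    out[] <- as.numeric(scores$table[key, scores$schema])
  }
  out
}

#' Sign-classify a stability change
#'
#' Zero-cutoff convention: ddG > 0 stabilizing, ddG < 0 destabilizing,
#' ddG = 0 neutral.
#'
#' @param ddg stability change in kcal/mol (finite).
#' @return `"stabilizing"`, `"destabilizing"` or `"neutral"`.
#' @export
classify_stability <- function(ddg) {
  if (length(ddg) != 1L || !is.finite(ddg)) {
    stop("ddg must be a single finite number")
  }
  if (ddg > 0) "stabilizing" else if (ddg < 0) "destabilizing" else "neutral"
}

#' Per-protein fraction of destabilizing mutations
#'
#' For each protein, the number of mutations whose selected ddG score is
#' negative divided by the number of scored mutations. Proteins with zero
#' scored mutations are reported as NA.
#'
#' @param scores a [load_provider_table()] result.
#' @param mutations list of [mutation_record()].
#' @param ddg_column which stability column to use.
#' @return named numeric vector, one fraction per protein.
#' @export
destabilizing_fraction <- function(scores, mutations,
                                   ddg_column = "ddg_ddmut") {
  if (!ddg_column %in% scores$schema) {
    stop("column ", ddg_column, " not in provider schema")
  }
  proteins <- unique(vapply(mutations, function(m) m$protein_id,
                            character(1)))
  out <- stats::setNames(rep(NA_real_, length(proteins)), proteins)
  for (p in proteins) {
    muts <- Filter(function(m) m$protein_id == p, mutations)
    vals <- vapply(muts, function(m) provider_lookup(scores, m)[[ddg_column]],
                   numeric(1))
    vals <- vals[is.finite(vals)]
    if (length(vals) > 0) out[p] <- mean(vals < 0)
  }
  out
}
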