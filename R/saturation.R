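# In silico saturation mutagenesis: predictions for all 19 possible
# substitutions at every modeled position of a protein, per-site summaries,
# and exports (long table, heatmap matrix, structure annotated with
# per-site scores).

#' Saturation mutagenesis over one protein
#'
#' Builds every possible missense mutation (19 substitutions per modeled
#' position), assembles the feature matrix restricted to the bank's feature
#' catalog, and predicts the disease-causing probability with the model the
#' bank routes this protein to. Positions whose features cannot be computed
#' are flagged, not dropped.
#'
#' @param protein a [protein_record()].
#' @param bank a [build_bank()] model bank containing the protein.
#' @param providers optional provider table; required only when the bank's
#'   models consume provider-backed features.
#' @param map pharmacophore map.
#' @param n_points surface sampling density.
#' @return object of class `saturation_table`: data.frame with columns
#'   `position`, `wt`, `mt`, `prob`, `model`, `flagged`.
#' @export
saturate <- function(protein, bank, providers = NULL,
                     map = load_pharmacophore_map(), n_points = 100) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(bank, "model_bank"))
  route <- route_model(bank, protein$protein_id)
  model <- route$model
  positions <- modeled_positions(protein)
  records <- list()
  for (pos in positions) {
    wt <- residue_letter(protein, pos)
    for (mt in setdiff(AA_ONE, wt)) {
      records[[length(records) + 1L]] <- mutation_record(
        protein$protein_id, pos, wt, mt)
    }
  }
  ds <- mutation_dataset(records,
                         stats::setNames(list(protein),
                                         protein$protein_id))
  fm <- assemble_matrix(ds, providers = providers,
                        features = model$features, map = map,
                        n_points = n_points)
  excl <- attr(fm, "exclusions")
  prob <- predict(model, fm)
  tab <- data.frame(
    position = fm$positions,
    wt = vapply(fm$keys, function(k) sub(".*_([A-Z])[0-9]+[A-Z]$", "\\1", k),
                character(1)),
    mt = vapply(fm$keys, function(k) sub(".*[0-9]([A-Z])$", "\\1", k),
                character(1)),
    prob = prob, model = route$which, flagged = FALSE,
    stringsAsFactors = FALSE)
  if (nrow(excl) > 0) {
    flagged <- data.frame(
      position = as.integer(sub(".*_[A-Z]([0-9]+)[A-Z]$", "\\1", excl$key)),
      wt = sub(".*_([A-Z])[0-9]+[A-Z]$", "\\1", excl$key),
      mt = sub(".*[0-9]([A-Z])$", "\\1", excl$key),
      prob = NA_real_, model = route$which, flagged = TRUE,
      stringsAsFactors = FALSE)
    tab <- rbind(tab, flagged)
    tab <- tab[order(tab$position, tab$mt), ]
  }
  rownames(tab) <- NULL
  structure(tab, class = c("saturation_table", "data.frame"),
            protein_id = protein$protein_id)
}

#' Per-site mean pathogenic probability
#'
#' Arithmetic mean of the 19 substitution probabilities at each position.
#' Positions with flagged (uncomputable) rows are marked partial and the
#' mean is taken over the available rows.
#'
#' @param table a [saturate()] result.
#' @return data.frame with `position`, `mean_prob`, `n`, `partial`.
#' @export
site_summary <- function(table) {
  stopifnot(inherits(table, "saturation_table"))
  out <- do.call(rbind, lapply(split(table, table$position), function(d) {
    data.frame(position = d$position[1],
               mean_prob = mean(d$prob, na.rm = TRUE),
               n = sum(!is.na(d$prob)),
               partial = any(d$flagged))
  }))
  rownames(out) <- NULL
  out[order(out$position), ]
}

#' Annotate a structure with per-position values
#'
#' Writes a PDB whose B-factor column carries, for every atom, its
#' residue's value linearly rescaled from \[0, 1\] to \[0, 100\]
#' (round-trippable through [load_protein()]); coordinates are untouched.
#' Residues without a value get sentinel 0 with a warning.
#'
#' @param protein a [protein_record()].
#' @param values named numeric vector (names = positions) in \[0, 1\].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
annotate_structure <- function(protein, values, path) {
  resis <- modeled_positions(protein)
  b <- rep(0, length(resis))
  names(b) <- resis
  hit <- intersect(names(values), as.character(resis))
  b[hit] <- values[hit] * 100
  missing_res <- setdiff(as.character(resis), names(values))
  if (length(missing_res) > 0) {
    warning("no value for residue(s) ",
            paste(utils::head(missing_res, 10), collapse = ", "),
            "; sentinel 0 written")
  }
  write_pdb(protein, path, bfactor = unname(b))
}

#' Export a saturation heatmap matrix
#'
#' Positions x 20 residues CSV of predicted probabilities; the self
#' (synonymous) cell is blank.
#'
#' @param table a [saturate()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_saturation_heatmap <- function(table, path) {
  stopifnot(inherits(table, "saturation_table"))
  positions <- sort(unique(table$position))
  m <- matrix(NA_real_, length(positions), 20,
              dimnames = list(positions, AA_ONE))
  for (i in seq_len(nrow(table))) {
    m[as.character(table$position[i]), table$mt[i]] <- table$prob[i]
  }
  df <- data.frame(position = positions,
                   wt = table$wt[match(positions, table$position)],
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
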