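# Dataset curation (cleaning, label corrections), grouped splitting and
# feature-matrix assembly from all generator modules plus providers.

#' Construct a mutation dataset
#'
#' @param records list of [mutation_record()].
#' @param proteins named list of [protein_record()] keyed by protein_id.
#' @param notes optional character provenance notes.
#' @return object of class `mutation_dataset`.
#' @export
mutation_dataset <- function(records, proteins, notes = character(0)) {
  stopifnot(is.list(records), is.list(proteins))
  structure(list(records = records, proteins = proteins, notes = notes),
            class = "mutation_dataset")
}

#' @export
print.mutation_dataset <- function(x, ...) {
  labs <- vapply(x$records, function(r) r$label, character(1))
  cat(sprintf("<mutation_dataset: %d mutations on %d proteins (%s)>\n",
              length(x$records), length(x$proteins),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}

#' Load a label-correction table
#'
#' Corrections are data, not code: a CSV with columns
#' `protein,position,wt,mt,label` whose rows force the given label onto the
#' matching mutation. The bundled file carries the curated receptor-gene
#' corrections applied to the primary dataset (six TREM2 mutations marked
#' Disease-causing).
#'
#' @param path CSV path; default the bundled correction list.
#' @return data.frame of corrections.
#' @export
load_corrections <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("trem2_corrections.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Clean a raw mutation set against its proteins
#'
#' Drops rows that do not map onto their protein's canonical sequence,
#' synonymous rows, rows for unknown proteins and duplicate keys (second
#' occurrence dropped), then applies label corrections. Cleaning is
#' idempotent. Every removal and every applied correction is reported.
#'
#' @param records list of [mutation_record()] (e.g. from
#'   [parse_mutation_table()]).
#' @param proteins named list of [protein_record()].
#' @param corrections optional corrections data.frame
#'   (see [load_corrections()]).
#' @return list with `dataset` (a [mutation_dataset()]) and `report`
#'   (data.frame of actions).
#' @export
clean_dataset <- function(records, proteins, corrections = NULL) {
  report <- data.frame(action = character(0), key = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  note <- function(action, key, detail = "") {
    report <<- rbind(report, data.frame(action = action, key = key,
                                        detail = detail,
                                        stringsAsFactors = FALSE))
  }
  kept <- list()
  seen <- character(0)
  for (r in records) {
    key <- mutation_key(r)
    if (!r$protein_id %in% names(proteins)) {
      note("rejected", key, "unknown protein")
      next
    }
    if (r$wt == r$mt) {
      note("rejected", key, "synonymous")
      next
    }
    if (!check_mutation_maps(r, proteins[[r$protein_id]])) {
      note("rejected", key, "does not map to canonical sequence")
      next
    }
    if (key %in% seen) {
      note("rejected", key, "duplicate")
      next
    }
    seen <- c(seen, key)
    kept[[length(kept) + 1L]] <- r
  }
  if (!is.null(corrections)) {
    for (i in seq_len(nrow(corrections))) {
      ckey <- sprintf("%s_%s%d%s", corrections$protein[i],
                      corrections$wt[i],
                      as.integer(corrections$position[i]),
                      corrections$mt[i])
      hit <- which(vapply(kept, mutation_key, character(1)) == ckey)
      if (length(hit) == 0) {
        warning("correction for ", ckey,
                " references a mutation absent after cleaning")
        next
      }
      newlab <- normalize_label(corrections$label[i])
      if (kept[[hit]]$label != newlab) {
        note("corrected", ckey,
             paste(kept[[hit]]$label, "->", newlab))
        kept[[hit]]$label <- newlab
      }
    }
  }
  list(dataset = mutation_dataset(kept, proteins), report = report)
}

#' Grouped train/validation/test split
#'
#' Groups rows by unique (protein, position), shuffles the groups with the
#' seeded generator, and fills the partitions greedily to the target group
#' counts, so each site lands wholly inside one partition and realized
#' fractions are within one group of the targets. Identical seed, identical
#' split.
#'
#' @param x a [mutation_dataset()] or feature matrix.
#' @param fractions length-3 positive fractions summing to 1.
#' @param seed integer seed.
#' @return named list `train`, `val`, `test` of objects of the input type.
#' @export
grouped_split <- function(x, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (inherits(x, "mutation_dataset")) {
    groups <- vapply(x$records, function(r) {
      paste(r$protein_id, r$position, sep = "@")
    }, character(1))
  } else if (inherits(x, "feature_matrix")) {
    groups <- paste(x$proteins, x$positions, sep = "@")
  } else {
    stop("x must be a mutation_dataset or feature_matrix")
  }
  ug <- unique(groups)
  if (length(ug) < 3) stop("need at least 3 (protein, position) groups")
  ug <- ug[withr_seed(seed, sample.int(length(ug)))]
  n_train <- round(fractions[1] * length(ug))
  n_val <- round(fractions[2] * length(ug))
  n_train <- max(1L, min(n_train, length(ug) - 2L))
  n_val <- max(1L, min(n_val, length(ug) - n_train - 1L))
  assign_of <- stats::setNames(
    rep(c("train", "val", "test"),
        c(n_train, n_val, length(ug) - n_train - n_val)), ug)
  part <- assign_of[groups]
  pick <- function(which) {
    idx <- which(part == which)
    if (inherits(x, "mutation_dataset")) {
      mutation_dataset(x$records[idx], x$proteins, x$notes)
    } else {
      subset_matrix(x, idx)
    }
  }
  list(train = pick("train"), val = pick("val"), test = pick("test"))
}

# ---------------------------------------------------------------------------
# Feature matrix container.

new_feature_matrix <- function(features, labels, keys, proteins, positions,
                               provenance) {
  stopifnot(nrow(features) == length(labels),
            length(keys) == length(labels))
  structure(list(features = features, labels = labels, keys = keys,
                 proteins = proteins, positions = positions,
                 provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d rows x %d features (%d proteins)>\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$proteins))))
  invisible(x)
}

subset_matrix <- function(matrix, idx) {
  new_feature_matrix(matrix$features[idx, , drop = FALSE],
                     matrix$labels[idx], matrix$keys[idx],
                     matrix$proteins[idx], matrix$positions[idx],
                     matrix$provenance)
}

#' Restrict a feature matrix to named columns
#'
#' @param matrix a feature matrix.
#' @param features column names to keep (order preserved as given).
#' @return a feature matrix with exactly those columns.
#' @export
restrict_features <- function(matrix, features) {
  missing_cols <- setdiff(features, colnames(matrix$features))
  if (length(missing_cols) > 0) {
    stop("feature(s) produced by no module: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  new_feature_matrix(matrix$features[, features, drop = FALSE],
                     matrix$labels, matrix$keys, matrix$proteins,
                     matrix$positions,
                     matrix$provenance[features])
}

#' The final 12-feature set
#'
#' Names of the twelve features the shipped models are built on (window
#' deltas and mutant properties from the AAindex catalog, neighbor
#' frequency, contact counts and graph-based signature components).
#'
#' @return character vector of 12 feature names.
#' @export
final_feature_set <- function() {
  c("aliphatic_freq", "ITPolar", "ITd_WeakPolar", "hydrophobic_mt",
    "MEIH800101_delta_2", "VASM830102_delta_3_norm", "CHAM830107_mt",
    "KLEP840101_mt", "FAUJ880112_mt", "Aro:Sul-11.00", "Neg:Sul-6.50",
    "Neg")
}

# ---------------------------------------------------------------------------
# Feature assembly.

feature_families <- function() {
  c("groups", "freq", "property", "substitution", "struct", "contacts",
    "signature", "providers")
}

families_for_features <- function(features, prop_ids, sub_ids) {
  fams <- character(0)
  for (f in features) {
    fam <- if (grepl("_freq$", f)) "freq"
    else if (f %in% paste0(rep(names(FIVE_GROUPS), 2),
                           rep(c("_wt", "_mt"), each = 5))) "groups"
    else if (grepl("^ITd_", f) || grepl("^IT[A-Z]", f)) "contacts"
    else if (grepl("^[A-Z][a-z]{2}:[A-Z][a-z]{2}-", f) ||
             f %in% unname(PHARMACOPHORE_ABBREV)) "signature"
    else if (f %in% names(PROVIDER_SCHEMA)) "providers"
    else if (f %in% c("rsa", "depth", "ss_H", "ss_E", "ss_C", "phi", "psi",
                      "plddt")) "struct"
    else if (any(startsWith(f, paste0(sub_ids, "_sub")))) "substitution"
    else if (any(vapply(prop_ids, function(p) startsWith(f, paste0(p, "_")),
                        logical(1)))) "property"
    else stop("requested feature produced by no module: ", f)
    fams <- c(fams, fam)
  }
  unique(fams)
}

#' Assemble a feature matrix for a mutation dataset
#'
#' Computes, for every mutation that maps onto its protein, the feature
#' families: five-group WT/mutant indicators, seven-group neighbor
#' frequencies, per-table property values and sliding-window deltas,
#' substitution-matrix scores, structural descriptors at the site,
#' interaction-contact counts (WT) and deltas (idealized mutant model),
#' cumulative graph-based signature components with pharmacophore changes,
#' and provider scores. Rows lacking a required provider score are excluded
#' and reported, never imputed (unless `impute_providers = TRUE`, which
#' median-imputes and is off by default). `features` restricts the output
#' to a named subset and only the needed families are computed.
#'
#' @param dataset a [mutation_dataset()].
#' @param providers optional [load_provider_table()] result.
#' @param features optional character vector naming the columns wanted.
#' @param map pharmacophore map for the contact/signature families.
#' @param cutoffs signature distance grid.
#' @param n_points surface sampling density for the struct family.
#' @param impute_providers median-impute missing provider scores instead of
#'   excluding rows.
#' @return a `feature_matrix`; excluded rows are reported in attribute
#'   `exclusions`.
#' @export
assemble_matrix <- function(dataset, providers = NULL, features = NULL,
                            map = load_pharmacophore_map(),
                            cutoffs = seq(1, 11, by = 0.5),
                            n_points = 100, impute_providers = FALSE) {
  stopifnot(inherits(dataset, "mutation_dataset"))
  prop_catalog <- builtin_property_catalog()
  sub_catalog <- builtin_substitution_catalog()
  fams <- if (is.null(features)) feature_families() else {
    families_for_features(features, names(prop_catalog),
                          names(sub_catalog))
  }
  if ("providers" %in% fams && is.null(providers) && !is.null(features)) {
    stop("provider-backed features requested but no provider table given")
  }
  records <- Filter(function(r) {
    r$protein_id %in% names(dataset$proteins) &&
      check_mutation_maps(r, dataset$proteins[[r$protein_id]])
  }, dataset$records)
  if (length(records) == 0) stop("no mutations map onto the proteins")

  struct_cache <- list()
  contact_cache <- list()
  signature_cache <- list()
  get_struct <- function(pid) {
    if (is.null(struct_cache[[pid]])) {
      struct_cache[[pid]] <<- structural_descriptors(
        dataset$proteins[[pid]], n_points = n_points)
    }
    struct_cache[[pid]]
  }
  get_wt_contacts <- function(pid, pos) {
    key <- paste(pid, pos)
    if (is.null(contact_cache[[key]])) {
      contact_cache[[key]] <<- type_contacts(dataset$proteins[[pid]], pos,
                                             map)
    }
    contact_cache[[key]]
  }
  get_signature <- function(pid, pos) {
    key <- paste(pid, pos)
    if (is.null(signature_cache[[key]])) {
      signature_cache[[key]] <<- graph_signature(dataset$proteins[[pid]],
                                                 pos, map, cutoffs)
    }
    signature_cache[[key]]
  }

  five <- group_scheme("five")
  rows <- vector("list", length(records))
  provenance <- character(0)
  exclusions <- data.frame(key = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  keep <- logical(length(records))
  for (k in seq_along(records)) {
    r <- records[[k]]
    protein <- dataset$proteins[[r$protein_id]]
    vals <- numeric(0)
    prov <- character(0)
    if ("groups" %in% fams) {
      gw <- assign_group(r$wt, five)
      gm <- assign_group(r$mt, five)
      v <- stats::setNames(
        c(as.numeric(names(FIVE_GROUPS) == gw),
          as.numeric(names(FIVE_GROUPS) == gm)),
        c(paste0(names(FIVE_GROUPS), "_wt"),
          paste0(names(FIVE_GROUPS), "_mt")))
      vals <- c(vals, v)
      prov <- c(prov, rep("seq_features", length(v)))
    }
    if ("freq" %in% fams) {
      v <- neighbor_frequency(protein$sequence, r$position)
      vals <- c(vals, v)
      prov <- c(prov, rep("seq_features", length(v)))
    }
    if ("property" %in% fams) {
      for (tab in prop_catalog) {
        v <- c(tab$values[[r$wt]], tab$values[[r$mt]])
        names(v) <- paste0(tab$table_id, c("_wt", "_mt"))
        for (kk in 0:3) {
          v[paste0(tab$table_id, "_delta_", kk)] <-
            window_delta(protein$sequence, r$position, r$mt, tab, kk)
          v[paste0(tab$table_id, "_delta_", kk, "_norm")] <-
            window_delta(protein$sequence, r$position, r$mt, tab, kk,
                         normalized = TRUE)
        }
        vals <- c(vals, v)
        prov <- c(prov, rep("seq_features", length(v)))
      }
    }
    if ("substitution" %in% fams) {
      for (tab in sub_catalog) {
        v <- stats::setNames(substitution_score(r$wt, r$mt, tab),
                             paste0(tab$table_id, "_sub"))
        vals <- c(vals, v)
        prov <- c(prov, "seq_features")
      }
    }
    if ("struct" %in% fams) {
      sd <- get_struct(r$protein_id)
      row <- sd[sd$resi == r$position, ]
      v <- c(rsa = row$rsa, depth = row$depth,
             ss_H = as.numeric(row$ss == "H"),
             ss_E = as.numeric(row$ss == "E"),
             ss_C = as.numeric(row$ss == "C"),
             phi = ifelse(is.na(row$phi), 0, row$phi),
             psi = ifelse(is.na(row$psi), 0, row$psi),
             plddt = row$plddt)
      vals <- c(vals, v)
      prov <- c(prov, rep("struct_features", length(v)))
    }
    if ("contacts" %in% fams) {
      wt_prof <- get_wt_contacts(r$protein_id, r$position)
      mut <- build_mutant_model(protein, r)
      mut_prof <- type_contacts(mut, r$position, map)
      v <- contact_feature_vector(wt_prof, mut_prof)
      vals <- c(vals, v)
      prov <- c(prov, rep("contacts_signatures", length(v)))
    }
    if ("signature" %in% fams) {
      v <- c(get_signature(r$protein_id, r$position),
             pharmacophore_change(protein, r, map))
      vals <- c(vals, v)
      prov <- c(prov, rep("contacts_signatures", length(v)))
    }
    keep[k] <- TRUE
    if ("providers" %in% fams && !is.null(providers)) {
      v <- provider_lookup(providers, r)
      if (any(is.na(v)) && !impute_providers) {
        exclusions <- rbind(exclusions, data.frame(
          key = mutation_key(r),
          reason = paste("missing provider score(s):",
                         paste(names(v)[is.na(v)], collapse = ", ")),
          stringsAsFactors = FALSE))
        keep[k] <- FALSE
      }
      vals <- c(vals, v)
      prov <- c(prov, rep("providers", length(v)))
    }
    rows[[k]] <- vals
    if (length(provenance) == 0) {
      provenance <- stats::setNames(prov, names(vals))
    }
  }
  features_df <- as.data.frame(do.call(rbind, rows[keep]),
                               check.names = FALSE)
  if (isTRUE(impute_providers)) {
    for (col in intersect(names(PROVIDER_SCHEMA), colnames(features_df))) {
      miss <- is.na(features_df[[col]])
      if (any(miss)) {
        features_df[[col]][miss] <- stats::median(features_df[[col]],
                                                  na.rm = TRUE)
      }
    }
  }
  kept_records <- records[keep]
  fm <- new_feature_matrix(
    features_df,
    vapply(kept_records, function(r) r$label, character(1)),
    vapply(kept_records, mutation_key, character(1)),
    vapply(kept_records, function(r) r$protein_id, character(1)),
    vapply(kept_records, function(r) r$position, integer(1)),
    provenance)
  if (!is.null(features)) fm <- restrict_features(fm, features)
  attr(fm, "exclusions") <- exclusions
  fm
}

#' Serialize a feature matrix to TSV (with a provenance comment block)
#'
#' @param matrix a feature matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fams <- split(names(matrix$provenance), matrix$provenance)
  for (fam in names(fams)) {
    writeLines(sprintf("# provenance %s: %d features", fam,
                       length(fams[[fam]])), con)
  }
  df <- cbind(data.frame(key = matrix$keys, protein = matrix$proteins,
                         position = matrix$positions,
                         label = matrix$labels,
                         stringsAsFactors = FALSE,
                         check.names = FALSE),
              matrix$features)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
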