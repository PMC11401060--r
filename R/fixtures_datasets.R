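# Planted-signal synthetic datasets: fixture proteins, mutation sets whose
# labels follow a stated rule (with a configurable flip rate), and matching
# provider score tables, all reproducible from a single seed. The planted
# rules reference features the pipeline actually computes, so selection and
# weighting tests have a recoverable ground truth.

#' Synthetic dataset configuration
#'
#' The stated world of the generator: 3 fixture proteins of 40 residues
#' with 40 mutations each, a neighborhood rule (disease-causing iff at
#' least two aliphatic residues fall inside the 15-residue window at the
#' site, mirroring the aliphatic-frequency signal), a 5% label flip rate,
#' and a 1 kcal/mol destabilizing shift of the pathogenic class in the
#' provider tables.
#'
#' @param seed integer master seed (all randomness derives from it).
#' @param n_proteins number of fixture proteins.
#' @param protein_length residues per protein (>= 12).
#' @param n_mutations mutations sampled per protein.
#' @param rule `"aliphatic_window"` (default) or `"hydrophobic_mt"`
#'   (disease iff the mutant residue is five-group hydrophobic).
#' @param epsilon label flip probability in \[0, 0.5).
#' @param effect_ddg mean ddG shift (kcal/mol) of the pathogenic class.
#' @param shifted_protein optional protein id whose rule is inverted
#'   (for weight-tuning experiments).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_proteins = 3, protein_length = 40,
                         n_mutations = 40,
                         rule = c("aliphatic_window", "hydrophobic_mt"),
                         epsilon = 0.05, effect_ddg = 1.0,
                         shifted_protein = NULL) {
  rule <- match.arg(rule)
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  if (protein_length < 12) stop("protein_length must be >= 12")
  if (n_mutations > 19 * protein_length) {
    stop("requested mutations exceed 19 x protein length")
  }
  structure(list(seed = as.integer(seed), n_proteins = n_proteins,
                 protein_length = protein_length,
                 n_mutations = n_mutations, rule = rule,
                 epsilon = epsilon, effect_ddg = effect_ddg,
                 shifted_protein = shifted_protein),
            class = "synth_config")
}

#' Named generator presets
#'
#' `"separable"` is the noise-free preset (epsilon = 0) used by the
#' end-to-end recovery checks; `"default"` keeps the stated 5% flip rate.
#'
#' @param preset preset name.
#' @param seed master seed.
#' @param ... overrides passed to [synth_config()].
#' @return a [synth_config()].
#' @export
synth_preset <- function(preset = c("default", "separable"), seed = 1,
                         ...) {
  preset <- match.arg(preset)
  if (preset == "separable") {
    synth_config(seed = seed, epsilon = 0, ...)
  } else {
    synth_config(seed = seed, ...)
  }
}

planted_rule_label <- function(config, protein, position, mt) {
  ali <- if (config$rule == "aliphatic_window") {
    len <- nchar(protein$sequence)
    idx <- setdiff(max(1L, position - 7L):min(len, position + 7L), position)
    letters1 <- strsplit(protein$sequence, "")[[1]][idx]
    sum(letters1 %in% SEVEN_GROUPS$aliphatic) >= 2
  } else {
    mt %in% FIVE_GROUPS$hydrophobic
  }
  inverted <- !is.null(config$shifted_protein) &&
    protein$protein_id == config$shifted_protein
  if (inverted) ali <- !ali
  if (ali) "Disease-causing" else "Neutral"
}

#' Generate a planted-signal synthetic dataset
#'
#' Builds `n_proteins` fixture helices with random sequences and confidence
#' values, samples `n_mutations` distinct missense mutations per protein,
#' labels them with the configured planted rule, flips each label with
#' probability `epsilon`, and fabricates a complete provider table with
#' class-conditional score distributions. Identical seeds give identical
#' output, including byte-identical files from [write_fixture_project()].
#'
#' @param config a [synth_config()].
#' @return list with `dataset` (a [mutation_dataset()]), `provider_table`
#'   (data.frame ready for [load_provider_table()] serialization) and
#'   `config`.
#' @export
synth_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  proteins <- list()
  records <- list()
  withr_seed(config$seed, {
    for (p in seq_len(config$n_proteins)) {
      pid <- sprintf("SYN%d", p)
      sequence <- paste(sample(AA_ONE, config$protein_length,
                               replace = TRUE), collapse = "")
      plddt <- round(stats::runif(config$protein_length, 70, 95), 2)
      proteins[[pid]] <- build_ideal_helix(sequence, plddt = plddt,
                                           protein_id = pid)
      seen <- character(0)
      made <- 0L
      while (made < config$n_mutations) {
        pos <- sample.int(config$protein_length, 1)
        wt <- substr(sequence, pos, pos)
        mt <- sample(setdiff(AA_ONE, wt), 1)
        key <- paste0(pos, mt)
        if (key %in% seen) next
        seen <- c(seen, key)
        made <- made + 1L
        label <- planted_rule_label(config, proteins[[pid]], pos, mt)
        if (stats::runif(1) < config$epsilon) {
          label <- if (label == "Disease-causing") "Neutral" else {
            "Disease-causing"
          }
        }
        records[[length(records) + 1L]] <- mutation_record(pid, pos, wt,
                                                           mt, label)
      }
    }
  })
  ds <- mutation_dataset(records, proteins,
                         notes = sprintf("synthetic seed %d rule %s",
                                         config$seed, config$rule))
  list(dataset = ds,
       provider_table = synth_provider_tables(ds, config),
       config = config)
}

#' Fabricate provider score tables for a labeled dataset
#'
#' Stability scores are drawn with the pathogenic-class mean shifted
#' negative by `effect_ddg`; conservation and disorder fields are drawn
#' inside their documented ranges with class-conditional means. Coverage
#' is complete over the dataset's mutations.
#'
#' @param dataset a labeled [mutation_dataset()].
#' @param config a [synth_config()].
#' @return data.frame in the provider TSV layout.
#' @export
synth_provider_tables <- function(dataset, config = synth_config()) {
  n <- length(dataset$records)
  is_dis <- vapply(dataset$records, function(r) r$label == "Disease-causing",
                   logical(1))
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  withr_seed(config$seed + 104729L, {
    ddg <- function() {
      round(stats::rnorm(n, mean = 0.5 - config$effect_ddg * is_dis,
                         sd = 1), 3)
    }
    data.frame(
      protein = vapply(dataset$records, function(r) r$protein_id,
                       character(1)),
      position = vapply(dataset$records, function(r) r$position,
                        integer(1)),
      wt = vapply(dataset$records, function(r) r$wt, character(1)),
      mt = vapply(dataset$records, function(r) r$mt, character(1)),
      ddg_mcsm = ddg(), ddg_saafecseq = ddg(), ddg_ddmut = ddg(),
      ddg_dynamut2 = ddg(),
      sift_score = round(ifelse(is_dis, stats::runif(n, 0, 0.2),
                                stats::runif(n, 0, 1)), 4),
      snap2_score = round(clip(stats::rnorm(n, ifelse(is_dis, 40, -40), 25),
                               -100, 100), 2),
      pssm_score = round(stats::rnorm(n, ifelse(is_dis, -2, 1), 1.5), 3),
      iupred_short = round(stats::runif(n, 0, 1), 4),
      iupred_long = round(stats::runif(n, 0, 1), 4),
      stringsAsFactors = FALSE)
  })
}

#' Write a complete toy project directory
#'
#' Emits FASTA and PDB files per protein, the mutation CSV, the provider
#' TSV and a config summary, so the whole pipeline can run from files.
#' Byte-identical for identical seeds.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_project <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  synth <- synth_dataset(config)
  ds <- synth$dataset
  for (pid in names(ds$proteins)) {
    write_fasta(ds$proteins[[pid]], file.path(dir, paste0(pid, ".fasta")))
    write_pdb(ds$proteins[[pid]], file.path(dir, paste0(pid, ".pdb")))
  }
  mut_df <- data.frame(
    protein = vapply(ds$records, function(r) r$protein_id, character(1)),
    position = vapply(ds$records, function(r) r$position, integer(1)),
    wt = vapply(ds$records, function(r) r$wt, character(1)),
    mt = vapply(ds$records, function(r) r$mt, character(1)),
    label = vapply(ds$records, function(r) r$label, character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(mut_df, file.path(dir, "mutations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(synth$provider_table,
                     file.path(dir, "providers.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("rule: %s", config$rule),
               sprintf("epsilon: %g", config$epsilon),
               sprintf("effect_ddg: %g", config$effect_ddg)),
             file.path(dir, "config.txt"))
  invisible(dir)
}
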