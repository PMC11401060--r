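# Shared fixtures, built once per test run. Everything is generated in
# code; no binary files.

polyA_helix <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- build_ideal_helix(strrep("A", 30), plddt = 90,
                                 protein_id = "HLX")
    }
    memo
  }
})

extended_chain <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- build_ideal_helix(strrep("A", 30), phi = 180, psi = 180,
                                 plddt = 90, protein_id = "EXT")
    }
    memo
  }
})

leu_bundle <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- build_helix_bundle(strrep("L", 18), strrep("L", 18),
                                  separation = 9, protein_id = "BUN")
    }
    memo
  }
})

# cheap feature families only (no surface/contact computation): used where
# model behaviour, not feature content, is under test
cheap_candidates <- function() {
  c("aliphatic_freq", "hydrophobic_freq", "aromatic_freq",
    "long_polar_freq", "short_polar_freq", "short_charged_polar_freq",
    "structure_breaking_freq",
    paste0(names(pathomiss:::FIVE_GROUPS), "_mt"),
    "KYTJ820101_mt", "KYTJ820101_delta_3", "MV_mt", "MW_delta_1",
    "pI_mt", "KLEP840101_mt")
}

cheap_matrix <- function(dataset, providers = NULL, extra = character(0)) {
  assemble_matrix(dataset, providers = providers,
                  features = c(cheap_candidates(), extra))
}

# constant-probability stub model usable wherever a bank model is expected
const_model <- function(p, features = "aliphatic_freq") {
  structure(list(p = p, features = features), class = "const_model")
}
predict.const_model <- function(object, newdata, ...) {
  n <- if (inherits(newdata, "feature_matrix")) nrow(newdata$features) else {
    nrow(newdata)
  }
  rep(object$p, n)
}
registerS3method("predict", "const_model", predict.const_model)

const_bank <- function(p, protein_id, which = "weighted") {
  m <- const_model(p)
  structure(list(generic = m,
                 weighted = stats::setNames(list(m), protein_id),
                 routing = stats::setNames(which, protein_id)),
            class = "model_bank")
}

write_provider_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  path
}
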