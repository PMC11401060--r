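# fixtures: ideal backbones and planted-signal dataset generation.

test_that("ideal backbones carry the requested geometry", {
  h <- polyA_helix()
  for (i in c(5, 15, 25)) {
    tor <- compute_torsions(h, i)
    expect_equal(unname(tor["phi"]), -57, tolerance = 0.02)
    expect_equal(unname(tor["psi"]), -47, tolerance = 0.03)
  }
  ca <- h$atoms[h$atoms$atom == "CA", c("x", "y", "z")]
  d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  ee <- function(p) {
    ca <- p$atoms[p$atoms$atom == "CA", c("x", "y", "z")]
    sqrt(sum((ca[nrow(ca), ] - ca[1, ])^2))
  }
  expect_gt(ee(extended_chain()), ee(polyA_helix()))
  expect_error(build_ideal_helix("AAAA", phi = NaN), "finite")
  # every residue type builds and passes the record validators
  all20 <- build_ideal_helix(paste(pathomiss:::AA_ONE, collapse = ""))
  expect_equal(nchar(all20$sequence), 20)
  expect_equal(length(unique(all20$atoms$resi)), 20)
})

test_that("synth_dataset plants the labeled rule with the stated flip rate", {
  config <- synth_config(seed = 101, epsilon = 0.1, n_mutations = 70)
  synth <- synth_dataset(config)
  ds <- synth$dataset
  expect_length(ds$records, 210)
  # counting oracle: recompute the rule labels independently and compare
  rule_label <- function(r) {
    protein <- ds$proteins[[r$protein_id]]
    len <- nchar(protein$sequence)
    idx <- setdiff(max(1, r$position - 7):min(len, r$position + 7),
                   r$position)
    ali <- sum(strsplit(protein$sequence, "")[[1]][idx] %in% c("I", "V"))
    if (ali >= 2) "Disease-causing" else "Neutral"
  }
  flips <- mean(vapply(ds$records, function(r) r$label != rule_label(r),
                       logical(1)))
  expect_lt(abs(flips - 0.1), 3 * sqrt(0.1 * 0.9 / 210))
  # epsilon = 0 plants the rule exactly
  clean <- synth_dataset(synth_preset("separable", seed = 102))
  expect_true(all(vapply(clean$dataset$records, function(r) {
    protein <- clean$dataset$proteins[[r$protein_id]]
    len <- nchar(protein$sequence)
    idx <- setdiff(max(1, r$position - 7):min(len, r$position + 7),
                   r$position)
    ali <- sum(strsplit(protein$sequence, "")[[1]][idx] %in% c("I", "V"))
    r$label == (if (ali >= 2) "Disease-causing" else "Neutral")
  }, logical(1))))
  expect_error(synth_config(n_mutations = 1000, protein_length = 12),
               "19 x")
  expect_error(synth_config(epsilon = 0.7), "epsilon")
})

test_that("synthetic provider tables are complete, in range, class-shifted", {
  config <- synth_config(seed = 103, n_mutations = 70, effect_ddg = 1)
  synth <- synth_dataset(config)
  ptab <- synth$provider_table
  prov <- load_provider_table(write_provider_tsv(ptab),
                              mutations = synth$dataset$records)
  expect_equal(prov$coverage, 1)
  expect_length(prov$missing, 0)
  is_dis <- vapply(synth$dataset$records,
                   function(r) r$label == "Disease-causing", logical(1))
  for (col in c("ddg_mcsm", "ddg_ddmut")) {
    expect_lt(mean(ptab[[col]][is_dis]), mean(ptab[[col]][!is_dis]))
  }
  expect_true(all(ptab$sift_score >= 0 & ptab$sift_score <= 1))
  expect_true(all(abs(ptab$snap2_score) <= 100))
})

test_that("fixture outputs pass the pipeline validators end to end", {
  config <- synth_config(seed = 104, n_proteins = 2, n_mutations = 15,
                         protein_length = 20)
  dir <- file.path(tempdir(), "fixproj104")
  write_fixture_project(config, dir)
  p1 <- load_protein(file.path(dir, "SYN1.fasta"),
                     file.path(dir, "SYN1.pdb"))
  expect_equal(nchar(p1$sequence), 20)
  parsed <- parse_mutation_table(file.path(dir, "mutations.csv"))
  expect_equal(nrow(parsed$rejected), 0)
  expect_length(parsed$records, 30)
  p2 <- load_protein(file.path(dir, "SYN2.fasta"),
                     file.path(dir, "SYN2.pdb"))
  cleaned <- clean_dataset(parsed$records,
                           list(SYN1 = p1, SYN2 = p2))
  expect_length(cleaned$dataset$records, 30)
  expect_equal(nrow(cleaned$report), 0)
  prov <- load_provider_table(file.path(dir, "providers.tsv"),
                              mutations = cleaned$dataset$records)
  expect_equal(prov$coverage, 1)
})
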