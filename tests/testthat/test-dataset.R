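# dataset_pipeline: cleaning with corrections, grouped splitting, assembly.

trem2_world <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      seqv <- strrep("A", 50)
      substr(seqv, 47, 47) <- "R"
      memo <<- list(TREM2 = build_ideal_helix(seqv, protein_id = "TREM2"))
    }
    memo
  }
})

test_that("clean_dataset applies the shipped corrections and reports", {
  proteins <- trem2_world()
  raw <- list(
    mutation_record("TREM2", 47, "R", "H", "Neutral"),
    mutation_record("TREM2", 10, "A", "V", "Neutral"),
    mutation_record("TREM2", 10, "A", "V", "Disease-causing"),  # duplicate
    mutation_record("TREM2", 12, "G", "V", "Neutral"),          # no map
    mutation_record("UNKNOWN", 3, "A", "V", "Neutral"))
  corr <- load_corrections()
  expect_equal(nrow(corr), 6)
  expect_setequal(
    sprintf("%s%d%s", corr$wt, corr$position, corr$mt),
    c("R47H", "R62H", "T66M", "R136Q", "H157Y", "T223I"))
  suppressWarnings(res <- clean_dataset(raw, proteins, corr))
  labs <- vapply(res$dataset$records, function(r) r$label, character(1))
  keys <- vapply(res$dataset$records, pathomiss:::mutation_key,
                 character(1))
  expect_equal(labs[keys == "TREM2_R47H"], "Disease-causing")
  expect_length(res$dataset$records, 2)
  expect_setequal(res$report$detail[res$report$action == "rejected"],
                  c("duplicate", "does not map to canonical sequence",
                    "unknown protein"))
  expect_true("corrected" %in% res$report$action)
  # idempotence: cleaning the cleaned records changes nothing
  res2 <- suppressWarnings(clean_dataset(res$dataset$records, proteins,
                                         corr))
  expect_equal(vapply(res2$dataset$records, pathomiss:::mutation_key,
                      character(1)), keys)
  expect_false(any(res2$report$action == "corrected"))
})

test_that("grouped_split partitions by site and is seed-deterministic", {
  synth <- synth_dataset(synth_config(seed = 4, n_mutations = 30))
  ds <- synth$dataset
  sp <- grouped_split(ds, seed = 1)
  n <- vapply(sp, function(d) length(d$records), integer(1))
  expect_equal(sum(n), length(ds$records))
  all_keys <- sort(vapply(ds$records, pathomiss:::mutation_key,
                          character(1)))
  split_keys <- sort(unname(unlist(lapply(sp, function(d) {
    vapply(d$records, pathomiss:::mutation_key, character(1))
  }))))
  expect_equal(split_keys, all_keys)
  # no (protein, position) group straddles partitions
  site_of <- function(d) unique(vapply(d$records, function(r) {
    paste(r$protein_id, r$position)
  }, character(1)))
  expect_length(intersect(site_of(sp$train), site_of(sp$val)), 0)
  expect_length(intersect(site_of(sp$train), site_of(sp$test)), 0)
  expect_length(intersect(site_of(sp$val), site_of(sp$test)), 0)
  # determinism and seed sensitivity
  sp_again <- grouped_split(ds, seed = 1)
  expect_identical(
    vapply(sp$train$records, pathomiss:::mutation_key, character(1)),
    vapply(sp_again$train$records, pathomiss:::mutation_key, character(1)))
  sp2 <- grouped_split(ds, seed = 2)
  expect_false(identical(
    sort(vapply(sp$train$records, pathomiss:::mutation_key, character(1))),
    sort(vapply(sp2$train$records, pathomiss:::mutation_key,
                character(1)))))
  tiny <- mutation_dataset(ds$records[1:2], ds$proteins)
  expect_error(grouped_split(tiny), "3")
})

test_that("grouped split property holds across random datasets and seeds", {
  for (seed in c(11, 12, 13)) {
    synth <- synth_dataset(synth_config(seed = seed, n_proteins = 2,
                                        n_mutations = 25))
    for (split_seed in c(1, 7)) {
      sp <- grouped_split(synth$dataset, seed = split_seed)
      n <- vapply(sp, function(d) length(d$records), integer(1))
      expect_equal(sum(n), 50)
      sites <- lapply(sp, function(d) unique(vapply(d$records, function(r) {
        paste(r$protein_id, r$position)
      }, character(1))))
      expect_equal(length(unique(unlist(sites))),
                   sum(lengths(sites)))  # sites partition cleanly
      # realized group fractions within one group of the 60/20/20 targets
      g <- lengths(sites)
      total <- sum(g)
      expect_lte(abs(g[["train"]] - 0.6 * total), 1 + 1e-9)
      expect_lte(abs(g[["val"]] - 0.2 * total), 1 + 1e-9)
    }
  }
})

test_that("assemble_matrix restricts to named features and reports exclusions", {
  synth <- synth_dataset(synth_config(seed = 6, n_proteins = 1,
                                      n_mutations = 10,
                                      protein_length = 25))
  ds <- synth$dataset
  fm <- cheap_matrix(ds)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm$features), 10)
  expect_setequal(colnames(fm$features), cheap_candidates())
  expect_error(assemble_matrix(ds, features = "no_such_feature"),
               "produced by no module")

  # provider-backed rows lacking scores are excluded and reported
  ptab <- synth$provider_table[-3, ]
  prov <- load_provider_table(write_provider_tsv(ptab))
  fm2 <- assemble_matrix(ds, providers = prov,
                         features = c("aliphatic_freq", "ddg_ddmut"))
  expect_equal(nrow(fm2$features), 9)
  excl <- attr(fm2, "exclusions")
  expect_equal(nrow(excl), 1)
  expect_match(excl$reason, "missing provider")
  expect_error(assemble_matrix(ds, features = "ddg_ddmut"),
               "no provider table")
})

test_that("the final 12-feature restriction matches the printed names", {
  synth <- synth_dataset(synth_config(seed = 8, n_proteins = 1,
                                      n_mutations = 4,
                                      protein_length = 20))
  fm <- assemble_matrix(synth$dataset, features = final_feature_set())
  expect_identical(colnames(fm$features), final_feature_set())
  expect_equal(ncol(fm$features), 12)
  expect_equal(nrow(fm$features), 4)
})

test_that("feature matrices serialize with provenance headers", {
  synth <- synth_dataset(synth_config(seed = 6, n_proteins = 1,
                                      n_mutations = 5,
                                      protein_length = 20))
  fm <- cheap_matrix(synth$dataset)
  f <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "# provenance seq_features")))
  body <- utils::read.delim(f, comment.char = "#", check.names = FALSE)
  expect_equal(nrow(body), 5)
  expect_true(all(c("key", "label", cheap_candidates()) %in%
                    colnames(body)))
})
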