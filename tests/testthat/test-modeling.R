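# modeling: sample weights, GBM training, greedy selection, model bank.

sep_world <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      synth <- synth_dataset(synth_preset("separable", seed = 21))
      fm <- cheap_matrix(synth$dataset)
      memo <<- list(synth = synth, fm = fm,
                    split = grouped_split(fm, seed = 2))
    }
    memo
  }
})

test_that("make_weights up-weights the target protein 11:1", {
  fm <- sep_world()$fm
  w <- make_weights(fm, weight_config("SYN1"))
  expect_setequal(unique(w), c(11, 1))
  expect_true(all(w[fm$proteins == "SYN1"] == 11))
  expect_true(all(w[fm$proteins != "SYN1"] == 1))
  expect_equal(make_weights(fm), rep(1, nrow(fm$features)))
  expect_warning(w2 <- make_weights(fm, weight_config("NOPE")), "absent")
  expect_equal(w2, rep(1, nrow(fm$features)))
  expect_error(weight_config("SYN1", w_target = 0), "positive")
})

test_that("training is deterministic, weight-neutral at w=1, and fits the planted rule", {
  w <- sep_world()
  cfg <- model_config()
  m1 <- train(w$split$train, cfg)
  m2 <- train(w$split$train, cfg)
  probe <- w$split$test
  expect_identical(predict(m1, probe), predict(m2, probe))
  m3 <- train(w$split$train, cfg, weights = rep(1, nrow(w$split$train$features)))
  expect_identical(predict(m1, probe), predict(m3, probe))
  # training-set separation on the noise-free preset
  fit_metrics <- compute_metrics(w$split$train$labels,
                                 predict(m1, w$split$train))
  expect_gte(fit_metrics$bacc, 0.99)
  # single-class labels refuse to train
  pos <- which(w$fm$labels == "Neutral")
  expect_error(train(pathomiss:::subset_matrix(w$fm, pos), cfg),
               "single-class")
})

test_that("predictions are invariant to feature column order", {
  w <- sep_world()
  model <- train(w$split$train, model_config())
  df <- w$split$test$features
  shuffled <- df[, rev(colnames(df))]
  expect_identical(predict(model, df), predict(model, shuffled))
  expect_error(predict(model, df[, 1:3]), "lacks feature")
})

test_that("greedy selection finds the planted determinant and stops", {
  w <- sep_world()
  cfg <- model_config()
  gs <- greedy_select(w$split$train, w$split$val, cfg,
                      candidates = cheap_candidates())
  expect_equal(gs$features[1], "aliphatic_freq")
  expect_equal(unname(gs$scores[1]), 1)
  expect_length(gs$features, 1)  # MCC 1 cannot improve further
  # duplicated informative column: exactly one copy selected
  fm_dup <- w$split$train
  fm_dup$features$aliphatic_freq_copy <- fm_dup$features$aliphatic_freq
  fm_dup$provenance <- c(fm_dup$provenance,
                         aliphatic_freq_copy = "seq_features")
  val_dup <- w$split$val
  val_dup$features$aliphatic_freq_copy <- val_dup$features$aliphatic_freq
  gs2 <- greedy_select(fm_dup, val_dup, cfg,
                       candidates = c("aliphatic_freq",
                                      "aliphatic_freq_copy"))
  expect_equal(gs2$features, "aliphatic_freq")  # tie broken by order
  expect_error(greedy_select(w$split$train, w$split$val, cfg,
                             candidates = character(0)), "empty")
})

test_that("greedy selection terminates under a cap on pure noise", {
  w <- sep_world()
  noise <- w$split$train
  withr::with_seed(5, {
    noise$labels <- sample(noise$labels)
  })
  gs <- greedy_select(noise, w$split$val, model_config(n_estimators = 20),
                      candidates = cheap_candidates()[1:6],
                      max_features = 3)
  expect_lte(length(gs$features), 3)
  if (length(gs$scores) > 1) {
    expect_true(all(diff(gs$scores) > 0))  # accepted steps improved
  }
})

test_that("build_bank trains generic plus weighted models with routing", {
  w <- sep_world()
  cfg <- model_config(n_estimators = 30)
  bank <- build_bank(w$split$train, config = cfg)
  expect_s3_class(bank, "model_bank")
  expect_length(bank$weighted, 3)
  expect_setequal(names(bank$routing), c("SYN1", "SYN2", "SYN3"))
  r <- route_model(bank, "SYN2")
  expect_equal(r$which, "weighted")
  expect_error(route_model(bank, "APP"), "not in the model bank")
  # default routing overrides send APOE/PSEN2-named proteins to generic
  bank2 <- build_bank(w$split$train, proteins = c("SYN1", "SYN2", "SYN3"),
                      config = cfg, route_to_generic = "SYN1")
  expect_equal(route_model(bank2, "SYN1")$which, "generic")
  expect_identical(route_model(bank2, "SYN1")$model, bank2$generic)
  # proteins without training rows fall back to generic
  expect_message(
    bank3 <- build_bank(w$split$train, proteins = c("SYN1", "GHOST"),
                        config = cfg),
    "no training rows")
  expect_equal(route_model(bank3, "GHOST")$which, "generic")
})
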