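# Gradient-boosting training, per-protein sample weighting, greedy forward
# feature selection, and the generic + per-protein model bank with its
# routing rule.

#' Gradient-boosting model configuration
#'
#' Defaults are the tuned boosting hyperparameters used throughout:
#' 80 estimators, learning rate 0.1, tree depth 7.
#'
#' @param n_estimators number of boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param max_depth maximum tree depth.
#' @param min_samples_leaf minimum rows per leaf.
#' @param seed integer recorded in every trained artifact. The fit itself
#'   is deterministic (exact greedy splits, no subsampling); the seed is
#'   metadata for provenance.
#' @return object of class `model_config`.
#' @export
model_config <- function(n_estimators = 80, learning_rate = 0.1,
                         max_depth = 7, min_samples_leaf = 1, seed = 42) {
  stopifnot(n_estimators >= 1, learning_rate > 0, max_depth >= 1,
            min_samples_leaf >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Sample-weight configuration for protein-specific training
#'
#' Rows of the target protein receive `w_target` (default 11), all other
#' rows `w_other` (default 1). With no target every row weighs 1.
#'
#' @param target_protein protein symbol or NULL.
#' @param w_target,w_other positive weights.
#' @return object of class `weight_config`.
#' @export
weight_config <- function(target_protein = NULL, w_target = 11,
                          w_other = 1) {
  if (w_target <= 0 || w_other <= 0) stop("weights must be positive")
  structure(list(target_protein = target_protein, w_target = w_target,
                 w_other = w_other),
            class = "weight_config")
}

#' Per-row sample weights for a feature matrix
#'
#' @param matrix a feature matrix (or a character vector of row proteins).
#' @param config a [weight_config()].
#' @return numeric weight vector aligned with rows.
#' @export
make_weights <- function(matrix, config = weight_config()) {
  proteins <- if (inherits(matrix, "feature_matrix")) matrix$proteins else {
    as.character(matrix)
  }
  if (is.null(config$target_protein)) {
    return(rep(1.0, length(proteins)))
  }
  if (!config$target_protein %in% proteins) {
    warning("target protein ", config$target_protein,
            " absent from the data; uniform weights returned")
    return(rep(1.0, length(proteins)))
  }
  ifelse(proteins == config$target_protein, config$w_target,
         config$w_other)
}

#' Train a gradient-boosted classifier
#'
#' Fits weighted gradient-boosted trees (logistic loss, Newton leaf
#' updates) on a feature matrix; the positive class is "Disease-causing".
#' The fit is deterministic for fixed data, weights and configuration.
#'
#' @param matrix a feature matrix with both classes present.
#' @param config a [model_config()].
#' @param weights optional per-row sample weights (default all 1).
#' @return object of class `gbm_model` carrying the trees, the ordered
#'   feature names, the config and the seed.
#' @export
train <- function(matrix, config = model_config(), weights = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  y <- as_binary_labels(matrix$labels)
  if (length(unique(y)) < 2) {
    stop("training labels are single-class; cannot fit a classifier")
  }
  X <- as.matrix(matrix$features)
  if (is.null(weights)) weights <- rep(1.0, nrow(X))
  if (length(weights) != nrow(X)) stop("weights do not align with rows")
  if (any(weights <= 0)) stop("sample weights must be positive")
  fit <- .gbm_fit_cpp(X, as.numeric(y), as.numeric(weights),
                      config$n_estimators, config$learning_rate,
                      config$max_depth, config$min_samples_leaf)
  structure(list(fit = fit, features = colnames(X), config = config,
                 seed = config$seed),
            class = "gbm_model")
}

#' @export
print.gbm_model <- function(x, ...) {
  cat(sprintf("<gbm_model: %d trees, depth %d, %d features>\n",
              x$config$n_estimators, x$config$max_depth,
              length(x$features)))
  invisible(x)
}

#' Predict disease-causing probability
#'
#' @param object a [train()]ed model.
#' @param newdata a feature matrix or data.frame carrying (at least) the
#'   model's feature columns, in any order.
#' @param ... unused.
#' @return numeric probabilities in \[0, 1\].
#' @export
predict.gbm_model <- function(object, newdata, ...) {
  df <- if (inherits(newdata, "feature_matrix")) newdata$features else {
    as.data.frame(newdata, check.names = FALSE)
  }
  missing_cols <- setdiff(object$features, colnames(df))
  if (length(missing_cols) > 0) {
    stop("newdata lacks feature column(s): ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  X <- as.matrix(df[, object$features, drop = FALSE])
  .gbm_predict_cpp(object$fit, X)
}

#' Greedy forward feature selection maximizing validation MCC
#'
#' Starting from the empty set, repeatedly adds the single candidate
#' feature whose inclusion (with a refit on the training matrix) maximizes
#' MCC on the validation matrix; stops when no candidate improves MCC by
#' more than `tol` or when `max_features` is reached. Ties break by
#' candidate column order, so the procedure is deterministic.
#'
#' @param train_matrix,val_matrix feature matrices sharing a column catalog.
#' @param config a [model_config()].
#' @param candidates candidate feature names (default: all shared columns).
#' @param tol minimum MCC improvement to continue.
#' @param max_features selection cap.
#' @param weights optional training-row weights.
#' @return list with `features` (ordered selection) and `scores`
#'   (validation MCC after each accepted step).
#' @export
greedy_select <- function(train_matrix, val_matrix,
                          config = model_config(), candidates = NULL,
                          tol = 1e-6, max_features = 30, weights = NULL) {
  cols <- intersect(colnames(train_matrix$features),
                    colnames(val_matrix$features))
  if (is.null(candidates)) candidates <- cols
  if (length(candidates) == 0) stop("empty candidate pool")
  bad <- setdiff(candidates, cols)
  if (length(bad) > 0) {
    stop("candidate feature(s) not in both matrices: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  selected <- character(0)
  scores <- numeric(0)
  best_score <- -Inf
  repeat {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0 || length(selected) >= max_features) break
    step_scores <- vapply(pool, function(feat) {
      fs <- c(selected, feat)
      model <- train(restrict_features(train_matrix, fs), config,
                     weights = weights)
      prob <- predict(model, restrict_features(val_matrix, fs))
      m <- compute_metrics(val_matrix$labels, prob)$mcc
      if (is.na(m)) -1 else m
    }, numeric(1))
    best_i <- which.max(step_scores)  # first max: tie-break by column order
    if (step_scores[best_i] <= best_score + tol) break
    best_score <- unname(step_scores[best_i])
    selected <- c(selected, pool[best_i])
    scores <- c(scores, best_score)
  }
  list(features = selected, scores = scores)
}

#' Build a generic + per-protein weighted model bank
#'
#' Trains one generic model on all rows and, for every listed protein, a
#' specialised model with that protein's rows up-weighted
#' (see [weight_config()]). The routing rule maps each protein to its
#' weighted model except for proteins in `route_to_generic` (default APOE
#' and PSEN2, whose weighted models underperform), which use the generic
#' model. Proteins without training rows are routed to the generic model.
#'
#' @param matrix training feature matrix.
#' @param proteins proteins to build weighted models for (default: all in
#'   the matrix).
#' @param config a [model_config()].
#' @param wconfig base [weight_config()] (target set per protein).
#' @param route_to_generic protein symbols forced onto the generic model.
#' @return object of class `model_bank`.
#' @export
build_bank <- function(matrix, proteins = NULL, config = model_config(),
                       wconfig = weight_config(),
                       route_to_generic = c("APOE", "PSEN2")) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (is.null(proteins)) proteins <- unique(matrix$proteins)
  generic <- train(matrix, config)
  weighted <- list()
  routing <- stats::setNames(rep("weighted", length(proteins)), proteins)
  for (p in proteins) {
    if (!p %in% matrix$proteins) {
      message("protein ", p, " has no training rows; routed to generic")
      routing[p] <- "generic"
      next
    }
    wc <- weight_config(p, wconfig$w_target, wconfig$w_other)
    weighted[[p]] <- train(matrix, config, weights = make_weights(matrix, wc))
  }
  routing[names(routing) %in% route_to_generic] <- "generic"
  structure(list(generic = generic, weighted = weighted,
                 routing = routing),
            class = "model_bank")
}

#' Resolve the model a protein routes to
#'
#' @param bank a [build_bank()] result.
#' @param protein protein symbol.
#' @return list with `model` and `which` (`"generic"` or `"weighted"`).
#' @export
route_model <- function(bank, protein) {
  stopifnot(inherits(bank, "model_bank"))
  if (!protein %in% names(bank$routing)) {
    stop("protein ", protein, " not in the model bank")
  }
  which <- bank$routing[[protein]]
  model <- if (which == "weighted" && !is.null(bank$weighted[[protein]])) {
    bank$weighted[[protein]]
  } else {
    which <- "generic"
    bank$generic
  }
  list(model = model, which = which)
}
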