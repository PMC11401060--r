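# Metrics, grouped cross-validation schemes, MCC-maximizing cutoff
# calibration for external predictor scores, and two-group rank tests.
# "Disease-causing" is the positive class throughout.

#' Classification metrics from labels and probabilities
#'
#' Thresholds the probabilities at `cutoff` and reports balanced accuracy,
#' F1, MCC, sensitivity (recall), specificity, precision, accuracy and the
#' rank-statistic AUC, plus the confusion counts. With single-class labels
#' the AUC (and class-conditional rates that are undefined) are NA.
#'
#' @param labels logical/0-1 vector, or characters where `"Disease-causing"`
#'   marks positives.
#' @param probabilities numeric vector in \[0, 1\].
#' @param cutoff decision threshold (predict positive when prob >= cutoff).
#' @return object of class `metrics_report` (named list).
#' @export
compute_metrics <- function(labels, probabilities, cutoff = 0.5) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(probabilities))
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  pred <- probabilities >= cutoff
  tp <- sum(pred & y)
  fp <- sum(pred & !y)
  tn <- sum(!pred & !y)
  fn <- sum(!pred & y)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else {
    2 * prec * sens / (prec + sens)
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else {
    (tp * tn - fp * fn) / mcc_den
  }
  auc <- if (length(unique(y)) < 2) NA_real_ else {
    r <- rank(probabilities)
    n_pos <- sum(y)
    n_neg <- sum(!y)
    (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  structure(list(
    bacc = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    f1 = f1, mcc = mcc, sensitivity = sens, specificity = spec,
    precision = prec, auc = auc,
    accuracy = (tp + tn) / length(y),
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn), cutoff = cutoff
  ), class = "metrics_report")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  if (any(!labels %in% c("Disease-causing", "Neutral"))) {
    stop("labels must be Disease-causing/Neutral (or logical/0-1)")
  }
  labels == "Disease-causing"
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics: bacc %.3f f1 %.3f mcc %.3f sens %.3f spec %.3f prec %.3f auc %s>\n",
    x$bacc, x$f1, x$mcc, x$sensitivity, x$specificity, x$precision,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Grouped k-fold cross-validation
#'
#' Folds are formed over unique (protein, position) groups so that repeated
#' substitutions at the same site never straddle a fold boundary.
#' Out-of-fold predicted probabilities are pooled and metrics computed once
#' on the pool (not averaged per fold).
#'
#' @param matrix a [assemble_matrix()] feature matrix with labels.
#' @param k number of folds (>= 2, <= number of groups).
#' @param config a [model_config()].
#' @param seed integer seed controlling fold assignment.
#' @param weights optional per-row sample weights.
#' @return a [compute_metrics()] report with attribute `folds`.
#' @export
kfold_cv <- function(matrix, k = 10, config = model_config(), seed = 1,
                     weights = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (k < 2) stop("k must be at least 2")
  groups <- paste(matrix$proteins, matrix$positions, sep = "@")
  ug <- unique(groups)
  if (k > length(ug)) stop("k exceeds the number of (protein, position) groups")
  rng <- seeded_rng(seed)
  ug <- ug[rng$sample(length(ug))]
  fold_of_group <- stats::setNames(rep(seq_len(k), length.out = length(ug)),
                                   ug)
  fold <- fold_of_group[groups]
  prob <- rep(NA_real_, nrow(matrix$features))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    model <- train(subset_matrix(matrix, train_idx), config,
                   weights = weights[train_idx])
    prob[test_idx] <- predict(model, subset_matrix(matrix, test_idx))
  }
  rep_out <- compute_metrics(matrix$labels, prob)
  attr(rep_out, "folds") <- fold
  rep_out
}

#' Leave-one-protein-out validation
#'
#' For each protein in the matrix, trains on all other proteins' rows and
#' evaluates on the held-out protein's mutations.
#'
#' @param matrix a feature matrix with at least two proteins.
#' @param config a [model_config()].
#' @return named list of [compute_metrics()] reports, one per protein.
#' @export
leave_one_protein_out <- function(matrix, config = model_config()) {
  stopifnot(inherits(matrix, "feature_matrix"))
  proteins <- unique(matrix$proteins)
  if (length(proteins) < 2) stop("need at least two proteins")
  out <- list()
  for (p in proteins) {
    held <- which(matrix$proteins == p)
    rest <- which(matrix$proteins != p)
    model <- train(subset_matrix(matrix, rest), config)
    prob <- predict(model, subset_matrix(matrix, held))
    out[[p]] <- compute_metrics(matrix$labels[held], prob)
  }
  out
}

#' MCC-maximizing score cutoff
#'
#' Scans every midpoint between adjacent sorted unique scores (plus the two
#' infinite sentinels) and returns the cutoff maximizing MCC; ties resolve
#' to the smallest cutoff. `orientation` declares whether a high score
#' means pathogenic (`"high"`) or a low one does (`"low"`).
#'
#' @param scores numeric predictor scores.
#' @param labels binary labels (positive = pathogenic).
#' @param orientation `"high"` or `"low"`.
#' @return list with `cutoff` and the achieved `mcc`.
#' @export
optimize_cutoff <- function(scores, labels, orientation = c("high", "low")) {
  orientation <- match.arg(orientation)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("scores are constant; no cutoff exists")
  cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  mcc_at <- function(cut) {
    pred <- if (orientation == "high") scores > cut else scores < cut
    tp <- sum(pred & y); fp <- sum(pred & !y)
    tn <- sum(!pred & !y); fn <- sum(!pred & y)
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    if (den == 0) -Inf else (tp * tn - fp * fn) / den
  }
  mccs <- vapply(cand, mcc_at, numeric(1))
  best <- which(mccs >= max(mccs) - 1e-12)[1]  # ties -> smallest cutoff
  list(cutoff = cand[best], mcc = mccs[best])
}

#' Two-group rank comparison
#'
#' Two-tailed Wilcoxon rank-sum (Mann-Whitney) test between two independent
#' groups of values: exact enumeration for small untied samples, normal
#' approximation with tie correction otherwise (the default behaviour of
#' [stats::wilcox.test()]). Significance is judged at the 5% level.
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @return object of class `comparison_result` with `statistic`, `p_value`,
#'   `n_a`, `n_b`, `significant`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values")
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n_a = length(values_a), n_b = length(values_b),
                 significant = wt$p.value < 0.05),
            class = "comparison_result")
}

# small deterministic RNG wrapper so split/fold seeds never disturb the
# caller's global RNG state
seeded_rng <- function(seed) {
  env <- new.env()
  env$sample <- function(n) {
    withr_seed(seed, sample.int(n))
  }
  env
}

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
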