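#' Confusion counts for one positive class
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @param positive the label treated as positive; all others are negative.
#' @return list with integer \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
confusion_counts <- function(truth, pred, positive) {
  t_pos <- as.character(truth) == positive
  p_pos <- as.character(pred) == positive
  list(TP = sum(t_pos & p_pos), TN = sum(!t_pos & !p_pos),
       FP = sum(!t_pos & p_pos), FN = sum(t_pos & !p_pos))
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion-matrix metrics
#'
#' Computes accuracy, recall (sensitivity), specificity, precision,
#' balanced accuracy, F1 and G-mean from one-vs-rest confusion counts.
#' Undefined ratios (0/0) are reported as \code{NA} and excluded from any
#' macro averaging. Two balanced-accuracy conventions are supported:
#' \code{"standard"} uses (recall + specificity)/2; \code{"as_printed"}
#' uses (precision + recall)/2, the convention some of the literature this
#' package follows reports. Recall is always TP/(TP+FN) and G-mean always
#' sqrt(recall * specificity).
#'
#' @param counts list with TP, TN, FP, FN (see
#'   \code{\link{confusion_counts}}).
#' @param mode \code{"standard"} (default) or \code{"as_printed"}.
#' @return Named numeric vector of metrics in [0, 1] (or \code{NA}).
#' @export
compute_metrics <- function(counts, mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be nonnegative")
  accuracy <- safe_div(TP + TN, TP + TN + FP + FN)
  recall <- safe_div(TP, TP + FN)
  specificity <- safe_div(TN, FP + TN)
  precision <- safe_div(TP, TP + FP)
  balanced_accuracy <- if (mode == "as_printed") {
    if (is.na(precision) || is.na(recall)) NA_real_
    else (precision + recall) / 2
  } else {
    if (is.na(recall) || is.na(specificity)) NA_real_
    else (recall + specificity) / 2
  }
  f1 <- if (is.na(recall) || is.na(precision) || (recall + precision) == 0)
    NA_real_ else 2 * recall * precision / (recall + precision)
  g_mean <- if (is.na(recall) || is.na(specificity)) NA_real_
            else sqrt(recall * specificity)
  c(accuracy = accuracy, recall = recall, specificity = specificity,
    precision = precision, balanced_accuracy = balanced_accuracy,
    f1 = f1, g_mean = g_mean)
}

#' Rank-statistic AUC for one positive class
#'
#' Mann-Whitney form: the probability that a random positive scores higher
#' than a random negative, with ties counted half. Equals the trapezoidal
#' area under the ROC curve.
#'
#' @param truth true labels.
#' @param scores numeric score for the positive class (higher = more
#'   positive).
#' @param positive the positive label.
#' @return AUC in [0, 1], or \code{NA} when either class is absent.
#' @export
auc_score <- function(truth, scores, positive) {
  pos <- as.character(truth) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest multi-class metrics with macro average
#'
#' Scores each class as positive against the rest, then macro-averages
#' each metric over the classes where it is defined.
#'
#' @param truth true labels (>= 2 classes among truth/pred levels).
#' @param pred predicted labels.
#' @param scores optional numeric matrix (samples x classes, columns named
#'   by class) of continuous outputs; enables per-class AUC.
#' @param mode metric convention, see \code{\link{compute_metrics}}.
#' @return list with \code{per_class} (data frame, one row per class) and
#'   \code{macro} (named numeric vector).
#' @export
one_vs_rest <- function(truth, pred, scores = NULL,
                        mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  classes <- if (is.factor(truth)) levels(truth)
             else sort(unique(as.character(truth)))
  if (length(classes) < 2) stop("need at least 2 classes")
  rows <- lapply(classes, function(cl) {
    m <- compute_metrics(confusion_counts(truth, pred, cl), mode = mode)
    auc <- if (!is.null(scores)) auc_score(truth, scores[, cl], cl)
           else NA_real_
    c(m, auc = auc)
  })
  per_class <- do.call(rbind, rows)
  per_class <- data.frame(class = classes, per_class,
                          stringsAsFactors = FALSE, row.names = NULL)
  macro <- colMeans(per_class[, -1, drop = FALSE], na.rm = TRUE)
  macro[is.nan(macro)] <- NA_real_
  list(per_class = per_class, macro = macro)
}

# stratified fold assignment: vector of fold ids (NA = always in training)
stratified_folds <- function(y, folds, seed) {
  y <- factor(y)
  assign <- rep(NA_integer_, length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) == 1) {
        warning(sprintf("class '%s' has a single member; kept in training", cl))
        next
      }
      idx <- sample(idx)
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Seeded stratified cross-validation of a train/predict pipeline
#'
#' Splits samples into stratified folds, fits the pipeline on the training
#' folds only and scores its predictions on the held-out fold. The
#' pipeline receives incomplete training data and must handle its own
#' imputation, so imputation statistics never see test folds. Samples with
#' missing labels are excluded. If any class has fewer members than
#' \code{folds}, the fold count is reduced (with a message) to the
#' smallest class size, floored at 2.
#'
#' @param X an \code{incomplete_matrix} (or numeric matrix).
#' @param y class labels.
#' @param pipeline function \code{(X_train, y_train, X_test) -> predicted
#'   labels for X_test}; the X arguments are \code{incomplete_matrix}
#'   objects.
#' @param folds number of folds (default 10).
#' @param trials number of repeats with different fold shuffles (default 1).
#' @param seed master seed; trial t uses \code{seed + t}.
#' @param metric \code{"accuracy"} (pooled over folds) or
#'   \code{"balanced_accuracy"} (macro one-vs-rest, standard mode).
#' @return list with \code{scores} (one per trial), \code{mean}, \code{sd},
#'   \code{folds} (count actually used).
#' @export
cross_validate <- function(X, y, pipeline, folds = 10, trials = 1, seed = 1,
                           metric = c("accuracy", "balanced_accuracy")) {
  metric <- match.arg(metric)
  if (!inherits(X, "incomplete_matrix")) X <- incomplete_matrix(as.matrix(X))
  y <- factor(y)
  keep <- !is.na(y)
  if (!all(keep)) {
    X <- incomplete_matrix(X$values[keep, , drop = FALSE],
                           X$mask[keep, , drop = FALSE],
                           X$feature_names, X$sample_ids[keep])
    y <- droplevels(y[keep])
  }
  if (folds < 2) stop("folds must be >= 2")
  min_class <- min(table(y))
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    message(sprintf("reduced to %d folds (smallest class has %d members)",
                    folds, min_class))
  }
  sub <- function(idx) incomplete_matrix(X$values[idx, , drop = FALSE],
                                         X$mask[idx, , drop = FALSE],
                                         X$feature_names, X$sample_ids[idx])
  scores <- numeric(trials)
  for (t in seq_len(trials)) {
    fold_id <- stratified_folds(y, folds, seed = seed + t)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(folds)) {
      te <- which(!is.na(fold_id) & fold_id == f)
      tr <- setdiff(seq_along(y), te)
      pred[te] <- factor(as.character(
        pipeline(sub(tr), y[tr], sub(te))), levels = levels(y))
    }
    evaluated <- !is.na(fold_id)
    scores[t] <- if (metric == "accuracy") {
      mean(pred[evaluated] == y[evaluated])
    } else {
      one_vs_rest(y[evaluated], pred[evaluated])$macro["balanced_accuracy"]
    }
  }
  list(scores = scores, mean = mean(scores),
       sd = if (trials > 1) stats::sd(scores) else NA_real_, folds = folds)
}

#' Imputation + voting-ELM pipeline for cross-validation
#'
#' Builds the \code{pipeline} closure \code{\link{cross_validate}} expects:
#' impute the training fold (fold-safe), train a V-ELM, impute the test
#' fold with training-fold statistics, predict.
#'
#' @param imputer \code{"mean"} or \code{"knn"}.
#' @param k KNN neighbour count.
#' @param hidden hidden-neuron count (\code{NULL} = auto).
#' @param n_models ensemble size.
#' @param seed seed for the ELM hidden layers.
#' @return A pipeline function.
#' @export
velm_pipeline <- function(imputer = "mean", k = 10, hidden = NULL,
                          n_models = 30, seed = 1) {
  force(imputer); force(k); force(hidden); force(n_models); force(seed)
  function(X_train, y_train, X_test) {
    imp <- impute_train_test(X_train, X_test, method = imputer, k = k)
    model <- train_velm(imp$train, y_train, hidden = hidden,
                        n_models = n_models, seed = seed)
    predict(model, imp$test)
  }
}
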