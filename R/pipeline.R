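#' Pipeline configuration
#'
#' Bundles every tunable of the rank -> impute -> forward-search ->
#' evaluate pipeline with defaults matching the method's published
#' settings: selection level alpha = 0.001, 30-member voting ensemble,
#' search patience 5, 10-fold cross-validation, 20 evaluation trials.
#'
#' @param alpha MCFS significance level.
#' @param n_bins,strategy discretization settings.
#' @param imputer \code{"mean"} or \code{"knn"}; \code{k} KNN neighbours.
#' @param hidden hidden neurons (\code{NULL} = \code{min(100, n_train-1)}).
#' @param n_models ensemble size.
#' @param pof forward-search step, percent of features.
#' @param patience non-improving rounds tolerated.
#' @param folds,trials cross-validation shape for the final evaluation
#'   (the search itself uses single-trial CV).
#' @param metric_mode \code{"standard"} or \code{"as_printed"} (see
#'   \code{\link{compute_metrics}}).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(alpha = 0.001, n_bins = "auto",
                            strategy = "equal_frequency",
                            imputer = "mean", k = 10, hidden = NULL,
                            n_models = 30, pof = 5, patience = 5,
                            folds = 10, trials = 20,
                            metric_mode = "standard", seed = 1) {
  structure(list(alpha = alpha, n_bins = n_bins, strategy = strategy,
                 imputer = imputer, k = k, hidden = hidden,
                 n_models = n_models, pof = pof, patience = patience,
                 folds = folds, trials = trials,
                 metric_mode = metric_mode, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full feature-selection and classification pipeline
#'
#' Executes the method's three stages in order on incomplete data:
#' (1) rank features with the missing-data chi-square filter — no
#' imputation happens before or inside this stage; (2) forward best-first
#' search over the selected prefix, imputing each candidate prefix and
#' scoring it with cross-validated voting-ELM; (3) final multi-trial
#' cross-validated evaluation of the best subset with one-vs-rest metrics.
#' If no feature clears \code{alpha}, the full ranking is searched with a
#' warning (a looser threshold is preferable to an empty set).
#'
#' @param X an \code{incomplete_matrix}.
#' @param y class labels.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{ranking} (\code{mcfs_ranking}), \code{fbfs}
#'   (\code{fbfs_result}), \code{best_features} (names), \code{cv}
#'   (final cross-validation result), \code{metrics} (one-vs-rest report
#'   from a held-out-style pooled prediction of the last trial) and
#'   \code{config}.
#' @export
run_pipeline <- function(X, y, config = pipeline_config()) {
  stopifnot(inherits(X, "incomplete_matrix"), inherits(config, "pipeline_config"))
  y <- factor(y)
  ranking <- mcfs_rank(X, y, alpha = config$alpha, n_bins = config$n_bins,
                       strategy = config$strategy)
  searched <- ranking$selected
  if (!length(searched)) {
    warning("no feature passed alpha = ", config$alpha,
            "; searching the full ranking")
    searched <- ranking$order
  }
  evaluator <- velm_evaluator(X, y, imputer = config$imputer, k = config$k,
                              hidden = config$hidden,
                              n_models = config$n_models,
                              folds = config$folds, trials = 1,
                              seed = config$seed)
  fb <- forward_best_first(searched, evaluator,
                           pof = config$pof, patience = config$patience)
  Xb <- incomplete_matrix(X$values[, fb$best_subset, drop = FALSE],
                          X$mask[, fb$best_subset, drop = FALSE],
                          X$feature_names[fb$best_subset], X$sample_ids)
  cv <- cross_validate(Xb, y,
                       velm_pipeline(imputer = config$imputer, k = config$k,
                                     hidden = config$hidden,
                                     n_models = config$n_models,
                                     seed = config$seed),
                       folds = config$folds, trials = config$trials,
                       seed = config$seed + 1000L)
  # pooled predictions of one CV pass for a per-class metrics report
  metrics <- pooled_cv_metrics(Xb, y, config)
  list(ranking = ranking, fbfs = fb,
       best_features = X$feature_names[fb$best_subset],
       cv = cv, metrics = metrics, config = config)
}

pooled_cv_metrics <- function(X, y, config) {
  y <- factor(y)
  keep <- !is.na(y)
  Xk <- incomplete_matrix(X$values[keep, , drop = FALSE],
                          X$mask[keep, , drop = FALSE],
                          X$feature_names, X$sample_ids[keep])
  yk <- droplevels(y[keep])
  folds <- min(config$folds, max(2L, min(table(yk))))
  fold_id <- stratified_folds(yk, folds, seed = config$seed + 2000L)
  pred <- factor(rep(NA_character_, length(yk)), levels = levels(yk))
  scores <- matrix(0, length(yk), nlevels(yk),
                   dimnames = list(NULL, levels(yk)))
  for (f in seq_len(folds)) {
    te <- which(!is.na(fold_id) & fold_id == f)
    tr <- setdiff(seq_along(yk), te)
    sub <- function(idx) incomplete_matrix(Xk$values[idx, , drop = FALSE],
                                           Xk$mask[idx, , drop = FALSE],
                                           Xk$feature_names,
                                           Xk$sample_ids[idx])
    imp <- impute_train_test(sub(tr), sub(te), method = config$imputer,
                             k = config$k)
    model <- train_velm(imp$train, yk[tr], hidden = config$hidden,
                        n_models = config$n_models, seed = config$seed)
    pred[te] <- predict(model, imp$test)
    for (mod in model$models)
      scores[te, ] <- scores[te, ] +
        predict(mod, imp$test, type = "score")[, levels(yk), drop = FALSE]
  }
  evaluated <- !is.na(fold_id)
  one_vs_rest(yk[evaluated], pred[evaluated],
              scores = scores[evaluated, , drop = FALSE],
              mode = config$metric_mode)
}
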