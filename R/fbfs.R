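#' Forward best-first search over a ranked feature list
#'
#' Grows the top-ranked feature prefix in steps of \code{pof} percent:
#' round t evaluates the top \code{ceiling(t * pof/100 * n)} features with
#' the supplied evaluator. The incumbent best score must be strictly
#' beaten to count as an improvement; after \code{patience} consecutive
#' non-improving rounds the search stops and the incumbent prefix is
#' returned. With \code{patience >= K = ceiling(100/pof)} the search is
#' exhaustive. Consecutive rounds that map to the same prefix size reuse
#' the cached score (the evaluator is assumed deterministic for a given
#' prefix).
#'
#' @param ranked integer vector of feature indices in rank order (best
#'   first), or an \code{mcfs_ranking} (its selected subset is used, or
#'   the full order if nothing was selected).
#' @param evaluator function \code{(feature_indices) -> numeric score}
#'   (higher is better), e.g. a cross-validated classifier.
#' @param pof percent-of-features step size in (0, 100]; default 5.
#' @param patience non-improving rounds tolerated before stopping
#'   (default 5).
#' @return An object of class \code{fbfs_result}: list with
#'   \code{trajectory} (data frame: round, size, score), \code{best_subset}
#'   (feature indices), \code{best_score}, \code{best_size},
#'   \code{rounds_evaluated}, \code{pof}, \code{patience}.
#' @export
forward_best_first <- function(ranked, evaluator, pof = 5, patience = 5) {
  if (inherits(ranked, "mcfs_ranking")) {
    ranked <- if (length(ranked$selected)) ranked$selected else ranked$order
  }
  ranked <- as.integer(ranked)
  n <- length(ranked)
  if (n < 1) stop("ranked feature list is empty")
  if (!(pof > 0 && pof <= 100)) stop("pof must be in (0, 100]")
  if (patience < 1) stop("patience must be >= 1")
  K <- as.integer(ceiling(100 / pof))
  best_score <- -Inf
  best_size <- 0L
  since_improve <- 0L
  rounds <- integer(0); sizes <- integer(0); scores <- numeric(0)
  cache <- new.env(parent = emptyenv())
  for (t in seq_len(K)) {
    size <- min(n, as.integer(ceiling(t * pof / 100 * n)))
    key <- as.character(size)
    sc <- if (!is.null(cache[[key]])) cache[[key]] else {
      v <- evaluator(ranked[seq_len(size)])
      if (!is.finite(v)) stop(sprintf("evaluator failed on prefix size %d", size))
      cache[[key]] <- v
      v
    }
    rounds <- c(rounds, t); sizes <- c(sizes, size); scores <- c(scores, sc)
    if (sc > best_score) {
      best_score <- sc
      best_size <- size
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= patience) break
    }
  }
  structure(list(
    trajectory = data.frame(round = rounds, size = sizes, score = scores),
    best_subset = ranked[seq_len(best_size)],
    best_score = best_score, best_size = best_size,
    rounds_evaluated = length(rounds), pof = pof, patience = patience),
    class = "fbfs_result")
}

#' @export
print.fbfs_result <- function(x, ...) {
  cat(sprintf(
    "fbfs_result: best prefix of %d features, score %.4f (%d rounds, pof %g%%, patience %d)\n",
    x$best_size, x$best_score, x$rounds_evaluated, x$pof, x$patience))
  invisible(x)
}

#' Cross-validated V-ELM evaluator for the forward search
#'
#' Returns the evaluator closure \code{\link{forward_best_first}} expects:
#' for a candidate feature subset it restricts the incomplete matrix to
#' those columns and runs seeded stratified cross-validation of the
#' impute-then-V-ELM pipeline (imputation is re-fit per prefix, on the
#' prefix's columns only, inside each training fold).
#'
#' @param X an \code{incomplete_matrix} with all candidate features.
#' @param y class labels.
#' @param imputer,k,hidden,n_models see \code{\link{velm_pipeline}}.
#' @param folds CV folds (default 10; reduced automatically for small
#'   classes).
#' @param trials CV repeats averaged into the score.
#' @param seed master seed.
#' @param metric score reported to the search (default accuracy).
#' @return function \code{(feature_indices) -> mean CV score}.
#' @export
velm_evaluator <- function(X, y, imputer = "mean", k = 10, hidden = NULL,
                           n_models = 30, folds = 10, trials = 1, seed = 1,
                           metric = "accuracy") {
  stopifnot(inherits(X, "incomplete_matrix"))
  force(y)
  function(feature_idx) {
    Xs <- incomplete_matrix(X$values[, feature_idx, drop = FALSE],
                            X$mask[, feature_idx, drop = FALSE],
                            X$feature_names[feature_idx], X$sample_ids)
    cv <- cross_validate(Xs, y,
                         velm_pipeline(imputer = imputer, k = k,
                                       hidden = hidden, n_models = n_models,
                                       seed = seed),
                         folds = folds, trials = trials, seed = seed,
                         metric = metric)
    cv$mean
  }
}
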