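#' Mean imputation
#'
#' Replaces every missing cell by the observed mean of its feature.
#' Observed cells pass through bit-identically; the operation is
#' idempotent and strictly column-local.
#'
#' @param X an \code{incomplete_matrix} (or numeric matrix with \code{NA}).
#' @param means optional named numeric vector of per-feature means to use
#'   instead of the observed means of \code{X} (e.g. training-fold means
#'   applied to a test fold).
#' @return Numeric matrix with no missing entries; attribute
#'   \code{provenance} records the imputer.
#' @export
mean_impute <- function(X, means = NULL) {
  vals <- if (inherits(X, "incomplete_matrix")) X$values else as.matrix(X)
  if (is.null(means)) {
    n_obs <- colSums(!is.na(vals))
    if (any(n_obs == 0))
      stop("feature(s) with no observed values: ",
           paste(colnames(vals)[n_obs == 0], collapse = ", "))
    means <- colMeans(vals, na.rm = TRUE)
  }
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (any(miss)) vals[miss, j] <- means[j]
  }
  attr(vals, "provenance") <- list(imputer = "mean")
  vals
}

#' K-nearest-neighbour imputation
#'
#' A missing cell (s, f) is filled with the weighted average of feature f
#' over the k nearest donor samples that observe f. Distance between two
#' samples is the root-mean-square difference over their commonly observed
#' features (computed on min-max normalized values so features are
#' commensurate); weights are 1/(d + 1e-8). Samples sharing no observed
#' feature with s are not eligible donors. When no donor exists the cell
#' falls back to the feature's observed mean. When fewer than k donors
#' exist, all of them are used.
#'
#' @param X an \code{incomplete_matrix} (or numeric matrix with \code{NA}).
#' @param k number of neighbours (default 10).
#' @param donors optional \code{incomplete_matrix}/matrix of donor samples
#'   (e.g. the training fold); defaults to \code{X} itself, in which case
#'   a sample is never its own donor.
#' @return Numeric matrix with no missing entries; attribute
#'   \code{provenance} records the imputer and k.
#' @export
knn_impute <- function(X, k = 10, donors = NULL) {
  vals <- if (inherits(X, "incomplete_matrix")) X$values else as.matrix(X)
  self_donor <- is.null(donors)
  dvals <- if (self_donor) vals
           else if (inherits(donors, "incomplete_matrix")) donors$values
           else as.matrix(donors)
  if (k < 1) stop("k must be >= 1")
  n_obs <- colSums(!is.na(dvals))
  if (any(n_obs == 0))
    stop("donor feature(s) with no observed values: ",
         paste(colnames(dvals)[n_obs == 0], collapse = ", "))
  feat_means <- colMeans(dvals, na.rm = TRUE)
  # normalize both grids with donor-side ranges so distances are commensurate
  lo <- apply(dvals, 2, min, na.rm = TRUE)
  hi <- apply(dvals, 2, max, na.rm = TRUE)
  rng <- ifelse(hi > lo, hi - lo, 1)
  norm <- function(v) sweep(sweep(v, 2, lo), 2, rng, "/")
  nx <- norm(vals)
  nd <- norm(dvals)
  out <- vals
  for (s in which(rowSums(is.na(vals)) > 0)) {
    diffs <- sweep(nd, 2, nx[s, ])        # donors x features
    sq <- diffs^2
    shared <- !is.na(sq)
    n_shared <- rowSums(shared)
    sq[!shared] <- 0
    dist <- sqrt(rowSums(sq) / pmax(n_shared, 1))
    dist[n_shared == 0] <- Inf
    if (self_donor) dist[s] <- Inf
    for (f in which(is.na(vals[s, ]))) {
      eligible <- which(!is.na(dvals[, f]) & is.finite(dist))
      if (length(eligible) == 0) {
        out[s, f] <- feat_means[f]
        next
      }
      nn <- eligible[order(dist[eligible])][seq_len(min(k, length(eligible)))]
      w <- 1 / (dist[nn] + 1e-8)
      out[s, f] <- sum(w * dvals[nn, f]) / sum(w)
    }
  }
  attr(out, "provenance") <- list(imputer = "knn", k = k)
  out
}

#' Impute a training and test fold without information leakage
#'
#' Fits imputation statistics on the training fold only: mean imputation
#' applies training-fold means to both folds; KNN imputation draws donors
#' for both folds from the training fold.
#'
#' @param X_train,X_test \code{incomplete_matrix} objects (X_test may be
#'   \code{NULL}).
#' @param method \code{"mean"} or \code{"knn"}.
#' @param k neighbours for KNN.
#' @return list with complete numeric matrices \code{train} and
#'   \code{test}.
#' @export
impute_train_test <- function(X_train, X_test = NULL,
                              method = c("mean", "knn"), k = 10) {
  method <- match.arg(method)
  tr_vals <- if (inherits(X_train, "incomplete_matrix")) X_train$values
             else as.matrix(X_train)
  if (method == "mean") {
    means <- colMeans(tr_vals, na.rm = TRUE)
    train <- mean_impute(tr_vals)
    test <- if (is.null(X_test)) NULL else mean_impute(X_test, means = means)
  } else {
    train <- knn_impute(tr_vals, k = k)
    test <- if (is.null(X_test)) NULL
            else knn_impute(X_test, k = k, donors = tr_vals)
  }
  list(train = train, test = test)
}
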