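#' Specification for a synthetic incomplete expression dataset
#'
#' Describes a class-structured matrix with a known set of informative
#' features: informative features get class-dependent means separated by
#' \code{effect_size} standard deviations between adjacent classes; the
#' remaining features are class-independent standard-normal noise. Cells
#' are then masked missing-completely-at-random (MCAR, uniform) or
#' missing-at-random (MAR, probability rising with a fully observed driver
#' feature), and values are min-max normalized to [-0.9, 0.9].
#'
#' @param n_samples,n_features,n_informative,n_classes dataset dimensions.
#' @param effect_size class-mean separation in within-class SD units
#'   (default 2).
#' @param missing_rate fraction of cells masked, in [0, 1) (default 0.1).
#' @param mechanism \code{"MCAR"} (default) or \code{"MAR"}.
#' @param seed integer seed; the same spec always generates a bit-identical
#'   dataset.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_samples = 60, n_features = 100,
                           n_informative = 5, n_classes = 3,
                           effect_size = 2, missing_rate = 0.1,
                           mechanism = c("MCAR", "MAR"), seed = 1) {
  mechanism <- match.arg(mechanism)
  if (n_informative > n_features)
    stop("n_informative must not exceed n_features")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (n_samples < 2 * n_classes) stop("too few samples for the class count")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (mechanism == "MAR" && n_informative >= n_features)
    stop("MAR needs at least one non-informative feature as driver")
  structure(list(n_samples = n_samples, n_features = n_features,
                 n_informative = n_informative, n_classes = n_classes,
                 effect_size = effect_size, missing_rate = missing_rate,
                 mechanism = mechanism, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic incomplete dataset with known ground truth
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{X} (\code{incomplete_matrix}), \code{y} (factor
#'   of balanced class labels) and \code{informative} (indices of the
#'   class-informative features).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; p <- spec$n_features
  with_seed(spec$seed, {
    y <- factor(rep_len(paste0("c", seq_len(spec$n_classes)), n))
    y <- y[sample(n)]
    vals <- matrix(stats::rnorm(n * p), n, p)
    informative <- sort(sample(p, spec$n_informative))
    for (f in informative) {
      shift <- spec$effect_size * (as.integer(y) - 1)
      vals[, f] <- vals[, f] + shift
    }
    mask <- matrix(TRUE, n, p)
    if (spec$missing_rate > 0) {
      if (spec$mechanism == "MCAR") {
        mask <- matrix(stats::runif(n * p) >= spec$missing_rate, n, p)
      } else {
        driver <- setdiff(seq_len(p), informative)[1]
        z <- as.vector(scale(vals[, driver]))
        p_miss <- stats::plogis(stats::qlogis(spec$missing_rate) + z)
        mask <- matrix(stats::runif(n * p) >= rep(p_miss, p), n, p)
        mask[, driver] <- TRUE
      }
      # every feature keeps at least one observed value
      dead <- which(colSums(mask) == 0)
      for (f in dead) mask[sample(n, 1), f] <- TRUE
    }
  })
  X <- incomplete_matrix(vals, mask,
                         feature_names = paste0("g", seq_len(p)),
                         sample_ids = paste0("s", seq_len(n)))
  X <- minmax_normalize(X)
  list(X = X, y = y, informative = informative)
}
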