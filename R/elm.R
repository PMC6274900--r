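# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Moore-Penrose pseudoinverse via SVD
#'
#' Singular values below \code{tol} times the largest are treated as zero.
#'
#' @param A numeric matrix.
#' @param tol relative cutoff (default 1e-12).
#' @return The pseudoinverse of \code{A}.
#' @export
pseudoinverse <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

one_hot <- function(y, classes = levels(y)) {
  y <- factor(y, levels = classes)
  T <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  T[cbind(seq_along(y), as.integer(y))] <- 1
  T
}

#' Train a single extreme learning machine
#'
#' Single-hidden-layer network with random frozen hidden weights: input
#' weights W (d1 x M_h) and biases b drawn uniformly from [-1, 1] under the
#' given seed, sigmoid activation, and output weights solved in closed form
#' as beta = pinv(H) T where H is the hidden-layer output matrix and T the
#' one-hot class targets. Same seed and data give a bit-identical model.
#'
#' @param X complete numeric matrix (samples x features), all finite.
#' @param y class labels (factor or coercible).
#' @param hidden number of hidden neurons M_h; default
#'   \code{max(5, min(50, ceiling(n/3)))}. A layer as wide as the training
#'   set interpolates it exactly (useful for capacity checks, set
#'   \code{hidden = n}), but generalizes poorly; the default keeps the
#'   random feature map well below interpolation capacity.
#' @param seed integer RNG seed for the hidden layer.
#' @return An object of class \code{elm}.
#' @export
train_elm <- function(X, y, hidden = NULL, seed = 1) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be complete and finite")
  if (!is.factor(y)) y <- factor(y)
  if (is.null(hidden)) hidden <- max(5L, min(50L, as.integer(ceiling(nrow(X) / 3))))
  hidden <- as.integer(hidden)
  if (hidden < 1) stop("hidden must be >= 1")
  d1 <- ncol(X)
  # one (weights, bias) block per neuron: widening the layer with the same
  # seed extends the neuron set instead of redrawing it
  Wb <- with_seed(seed,
                  matrix(stats::runif((d1 + 1) * hidden, -1, 1),
                         d1 + 1, hidden))
  W <- Wb[seq_len(d1), , drop = FALSE]
  b <- Wb[d1 + 1, ]
  H <- sigmoid(X %*% W + matrix(b, nrow(X), hidden, byrow = TRUE))
  T <- one_hot(y)
  beta <- pseudoinverse(H) %*% T
  structure(list(W = W, b = b, beta = beta, classes = levels(y),
                 activation = "sigmoid", hidden = hidden, seed = seed),
            class = "elm")
}

#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object$W))
    stop(sprintf("feature count mismatch: model expects %d, got %d",
                 nrow(object$W), ncol(X)))
  H <- sigmoid(X %*% object$W +
                 matrix(object$b, nrow(X), object$hidden, byrow = TRUE))
  scores <- H %*% object$beta
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Train a majority-voting ELM ensemble
#'
#' Trains \code{n_models} ELMs on identical data with distinct seeds
#' (derived from \code{seed}); prediction is by majority vote with ties
#' broken by summed continuous outputs, then class index. Voting reduces
#' the variance a single random hidden layer induces near class
#' boundaries.
#'
#' @inheritParams train_elm
#' @param n_models ensemble size (default 30).
#' @return An object of class \code{velm}.
#' @export
train_velm <- function(X, y, hidden = NULL, n_models = 30, seed = 1) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (!is.factor(y)) y <- factor(y)
  models <- lapply(seq_len(n_models), function(i)
    train_elm(X, y, hidden = hidden, seed = seed + i))
  structure(list(models = models, classes = levels(y),
                 n_models = n_models, seed = seed),
            class = "velm")
}

#' @export
predict.velm <- function(object, newdata, ...) {
  classes <- object$classes
  n <- nrow(as.matrix(newdata))
  votes <- matrix(0L, n, length(classes))
  score_sum <- matrix(0, n, length(classes))
  for (mod in object$models) {
    sc <- predict(mod, newdata, type = "score")
    pick <- max.col(sc, ties.method = "first")
    votes[cbind(seq_len(n), pick)] <- votes[cbind(seq_len(n), pick)] + 1L
    score_sum <- score_sum + sc
  }
  out <- integer(n)
  for (s in seq_len(n)) {
    top <- which(votes[s, ] == max(votes[s, ]))
    if (length(top) > 1) {
      best <- top[score_sum[s, top] == max(score_sum[s, top])]
      top <- best[1]  # remaining ties: smallest class index
    }
    out[s] <- top[1]
  }
  factor(classes[out], levels = classes)
}
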