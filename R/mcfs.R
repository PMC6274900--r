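#' Build the augmented frequency table of a feature vs. the class
#'
#' Counts co-occurrences of an ordered discretized feature and the class
#' variable in an (m+1) x (l+1) table: rows 0..m-1 are observed feature
#' categories in bin order, the trailing row collects samples whose feature
#' value is missing; columns likewise for the class, with the trailing
#' column for missing labels.
#'
#' @param feature a \code{discretized_feature} or an integer code vector
#'   (0-based, \code{NA} = missing).
#' @param labels factor (its level order is respected) or vector coercible
#'   to factor; \code{NA} = missing label.
#' @return An object of class \code{frequency_table}: integer matrix with
#'   dimnames, last row/column named \code{"?"}.
#' @export
build_frequency_table <- function(feature, labels) {
  codes <- if (inherits(feature, "discretized_feature")) feature$codes
           else as.integer(feature)
  if (!is.factor(labels)) labels <- factor(labels)
  if (length(codes) != length(labels))
    stop("feature and labels must have equal length")
  lev <- levels(labels)
  l <- length(lev)
  if (l < 2)
    stop("need at least 2 observed classes for a supervised operation")
  m <- if (any(!is.na(codes))) max(codes, na.rm = TRUE) + 1L else 0L
  F <- matrix(0L, m + 1L, l + 1L,
              dimnames = list(c(if (m > 0) paste0("bin", seq_len(m) - 1L), "?"),
                              c(lev, "?")))
  ri <- ifelse(is.na(codes), m, codes) + 1L
  ci <- ifelse(is.na(labels), l, as.integer(labels) - 1L) + 1L
  for (s in seq_along(codes)) F[ri[s], ci[s]] <- F[ri[s], ci[s]] + 1L
  structure(F, class = c("frequency_table", "matrix"))
}

#' Redistribute missing-value mass into the observed contingency table
#'
#' Converts the augmented (m+1) x (l+1) frequency table into an m x l
#' contingency table by sharing each missing-cell count among observed
#' cells proportionally to the observed marginals:
#' \deqn{f'_{ij} = f_{ij} + f_{i,?} c_j / N + f_{?,j} r_i / N + f_{?,?} f_{ij} / N}
#' where \eqn{r_i, c_j, N} are row sums, column sums and the grand total of
#' the fully observed block. The grand total of the result equals the total
#' sample count (missing mass is conserved, not discarded), and a table
#' with no missing mass passes through unchanged.
#'
#' @param F a \code{frequency_table}.
#' @return A numeric m x l matrix of class \code{contingency_table}, or a
#'   degenerate marker (attribute \code{degenerate = TRUE}, 0 x 0 matrix)
#'   when no fully observed sample exists.
#' @export
redistribute_missing <- function(F) {
  m <- nrow(F) - 1L
  l <- ncol(F) - 1L
  obs <- F[seq_len(m), seq_len(l), drop = FALSE]
  N <- sum(obs)
  if (m < 1 || N == 0) {
    out <- matrix(numeric(0), 0, 0)
    attr(out, "degenerate") <- TRUE
    class(out) <- c("contingency_table", "matrix")
    return(out)
  }
  rows <- rowSums(obs)
  cols <- colSums(obs)
  f_i_miss <- F[seq_len(m), l + 1L]
  f_miss_j <- F[m + 1L, seq_len(l)]
  f_mm <- F[m + 1L, l + 1L]
  M <- obs +
    outer(f_i_miss, cols) / N +
    outer(rows, f_miss_j) / N +
    f_mm * obs / N
  dimnames(M) <- dimnames(obs)
  attr(M, "degenerate") <- FALSE
  class(M) <- c("contingency_table", "matrix")
  M
}

#' Expected frequencies of a contingency table
#'
#' \eqn{E_{ij} = r_i c_j / N} from the row sums, column sums and grand
#' total of \code{M}. Row and column sums of the result equal those of
#' \code{M} exactly (independence model with matched marginals).
#'
#' @param M numeric contingency table with positive grand total.
#' @return Numeric matrix of expected frequencies, same shape as \code{M}.
#' @export
expected_frequencies <- function(M) {
  N <- sum(M)
  if (N <= 0) stop("contingency table has non-positive grand total")
  outer(rowSums(M), colSums(M)) / N
}

#' Recursive adjacent-row aggregation for small-sample tables
#'
#' The chi-square approximation needs most expected frequencies above 5.
#' While fewer than 80\% of expected frequencies exceed 5 and the table has
#' more than 2 rows, the row holding the globally smallest expected
#' frequency is merged (element-wise sum) with an adjacent row — the
#' neighbour with more expected frequencies below 5; ties go to the
#' neighbour with the smaller total expected mass, then to the upper
#' neighbour. Bin-ordered rows make adjacency meaningful. The grand total
#' is unchanged and at most (rows - 2) merges occur.
#'
#' @param M numeric contingency table (>= 2 rows to do anything).
#' @return The aggregated table, with attribute \code{n_merges}.
#' @export
aggregate_rows <- function(M) {
  M <- unclass(M)
  attr(M, "degenerate") <- NULL
  n_merges <- 0L
  repeat {
    if (nrow(M) <= 2) break
    E <- expected_frequencies(M)
    if (mean(E > 5) >= 0.8) break
    # globally smallest expected frequency, first in row-major order
    ord <- order(as.vector(t(E)))[1]
    i <- ((ord - 1) %/% ncol(E)) + 1
    if (i == 1) {
      j <- 2L
    } else if (i == nrow(M)) {
      j <- nrow(M) - 1L
    } else {
      up <- sum(E[i - 1, ] < 5)
      dn <- sum(E[i + 1, ] < 5)
      if (up > dn) j <- i - 1L
      else if (dn > up) j <- i + 1L
      else if (sum(E[i - 1, ]) < sum(E[i + 1, ])) j <- i - 1L
      else if (sum(E[i + 1, ]) < sum(E[i - 1, ])) j <- i + 1L
      else j <- i - 1L
    }
    keep <- min(i, j)
    M[keep, ] <- M[i, ] + M[j, ]
    M <- M[-max(i, j), , drop = FALSE]
    n_merges <- n_merges + 1L
  }
  out <- M
  attr(out, "n_merges") <- n_merges
  class(out) <- c("contingency_table", "matrix")
  out
}

#' Pearson chi-square statistic and p-value of a contingency table
#'
#' \eqn{\chi^2 = \sum_{ij} (E_{ij} - M_{ij})^2 / E_{ij}} over cells with
#' \eqn{E_{ij} > 0}; degrees of freedom (rows - 1)(cols - 1) using the
#' post-aggregation row count; p-value is the upper tail of the chi-square
#' distribution. Zero-sum rows/columns are dropped first (they carry no
#' information and would produce 0/0). Tables with fewer than 2 rows or
#' columns after dropping are degenerate and score p = 1.
#'
#' @param M numeric contingency table (typically after
#'   \code{\link{aggregate_rows}}).
#' @return list with \code{chi2}, \code{df}, \code{p_value},
#'   \code{degenerate}.
#' @export
chi_square_pvalue <- function(M) {
  M <- unclass(M)
  if (length(M)) {
    M <- M[rowSums(M) > 0, , drop = FALSE]
    M <- M[, colSums(M) > 0, drop = FALSE]
  }
  if (nrow(M) < 2 || ncol(M) < 2)
    return(list(chi2 = 0, df = 0L, p_value = 1, degenerate = TRUE))
  E <- expected_frequencies(M)
  chi2 <- sum((E - M)^2 / E)
  df <- (nrow(M) - 1L) * (ncol(M) - 1L)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Score one feature against the class on incomplete data
#'
#' Full single-feature path: discretize, count the augmented frequency
#' table, redistribute missing mass, drop empty rows/columns, aggregate
#' rows for chi-square validity, compute the statistic and p-value.
#' Degenerate features (constant, all-missing, or no fully observed
#' sample) receive p = 1 rather than an error.
#'
#' @param x numeric feature vector with \code{NA} for missing.
#' @param labels class factor (missing labels allowed).
#' @param n_bins,strategy passed to \code{\link{discretize_feature}};
#'   ignored when \code{x} is already a \code{discretized_feature}.
#' @param aggregate apply \code{\link{aggregate_rows}} (default TRUE).
#' @return list with \code{chi2}, \code{df}, \code{p_value},
#'   \code{degenerate}.
#' @export
mcfs_score_feature <- function(x, labels, n_bins = "auto",
                               strategy = "equal_frequency",
                               aggregate = TRUE) {
  disc <- if (inherits(x, "discretized_feature")) x
          else discretize_feature(x, n_bins, strategy)
  if (disc$degenerate)
    return(list(chi2 = 0, df = 0L, p_value = 1, degenerate = TRUE))
  F <- build_frequency_table(disc, labels)
  M <- redistribute_missing(F)
  if (isTRUE(attr(M, "degenerate")))
    return(list(chi2 = 0, df = 0L, p_value = 1, degenerate = TRUE))
  Mu <- unclass(M)
  Mu <- Mu[rowSums(Mu) > 0, , drop = FALSE]
  Mu <- Mu[, colSums(Mu) > 0, drop = FALSE]
  if (nrow(Mu) < 2 || ncol(Mu) < 2)
    return(list(chi2 = 0, df = 0L, p_value = 1, degenerate = TRUE))
  if (aggregate) Mu <- aggregate_rows(Mu)
  chi_square_pvalue(Mu)
}

#' Rank all features by missing-data chi-square relevance
#'
#' Scores every feature with \code{\link{mcfs_score_feature}} and sorts
#' ascending by p-value (descending relevance). Ties break toward the
#' larger chi-square statistic, then the original feature index, so the
#' ordering is stable and invariant to input column order. Features with
#' p-value below \code{alpha} are marked selected; degenerate features
#' rank last with p = 1.
#'
#' @param X an \code{incomplete_matrix}.
#' @param labels class factor of length \code{nrow(X)}.
#' @param alpha significance level in (0, 1); default 0.001.
#' @param n_bins,strategy discretization settings (see
#'   \code{\link{discretize_feature}}).
#' @param aggregate apply small-sample row aggregation (default TRUE).
#' @return An object of class \code{mcfs_ranking}: list with
#'   \code{scores} (data frame: feature, chi2, df, p_value, degenerate,
#'   rank, selected — in ranked order), \code{order} (feature indices by
#'   rank), \code{selected} (indices with p < alpha, in rank order) and
#'   \code{alpha}.
#' @export
mcfs_rank <- function(X, labels, alpha = 0.001, n_bins = "auto",
                      strategy = "equal_frequency", aggregate = TRUE) {
  stopifnot(inherits(X, "incomplete_matrix"))
  if (!is.factor(labels)) labels <- factor(labels)
  if (length(labels) != nrow(X$values))
    stop("labels length must equal the number of samples")
  if (nlevels(droplevels(labels[!is.na(labels)])) < 2)
    stop("need at least 2 observed classes")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  p <- ncol(X$values)
  res <- vector("list", p)
  for (j in seq_len(p)) {
    res[[j]] <- mcfs_score_feature(X$values[, j], labels,
                                   n_bins = n_bins, strategy = strategy,
                                   aggregate = aggregate)
  }
  chi2 <- vapply(res, `[[`, numeric(1), "chi2")
  df <- vapply(res, function(r) as.integer(r$df), integer(1))
  pval <- vapply(res, `[[`, numeric(1), "p_value")
  degen <- vapply(res, `[[`, logical(1), "degenerate")
  ord <- order(pval, -chi2, seq_len(p))
  scores <- data.frame(
    feature = X$feature_names[ord],
    index = ord,
    chi2 = chi2[ord],
    df = df[ord],
    p_value = pval[ord],
    degenerate = degen[ord],
    rank = seq_len(p),
    selected = pval[ord] < alpha,
    stringsAsFactors = FALSE
  )
  structure(list(scores = scores, order = ord,
                 selected = ord[pval[ord] < alpha], alpha = alpha),
            class = "mcfs_ranking")
}

#' @export
print.mcfs_ranking <- function(x, n = 10, ...) {
  cat(sprintf("mcfs_ranking: %d features, %d selected at alpha = %g\n",
              nrow(x$scores), length(x$selected), x$alpha))
  print(utils::head(x$scores, n))
  invisible(x)
}
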