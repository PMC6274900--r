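#' Construct an incomplete expression matrix
#'
#' Canonical container for a samples x features expression grid with an
#' explicit missingness mask. Missing cells are stored as \code{NA} in
#' \code{values} and as \code{FALSE} in \code{mask}; all downstream
#' statistics ignore unmasked cells.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   \code{NA} entries are treated as missing.
#' @param mask logical matrix of the same shape; \code{TRUE} = observed.
#'   Defaults to \code{!is.na(values)}.
#' @param feature_names character vector of unique feature names; defaults
#'   to column names or \code{f1, f2, ...}.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   row names or \code{s1, s2, ...}.
#' @return An object of class \code{incomplete_matrix} with elements
#'   \code{values}, \code{mask}, \code{feature_names}, \code{sample_ids}.
#' @export
incomplete_matrix <- function(values, mask = !is.na(values),
                              feature_names = colnames(values),
                              sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  mask <- matrix(as.logical(mask), nrow = nrow(values), ncol = ncol(values))
  if (!identical(dim(values), dim(mask)))
    stop("values and mask must have identical shape")
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(values)))
  feature_names <- as.character(feature_names)
  if (anyDuplicated(feature_names))
    stop("feature_names must be unique")
  if (is.null(sample_ids))
    sample_ids <- paste0("s", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  values[!mask] <- NA_real_
  dimnames(values) <- list(sample_ids, feature_names)
  dimnames(mask) <- dimnames(values)
  structure(
    list(values = values, mask = mask,
         feature_names = feature_names, sample_ids = sample_ids),
    class = "incomplete_matrix"
  )
}

#' @export
dim.incomplete_matrix <- function(x) dim(x$values)

#' @export
print.incomplete_matrix <- function(x, ...) {
  n_miss <- sum(!x$mask)
  cat(sprintf("incomplete_matrix: %d samples x %d features, %d missing cells (%.1f%%)\n",
              nrow(x$values), ncol(x$values), n_miss,
              100 * n_miss / length(x$mask)))
  invisible(x)
}

#' @export
t.incomplete_matrix <- function(x) {
  incomplete_matrix(t(x$values), t(x$mask),
                    feature_names = x$sample_ids, sample_ids = x$feature_names)
}

#' Read a delimited expression table with missing-value tokens
#'
#' Parses a TSV/CSV expression table into an \code{incomplete_matrix} plus
#' a label vector. Cells matching a missing token become unmasked; any
#' other cell that fails numeric parsing raises an error naming its
#' row and column. The internal layout is always samples x features;
#' \code{orientation = "features_rows"} files are transposed on read.
#'
#' @param path file path to a delimited text file with a header.
#' @param orientation \code{"samples_rows"} (default) or \code{"features_rows"}.
#' @param missing_tokens character vector of tokens marking missing values.
#' @param label_field name of the column (or row, for \code{features_rows})
#'   holding class labels; set \code{NULL} if the file has no labels.
#' @param sep field separator; guessed from the file extension by default.
#' @return \code{list(X = incomplete_matrix, y = factor or NULL)}. Labels
#'   matching a missing token become \code{NA}.
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_rows", "features_rows"),
                                  missing_tokens = c("?", "NA", ""),
                                  label_field = "class",
                                  sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           row.names = 1, na.strings = NULL,
                           comment.char = "", quote = "\"")
  if (orientation == "features_rows") {
    raw <- as.data.frame(t(as.matrix(raw)), check.names = FALSE,
                         stringsAsFactors = FALSE)
  }
  y <- NULL
  if (!is.null(label_field)) {
    if (!label_field %in% colnames(raw))
      stop(sprintf("label field '%s' not found in table", label_field))
    ylab <- raw[[label_field]]
    ylab[ylab %in% missing_tokens] <- NA_character_
    y <- factor(ylab)
    raw <- raw[, setdiff(colnames(raw), label_field), drop = FALSE]
  }
  vals <- as.matrix(raw)
  miss <- matrix(vals %in% missing_tokens, nrow(vals), ncol(vals))
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- !miss & is.na(num) & !is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("cannot parse cell at row '%s', column '%s': '%s'",
                 rownames(raw)[idx[1]], colnames(raw)[idx[2]],
                 vals[idx[1], idx[2]]))
  }
  num[miss] <- NA_real_
  X <- incomplete_matrix(num, mask = !miss & !is.na(num),
                         feature_names = colnames(raw),
                         sample_ids = rownames(raw))
  list(X = X, y = y)
}

#' Write an incomplete matrix (and labels) back to delimited text
#'
#' Inverse of \code{\link{read_expression_table}} for the samples-rows
#' orientation; missing cells are written as \code{missing_token}.
#'
#' @param X an \code{incomplete_matrix}.
#' @param path output file path.
#' @param y optional label vector (written as a trailing column).
#' @param label_field column name for labels.
#' @param missing_token token written for unobserved cells.
#' @param sep field separator.
#' @export
write_expression_table <- function(X, path, y = NULL, label_field = "class",
                                   missing_token = "?", sep = "\t") {
  vals <- X$values
  out <- matrix(as.character(vals), nrow(vals), ncol(vals))
  out[!X$mask] <- missing_token
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  colnames(df) <- X$feature_names
  if (!is.null(y)) {
    ych <- as.character(y)
    ych[is.na(ych)] <- missing_token
    df[[label_field]] <- ych
  }
  df <- cbind(sample = X$sample_ids, df)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Min-max normalize each feature to [-0.9, 0.9]
#'
#' Applies x' = -0.9 + (x - min) / (max - min) * 1.8 per feature, with min
#' and max taken over observed values only. Constant features map to 0
#' (the range midpoint). The mask is unchanged.
#'
#' @param X an \code{incomplete_matrix}.
#' @return A normalized \code{incomplete_matrix}.
#' @export
minmax_normalize <- function(X) {
  stopifnot(inherits(X, "incomplete_matrix"))
  vals <- X$values
  n_obs <- colSums(X$mask)
  if (any(n_obs == 0))
    stop("feature(s) with no observed values: ",
         paste(X$feature_names[n_obs == 0], collapse = ", "))
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    lo <- min(v, na.rm = TRUE)
    hi <- max(v, na.rm = TRUE)
    if (hi > lo) {
      vals[, j] <- -0.9 + (v - lo) / (hi - lo) * 1.8
    } else {
      vals[X$mask[, j], j] <- 0
    }
  }
  incomplete_matrix(vals, X$mask, X$feature_names, X$sample_ids)
}

#' Default bin count for discretization
#'
#' \code{min(5, floor(sqrt(n_observed)))}, clamped to at least 2: keeps
#' expected cell frequencies large enough that row aggregation rarely
#' degenerates while preserving some resolution.
#'
#' @param n_observed number of observed values in the feature.
#' @return integer bin count.
#' @export
default_bins <- function(n_observed) {
  max(2L, min(5L, as.integer(floor(sqrt(n_observed)))))
}

#' Discretize one feature into ordered bins
#'
#' Bins observed values into at most \code{n_bins} ordered categories
#' (codes 0..m-1). Edges are computed on observed values only; duplicate
#' quantile edges collapse, so the realized category count m may be
#' smaller than \code{n_bins}. Missing entries stay missing. Codes are
#' monotone in the raw value, which makes "adjacent row" merging in the
#' aggregation step meaningful.
#'
#' @param x numeric vector with \code{NA} for missing entries.
#' @param n_bins requested number of bins (>= 2), or \code{"auto"} for
#'   \code{\link{default_bins}}.
#' @param strategy \code{"equal_frequency"} (quantile edges) or
#'   \code{"equal_width"}.
#' @return An object of class \code{discretized_feature}: list with
#'   \code{codes} (0-based integer, \code{NA} = missing), \code{bin_edges}
#'   (interior cut points), \code{m} (realized category count) and
#'   \code{degenerate} (fewer than 2 distinct observed values).
#' @export
discretize_feature <- function(x, n_bins = "auto",
                               strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  x <- as.numeric(x)
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 2) {
    return(structure(list(codes = rep(NA_integer_, length(x)),
                          bin_edges = numeric(0), m = 0L, degenerate = TRUE),
                     class = "discretized_feature"))
  }
  if (identical(n_bins, "auto")) n_bins <- default_bins(length(obs))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("n_bins must be >= 2")
  edges <- switch(strategy,
    equal_frequency = unique(unname(
      stats::quantile(obs, probs = seq_len(n_bins - 1) / n_bins, type = 7))),
    equal_width = {
      e <- seq(min(obs), max(obs), length.out = n_bins + 1)
      unique(e[-c(1, length(e))])
    })
  # bins are (-Inf, e1], (e1, e2], ..., (ek, Inf); code = #edges strictly < x
  raw_codes <- findInterval(x, edges, left.open = TRUE)
  present <- sort(unique(raw_codes[!is.na(raw_codes)]))
  codes <- match(raw_codes, present) - 1L
  m <- length(present)
  structure(list(codes = as.integer(codes), bin_edges = edges,
                 m = m, degenerate = m < 2L),
            class = "discretized_feature")
}
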