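# Independent oracles and fixture builders shared across tests.

# The weather/trip toy table used in the worked examples: 8 samples, three
# ordinal features (1 = low, 2 = medium, 3 = high), binary class, four
# missing cells. Built in code so tests do not depend on installed files.
toy_trip <- function() {
  vals <- rbind(
    c(1, 1, 3),   # u1 yes
    c(2, 2, 2),   # u2 yes
    c(3, 3, NA),  # u3 yes
    c(1, 2, 3),   # u4 no
    c(NA, NA, 3), # u5 no
    c(2, 3, 1),   # u6 yes
    c(NA, 1, 1),  # u7 yes
    c(3, 3, 3)    # u8 no
  )
  colnames(vals) <- c("wind", "humidity", "temperature")
  rownames(vals) <- paste0("u", 1:8)
  list(X = incomplete_matrix(vals),
       y = factor(c("yes", "yes", "yes", "no", "no", "yes", "yes", "no"),
                  levels = c("yes", "no")))
}

# random augmented frequency table: (m+1) x (l+1) integer counts with at
# least one fully observed sample
random_frequency_table <- function(m = sample(2:8, 1), l = sample(2:5, 1),
                                   lambda = 4) {
  repeat {
    F <- matrix(rpois((m + 1) * (l + 1), lambda), m + 1, l + 1)
    if (sum(F[seq_len(m), seq_len(l)]) > 0) break
  }
  class(F) <- c("frequency_table", "matrix")
  F
}

# literal step-by-step simulation of the recursive aggregation loop,
# written independently of the package implementation (explicit while
# loop, scalar expected-frequency computation, same declared tie-breaks)
oracle_aggregate <- function(M) {
  M <- unclass(M)
  merges <- 0L
  expected_tab <- function(A) {
    E <- matrix(0, nrow(A), ncol(A))
    tot <- sum(A)
    for (a in seq_len(nrow(A)))
      for (b in seq_len(ncol(A)))
        E[a, b] <- sum(A[a, ]) * sum(A[, b]) / tot
    E
  }
  while (TRUE) {
    if (nrow(M) <= 2) break
    E <- expected_tab(M)
    ratio <- sum(E > 5) / length(E)
    if (ratio >= 0.8) break
    # smallest expected frequency, scanning row by row
    best <- c(1, 1)
    for (a in seq_len(nrow(E)))
      for (b in seq_len(ncol(E)))
        if (E[a, b] < E[best[1], best[2]]) best <- c(a, b)
    i <- best[1]
    if (i == 1) nb <- 2
    else if (i == nrow(M)) nb <- nrow(M) - 1
    else {
      below5_up <- sum(E[i - 1, ] < 5)
      below5_dn <- sum(E[i + 1, ] < 5)
      nb <- if (below5_up > below5_dn) i - 1
            else if (below5_dn > below5_up) i + 1
            else if (sum(E[i - 1, ]) < sum(E[i + 1, ])) i - 1
            else if (sum(E[i + 1, ]) < sum(E[i - 1, ])) i + 1
            else i - 1
    }
    merged <- M[i, ] + M[nb, ]
    M[min(i, nb), ] <- merged
    M <- M[-max(i, nb), , drop = FALSE]
    merges <- merges + 1L
  }
  list(table = M, merges = merges)
}

# two well-separated Gaussian blobs for classifier sanity checks
make_blobs <- function(n = 40, sep = 6, d = 2, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  X <- rbind(matrix(rnorm(half * d), half, d),
             matrix(rnorm((n - half) * d, mean = sep), n - half, d))
  y <- factor(rep(c("a", "b"), c(half, n - half)))
  idx <- sample(n)
  list(X = X[idx, , drop = FALSE], y = y[idx])
}

# trapezoidal area under the empirical ROC curve (independent AUC oracle)
trapezoid_auc <- function(truth, scores, positive) {
  pos <- as.character(truth) == positive
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
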