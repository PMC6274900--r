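test_that("frequency table counts the toy trip features correctly", {
  toy <- toy_trip()
  # wind: ordinal codes 0/1/2 with NA missing
  F1 <- build_frequency_table(as.integer(toy$X$values[, "wind"]) - 1L, toy$y)
  expect_equal(unname(unclass(F1)),
               rbind(c(1, 1, 0), c(2, 0, 0), c(1, 1, 0), c(1, 1, 0)))
  # humidity: hand count over the 8 records
  F2 <- build_frequency_table(as.integer(toy$X$values[, "humidity"]) - 1L,
                              toy$y)
  expect_equal(unname(unclass(F2)),
               rbind(c(2, 0, 0), c(1, 1, 0), c(2, 1, 0), c(0, 1, 0)))
  # fully observed feature: trailing row and column all zero
  F3 <- build_frequency_table(c(0L, 1L, 0L, 1L), factor(c("a", "b", "a", "b")))
  expect_true(all(F3[nrow(F3), ] == 0) && all(F3[, ncol(F3)] == 0))
  expect_error(build_frequency_table(c(0L, 1L), factor(c("a", "a"))),
               "2 observed classes")
})

test_that("missing-mass redistribution reproduces the worked example", {
  toy <- toy_trip()
  F <- build_frequency_table(as.integer(toy$X$values[, "wind"]) - 1L, toy$y)
  obs <- F[1:3, 1:2]
  expect_equal(unname(rowSums(obs)), c(2, 2, 2))
  expect_equal(unname(colSums(obs)), c(4, 2))
  expect_equal(sum(obs), 6)
  M <- redistribute_missing(F)
  expect_equal(unname(unclass(M)),
               rbind(c(4, 4), c(7, 1), c(4, 4)) / 3, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(M), 8)  # all 8 samples' mass conserved

  # humidity: hand evaluation with N = 7, r_low = 2, f_{?,no} = 1
  F2 <- build_frequency_table(as.integer(toy$X$values[, "humidity"]) - 1L,
                              toy$y)
  M2 <- redistribute_missing(F2)
  expect_equal(M2[1, 2], 2 / 7, tolerance = 1e-12)
})

test_that("tables without missing mass pass through redistribution unchanged", {
  F <- rbind(c(3, 1, 0), c(0, 4, 0), c(0, 0, 0))
  class(F) <- c("frequency_table", "matrix")
  M <- redistribute_missing(F)
  expect_equal(unname(unclass(M)), rbind(c(3, 1), c(0, 4)),
               ignore_attr = TRUE)
})

test_that("redistribution conserves total sample mass on random tables", {
  set.seed(11)
  for (rep in 1:200) {
    F <- random_frequency_table()
    M <- redistribute_missing(F)
    expect_equal(sum(M), sum(F), tolerance = 1e-9)
    expect_true(all(M >= 0))
  }
})

test_that("no fully observed sample makes a feature unscorable, not a crash", {
  F <- rbind(c(0, 0, 2), c(0, 0, 1), c(3, 1, 0))
  class(F) <- c("frequency_table", "matrix")
  M <- redistribute_missing(F)
  expect_true(attr(M, "degenerate"))
  sc <- mcfs_score_feature(c(NA, NA, NA, 1), factor(c("a", "b", "a", NA)))
  expect_true(sc$degenerate)
  expect_equal(sc$p_value, 1)
})

test_that("expected frequencies follow the marginal product rule", {
  expect_equal(expected_frequencies(rbind(c(1, 1), c(1, 1))),
               rbind(c(1, 1), c(1, 1)))
  # worked-example table: r = 8/3 each, c = (5, 3), N = 8
  M <- rbind(c(4, 4), c(7, 1), c(4, 4)) / 3
  E <- expected_frequencies(M)
  expect_equal(E[1, 1], (8 / 3) * 5 / 8, tolerance = 1e-12)
  expect_equal(rowSums(E), rowSums(M), tolerance = 1e-9)
  expect_equal(colSums(E), colSums(M), tolerance = 1e-9)
  expect_equal(sum(E), sum(M), tolerance = 1e-9)
})

test_that("aggregation guards: large tables untouched, 2-row tables pass through", {
  big <- rbind(c(20, 30), c(25, 15), c(30, 40))
  expect_equal(unname(unclass(aggregate_rows(big))), big, ignore_attr = TRUE)
  tiny <- rbind(c(1, 0), c(0, 1))
  out <- aggregate_rows(tiny)
  expect_equal(unname(unclass(out)), tiny, ignore_attr = TRUE)
  expect_equal(attr(out, "n_merges"), 0L)
})

test_that("aggregation merges the sparse rows of the 4x2 example", {
  M <- rbind(c(1, 1), c(1, 1), c(20, 20), c(20, 20))
  out <- aggregate_rows(M)
  # hand simulation: row 1 merges into row 2, then the merged row into row 3
  expect_equal(unname(unclass(out)), rbind(c(22, 22), c(20, 20)),
               ignore_attr = TRUE)
  expect_equal(attr(out, "n_merges"), 2L)
  expect_equal(sum(out), sum(M))
})

test_that("aggregation matches the literal loop simulation on random tables", {
  set.seed(23)
  for (rep in 1:60) {
    m <- sample(3:7, 1); l <- sample(2:4, 1)
    M <- matrix(rexp(m * l, rate = 1 / sample(c(1, 3, 8), 1)), m, l)
    M <- M[rowSums(M) > 0, , drop = FALSE]
    if (nrow(M) < 2) next
    got <- aggregate_rows(M)
    want <- oracle_aggregate(M)
    expect_equal(unname(unclass(got)), unname(want$table),
                 ignore_attr = TRUE)
    expect_equal(attr(got, "n_merges"), want$merges)
    expect_lte(want$merges, nrow(M) - 2)
    expect_equal(sum(got), sum(M), tolerance = 1e-9)
  }
})

test_that("chi-square statistic matches hand values and textbook oracle", {
  # proportional rows = independence
  ind <- chi_square_pvalue(rbind(c(2, 4), c(3, 6)))
  expect_equal(ind$chi2, 0, tolerance = 1e-12)
  expect_equal(ind$p_value, 1)
  # perfectly dependent 2x2
  dep <- chi_square_pvalue(rbind(c(10, 0), c(0, 10)))
  expect_equal(dep$chi2, 20, tolerance = 1e-12)
  expect_equal(dep$df, 1L)
  # homogeneity of degree 1: doubling counts doubles the statistic
  M <- rbind(c(8, 2), c(3, 7))
  expect_equal(chi_square_pvalue(2 * M)$chi2, 2 * chi_square_pvalue(M)$chi2,
               tolerance = 1e-12)
  # independent textbook implementation agrees on complete data
  set.seed(31)
  for (rep in 1:50) {
    T <- matrix(rpois(6, 20) + 6, 3, 2)
    ours <- chi_square_pvalue(T)
    ref <- suppressWarnings(chisq.test(T, correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$df, unname(as.integer(ref$parameter)))
  }
})

test_that("scored p-values stay in [0,1] and decrease in chi2 at fixed df", {
  # tables with growing dependence at fixed shape: p must fall as chi2 rises
  ps <- chis <- numeric(0)
  for (shift in 0:8) {
    M <- rbind(c(10 + shift, 10 - shift), c(10 - shift, 10 + shift))
    out <- chi_square_pvalue(M)
    chis <- c(chis, out$chi2); ps <- c(ps, out$p_value)
  }
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(diff(chis) > 0))
  expect_true(all(diff(ps) < 0))
  # zero-sum columns are dropped with the df reduced accordingly
  M <- rbind(c(5, 0, 9), c(7, 0, 2))
  out <- chi_square_pvalue(M)
  expect_equal(out$df, 1L)
  expect_false(out$degenerate)
})

test_that("ranking orders by p-value and is invariant to column order", {
  d <- generate_dataset(synthetic_spec(n_samples = 60, n_features = 30,
                                       n_informative = 3, effect_size = 2,
                                       missing_rate = 0.1, seed = 3))
  r <- mcfs_rank(d$X, d$y, alpha = 0.05)
  expect_equal(r$scores$p_value, sort(r$scores$p_value))
  expect_true(all(r$scores$p_value[r$scores$selected] < 0.05))
  expect_setequal(r$selected, r$order[seq_along(r$selected)])

  # permute the columns: the ranked feature names must be identical
  perm <- sample(ncol(d$X$values))
  Xp <- incomplete_matrix(d$X$values[, perm], d$X$mask[, perm],
                          d$X$feature_names[perm], d$X$sample_ids)
  rp <- mcfs_rank(Xp, d$y, alpha = 0.05)
  expect_equal(rp$scores$feature, r$scores$feature)
  expect_equal(rp$scores$p_value, r$scores$p_value)
})

test_that("degenerate features rank last with p-value one", {
  set.seed(5)
  vals <- cbind(informative = rep(c(0, 3), each = 10) + rnorm(20, sd = 0.1),
                flat = rep(1, 20),
                noise = rnorm(20))
  X <- incomplete_matrix(vals)
  y <- factor(rep(c("a", "b"), each = 10))
  r <- mcfs_rank(X, y, alpha = 0.01)
  expect_equal(r$scores$feature[1], "informative")
  flat_row <- r$scores[r$scores$feature == "flat", ]
  expect_true(flat_row$degenerate)
  expect_equal(flat_row$p_value, 1)
  expect_gte(flat_row$rank, 2)
})

test_that("selections nest as alpha shrinks", {
  d <- generate_dataset(synthetic_spec(n_samples = 80, n_features = 60,
                                       n_informative = 6, effect_size = 1.5,
                                       missing_rate = 0.1, seed = 17))
  alphas <- c(0.01, 0.005, 0.001, 0.0005, 0.0001)
  sels <- lapply(alphas, function(a) mcfs_rank(d$X, d$y, alpha = a)$selected)
  sizes <- lengths(sels)
  expect_true(all(diff(sizes) <= 0))
  for (i in seq_len(length(sels) - 1))
    expect_true(all(sels[[i + 1]] %in% sels[[i]]))
})
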