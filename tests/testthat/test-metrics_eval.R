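test_that("confusion metrics match hand arithmetic in both conventions", {
  perfect <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_true(all(perfect == 1))
  perfect_p <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0),
                               mode = "as_printed")
  expect_true(all(perfect_p == 1))

  # no positives predicted or present: precision undefined, accuracy 1
  degen <- compute_metrics(list(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(degen["accuracy"]), 1)
  expect_true(is.na(degen["precision"]))
  expect_true(is.na(degen["recall"]))

  m <- compute_metrics(list(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["recall"]), 3 / 5)
  expect_equal(unname(m["specificity"]), 4 / 5)
  expect_equal(unname(m["precision"]), 3 / 4)
  expect_equal(unname(m["balanced_accuracy"]), (3 / 5 + 4 / 5) / 2)
  expect_equal(unname(m["f1"]), 2 * 0.6 * 0.75 / (0.6 + 0.75))
  expect_equal(unname(m["g_mean"]), sqrt(0.6 * 0.8))
  mp <- compute_metrics(list(TP = 3, TN = 4, FP = 1, FN = 2),
                        mode = "as_printed")
  expect_equal(unname(mp["balanced_accuracy"]), (3 / 4 + 3 / 5) / 2)
  # only the balanced-accuracy convention changes between modes
  expect_equal(m[names(m) != "balanced_accuracy"],
               mp[names(mp) != "balanced_accuracy"])
})

test_that("rank-statistic AUC equals the trapezoidal ROC integral", {
  set.seed(19)
  for (rep in 1:100) {
    n <- sample(6:30, 1)
    truth <- factor(sample(c("pos", "neg"), n, replace = TRUE))
    if (length(unique(truth)) < 2) next
    scores <- rnorm(n)
    expect_equal(auc_score(truth, scores, "pos"),
                 trapezoid_auc(truth, scores, "pos"), tolerance = 1e-12)
  }
  # perfect separation
  truth <- factor(rep(c("pos", "neg"), each = 5))
  expect_equal(auc_score(truth, c(6:10, 1:5), "pos"), 1)
  # single-class input is undefined, not an error
  expect_true(is.na(auc_score(factor(rep("pos", 4)), rnorm(4), "pos")))
})

test_that("one-vs-rest macro averages sit between the per-class extremes", {
  truth <- factor(c("a", "a", "a", "b", "b", "b", "c", "c", "c"))
  pred <- factor(c("a", "a", "b", "b", "b", "c", "c", "c", "a"),
                  levels = levels(truth))
  ovr <- one_vs_rest(truth, pred)
  # hand-enumerated per-class confusion over the 9 decisions
  expect_equal(ovr$per_class$accuracy, rep(7 / 9, 3), tolerance = 1e-12)
  expect_equal(ovr$per_class$recall, rep(2 / 3, 3), tolerance = 1e-12)
  expect_equal(ovr$per_class$specificity, rep(5 / 6, 3), tolerance = 1e-12)
  for (col in c("accuracy", "recall", "balanced_accuracy")) {
    expect_gte(ovr$macro[[col]], min(ovr$per_class[[col]]))
    expect_lte(ovr$macro[[col]], max(ovr$per_class[[col]]))
  }
  # two classes: the macro equals the symmetric average of both reports
  t2 <- factor(c("x", "x", "y", "y", "y"))
  p2 <- factor(c("x", "y", "y", "y", "x"), levels = c("x", "y"))
  ovr2 <- one_vs_rest(t2, p2)
  expect_equal(unname(ovr2$macro["recall"]),
               mean(ovr2$per_class$recall))
  expect_equal(ovr2$per_class$accuracy[1], ovr2$per_class$accuracy[2])
})

test_that("stratified cross-validation partitions samples and is seeded", {
  d <- generate_dataset(synthetic_spec(n_samples = 40, n_features = 5,
                                       n_classes = 2, missing_rate = 0,
                                       seed = 9))
  seen <- integer(0)
  pipeline <- function(X_tr, y_tr, X_te) {
    seen <<- c(seen, match(X_te$sample_ids, d$X$sample_ids))
    factor(rep(levels(y_tr)[1], nrow(X_te$values)), levels = levels(y_tr))
  }
  cv1 <- cross_validate(d$X, d$y, pipeline, folds = 5, seed = 3)
  expect_equal(sort(seen), 1:40)  # each sample tested exactly once
  # constant prediction scores the majority-class frequency
  expect_equal(cv1$mean, max(table(d$y)) / 40)
  # determinism: identical seed, identical folds and scores
  seen_first <- seen
  seen2 <- integer(0)
  pipeline2 <- function(X_tr, y_tr, X_te) {
    seen2 <<- c(seen2, match(X_te$sample_ids, d$X$sample_ids))
    factor(rep(levels(y_tr)[1], nrow(X_te$values)), levels = levels(y_tr))
  }
  cv2 <- cross_validate(d$X, d$y, pipeline2, folds = 5, seed = 3)
  expect_identical(seen_first, seen2)
  expect_identical(cv1$scores, cv2$scores)
})

test_that("folds shrink for small classes and missing labels are excluded", {
  set.seed(2)
  X <- incomplete_matrix(matrix(rnorm(30), 15, 2))
  y <- factor(c(rep("a", 10), rep("b", 4), NA))
  counted <- 0L
  pipeline <- function(X_tr, y_tr, X_te) {
    counted <<- counted + nrow(X_te$values)
    factor(rep("a", nrow(X_te$values)), levels = levels(y_tr))
  }
  expect_message(
    cv <- cross_validate(X, y, pipeline, folds = 10, seed = 1),
    "reduced to 4 folds")
  expect_equal(cv$folds, 4L)
  expect_equal(counted, 14L)  # the NA-labelled sample is never evaluated
})

test_that("the velm pipeline classifies separable incomplete data in CV", {
  d <- generate_dataset(synthetic_spec(n_samples = 40, n_features = 6,
                                       n_informative = 4, n_classes = 2,
                                       effect_size = 3, missing_rate = 0.1,
                                       seed = 14))
  cv <- cross_validate(d$X, d$y,
                       velm_pipeline(imputer = "mean", n_models = 10, seed = 5),
                       folds = 5, trials = 2, seed = 7)
  expect_gte(cv$mean, 0.9)
  expect_equal(length(cv$scores), 2L)
})
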