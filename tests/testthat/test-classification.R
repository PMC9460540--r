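test_that("nested splits respect the 80/20 fractions and stratification", {
  y <- rep(c(0L, 1L), each = 46L)
  sp <- make_splits(y, seed = 1)
  expect_equal(length(sp$test), 18L)
  expect_equal(length(sp$train), 74L)
  expect_equal(unname(table(y[sp$test])), c(9L, 9L), ignore_attr = TRUE)
  expect_equal(unname(table(y[sp$train])), c(37L, 37L), ignore_attr = TRUE)
  expect_setequal(c(sp$train2, sp$cv), sp$train)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train2, sp$cv), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  # reproducible from the seed, different across seeds
  expect_identical(sp, make_splits(y, seed = 1))
  expect_false(identical(sp$test, make_splits(y, seed = 2)$test))
  expect_error(make_splits(rep(c(0, 1), c(3, 40)), seed = 1), "at least 5")
})

test_that("metrics follow their confusion-matrix definitions", {
  m <- evaluate_metrics(truth = c(rep(1, 5), rep(0, 5)),
                        predicted = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(m$tp, 3)
  expect_equal(m$fp, 1)
  expect_equal(m$tn, 4)
  expect_equal(m$fn, 2)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  perfect <- evaluate_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  allpos <- evaluate_metrics(c(0, 1, 0, 1), c(1, 1, 1, 1))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  # single-class truth: the undefined metric is NA, not NaN-propagated
  onecls <- evaluate_metrics(c(1, 1, 1), c(1, 0, 1))
  expect_true(is.na(onecls$specificity))
  expect_equal(onecls$sensitivity, 2 / 3)
})

test_that("family selection uses CV accuracy with SVM-first tie-breaking", {
  d <- separable_scores()
  sp <- make_splits(d$y, seed = 3)
  sel <- select_family(d$x[sp$train2, ], d$y[sp$train2],
                       d$x[sp$cv, ], d$y[sp$cv])
  expect_equal(sel$accuracies$family, c("SVM", "kNN", "NN"))
  expect_true(all(sel$accuracies$cv_accuracy == 1))
  expect_equal(sel$family, "SVM") # tie broken by fixed order
  tune <- tune_family("NN", d$x[sp$train2, ], d$y[sp$train2],
                      d$x[sp$cv, ], d$y[sp$cv])
  expect_equal(tune$parameter, 1L) # smallest tying hidden size
  expect_equal(nrow(tune$accuracies), 10L)
})

test_that("kNN with euclidean distance and k = 1 matches class::knn", {
  d <- separable_scores(gap = 1.5, seed = 21)
  sp <- make_splits(d$y, seed = 4)
  model <- lfptarget:::fit_family("kNN", "euclidean", d$x[sp$train, ],
                                  d$y[sp$train])
  ours <- predict(model, d$x[sp$test, ])
  ref <- as.integer(as.character(class::knn(
    as.matrix(d$x[sp$train, ]), as.matrix(d$x[sp$test, ]),
    factor(d$y[sp$train]), k = 1)))
  expect_equal(ours, ref)
})

test_that("all four kNN distance metrics are computed and can disagree", {
  d <- separable_scores(gap = 1, seed = 33)
  # stretch one feature so seuclidean and euclidean differ
  d$x[[2]] <- d$x[[2]] * 50
  sp <- make_splits(d$y, seed = 5)
  tune <- tune_family("kNN", d$x[sp$train2, ], d$y[sp$train2],
                      d$x[sp$cv, ], d$y[sp$cv])
  expect_equal(tune$accuracies$parameter,
               c("seuclidean", "euclidean", "correlation", "spearman"))
  expect_true(all(is.finite(tune$accuracies$cv_accuracy)))
  dse <- lfptarget:::knn_distance(d$x[sp$train, ], d$x[sp$test, ], "seuclidean")
  deu <- lfptarget:::knn_distance(d$x[sp$train, ], d$x[sp$test, ], "euclidean")
  expect_false(isTRUE(all.equal(dse, deu)))
})

test_that("the outer test set cannot influence model choice", {
  d <- separable_scores(gap = 2, seed = 13)
  sp <- make_splits(d$y, seed = 7)
  choose <- function(x) {
    sel <- select_family(x[sp$train2, ], d$y[sp$train2], x[sp$cv, ], d$y[sp$cv])
    tune <- tune_family(sel$family, x[sp$train2, ], d$y[sp$train2],
                        x[sp$cv, ], d$y[sp$cv])
    list(sel$family, tune$parameter)
  }
  corrupted <- d$x
  corrupted[sp$test, ] <- corrupted[sp$test, ] * 1e3 + 57
  expect_identical(choose(d$x), choose(corrupted))
})

test_that("final evaluation refits on the outer training set", {
  d <- separable_scores(gap = 6, seed = 17)
  sp <- make_splits(d$y, seed = 8)
  fin <- final_fit_evaluate("SVM", "linear", d$x[sp$train, ], d$y[sp$train],
                            d$x[sp$test, ], d$y[sp$test])
  expect_s3_class(fin$model, "lfp_classifier")
  expect_equal(fin$metrics$accuracy, 1)
  expect_equal(fin$metrics$tp + fin$metrics$tn + fin$metrics$fp +
                 fin$metrics$fn, length(sp$test))
})
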