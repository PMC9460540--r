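#' Nested train/validation/test split
#'
#' Realizes the nested splitting scheme used for model selection: the data
#' are split 80/20 into an outer training and test set, and the outer
#' training set is split again 80/20 into "training set 2" and a
#' cross-validation (CV) set. Splits are stratified by class by default
#' (each class contributes its own 20% rounded down) and reproducible from
#' the seed. The outer test set is untouched until final evaluation.
#'
#' @param classes Vector of 0/1 class labels, one per row.
#' @param seed Integer seed.
#' @param test_frac,cv_frac Held-out fractions of the outer and inner
#'   splits.
#' @param stratified Stratify by class?
#' @return A list of integer row-index vectors: `train`, `test`, `train2`,
#'   `cv` (with `train = union(train2, cv)`).
#' @export
make_splits <- function(classes, seed, test_frac = 0.2, cv_frac = 0.2,
                        stratified = TRUE) {
  n <- length(classes)
  if (stratified && any(table(classes) < 5L)) {
    stop("each class needs at least 5 rows to stratify the nested split")
  }
  holdout <- function(idx, frac) {
    m <- floor(length(idx) * frac)
    shuffled <- sample(idx)
    list(out = sort(shuffled[seq_len(m)]),
         rest = sort(shuffled[-seq_len(m)]))
  }
  split_once <- function(idx, frac) {
    if (stratified) {
      parts <- lapply(split(idx, classes[idx]), holdout, frac = frac)
      list(out = sort(unlist(lapply(parts, `[[`, "out"), use.names = FALSE)),
           rest = sort(unlist(lapply(parts, `[[`, "rest"), use.names = FALSE)))
    } else {
      holdout(idx, frac)
    }
  }
  with_seed_(seed, {
    outer <- split_once(seq_len(n), test_frac)
    inner <- split_once(outer$rest, cv_frac)
    list(train = outer$rest, test = outer$out,
         train2 = inner$rest, cv = inner$out)
  })
}

#' Classifier families and parameter grids
#'
#' The three candidate families with their varying parameter grids and the
#' standard value used during family selection: SVM kernels (standard rbf;
#' polynomial degree fixed at 3), kNN distance metrics (standard
#' seuclidean, i.e. standardized Euclidean), and single-hidden-layer neural
#' network sizes 1-10 (standard 5).
#'
#' @return Named list with `grid` and `standard` per family.
#' @export
model_grids <- function() {
  list(
    SVM = list(grid = c("linear", "rbf", "polynomial"), standard = "rbf"),
    kNN = list(grid = c("seuclidean", "euclidean", "correlation", "spearman"),
               standard = "seuclidean"),
    NN  = list(grid = 1:10, standard = 5L)
  )
}

# ---- kNN with the four distance metrics -------------------------------------

knn_distance <- function(train_x, test_x, metric, seuclid_scale = NULL) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  switch(metric,
    euclidean = ,
    seuclidean = {
      w <- if (metric == "seuclidean") {
        s <- if (is.null(seuclid_scale)) apply(train_x, 2, stats::sd)
             else seuclid_scale
        s[s == 0] <- 1
        1 / s^2
      } else rep(1, ncol(train_x))
      d2 <- outer(rowSums(sweep(test_x^2, 2, w, "*")),
                  rowSums(sweep(train_x^2, 2, w, "*")), "+") -
        2 * (sweep(test_x, 2, w, "*") %*% t(train_x))
      sqrt(pmax(d2, 0))
    },
    correlation = {
      r <- suppressWarnings(stats::cor(t(test_x), t(train_x)))
      r[is.na(r)] <- 0
      1 - r
    },
    spearman = {
      r <- suppressWarnings(stats::cor(t(test_x), t(train_x),
                                       method = "spearman"))
      r[is.na(r)] <- 0
      1 - r
    },
    stop("unknown kNN distance metric: ", metric)
  )
}

knn_predict <- function(train_x, train_y, test_x, metric, k = 1L) {
  d <- knn_distance(train_x, test_x, metric)
  apply(d, 1L, function(row) {
    nb <- train_y[order(row)[seq_len(k)]]
    as.integer(names(which.max(table(nb))))
  })
}

# ---- family fitting ---------------------------------------------------------

fit_family <- function(family, param, x, y, init_seed = 1L, knn_k = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  fit <- switch(family,
    SVM = {
      kernel <- c(linear = "linear", rbf = "radial",
                  polynomial = "polynomial")[[param]]
      e1071::svm(x = x, y = factor(y, levels = c(0, 1)), kernel = kernel,
                 degree = 3)
    },
    kNN = list(train_x = x, train_y = y, metric = param, k = knn_k),
    NN = {
      df <- data.frame(x)
      df$.cls <- factor(y, levels = c(0, 1))
      with_seed_(init_seed,
        nnet::nnet(.cls ~ ., data = df, size = as.integer(param),
                   trace = FALSE, maxit = 200))
    },
    stop("unknown classifier family: ", family)
  )
  structure(list(family = family, param = param, fit = fit,
                 init_seed = init_seed),
            class = "lfp_classifier")
}

#' @export
predict.lfp_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  switch(object$family,
    SVM = as.integer(as.character(stats::predict(object$fit, x))),
    kNN = knn_predict(object$fit$train_x, object$fit$train_y, x,
                      object$fit$metric, object$fit$k),
    NN = {
      p <- stats::predict(object$fit, data.frame(x), type = "class")
      as.integer(p)
    }
  )
}

#' Binary classification metrics
#'
#' Confusion counts and the derived accuracy (correct / total),
#' sensitivity (TP / (TP + FN), effectiveness on in-target samples) and
#' specificity (TN / (TN + FP), effectiveness on off-target samples). A
#' metric whose denominator is zero (single-class truth) is reported as
#' `NA`.
#'
#' @param truth,predicted Integer 0/1 vectors.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  fn <- sum(truth == 1 & predicted == 0)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

cv_accuracy <- function(model, cv_x, cv_y) {
  mean(predict(model, cv_x) == cv_y)
}

#' Select the best classifier family at standard parameters
#'
#' Trains the three families with their standard parameters on training set
#' 2 and compares accuracies on the CV set. Ties are broken by the fixed
#' order SVM, kNN, NN. A family whose training fails is excluded with a
#' warning.
#'
#' @param train2_x,train2_y Training set 2 (component scores and labels).
#' @param cv_x,cv_y CV set.
#' @param init_seed Seed for neural-network weight initialization.
#' @return A list with `family` (the winner) and `accuracies` (a tibble of
#'   per-family CV accuracy).
#' @export
select_family <- function(train2_x, train2_y, cv_x, cv_y, init_seed = 1L) {
  grids <- model_grids()
  acc <- purrr::map_dbl(names(grids), function(fam) {
    tryCatch({
      m <- fit_family(fam, grids[[fam]]$standard, train2_x, train2_y,
                      init_seed)
      cv_accuracy(m, cv_x, cv_y)
    }, error = function(e) {
      warning("family ", fam, " failed to train: ", conditionMessage(e))
      -Inf
    })
  })
  tbl <- tibble::tibble(family = names(grids),
                        standard = vapply(grids, function(g)
                          as.character(g$standard), character(1)),
                        cv_accuracy = acc)
  if (all(!is.finite(acc))) stop("no classifier family could be trained")
  list(family = names(grids)[which.max(acc)], accuracies = tbl)
}

#' Sweep the selected family's parameter grid
#'
#' Retrains the selected family on training set 2 for every value of its
#' parameter grid and evaluates each on the CV set; returns the grid value
#' with the highest CV accuracy (first in grid order on ties).
#'
#' @param family `"SVM"`, `"kNN"` or `"NN"`.
#' @inheritParams select_family
#' @return A list with `parameter` (best grid value) and `accuracies` (a
#'   tibble of per-value CV accuracy).
#' @export
tune_family <- function(family, train2_x, train2_y, cv_x, cv_y,
                        init_seed = 1L) {
  grid <- model_grids()[[family]]$grid
  acc <- purrr::map_dbl(grid, function(p) {
    tryCatch(cv_accuracy(fit_family(family, p, train2_x, train2_y, init_seed),
                         cv_x, cv_y),
             error = function(e) -Inf)
  })
  list(parameter = grid[[which.max(acc)]],
       accuracies = tibble::tibble(parameter = as.character(grid),
                                   cv_accuracy = acc))
}

#' Final fit and held-out evaluation
#'
#' Refits the chosen family/parameter on the full outer training set and
#' computes metrics on the untouched outer test set.
#'
#' @param family,parameter Chosen family and grid value.
#' @param train_x,train_y Outer training set.
#' @param test_x,test_y Outer test set.
#' @param init_seed Seed for neural-network initialization.
#' @return A list with `model` (an `lfp_classifier`) and `metrics` (see
#'   [evaluate_metrics()]).
#' @export
final_fit_evaluate <- function(family, parameter, train_x, train_y,
                               test_x, test_y, init_seed = 1L) {
  model <- fit_family(family, parameter, train_x, train_y, init_seed)
  list(model = model,
       metrics = evaluate_metrics(test_y, predict(model, test_x)))
}
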