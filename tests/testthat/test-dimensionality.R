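# two-class toy table over the 17 canonical features
toy_features <- function(n0 = 20, n1 = 20, seed = 5, shift = NULL) {
  withr::with_seed(seed, {
    X <- matrix(rnorm((n0 + n1) * 17), ncol = 17,
                dimnames = list(NULL, feature_names()))
    if (!is.null(shift)) {
      X[(n0 + 1):(n0 + n1), names(shift)] <-
        sweep(X[(n0 + 1):(n0 + n1), names(shift), drop = FALSE], 2, shift, "+")
    }
    out <- tibble::as_tibble(as.data.frame(X))
    out$class <- rep(c(0L, 1L), c(n0, n1))
    out
  })
}

test_that("the ranking criterion matches the pooled-variance t formula", {
  # sample mean 0/1, sample sd exactly 1 in both classes, n = 4 each
  base <- c(-3, -1, 1, 3) / sqrt(20 / 3)
  df <- toy_features(4, 4)
  df$bpg <- c(base, base + 1)
  r <- rank_features(df)
  expect_equal(r$criterion[r$feature == "bpg"], 1 / sqrt(1 / 4 + 1 / 4),
               tolerance = 1e-10)
  # doubling the separation doubles the criterion
  df2 <- df
  df2$bpg <- c(base, base + 2)
  r2 <- rank_features(df2)
  expect_equal(r2$criterion[r2$feature == "bpg"],
               2 * r$criterion[r$feature == "bpg"], tolerance = 1e-10)
})

test_that("the ranking criterion equals |t| from a pooled-variance t-test", {
  df <- toy_features(15, 12, seed = 8, shift = c(bpg = 2, plv = 0.5))
  r <- rank_features(df)
  for (f in c("bpg", "plv", "var", "md")) {
    tt <- stats::t.test(df[[f]][df$class == 1], df[[f]][df$class == 0],
                        var.equal = TRUE)
    expect_equal(r$criterion[r$feature == f], abs(unname(tt$statistic)),
                 tolerance = 1e-10)
  }
})

test_that("ranking is scale-invariant, sorts descending and flags null features", {
  df <- toy_features(shift = c(bpg = 3))
  r <- rank_features(df)
  expect_equal(r$feature[1], "bpg")
  expect_false(is.unsorted(rev(r$criterion)))
  expect_equal(nrow(r), 17L)
  df_scaled <- df
  df_scaled$bpg <- df_scaled$bpg * 1e6
  expect_equal(rank_features(df_scaled)$criterion, r$criterion,
               tolerance = 1e-9)
  # a feature identical in both classes ranks last with criterion 0
  df0 <- df
  df0$md <- rep(c(-1, 0, 1, 2), 10)
  r0 <- rank_features(df0)
  expect_equal(r0$criterion[r0$feature == "md"], 0)
  expect_equal(r0$feature[17], "md")
  expect_error(rank_features(df[df$class == 1, ]), "two classes")
})

test_that("the projection retains the minimal component count at threshold", {
  df <- toy_features(50, 50, seed = 2, shift = c(bpg = 1))
  pr <- fit_projection(df)
  cum <- cumsum(pr$explained)
  expect_gte(cum[pr$k], 0.99)
  if (pr$k > 1) expect_lt(cum[pr$k - 1], 0.99)
  # isotropic noise: every scaled direction carries ~1/17 > 1% of variance
  expect_equal(pr$k, 17L)
  # two perfectly correlated informative columns collapse to one component
  two <- tibble::tibble(a = rnorm(50))
  two$b <- 2 * two$a
  pr2 <- fit_projection(two, feature_cols = c("a", "b"))
  expect_equal(pr2$k, 1L)
  # threshold 1 keeps the full rank of the centered matrix
  dup <- df
  dup$bpt <- dup$bpd
  pr_full <- fit_projection(dup, var_threshold = 1)
  expect_equal(pr_full$k, 16L)
  expect_error(fit_projection(tibble::tibble(a = rep(1, 5), b = rep(2, 5)),
                              feature_cols = c("a", "b")), "zero variance")
})

test_that("projection applies training constants and preserves variance", {
  df <- toy_features(40, 40, seed = 3, shift = c(bpg = 2))
  pr <- fit_projection(df)
  scores <- predict(pr, df)
  expect_equal(ncol(scores), pr$k)
  # per-component score variances reproduce the explained-variance fractions
  all_scores <- predict(pr, df, k = 17)
  v <- apply(all_scores, 2, stats::var)
  expect_equal(unname(v / sum(v)), pr$explained, tolerance = 1e-8)
  # a row at the training mean projects to the origin
  mu <- df[1, ]
  mu[feature_names()] <- as.list(pr$center)
  expect_equal(unname(unlist(predict(pr, mu))), numeric(pr$k) + 0,
               tolerance = 1e-10)
  # k components reconstruct >= 99% of the scaled variance
  Z <- sweep(sweep(as.matrix(df[, feature_names()]), 2, pr$center), 2,
             pr$scale, "/")
  recon <- as.matrix(scores) %*% t(pr$rotation[, seq_len(pr$k)])
  expect_gte(1 - sum((Z - recon)^2) / sum(sweep(Z, 2, colMeans(Z))^2), 0.99)
  expect_error(predict(pr, df[, 1:5]), "missing feature")
})

test_that("k never increases with the threshold", {
  df <- toy_features(30, 30, seed = 9, shift = c(bpg = 1, bpa = 1))
  ks <- vapply(c(0.5, 0.8, 0.95, 0.99, 1), function(th)
    fit_projection(df, var_threshold = th)$k, integer(1))
  expect_false(is.unsorted(ks))
  expect_lte(ks[4], 17L)
})
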