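# ---- PCA ----

test_that("PCA variance fractions behave at analytic extremes", {
  ## rank-1 data: all variance on one axis
  v <- c(1, 2, 3)
  x <- outer(rnorm(20), v)
  ds1 <- labeled_dataset(x, rep(c(-1, 1), 10))
  p1 <- fit_pca(ds1, k = 1)
  expect_equal(p1$model$variance_fraction, 1.0, tolerance = 1e-10)

  ## isotropic data: each of d axes carries ~1/d
  ## top sample eigenvalue of isotropic data sits ~ (1 + sqrt(d/n))^2 above
  ## 1, so allow that sampling bias around the 1/d population value
  ds2 <- generate_two_class(1500, 1500, d = 4, separation = 0, seed = 10)
  p2 <- fit_pca(ds2, k = 1)
  expect_lt(abs(p2$model$variance_fraction - 1 / 4), 0.02)
})

test_that("full-rank projection is an isometry and conserves total variance", {
  ds <- generate_two_class(25, 15, d = 6, separation = 1, seed = 11)
  p <- fit_pca(ds, k = 6)
  d_orig <- dist(ds$features)
  d_proj <- dist(p$projected$features)
  expect_equal(as.vector(d_proj), as.vector(d_orig), tolerance = 1e-8)
  expect_equal(sum(p$model$eigenvalues), sum(diag(stats::cov(ds$features))),
               tolerance = 1e-8)
  ## loadings orthonormal, eigenvalues sorted
  G <- crossprod(p$model$loadings)
  expect_equal(G, diag(6), tolerance = 1e-8)
  expect_true(all(diff(p$model$eigenvalues) <= 1e-12))
})

test_that("PCA projections follow the documented sign convention and persist", {
  ds <- generate_two_class(40, 20, d = 5, separation = 1, seed = 12)
  p <- fit_pca(ds, k = 3)
  for (j in 1:3) {
    col <- p$model$loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
  f <- withr::local_tempfile(fileext = ".json")
  write_pca_json(p$model, f)
  back <- read_pca_json(f)
  expect_equal(back$loadings, p$model$loadings, tolerance = 1e-12)
  expect_equal(predict(back, ds)$features, p$projected$features, tolerance = 1e-12)
  expect_error(fit_pca(ds, k = 9), "exceeds")
})

# ---- split ----

test_that("a 2/3 split of the 502-sample cohort yields 334 training samples", {
  ds <- generate_two_class(424, 78, d = 4, seed = 13)
  sp <- split_dataset(ds, train_fraction = 2 / 3, seed = 14)
  expect_equal(nrow(sp$train$features), 334)
  expect_equal(nrow(sp$test$features), 168)
  ## stratification: proportional to rounding
  expect_equal(unname(class_counts(sp$train)[["neg"]]), 282)
  expect_equal(unname(class_counts(sp$train)[["pos"]]), 52)
  ## explicit per-class-count mode reproduces published cohort composition
  sp2 <- split_dataset(ds, class_counts = c(neg = 286, pos = 48), seed = 14)
  expect_equal(unname(class_counts(sp2$train)), c(286, 48))
  expect_equal(unname(class_counts(sp2$test)), c(138, 30))
})

test_that("split is a seeded partition and respects boundary cases", {
  ds <- generate_two_class(9, 6, d = 2, seed = 15)
  sp <- split_dataset(ds, train_fraction = 2 / 3, seed = 16)
  ids <- sort(c(sp$train$sample_ids, sp$test$sample_ids))
  expect_identical(ids, sort(ds$sample_ids))
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
  sp_b <- split_dataset(ds, train_fraction = 2 / 3, seed = 16)
  expect_identical(sp_b, sp)

  ## train = n - 1 leaves a single-sample test set, still valid
  sp1 <- split_dataset(ds, train_fraction = 14.5 / 15, stratified = FALSE, seed = 17)
  expect_equal(nrow(sp1$test$features), 1)

  expect_error(split_dataset(ds, train_fraction = 1.2), "between 0 and 1")
  one_class <- labeled_dataset(matrix(rnorm(6), 3), c(1, 1, 1))
  expect_error(split_dataset(one_class, seed = 1), "both classes")
})

# ---- SMOTE ----

test_that("SMOTE balances the published 286/48 training composition to 286/286", {
  tr <- generate_two_class(286, 48, d = 4, separation = 1, seed = 18)
  bal <- smote_oversample(tr, seed = 19)
  expect_equal(unname(class_counts(bal)), c(286, 286))
  ## originals retained unchanged, in order
  expect_equal(bal$features[1:334, ], tr$features)
  expect_identical(bal$labels[1:334], tr$labels)
})

test_that("synthetic points are convex combinations of minority neighbours", {
  tr <- generate_two_class(20, 6, d = 3, separation = 2, seed = 20)
  bal <- smote_oversample(tr, k_neighbors = 3, seed = 21)
  xmin <- tr$features[tr$labels == 1, ]
  syn <- bal$features[-seq_len(26), , drop = FALSE]
  pairs <- utils::combn(nrow(xmin), 2)
  for (s in seq_len(nrow(syn))) {
    ## exhaustively: some minority pair (p, q) has d(p,s) + d(s,q) = d(p,q)
    slack <- apply(pairs, 2, function(pq) {
      p <- xmin[pq[1], ]; q <- xmin[pq[2], ]
      sqrt(sum((p - syn[s, ])^2)) + sqrt(sum((syn[s, ] - q)^2)) -
        sqrt(sum((p - q)^2))
    })
    expect_lt(min(slack), 1e-9)
    ## and within the per-coordinate bounding box of the minority class
    expect_true(all(syn[s, ] >= apply(xmin, 2, min) - 1e-12))
    expect_true(all(syn[s, ] <= apply(xmin, 2, max) + 1e-12))
  }
})

test_that("SMOTE edge cases: balanced input unchanged, singleton minority rejected", {
  bal_in <- generate_two_class(10, 10, d = 2, seed = 22)
  expect_identical(smote_oversample(bal_in, seed = 23), bal_in)
  tiny <- labeled_dataset(matrix(rnorm(8), 4), c(-1, -1, -1, 1))
  expect_error(smote_oversample(tiny, seed = 1), "fewer than 2")
  a <- smote_oversample(generate_two_class(12, 5, d = 2, seed = 24), seed = 25)
  b <- smote_oversample(generate_two_class(12, 5, d = 2, seed = 24), seed = 25)
  expect_identical(a, b)
})
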