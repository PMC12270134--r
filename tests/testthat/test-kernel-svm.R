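# ---- kernel matrices ----

test_that("quantum kernel equals the Gram matrix of explicitly prepared states", {
  set.seed(60)
  cfg <- embedding_config(3)
  x <- matrix(runif(30, -1, 2), 10, 3)
  ds <- labeled_dataset(x, rep(c(-1, 1), 5))
  K <- quantum_kernel_matrix(ds, embed_config = cfg)
  expect_equal(diag(K$values), rep(1, 10), tolerance = 1e-9)
  expect_equal(K$values, t(K$values), tolerance = 1e-9)
  ## brute-force oracle path
  S <- vapply(1:10, function(i) oracle_state(x[i, ], 3, 3), complex(8))
  Kref <- Mod(t(Conj(S)) %*% S)^2
  expect_equal(K$values, Kref, tolerance = 1e-10)
  expect_true(all(K$values >= 0 & K$values <= 1))
})

test_that("train-kind fidelity kernels are PSD up to rounding", {
  set.seed(61)
  cfg <- embedding_config(2)
  x <- matrix(runif(40, -2, 2), 20, 2)
  K <- quantum_kernel_matrix(x, embed_config = cfg)
  expect_gte(min(eigen(K$values, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("cross kernels align rows with new samples and columns with training", {
  set.seed(62)
  cfg <- embedding_config(2)
  tr <- matrix(runif(12), 6, 2)
  te <- matrix(runif(6), 3, 2)
  K <- quantum_kernel_matrix(te, tr, embed_config = cfg)
  expect_equal(dim(K$values), c(3, 6))
  expect_equal(K$values[2, 5], state_fidelity(te[2, ], tr[5, ], cfg),
               tolerance = 1e-12)
})

test_that("RBF kernel matches a naive double-loop recomputation", {
  set.seed(63)
  A <- matrix(rnorm(15), 5, 3)
  B <- matrix(rnorm(12), 4, 3)
  gamma <- 0.7
  K <- rbf_kernel_matrix(A, B, gamma = gamma)
  ref <- matrix(0, 5, 4)
  for (i in 1:5) for (j in 1:4)
    ref[i, j] <- exp(-gamma * sum((A[i, ] - B[j, ])^2))
  expect_equal(K$values, ref, tolerance = 1e-12)
  expect_equal(rbf_kernel_matrix(A, gamma = 0)$values, matrix(1, 5, 5))
  expect_equal(diag(rbf_kernel_matrix(A, gamma = 2)$values), rep(1, 5))
  expect_error(rbf_kernel_matrix(A, B, gamma = -1), "nonnegative")
})

# ---- dual SVC ----

test_that("the two-point toy recovers the hand-solved dual", {
  K <- kernel_matrix(matrix(c(1, -1, -1, 1), 2), "train")
  fit <- fit_svc_precomputed(K, c(1, -1), C = 10)
  expect_equal(fit$alpha, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(fit$t, 0, tolerance = 1e-8)
  ## small C activates the box constraint
  fit_c <- fit_svc_precomputed(K, c(1, -1), C = 0.1)
  expect_equal(fit_c$alpha, c(0.1, 0.1), tolerance = 1e-10)
})

test_that("dual solutions agree with the kernlab QP oracle on random toys", {
  skip_if_not_installed("kernlab")
  set.seed(64)
  for (trial in 1:20) {
    n <- 14
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rep(c(1, -1), each = n / 2)
    X[y == 1, 1] <- X[y == 1, 1] + runif(1, 0.5, 2)
    K <- X %*% t(X)
    C <- sample(c(0.05, 0.3, 1, 10), 1)
    fit <- suppressWarnings(fit_svc_precomputed(kernel_matrix(K, "train"), y, C))
    ## dual feasibility
    expect_true(all(fit$alpha >= -1e-10 & fit$alpha <= C + 1e-10))
    expect_lt(abs(sum(fit$alpha * fit$y)), 1e-8)
    expect_gte(fit$objective, 0)
    qp <- kernlab::ipop(c = matrix(-1, n), H = (y %*% t(y)) * K,
                        A = t(y), b = 0, l = matrix(0, n), u = matrix(C, n),
                        r = 0)
    a_ref <- kernlab::primal(qp)
    ## never worse than the reference optimum (to its tolerance), and in
    ## exact agreement where the interior-point oracle is well converged
    expect_gte(fit$objective, dual_objective(a_ref, y, K) - 1e-6)
    if (C <= 1) expect_lt(abs(fit$objective - dual_objective(a_ref, y, K)), 1e-6)
  }
})

test_that("separable data at large C is classified perfectly in-sample", {
  ds <- make_sep_toy(12, gap = 5, seed = 65)
  K <- linear_kernel_matrix(ds)
  fit <- suppressWarnings(fit_svc_precomputed(K, ds$labels, C = 1e4))
  pred <- predict(fit, K)
  expect_identical(pred, ds$labels)
})

test_that("predictions obey the documented tie rule and alignment checks", {
  ds <- make_sep_toy(6, gap = 5, seed = 66)
  K <- linear_kernel_matrix(ds)
  fit <- suppressWarnings(fit_svc_precomputed(K, ds$labels, C = 100))
  fit$t <- 0
  zero_row <- matrix(0, 1, fit$n)
  expect_equal(predict(fit, zero_row), fit$majority)
  Kc <- linear_kernel_matrix(ds$features[c(1, 1), ], ds)
  p2 <- predict(fit, Kc)
  expect_identical(p2[1], p2[2])
  expect_error(predict(fit, matrix(0, 2, 3)), "columns")
  expect_error(fit_svc_precomputed(K, rep(1, 12), C = 1), "single-class")
  bad <- kernel_matrix(matrix(c(1, 2, 2, 1), 2), "train")   # eigenvalues 3, -1
  expect_error(fit_svc_precomputed(bad, c(1, -1), C = 1, psd_tol = 1e-8),
               "not PSD")
})

test_that("linear-kernel dual predictions match a reference linear SVM", {
  skip_if_not_installed("e1071")
  set.seed(67)
  for (trial in 1:20) {
    ds <- make_sep_toy(8, gap = 4, seed = 200 + trial)
    C <- 10
    fit <- suppressWarnings(
      fit_svc_precomputed(linear_kernel_matrix(ds), ds$labels, C = C))
    pred <- predict(fit, linear_kernel_matrix(ds))
    ref <- e1071::svm(ds$features, factor(ds$labels), kernel = "linear",
                      cost = C, scale = FALSE)
    pref <- as.integer(as.character(predict(ref, ds$features)))
    expect_identical(pred, pref)
  }
})

# ---- grid search ----

test_that("a single-candidate grid wins and is refined around itself", {
  ds <- make_sep_toy(10, gap = 4, seed = 68)
  gs <- grid_search_two_stage(
    ds,
    fit_fun = function(tr, p)
      suppressWarnings(fit_svc_precomputed(linear_kernel_matrix(tr), tr$labels,
                                           C = p$C)),
    predict_fun = function(m, tr, te) predict(m, linear_kernel_matrix(te, tr)),
    grid = data.frame(C = 1), folds = 2, seed = 69)
  expect_equal(nrow(gs$stage1), 1)
  expect_equal(nrow(gs$stage2), 5)            # one decade around the winner
  expect_equal(range(gs$stage2$C), c(10^-0.5, 10^0.5), tolerance = 1e-10)
  expect_gte(gs$best_score, max(gs$stage1$mean_score))
})

test_that("ties break toward the smaller C when the parameter is irrelevant", {
  ds <- make_sep_toy(10, gap = 6, seed = 70)
  ## classifier ignores its parameters entirely -> all candidates tie
  gs <- grid_search_two_stage(
    ds,
    fit_fun = function(tr, p) p,
    predict_fun = function(m, tr, te) ifelse(te$features[, 1] > 0, 1L, -1L),
    grid = data.frame(C = c(100, 1, 0.1)), folds = 2, seed = 71, refine = FALSE)
  expect_equal(gs$best$C, 0.1)
  expect_equal(gs$best_score, 1)
})

test_that("reported mean F1 equals the hand-recomputed per-fold average", {
  set.seed(72)
  x <- matrix(rnorm(20), 10, 2)
  x[, 1] <- x[, 1] + rep(c(1.2, -1.2), each = 5)
  ds <- labeled_dataset(x, rep(c(1, -1), each = 5))
  folds <- 2
  seed <- 73
  predictor <- function(te) ifelse(te$features[, 1] > 0, 1L, -1L)
  gs <- grid_search_two_stage(
    ds, fit_fun = function(tr, p) NULL,
    predict_fun = function(m, tr, te) predictor(te),
    grid = data.frame(C = 1), folds = folds, seed = seed, refine = FALSE)
  fold_id <- qembed:::stratified_folds(ds$labels, folds, seed)
  manual <- mean(vapply(seq_len(folds), function(fd) {
    va <- which(fold_id == fd)
    oracle_f1(ds$labels[va], predictor(subset_dataset(ds, va)))
  }, numeric(1)))
  expect_equal(gs$stage1$mean_score, manual, tolerance = 1e-12)
})
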