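test_that("confusion matrices count with +1 as positive and swap symmetrically", {
  cm <- confusion(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]), c(TP = 2, TN = 2, FP = 0, FN = 0))
  cm2 <- confusion(c(1, 1, -1, -1), c(-1, -1, -1, -1))
  expect_equal(unlist(cm2[c("TP", "FN", "TN", "FP")]), c(TP = 0, FN = 2, TN = 2, FP = 0))
  ## swapping the positive designation exchanges TP<->TN and FP<->FN
  yt <- c(1, 1, -1, -1, 1); yp <- c(1, -1, -1, 1, 1)
  a <- confusion(yt, yp, positive = 1)
  b <- confusion(yt, yp, positive = -1)
  expect_equal(c(a$TP, a$TN, a$FP, a$FN), c(b$TN, b$TP, b$FN, b$FP))
  expect_error(confusion(c(1, -1), c(1)), "equal length")
})

test_that("perfect and degenerate classifiers give the expected metric values", {
  perfect <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  for (m in c("TPR", "SPC", "PPV", "NPV", "ACC", "F1", "MCC"))
    expect_equal(perfect[[m]], 1)
  for (m in c("FPR", "FDR", "FNR")) expect_equal(perfect[[m]], 0)
  expect_length(perfect$undefined, 0)

  allneg <- compute_metrics(list(TP = 0, TN = 8, FP = 0, FN = 2))
  expect_equal(allneg$TPR, 0)
  expect_equal(allneg$PPV, 0)
  expect_true(all(c("PPV", "FDR", "MCC") %in% allneg$undefined))
})

test_that("complementarity identities hold whenever denominators are nonzero", {
  set.seed(100)
  for (i in 1:50) {
    cm <- list(TP = sample(1:20, 1), TN = sample(1:20, 1),
               FP = sample(1:20, 1), FN = sample(1:20, 1))
    r <- compute_metrics(cm)
    expect_equal(r$TPR + r$FNR, 1, tolerance = 1e-12)
    expect_equal(r$SPC + r$FPR, 1, tolerance = 1e-12)
    expect_equal(r$PPV + r$FDR, 1, tolerance = 1e-12)
    expect_gte(r$MCC, -1); expect_lte(r$MCC, 1)
    expect_gte(r$F1, 0); expect_lte(r$ACC, 1)
  }
})

test_that("MCC matches a direct formula oracle over exhaustive small counts", {
  grid <- expand.grid(TP = 0:4, TN = 0:4, FP = 0:4, FN = 0:4)
  grid <- grid[rowSums(grid) > 0, ]
  for (i in seq_len(nrow(grid))) {
    cm <- as.list(grid[i, ])
    r <- compute_metrics(cm)
    expect_equal(r$MCC, oracle_mcc(cm$TP, cm$TN, cm$FP, cm$FN), tolerance = 1e-12)
    expect_gte(r$MCC, -1); expect_lte(r$MCC, 1)
  }
  ## independence on a balanced design -> MCC 0
  expect_equal(compute_metrics(list(TP = 3, TN = 3, FP = 3, FN = 3))$MCC, 0)
})

test_that("comparative scoring is antisymmetric and detects rounded ties", {
  a <- compute_metrics(list(TP = 10, TN = 40, FP = 10, FN = 5))
  b <- compute_metrics(list(TP = 8, TN = 45, FP = 5, FN = 7))
  ab <- comparative_score(a, b)
  ba <- comparative_score(b, a)
  expect_equal(ab$wins_a, ba$wins_b)
  expect_equal(ab$wins_b, ba$wins_a)
  expect_equal(ab$ties, ba$ties)
  expect_equal(ab$wins_a + ab$wins_b + ab$ties, 10)
  same <- comparative_score(a, a)
  expect_equal(c(same$wins_a, same$wins_b, same$ties), c(0, 0, 10))
  ## values differing beyond 3 decimals tie at reported precision
  x <- as.list(a[qembed:::metric_names()])
  y <- x
  y$TPR <- y$TPR + 4e-4
  cs <- comparative_score(x, y, digits = 3)
  expect_equal(cs$ties, 10)
})

test_that("cross-validation partitions samples and aggregates with population sd", {
  ds <- make_sep_toy(10, gap = 4, seed = 101)
  const_fit <- function(tr) NULL
  const_pred <- function(m, tr, te) rep(1L, nrow(te$features))
  cv <- crossval_report(ds, const_fit, const_pred, folds = 5, seed = 102)
  expect_equal(cv$folds, 5)
  expect_true(all(cv$sd == 0))                 # constant classifier
  expect_equal(sort(unlist(lapply(1:5, function(f) which(cv$fold_id == f)))),
               1:20)
  ## every fold report identical
  for (f in 2:5) expect_equal(cv$per_fold[[f]], cv$per_fold[[1]])

  ## mean F1 equals the hand-recomputed fold average for a real classifier
  sign_pred <- function(m, tr, te) ifelse(te$features[, 1] > 0, 1L, -1L)
  cv2 <- crossval_report(ds, const_fit, sign_pred, folds = 2, seed = 103)
  fold_id <- qembed:::stratified_folds(ds$labels, 2, 103)
  manual <- mean(vapply(1:2, function(f) {
    va <- which(fold_id == f)
    oracle_f1(ds$labels[va], ifelse(ds$features[va, 1] > 0, 1L, -1L))
  }, numeric(1)))
  expect_equal(unname(cv2$mean["F1"]), manual, tolerance = 1e-12)
  expect_error(crossval_report(ds, const_fit, const_pred, folds = 11, seed = 1),
               "cannot be split")
})

test_that("comparison tables render the ten metrics plus the scoreboard row", {
  a <- compute_metrics(list(TP = 10, TN = 40, FP = 10, FN = 5))
  b <- compute_metrics(list(TP = 8, TN = 45, FP = 5, FN = 7))
  tab <- format_comparison_table(a, b, names_ab = c("SVC", "QSVC"))
  expect_length(tab, 13)                       # header + rule + 10 metrics + score
  expect_match(tab[1], "SVC.*QSVC")
  expect_match(tab[13], "Comparative score")
})
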