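#' Two-stage grid search with stratified cross-validated F1
#'
#' Stage 1 scans a coarse (typically logarithmic) grid of hyperparameter
#' candidates, scoring each by mean validation F1 over stratified k-fold
#' cross-validation. Stage 2 rescans a refined grid of 5 points per numeric
#' axis spanning one decade geometrically centered on the stage-1 winner.
#' Ties (scores equal within 1e-12) break toward the smaller `C` (then the
#' smaller value of the other axes), a deterministic documented rule.
#'
#' @param train a [labeled_dataset()].
#' @param fit_fun `function(train_ds, params)` returning a fitted classifier.
#' @param predict_fun `function(model, train_ds, test_ds)` returning -1/+1
#'   labels for `test_ds` (the training fold is passed so kernel methods can
#'   form the cross kernel).
#' @param grid data.frame of candidate hyperparameters (one column per axis,
#'   e.g. `C`, `gamma`).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param refine logical; run the stage-2 refinement (default TRUE).
#' @param score metric name from [compute_metrics()] used as the selection
#'   criterion (default `"F1"`).
#' @return object of class `grid_search_result`: `best` (named list of the
#'   winning hyperparameters), `best_score`, `stage1`/`stage2` score tables
#'   (candidate columns plus `mean_score`).
#' @export
grid_search_two_stage <- function(train, fit_fun, predict_fun, grid,
                                  folds = 5, seed = NULL, refine = TRUE,
                                  score = "F1") {
  stopifnot(inherits(train, "labeled_dataset"), is.data.frame(grid), nrow(grid) >= 1L)
  folds <- stop_if_not_count(folds, "folds", min = 2L)
  fold_id <- stratified_folds(train$labels, folds, seed)

  score_grid <- function(g) {
    g$mean_score <- vapply(seq_len(nrow(g)), function(i) {
      params <- as.list(g[i, , drop = FALSE])
      params$mean_score <- NULL
      fold_scores <- vapply(seq_len(folds), function(fd) {
        tr <- subset_dataset(train, which(fold_id != fd))
        va <- subset_dataset(train, which(fold_id == fd))
        model <- fit_fun(tr, params)
        pred <- predict_fun(model, tr, va)
        rep_ <- compute_metrics(confusion(va$labels, pred))
        rep_[[score]]
      }, numeric(1))
      mean(fold_scores)
    }, numeric(1))
    g
  }

  order_candidates <- function(g) {
    axes <- setdiff(names(g), "mean_score")
    pref <- if ("C" %in% axes) c("C", setdiff(axes, "C")) else axes
    g[do.call(order, g[pref]), , drop = FALSE]
  }

  stage1 <- score_grid(order_candidates(grid))
  best1 <- stage1[which.max(stage1$mean_score >= max(stage1$mean_score) - 1e-12), ,
                  drop = FALSE]

  stage2 <- NULL
  best <- best1
  if (refine) {
    axes <- setdiff(names(grid), "mean_score")
    refined <- lapply(axes, function(ax) {
      center <- best1[[ax]]
      if (is.numeric(center) && center > 0)
        10^(log10(center) + seq(-0.5, 0.5, length.out = 5))
      else unique(grid[[ax]])
    })
    names(refined) <- axes
    g2 <- expand.grid(refined, KEEP.OUT.ATTRS = FALSE)
    stage2 <- score_grid(order_candidates(g2))
    cand <- rbind(stage1, stage2)
    cand <- order_candidates(cand)
    best <- cand[which.max(cand$mean_score >= max(cand$mean_score) - 1e-12), ,
                 drop = FALSE]
  }
  bs <- best$mean_score
  best$mean_score <- NULL
  structure(list(best = as.list(best), best_score = bs,
                 stage1 = stage1, stage2 = stage2, score = score),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> best mean %s = %.4f at %s\n", x$score,
              x$best_score,
              paste(sprintf("%s = %.4g", names(x$best), unlist(x$best)),
                    collapse = ", ")))
  invisible(x)
}

#' Default stage-1 hyperparameter grids
#'
#' `C` spans `10^-3 ... 10^3` (7 points); `gamma`, used only by the RBF
#' kernel, spans `10^-4 ... 10^1` (6 points). The fidelity kernel has no
#' bandwidth parameter, so the quantum grid searches `C` only.
#' @param kernel `"rbf"` or `"quantum"`.
#' @return data.frame grid.
#' @export
default_svc_grid <- function(kernel = c("rbf", "quantum")) {
  kernel <- match.arg(kernel)
  if (kernel == "rbf")
    expand.grid(C = 10^seq(-3, 3), gamma = 10^seq(-4, 1), KEEP.OUT.ATTRS = FALSE)
  else
    data.frame(C = 10^seq(-3, 3))
}

## stratified fold assignment: per class, shuffled then dealt round-robin
stratified_folds <- function(labels, folds, seed = NULL) {
  cc <- table(labels)
  if (any(cc < folds))
    stop(sprintf("class with %d samples cannot be split into %d folds",
                 min(cc), folds), call. = FALSE)
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}
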