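#' Principal component analysis for qubit reduction
#'
#' Fits PCA on a labeled dataset and projects it onto the top `k` components.
#' Each retained component becomes one qubit downstream, so `k` is chosen in
#' the 4-12 range typical for desk-scale statevector simulation. Loadings
#' follow a fixed sign convention (the largest-magnitude entry of each loading
#' is positive) so projections are reproducible across platforms.
#'
#' @param ds a [labeled_dataset()].
#' @param k number of components to keep, `1 <= k <= d`.
#' @return A list with `model` (class `pca_fit`: `mean`, `loadings` (d x k,
#'   orthonormal), `eigenvalues` (all d, descending), `variance_fraction`) and
#'   `projected` (the dataset projected onto the k components).
#' @export
fit_pca <- function(ds, k) {
  stopifnot(inherits(ds, "labeled_dataset"))
  d <- ncol(ds$features)
  n <- nrow(ds$features)
  k <- stop_if_not_count(k, "k")
  if (k > d) stop(sprintf("k = %d exceeds feature count d = %d", k, d), call. = FALSE)
  if (n < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  mu <- colMeans(ds$features)
  xc <- sweep(ds$features, 2L, mu)
  sv <- svd(xc)
  eigenvalues <- sv$d^2 / (n - 1)
  loadings <- sv$v
  ## sign convention: largest-|.| entry of each loading positive
  for (j in seq_len(ncol(loadings))) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) loadings[, j] <- -loadings[, j]
  }
  model <- structure(list(mean = mu,
                          loadings = loadings[, seq_len(k), drop = FALSE],
                          eigenvalues = eigenvalues,
                          k = k,
                          variance_fraction = sum(eigenvalues[seq_len(k)]) / sum(eigenvalues)),
                     class = "pca_fit")
  list(model = model, projected = predict(model, ds))
}

#' Project a dataset onto fitted principal components
#' @param object a `pca_fit`.
#' @param newdata a [labeled_dataset()] with the original feature dimension.
#' @param ... unused.
#' @export
predict.pca_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "labeled_dataset"))
  if (ncol(newdata$features) != length(object$mean))
    stop("newdata feature dimension does not match the fitted PCA", call. = FALSE)
  proj <- sweep(newdata$features, 2L, object$mean) %*% object$loadings
  labeled_dataset(proj, newdata$labels, sample_ids = newdata$sample_ids,
                  feature_ids = sprintf("PC%d", seq_len(object$k)))
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> %d -> %d components, variance fraction %.3f\n",
              length(x$mean), x$k, x$variance_fraction))
  invisible(x)
}

#' Persist / restore a PCA model as JSON
#' @param model a `pca_fit`.
#' @param path JSON file path.
#' @export
write_pca_json <- function(model, path) {
  stopifnot(inherits(model, "pca_fit"))
  jsonlite::write_json(list(mean = model$mean,
                            loadings = model$loadings,
                            eigenvalues = model$eigenvalues,
                            k = model$k,
                            variance_fraction = model$variance_fraction),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(obj$mean),
                 loadings = matrix(as.numeric(obj$loadings), ncol = obj$k),
                 eigenvalues = as.numeric(obj$eigenvalues),
                 k = as.integer(obj$k),
                 variance_fraction = as.numeric(obj$variance_fraction)),
            class = "pca_fit")
}

#' Train/test split
#'
#' Partitions a dataset into a training set of exactly
#' `floor(train_fraction * n)` samples and the complementary test set, with a
#' seeded shuffle. Stratified mode (the default) preserves class proportions
#' to rounding; `class_counts` mode takes an explicitly requested number of
#' training samples per class, which reproduces published cohort splits whose
#' per-class counts deviate from exact proportionality.
#'
#' @param ds a [labeled_dataset()] containing both classes.
#' @param train_fraction fraction of samples assigned to training (default 2/3).
#' @param stratified preserve class proportions (default TRUE).
#' @param class_counts optional named vector `c(neg = ..., pos = ...)` of
#'   training counts per internal class; overrides `train_fraction`.
#' @param seed integer seed for the shuffle.
#' @return list with elements `train` and `test` (both [labeled_dataset()]s).
#' @examples
#' ds <- generate_two_class(424, 78, d = 4, seed = 1)
#' sp <- split_dataset(ds, seed = 2)      # 334 train / 168 test
#' @export
split_dataset <- function(ds, train_fraction = 2 / 3, stratified = TRUE,
                          class_counts = NULL, seed = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  n <- nrow(ds$features)
  cc <- class_counts(ds)
  if (any(cc == 0L)) stop("both classes must be present before splitting", call. = FALSE)

  idx_neg <- which(ds$labels == -1L)
  idx_pos <- which(ds$labels == 1L)

  take <- with_seed(seed, {
    idx_neg <- sample(idx_neg)
    idx_pos <- sample(idx_pos)
    if (!is.null(class_counts)) {
      t_neg <- stop_if_not_count(class_counts[["neg"]], "class_counts['neg']", min = 0L)
      t_pos <- stop_if_not_count(class_counts[["pos"]], "class_counts['pos']", min = 0L)
      if (t_neg > length(idx_neg) || t_pos > length(idx_pos))
        stop("requested per-class training counts exceed class sizes", call. = FALSE)
      c(idx_neg[seq_len(t_neg)], idx_pos[seq_len(t_pos)])
    } else if (stratified) {
      if (train_fraction <= 0 || train_fraction >= 1)
        stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
      target <- floor(train_fraction * n)
      raw <- c(neg = train_fraction * length(idx_neg),
               pos = train_fraction * length(idx_pos))
      base <- floor(raw)
      ## distribute the remainder by largest fractional part to hit the target
      short <- target - sum(base)
      if (short > 0) {
        ord <- order(raw - base, decreasing = TRUE)
        base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1L
      } else if (short < 0) {
        ord <- order(raw - base)
        base[ord[seq_len(-short)]] <- base[ord[seq_len(-short)]] - 1L
      }
      c(idx_neg[seq_len(base[["neg"]])], idx_pos[seq_len(base[["pos"]])])
    } else {
      if (train_fraction <= 0 || train_fraction >= 1)
        stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
      all_idx <- sample(n)
      all_idx[seq_len(floor(train_fraction * n))]
    }
  })
  take <- sort(take)
  rest <- setdiff(seq_len(n), take)
  if (length(take) == 0L || length(rest) == 0L)
    stop("split would leave an empty train or test set", call. = FALSE)
  list(train = subset_dataset(ds, take), test = subset_dataset(ds, rest))
}

#' SMOTE minority oversampling
#'
#' Upsamples the minority class to the majority count by synthetic
#' interpolation: each synthetic sample lies on the segment between a minority
#' sample `x_i` and one of its `k_neighbors` nearest minority neighbours,
#' `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`. Majority and original
#' minority samples pass through unchanged; an already balanced input is
#' returned as-is.
#'
#' @param train a [labeled_dataset()].
#' @param k_neighbors number of nearest minority neighbours considered
#'   (default 5, truncated to minority size minus one).
#' @param seed integer seed.
#' @return A balanced [labeled_dataset()]; synthetic samples get ids suffixed
#'   `_syn<i>`.
#' @examples
#' tr <- generate_two_class(286, 48, d = 4, seed = 1)
#' class_counts(smote_oversample(tr, seed = 2))  # 286 / 286
#' @export
smote_oversample <- function(train, k_neighbors = 5, seed = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  k_neighbors <- stop_if_not_count(k_neighbors, "k_neighbors")
  cc <- class_counts(train)
  if (cc[["neg"]] == cc[["pos"]]) return(train)
  minority <- if (cc[["pos"]] < cc[["neg"]]) 1L else -1L
  idx_min <- which(train$labels == minority)
  n_min <- length(idx_min)
  n_syn <- abs(cc[["neg"]] - cc[["pos"]])
  if (n_min < 2L)
    stop("minority class has fewer than 2 samples; SMOTE needs at least one neighbour",
         call. = FALSE)
  xmin <- train$features[idx_min, , drop = FALSE]
  k_eff <- min(k_neighbors, n_min - 1L)
  ## pairwise distances within the minority class
  dmat <- as.matrix(stats::dist(xmin))
  diag(dmat) <- Inf
  nn_idx <- t(apply(dmat, 1L, function(row) order(row)[seq_len(k_eff)]))

  syn <- with_seed(seed, {
    parents <- rep(seq_len(n_min), length.out = n_syn)
    picks <- sample.int(k_eff, n_syn, replace = TRUE)
    u <- stats::runif(n_syn)
    out <- matrix(NA_real_, n_syn, ncol(xmin))
    for (s in seq_len(n_syn)) {
      p <- parents[s]
      q <- nn_idx[p, picks[s]]
      out[s, ] <- xmin[p, ] + u[s] * (xmin[q, ] - xmin[p, ])
    }
    out
  })
  labeled_dataset(rbind(train$features, syn),
                  c(train$labels, rep(minority, n_syn)),
                  sample_ids = c(train$sample_ids, sprintf("syn%04d", seq_len(n_syn))),
                  feature_ids = train$feature_ids)
}
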