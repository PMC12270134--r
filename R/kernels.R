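#' Kernel matrix container
#'
#' @param values numeric matrix of kernel evaluations.
#' @param kind `"train"` (square, symmetric, unit diagonal) or `"cross"`
#'   (rows = new samples, columns = training samples).
#' @param row_ids,col_ids identifiers.
#' @return object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, kind = c("train", "cross"),
                          row_ids = NULL, col_ids = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (kind == "train" && nrow(values) != ncol(values))
    stop("train kernel must be square", call. = FALSE)
  structure(list(values = values, kind = kind,
                 row_ids = row_ids %||% sprintf("r%d", seq_len(nrow(values))),
                 col_ids = col_ids %||% sprintf("c%d", seq_len(ncol(values)))),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %s, %d x %d, range [%.3f, %.3f]\n", x$kind,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Heatmap of a kernel matrix
#' @param x a `kernel_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.kernel_matrix <- function(x, ...) {
  v <- x$values
  graphics::image(seq_len(ncol(v)), seq_len(nrow(v)), t(v[rev(seq_len(nrow(v))), ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "column sample", ylab = "row sample", ...)
  invisible(x)
}

#' Quantum fidelity kernel matrix
#'
#' Gram matrix of state fidelities between embedded samples:
#' `K[i, j] = |<psi(g(b_j)) | psi(g(a_i))>|^2` where `g` is the NQE network
#' (identity when `nqe` is `NULL`) and `psi` the feature-map state. Each
#' state is prepared once and the Gram matrix formed from the full set of
#' pairwise inner products; a train-kind kernel is exactly symmetric with
#' unit diagonal up to floating error.
#'
#' @param A a [labeled_dataset()] or feature matrix.
#' @param B optional second dataset; `NULL` means `A` vs itself (train kind).
#' @param nqe optional trained [nqe_model()] applied before embedding.
#' @param embed_config an [embedding_config()].
#' @return a `kernel_matrix` (train kind when `B` is `NULL`, rows of the cross
#'   kind indexing `A`).
#' @export
quantum_kernel_matrix <- function(A, B = NULL, nqe = NULL, embed_config) {
  xa <- dataset_features(A)
  ida <- dataset_ids(A)
  if (!is.null(nqe)) xa <- nqe_forward(xa, nqe)
  if (ncol(xa) != embed_config$n_qubits)
    stop("embedded feature dimension does not match n_qubits", call. = FALSE)
  Sa <- prepare_states_matrix(xa, embed_config)
  if (is.null(B)) {
    G <- Mod(t(Conj(Sa)) %*% Sa)^2
    G <- (G + t(G)) / 2
    return(kernel_matrix(pmin(pmax(G, 0), 1), "train", ida, ida))
  }
  xb <- dataset_features(B)
  idb <- dataset_ids(B)
  if (!is.null(nqe)) xb <- nqe_forward(xb, nqe)
  Sb <- prepare_states_matrix(xb, embed_config)
  G <- Mod(t(Conj(Sb)) %*% Sa)^2   # rows index A
  kernel_matrix(pmin(pmax(t(G), 0), 1), "cross", ida, idb)
}

#' Gaussian RBF kernel matrix
#'
#' `K[i, j] = exp(-gamma * ||a_i - b_j||^2)`, the classical baseline kernel.
#' @inheritParams quantum_kernel_matrix
#' @param gamma nonnegative bandwidth parameter.
#' @export
rbf_kernel_matrix <- function(A, B = NULL, gamma) {
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  xa <- dataset_features(A)
  xb <- if (is.null(B)) xa else dataset_features(B)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  d2 <- pmax(d2, 0)
  kernel_matrix(exp(-gamma * d2), if (is.null(B)) "train" else "cross",
                dataset_ids(A), if (is.null(B)) dataset_ids(A) else dataset_ids(B))
}

#' Linear kernel matrix
#'
#' `K[i, j] = a_i . b_j`.
#' @inheritParams quantum_kernel_matrix
#' @export
linear_kernel_matrix <- function(A, B = NULL) {
  xa <- dataset_features(A)
  xb <- if (is.null(B)) xa else dataset_features(B)
  kernel_matrix(xa %*% t(xb), if (is.null(B)) "train" else "cross",
                dataset_ids(A), if (is.null(B)) dataset_ids(A) else dataset_ids(B))
}

dataset_features <- function(x) {
  if (inherits(x, "labeled_dataset")) x$features else as.matrix(x)
}
dataset_ids <- function(x) {
  if (inherits(x, "labeled_dataset")) x$sample_ids
  else sprintf("r%d", seq_len(nrow(as.matrix(x))))
}

#' Export a kernel matrix to CSV
#' @param km a `kernel_matrix`.
#' @param path CSV path (row/col ids preserved).
#' @export
write_kernel_csv <- function(km, path) {
  v <- km$values
  dimnames(v) <- list(km$row_ids, km$col_ids)
  utils::write.csv(v, path)
  invisible(path)
}
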