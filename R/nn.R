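#' Classical feed-forward neural network classifier
#'
#' Baseline MLP with configurable hidden layers (tanh activation, matching
#' the embedding network), a single logistic output unit, and full-batch
#' gradient descent on binary cross-entropy. Seeded and reproducible:
#' `epochs = 0` returns the untrained random initialization.
#'
#' @param train a [labeled_dataset()] with both classes.
#' @param hidden integer vector of hidden-layer widths (length = number of
#'   hidden layers; default one layer of `2 * d` units).
#' @param learning_rate gradient-descent step size.
#' @param epochs number of full-batch updates.
#' @param seed integer seed for weight initialization.
#' @return object of class `nn_classifier` with the weight list, training
#'   loss history (`loss_history`, one cross-entropy value per epoch) and the
#'   hyperparameters.
#' @export
fit_nn <- function(train, hidden = NULL, learning_rate = 0.05, epochs = 500,
                   seed = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (any(class_counts(train) == 0L))
    stop("training set must contain both classes", call. = FALSE)
  stopifnot(learning_rate > 0, epochs >= 0)
  d <- ncol(train$features)
  hidden <- as.integer(hidden %||% (2L * d))
  stopifnot(all(hidden >= 1L))
  sizes <- c(d, hidden, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  with_seed(seed, {
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l + 1L] * sizes[l], sd = 1 / sqrt(sizes[l])),
                        sizes[l + 1L], sizes[l])
      b[[l]] <- numeric(sizes[l + 1L])
    }
  })
  x <- t(train$features)                    # d x n
  t01 <- as.numeric(train$labels == 1L)
  n <- ncol(x)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ## forward
    acts <- vector("list", L + 1L); acts[[1L]] <- x
    for (l in seq_len(L)) {
      z <- W[[l]] %*% acts[[l]] + b[[l]]
      acts[[l + 1L]] <- if (l < L) tanh(z) else 1 / (1 + exp(-z))
    }
    p <- pmin(pmax(as.vector(acts[[L + 1L]]), 1e-12), 1 - 1e-12)
    history[ep] <- -mean(t01 * log(p) + (1 - t01) * log(1 - p))
    ## backward: logistic + BCE gives delta = p - t at the output
    delta <- matrix(p - t01, 1L, n)
    for (l in rev(seq_len(L))) {
      gW <- delta %*% t(acts[[l]]) / n
      gb <- rowSums(delta) / n
      if (l > 1L) delta <- (t(W[[l]]) %*% delta) * (1 - acts[[l]]^2)
      W[[l]] <- W[[l]] - learning_rate * gW
      b[[l]] <- b[[l]] - learning_rate * gb
    }
  }
  structure(list(W = W, b = b, hidden = hidden, learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = seed, loss_history = history),
            class = "nn_classifier")
}

#' Predict with the neural network classifier
#' @param object an `nn_classifier`.
#' @param newdata a [labeled_dataset()] or feature matrix.
#' @param type `"class"` (-1/+1 labels by 0.5 threshold) or `"prob"`
#'   (probability of the +1 class).
#' @param ... unused.
#' @export
predict.nn_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  a <- t(dataset_features(newdata))
  L <- length(object$W)
  for (l in seq_len(L)) {
    z <- object$W[[l]] %*% a + object$b[[l]]
    a <- if (l < L) tanh(z) else 1 / (1 + exp(-z))
  }
  p <- as.vector(a)
  if (type == "prob") p else ifelse(p >= 0.5, 1L, -1L)
}

#' @export
print.nn_classifier <- function(x, ...) {
  cat(sprintf("<nn_classifier> hidden [%s], lr %g, %d epochs, final BCE %.4f\n",
              paste(x$hidden, collapse = ", "), x$learning_rate, x$epochs,
              if (x$epochs > 0) x$loss_history[x$epochs] else NA))
  invisible(x)
}
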