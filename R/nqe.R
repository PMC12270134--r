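#' Neural Quantum Embedding model
#'
#' A feed-forward network `g(x, w)` mapping input features to the angles fed
#' into the quantum feature map. Training (see [train_nqe()]) adjusts `w` so
#' that embedded states of same-class samples overlap while different-class
#' states become near-orthogonal. Architecture: input dimension `d_in`, one
#' hidden layer of `hidden` units (default `2 * d_in`, matching the study
#' configuration of one hidden layer with twice the feature count) with tanh
#' activation, linear output of dimension `d_out` (default `d_in`, one output
#' angle per qubit; `d_out < d_in` is supported for compressive embeddings).
#'
#' @param d_in input feature dimension.
#' @param d_out output (qubit) dimension, default `d_in`.
#' @param hidden hidden-layer width, default `2 * d_in`.
#' @param init `"random"` (scaled normal, seeded) or `"zero"` (all weights and
#'   biases zero: every sample embeds to the same state, a useful analytic
#'   baseline).
#' @param seed seed for random initialization.
#' @return object of class `nqe_model` with weight matrices `W1` (`hidden x
#'   d_in`), `b1`, `W2` (`d_out x hidden`), `b2`, and a `trained` flag.
#' @export
nqe_model <- function(d_in, d_out = d_in, hidden = 2L * d_in,
                      init = c("random", "zero"), seed = NULL) {
  d_in <- stop_if_not_count(d_in, "d_in")
  d_out <- stop_if_not_count(d_out, "d_out")
  hidden <- stop_if_not_count(hidden, "hidden")
  init <- match.arg(init)
  w <- if (init == "zero") {
    list(W1 = matrix(0, hidden, d_in), b1 = numeric(hidden),
         W2 = matrix(0, d_out, hidden), b2 = numeric(d_out))
  } else {
    with_seed(seed, list(
      W1 = matrix(stats::rnorm(hidden * d_in, sd = 1 / sqrt(d_in)), hidden, d_in),
      b1 = numeric(hidden),
      W2 = matrix(stats::rnorm(d_out * hidden, sd = 1 / sqrt(hidden)), d_out, hidden),
      b2 = numeric(d_out)))
  }
  structure(c(w, list(d_in = d_in, d_out = d_out, hidden = hidden,
                      trained = FALSE, loss_history = numeric(0))),
            class = "nqe_model")
}

#' @export
print.nqe_model <- function(x, ...) {
  cat(sprintf("<nqe_model> %d -> %d (hidden %d, tanh), %s\n", x$d_in, x$d_out,
              x$hidden, if (x$trained) sprintf("trained (%d iterations)",
                                               length(x$loss_history))
              else "untrained"))
  invisible(x)
}

#' Forward pass of the embedding network
#'
#' @param x numeric vector of length `d_in` or a matrix with `d_in` columns.
#' @param model an [nqe_model()].
#' @return embedded vector of length `d_out` (or a matrix of embedded rows).
#' @export
nqe_forward <- function(x, model) {
  stopifnot(inherits(model, "nqe_model"))
  if (is.matrix(x)) {
    if (ncol(x) != model$d_in) stop("input dimension mismatch", call. = FALSE)
    return(t(apply(x, 1L, function(r) nqe_net_forward(model, r)$out)))
  }
  if (length(x) != model$d_in) stop("input dimension mismatch", call. = FALSE)
  nqe_net_forward(model, x)$out
}

nqe_net_forward <- function(model, x) {
  z1 <- as.vector(model$W1 %*% x) + model$b1
  a1 <- tanh(z1)
  out <- as.vector(model$W2 %*% a1) + model$b2
  list(a1 = a1, out = out)
}

## gradient of a scalar loss wrt weights, given d loss / d out
nqe_net_backward <- function(model, x, cache, gout) {
  dW2 <- outer(gout, cache$a1)
  db2 <- gout
  da1 <- as.vector(t(model$W2) %*% gout)
  dz1 <- da1 * (1 - cache$a1^2)
  list(W1 = outer(dz1, x), b1 = dz1, W2 = dW2, b2 = db2)
}

#' Fidelity pair loss
#'
#' The training loss for one ordered sample pair:
#' `F = (|<x_j|x_k>|^2 - 0.5 (1 + y_j y_k))^2`, where the overlap is computed
#' between the quantum states embedding the network outputs `g(x_j, w)` and
#' `g(x_k, w)`. Same-label pairs are pushed toward overlap 1, different-label
#' pairs toward orthogonality; the loss always lies in `[0, 1]`.
#'
#' @param x_j,x_k input feature vectors.
#' @param y_j,y_k class labels in `{-1, +1}`.
#' @param model an [nqe_model()].
#' @param embed_config an [embedding_config()] with `n_qubits = d_out`.
#' @return scalar loss in `[0, 1]`.
#' @export
pair_loss <- function(x_j, x_k, y_j, y_k, model, embed_config) {
  if (!all(c(y_j, y_k) %in% c(-1, 1)))
    stop("labels must be -1/+1", call. = FALSE)
  f <- state_fidelity(nqe_forward(x_j, model), nqe_forward(x_k, model), embed_config)
  (f - 0.5 * (1 + y_j * y_k))^2
}

#' NQE training configuration
#'
#' Defaults follow the study configuration: learning rate 0.01, 1000
#' iterations, 10 sample pairs per stochastic-gradient step.
#' @param learning_rate SGD step size.
#' @param iterations number of SGD steps.
#' @param batch_size number of ordered sample pairs per step.
#' @param seed integer seed controlling initialization and pair sampling.
#' @export
nqe_train_config <- function(learning_rate = 0.01, iterations = 1000,
                             batch_size = 10, seed = NULL) {
  stopifnot(learning_rate > 0, iterations >= 0, batch_size >= 1)
  list(learning_rate = learning_rate, iterations = as.integer(iterations),
       batch_size = as.integer(batch_size), seed = seed)
}

#' Train a Neural Quantum Embedding
#'
#' Runs plain stochastic gradient descent on the fidelity pair loss. Each
#' iteration samples `batch_size` ordered pairs uniformly with replacement,
#' computes the mean [pair_loss()] and its exact gradient (analytic
#' backpropagation through the network composed with adjoint differentiation
#' of the state fidelity with respect to the embedding angles), and takes one
#' descent step. Fully determined by `config$seed`.
#'
#' @param train a [labeled_dataset()] with both classes present.
#' @param model an [nqe_model()]; default is a random-initialized network with
#'   `d_in = d_out =` the feature dimension.
#' @param config an [nqe_train_config()].
#' @param embed_config an [embedding_config()]; default 3 repetitions on
#'   `d_out` qubits.
#' @return the trained `nqe_model`, with `loss_history` (mean batch loss per
#'   iteration, all values in `[0, 1]`).
#' @export
train_nqe <- function(train, model = NULL, config = nqe_train_config(),
                      embed_config = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  cc <- class_counts(train)
  if (any(cc == 0L))
    stop("training set must contain both classes", call. = FALSE)
  d <- ncol(train$features)
  model <- model %||% nqe_model(d, seed = derive_seed(config$seed, 1L))
  if (model$d_in != d) stop("model input dimension does not match data", call. = FALSE)
  embed_config <- embed_config %||% embedding_config(model$d_out)
  if (embed_config$n_qubits != model$d_out)
    stop("embedding n_qubits must equal the model output dimension", call. = FALSE)
  if (config$iterations == 0L) return(model)

  x <- train$features
  y <- train$labels
  n <- nrow(x)
  lr <- config$learning_rate
  history <- numeric(config$iterations)

  with_seed(derive_seed(config$seed, 2L), {
    for (it in seq_len(config$iterations)) {
      jj <- sample.int(n, config$batch_size, replace = TRUE)
      kk <- sample.int(n, config$batch_size, replace = TRUE)
      gW1 <- matrix(0, model$hidden, model$d_in); gb1 <- numeric(model$hidden)
      gW2 <- matrix(0, model$d_out, model$hidden); gb2 <- numeric(model$d_out)
      loss <- 0
      for (b in seq_len(config$batch_size)) {
        xj <- x[jj[b], ]; xk <- x[kk[b], ]
        cj <- nqe_net_forward(model, xj)
        ck <- nqe_net_forward(model, xk)
        fg <- fidelity_with_grad(cj$out, ck$out, embed_config)
        target <- 0.5 * (1 + y[jj[b]] * y[kk[b]])
        diffv <- fg$fidelity - target
        loss <- loss + diffv^2
        gF <- 2 * diffv
        bj <- nqe_net_backward(model, xj, cj, gF * fg$grad_u)
        bk <- nqe_net_backward(model, xk, ck, gF * fg$grad_v)
        gW1 <- gW1 + bj$W1 + bk$W1; gb1 <- gb1 + bj$b1 + bk$b1
        gW2 <- gW2 + bj$W2 + bk$W2; gb2 <- gb2 + bj$b2 + bk$b2
      }
      m <- config$batch_size
      model$W1 <- model$W1 - lr * gW1 / m
      model$b1 <- model$b1 - lr * gb1 / m
      model$W2 <- model$W2 - lr * gW2 / m
      model$b2 <- model$b2 - lr * gb2 / m
      history[it] <- loss / m
    }
  })
  model$trained <- TRUE
  model$loss_history <- c(model$loss_history, history)
  model
}

#' Plot the NQE training-loss curve
#' @param x a trained `nqe_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nqe_model <- function(x, ...) {
  if (!length(x$loss_history)) stop("model has no loss history", call. = FALSE)
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "iteration", ylab = "mean batch fidelity loss", ...)
  invisible(x)
}

#' Persist / restore an NQE model as JSON
#' @param model an `nqe_model`.
#' @param path JSON file path.
#' @export
write_nqe_json <- function(model, path) {
  stopifnot(inherits(model, "nqe_model"))
  jsonlite::write_json(list(W1 = model$W1, b1 = model$b1, W2 = model$W2,
                            b2 = model$b2, d_in = model$d_in, d_out = model$d_out,
                            hidden = model$hidden, trained = model$trained,
                            loss_history = model$loss_history),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nqe_json
#' @export
read_nqe_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W1 = matrix(as.numeric(o$W1), o$hidden, o$d_in),
                 b1 = as.numeric(o$b1),
                 W2 = matrix(as.numeric(o$W2), o$d_out, o$hidden),
                 b2 = as.numeric(o$b2),
                 d_in = as.integer(o$d_in), d_out = as.integer(o$d_out),
                 hidden = as.integer(o$hidden), trained = isTRUE(o$trained),
                 loss_history = as.numeric(o$loss_history)),
            class = "nqe_model")
}

#' Write a loss history to CSV (iteration, loss)
#' @param model a trained `nqe_model`.
#' @param path CSV path.
#' @export
write_loss_history_csv <- function(model, path) {
  utils::write.csv(data.frame(iteration = seq_along(model$loss_history),
                              loss = model$loss_history),
                   path, row.names = FALSE)
  invisible(path)
}
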