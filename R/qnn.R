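#' Variational quantum classifier (sampler-style QNN)
#'
#' Circuit: the ZZ feature-map state of the input (with `feature_map_reps`
#' repetitions), followed by `ansatz_layers` trainable layers, each a
#' single-qubit Y-rotation per qubit and a CNOT entangling ring. Readout is
#' the parity of the measured bitstring: the predicted probability of class
#' +1 is the total probability of odd-parity basis outcomes, computed from
#' the exact statevector. Training minimizes binary cross-entropy over the
#' rotation angles with exact parameter-shift gradients.
#'
#' @param n_qubits number of qubits (= input feature dimension).
#' @param feature_map_reps repetitions of the embedding block (default 2).
#' @param ansatz_layers number of trainable layers (default 2).
#' @param theta optional initial angles, `n_qubits x ansatz_layers`.
#' @param seed seed for random angle initialization in `[-pi, pi]`.
#' @return object of class `qnn_model`.
#' @export
qnn_model <- function(n_qubits, feature_map_reps = 2, ansatz_layers = 2,
                      theta = NULL, seed = NULL) {
  n_qubits <- stop_if_not_count(n_qubits, "n_qubits")
  feature_map_reps <- stop_if_not_count(feature_map_reps, "feature_map_reps")
  ansatz_layers <- stop_if_not_count(ansatz_layers, "ansatz_layers")
  theta <- theta %||% with_seed(seed,
    matrix(stats::runif(n_qubits * ansatz_layers, -pi, pi), n_qubits, ansatz_layers))
  stopifnot(nrow(theta) == n_qubits, ncol(theta) == ansatz_layers)
  structure(list(n_qubits = n_qubits, feature_map_reps = feature_map_reps,
                 ansatz_layers = ansatz_layers, theta = theta,
                 trained = FALSE, loss_history = numeric(0)),
            class = "qnn_model")
}

#' @export
print.qnn_model <- function(x, ...) {
  cat(sprintf("<qnn_model> %d qubits, %d feature-map reps, %d ansatz layers, %s\n",
              x$n_qubits, x$feature_map_reps, x$ansatz_layers,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

## Ry(theta) on qubit q: [[cos(t/2), -sin(t/2)], [sin(t/2), cos(t/2)]]
apply_ry <- function(state, q, theta) {
  N <- length(state)
  bit <- bitwShiftL(1L, q - 1L)
  i0 <- which(bitwAnd(0:(N - 1L), bit) == 0L)
  i1 <- i0 + bit
  c_ <- cos(theta / 2); s_ <- sin(theta / 2)
  a0 <- state[i0]; a1 <- state[i1]
  state[i0] <- c_ * a0 - s_ * a1
  state[i1] <- s_ * a0 + c_ * a1
  state
}

## entangling ring: CNOT(q -> q+1) for q = 1..n-1 plus CNOT(n -> 1) when n > 2
cnot_ring <- function(state, n) {
  if (n < 2L) return(state)
  for (q in seq_len(n - 1L)) state <- apply_cnot(state, q, q + 1L)
  if (n > 2L) state <- apply_cnot(state, n, 1L)
  state
}

qnn_ansatz <- function(state, theta) {
  n <- nrow(theta)
  for (a in seq_len(ncol(theta))) {
    for (q in seq_len(n)) state <- apply_ry(state, q, theta[q, a])
    state <- cnot_ring(state, n)
  }
  state
}

## parity mask: TRUE for odd-parity basis indices
parity_mask <- function(n) {
  b <- 0:(2L^n - 1L)
  ones <- vapply(b, function(v) sum(as.integer(intToBits(v))[seq_len(n)]), integer(1))
  ones %% 2L == 1L
}

#' QNN forward pass
#'
#' @param x feature vector of length `n_qubits`.
#' @param model a [qnn_model()].
#' @param embed_config an [embedding_config()] used for the feature-map state
#'   (its `reps` is overridden by the model's `feature_map_reps`).
#' @return probability of class +1 (odd-parity readout), in `[0, 1]`.
#' @export
qnn_forward <- function(x, model, embed_config) {
  stopifnot(inherits(model, "qnn_model"))
  qnn_prob(x, model$theta, model, embed_config)
}

qnn_prob <- function(x, theta, model, embed_config) {
  cfg <- embed_config
  if (cfg$reps != model$feature_map_reps) {
    cfg$reps <- model$feature_map_reps
  }
  state <- unclass(prepare_state(x, cfg))
  state <- qnn_ansatz(state, theta)
  p <- sum(Mod(state[parity_mask(model$n_qubits)])^2)
  min(max(p, 0), 1)
}

## dP/dtheta_i by the parameter-shift rule (Ry generator has eigenvalues +-1/2)
qnn_prob_grad <- function(x, theta, model, embed_config) {
  g <- matrix(0, nrow(theta), ncol(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + pi / 2
    tm <- theta; tm[i] <- tm[i] - pi / 2
    g[i] <- (qnn_prob(x, tp, model, embed_config) -
               qnn_prob(x, tm, model, embed_config)) / 2
  }
  g
}

#' Train the QNN by gradient descent on cross-entropy
#'
#' Full-batch gradient descent; each angle gradient is assembled from two
#' shifted circuit evaluations (the parameter-shift rule), so the gradient is
#' exact up to floating error. `epochs = 0` leaves the angles unchanged.
#'
#' @param train a [labeled_dataset()] with both classes.
#' @param model a [qnn_model()]; default built from the data dimension.
#' @param embed_config an [embedding_config()].
#' @param epochs number of updates (default 30).
#' @param learning_rate step size (default 0.2).
#' @param seed seed for default model initialization.
#' @return the trained `qnn_model` with `loss_history`.
#' @export
fit_qnn <- function(train, model = NULL, embed_config = NULL, epochs = 30,
                    learning_rate = 0.2, seed = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (any(class_counts(train) == 0L))
    stop("training set must contain both classes", call. = FALSE)
  d <- ncol(train$features)
  model <- model %||% qnn_model(d, seed = derive_seed(seed, 3L))
  embed_config <- embed_config %||% embedding_config(d)
  stopifnot(model$n_qubits == d, epochs >= 0, learning_rate > 0)
  x <- train$features
  t01 <- as.numeric(train$labels == 1L)
  n <- nrow(x)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    grad <- matrix(0, nrow(model$theta), ncol(model$theta))
    loss <- 0
    for (i in seq_len(n)) {
      p <- qnn_prob(x[i, ], model$theta, model, embed_config)
      pc <- min(max(p, 1e-10), 1 - 1e-10)
      loss <- loss - (t01[i] * log(pc) + (1 - t01[i]) * log(1 - pc))
      dldp <- (pc - t01[i]) / (pc * (1 - pc))
      grad <- grad + dldp * qnn_prob_grad(x[i, ], model$theta, model, embed_config)
    }
    model$theta <- model$theta - learning_rate * grad / n
    history[ep] <- loss / n
  }
  if (epochs > 0) model$trained <- TRUE
  model$loss_history <- c(model$loss_history, history)
  model
}

#' Predict with a QNN
#' @param object a `qnn_model`.
#' @param newdata a [labeled_dataset()] or feature matrix.
#' @param embed_config an [embedding_config()].
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.qnn_model <- function(object, newdata, embed_config,
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- dataset_features(newdata)
  p <- vapply(seq_len(nrow(x)),
              function(i) qnn_prob(x[i, ], object$theta, object, embed_config),
              numeric(1))
  if (type == "prob") p else ifelse(p >= 0.5, 1L, -1L)
}
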