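#' Soft-margin SVC fitted in the dual on a precomputed kernel
#'
#' Maximizes the dual objective
#' `sum_k alpha_k - 1/2 sum_{j,k} alpha_j alpha_k y_j y_k K_jk`
#' subject to the box constraint `0 <= alpha_k <= C` and the equality
#' constraint `sum_k alpha_k y_k = 0`, by SMO-style pairwise coordinate
#' ascent on the maximally KKT-violating pair. The bias `t` of the decision
#' function `sign(sum_k alpha_k y_k K(x, x_k) - t)` is taken from the KKT
#' conditions, averaged over unbounded support vectors.
#'
#' A train kernel whose minimum eigenvalue lies in `[-psd_tol, 0)` (floating
#' noise from statevector products) is repaired by clipping negative
#' eigenvalues to zero, with a warning; eigenvalues below `-psd_tol` are an
#' error.
#'
#' @param K a train-kind [kernel_matrix()] (or square matrix).
#' @param y labels in -1/+1 (0/1 accepted), one per training sample.
#' @param C box parameter, `C > 0`.
#' @param tol KKT violation tolerance of the solver.
#' @param psd_tol negative-eigenvalue tolerance for PSD repair.
#' @param max_passes safety cap on optimization sweeps.
#' @return object of class `svc_fit`: `alpha`, `y`, `C`, `t` (bias),
#'   `support` (indices with `alpha > 1e-8`), `objective` (attained dual
#'   value), plus the (repaired) training kernel.
#' @examples
#' K <- kernel_matrix(matrix(c(1, -1, -1, 1), 2), "train")
#' fit <- fit_svc_precomputed(K, c(1, -1), C = 10)
#' fit$alpha  # 0.5 0.5
#' @export
fit_svc_precomputed <- function(K, y, C, tol = 1e-8, psd_tol = 1e-8,
                                max_passes = 200000L) {
  Km <- if (inherits(K, "kernel_matrix")) {
    if (K$kind != "train") stop("a train-kind kernel is required", call. = FALSE)
    K$values
  } else as.matrix(K)
  if (nrow(Km) != ncol(Km)) stop("train kernel must be square", call. = FALSE)
  y <- canonicalize_labels(y)$labels
  n <- length(y)
  if (n != nrow(Km)) stop("label length does not match kernel size", call. = FALSE)
  if (length(unique(y)) < 2L) stop("single-class labels: nothing to separate", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stop("C must be > 0", call. = FALSE)

  ## symmetrize + PSD repair
  Km <- (Km + t(Km)) / 2
  ev <- eigen(Km, symmetric = TRUE)
  lam_min <- min(ev$values)
  if (lam_min < -psd_tol)
    stop(sprintf("kernel is not PSD (min eigenvalue %.3g < -%.1g)", lam_min, psd_tol),
         call. = FALSE)
  if (lam_min < 0) {
    ## dust below 1e-13 is clipped silently; anything larger gets a warning
    if (lam_min < -1e-13)
      warning(sprintf("clipping %d slightly negative kernel eigenvalues (min %.3g) to zero",
                      sum(ev$values < 0), lam_min))
    Km <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    Km <- (Km + t(Km)) / 2
  }

  alpha <- numeric(n)
  f <- numeric(n)           # f_i = sum_j alpha_j y_j K_ij
  Fv <- function() f - y    # Keerthi's F_i
  passes <- 0L
  repeat {
    passes <- passes + 1L
    Fi <- f - y
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == -1 & alpha < C - 1e-12) | (y == 1 & alpha > 1e-12)
    if (!any(up) || !any(lo)) break
    i_up <- which(up)[which.min(Fi[up])]
    i_lo <- which(lo)[which.max(Fi[lo])]
    if (Fi[i_lo] - Fi[i_up] < 2 * tol || passes > max_passes) break
    step <- smo_pair_step(alpha, f, y, Km, C, i_lo, i_up)
    alpha <- step$alpha; f <- step$f
  }

  obj <- sum(alpha) - 0.5 * sum((alpha * y) * (Km %*% (alpha * y)))
  ## bias from unbounded support vectors: y_i (f_i - t) = 1 -> t = f_i - y_i
  free_sv <- which(alpha > 1e-8 & alpha < C - 1e-8)
  t_bias <- if (length(free_sv)) mean(f[free_sv] - y[free_sv]) else {
    Fi <- f - y
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == -1 & alpha < C - 1e-12) | (y == 1 & alpha > 1e-12)
    b_up <- if (any(up)) min(Fi[up]) else 0
    b_lo <- if (any(lo)) max(Fi[lo]) else 0
    (b_up + b_lo) / 2
  }

  structure(list(alpha = alpha, y = y, C = C, t = t_bias,
                 support = which(alpha > 1e-8), objective = obj,
                 kernel = Km, n = n,
                 majority = if (sum(y == 1) > sum(y == -1)) 1L else -1L),
            class = "svc_fit")
}

## analytic two-variable SMO update (Platt), indices i1, i2
smo_pair_step <- function(alpha, f, y, Km, C, i1, i2) {
  if (i1 == i2) return(list(alpha = alpha, f = f))
  E1 <- f[i1] - y[i1]; E2 <- f[i2] - y[i2]
  s <- y[i1] * y[i2]
  if (s < 0) {
    L <- max(0, alpha[i2] - alpha[i1]); H <- min(C, C + alpha[i2] - alpha[i1])
  } else {
    L <- max(0, alpha[i1] + alpha[i2] - C); H <- min(C, alpha[i1] + alpha[i2])
  }
  if (H - L < 1e-15) return(list(alpha = alpha, f = f))
  eta <- Km[i1, i1] + Km[i2, i2] - 2 * Km[i1, i2]
  a2_old <- alpha[i2]
  a2 <- if (eta > 1e-15) {
    min(max(a2_old + y[i2] * (E1 - E2) / eta, L), H)
  } else {
    ## flat direction: move to the endpoint with the better objective
    obj_at <- function(a2v) {
      a1v <- alpha[i1] + s * (a2_old - a2v)
      d1 <- (a1v - alpha[i1]) * y[i1]; d2 <- (a2v - a2_old) * y[i2]
      (a1v - alpha[i1]) + (a2v - a2_old) -
        (d1 * f[i1] + d2 * f[i2]) -
        0.5 * (d1^2 * Km[i1, i1] + d2^2 * Km[i2, i2] + 2 * d1 * d2 * Km[i1, i2])
    }
    if (obj_at(L) >= obj_at(H)) L else H
  }
  a1 <- alpha[i1] + s * (a2_old - a2)
  d1 <- (a1 - alpha[i1]) * y[i1]
  d2 <- (a2 - a2_old) * y[i2]
  f <- f + d1 * Km[, i1] + d2 * Km[, i2]
  alpha[i1] <- a1; alpha[i2] <- a2
  list(alpha = alpha, f = f)
}

#' @export
print.svc_fit <- function(x, ...) {
  cat(sprintf("<svc_fit> n = %d, C = %g, %d support vectors, dual objective %.6g\n",
              x$n, x$C, length(x$support), x$objective))
  invisible(x)
}

#' @export
coef.svc_fit <- function(object, ...) {
  c(stats::setNames(object$alpha, sprintf("alpha%d", seq_len(object$n))),
    t = object$t)
}

#' Predict labels from a cross kernel
#'
#' Decision value `sum_k alpha_k y_k K(x, x_k) - t`; the label is its sign. A
#' decision value of exactly zero resolves to the majority training class
#' (documented tie rule).
#'
#' @param object an `svc_fit`.
#' @param K_cross a cross-kind [kernel_matrix()] (rows = new samples, columns
#'   aligned with the training samples) or plain matrix.
#' @param decision_values if TRUE return the raw decision values.
#' @param ... unused.
#' @return integer labels in -1/+1 (or decision values).
#' @export
predict.svc_fit <- function(object, K_cross, decision_values = FALSE, ...) {
  Kc <- if (inherits(K_cross, "kernel_matrix")) K_cross$values else as.matrix(K_cross)
  if (ncol(Kc) != object$n)
    stop(sprintf("cross kernel has %d columns but the model was trained on %d samples",
                 ncol(Kc), object$n), call. = FALSE)
  dec <- as.vector(Kc %*% (object$alpha * object$y)) - object$t
  if (decision_values) return(dec)
  out <- ifelse(dec > 0, 1L, ifelse(dec < 0, -1L, object$majority))
  as.integer(out)
}
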