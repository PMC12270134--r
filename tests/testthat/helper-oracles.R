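# Independent oracles used across the suite. These deliberately avoid the
# package's gate primitives: the statevector oracle builds the commuting
# phase block as an explicit 2^n diagonal table from bit arithmetic and
# applies the Hadamard layer as a dense kronecker-product matrix.

oracle_bits <- function(b, n) as.integer(intToBits(b))[seq_len(n)]

oracle_state <- function(u, n, reps, single_map = function(x) 2 * x,
                         pair_map = function(a, b) (pi - a) * (pi - b),
                         pairs = NULL) {
  if (is.null(pairs) && n >= 2) {
    cmb <- utils::combn(n, 2)
    pairs <- cbind(cmb[1, ], cmb[2, ])
  }
  N <- 2^n
  H1 <- matrix(c(1, 1, 1, -1), 2) / sqrt(2)
  H <- Reduce(kronecker, rep(list(H1), n))
  phi_s <- single_map(u)
  theta <- vapply(0:(N - 1), function(b) {
    bits <- oracle_bits(b, n)
    z <- 1 - 2 * bits
    th <- sum(phi_s * z)
    if (!is.null(pairs) && nrow(pairs) > 0) {
      for (p in seq_len(nrow(pairs))) {
        j <- pairs[p, 1]; k <- pairs[p, 2]
        th <- th + pair_map(u[j], u[k]) * z[j] * z[k]
      }
    }
    th
  }, numeric(1))
  s <- c(1, rep(0, N - 1)) + 0i
  for (l in seq_len(reps)) s <- exp(1i * theta) * as.vector(H %*% s)
  s
}

oracle_fidelity <- function(u, v, n, reps) {
  Mod(sum(Conj(oracle_state(v, n, reps)) * oracle_state(u, n, reps)))^2
}

# F1 from raw counts, written out independently of compute_metrics()
oracle_f1 <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == -1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

# direct MCC formula on a 2x2 table
oracle_mcc <- function(TP, TN, FP, FN) {
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
}

# dual objective for given alpha on a precomputed kernel
dual_objective <- function(alpha, y, K) {
  sum(alpha) - 0.5 * sum((alpha * y) * (K %*% (alpha * y)))
}

# well-separated two-class toy in the plane
make_sep_toy <- function(n_per = 10, gap = 4, seed = 1) {
  withr_seed <- function(s, e) qembed:::with_seed(s, e)
  withr_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2, sd = 0.5), ncol = 2),
               matrix(rnorm(n_per * 2, sd = 0.5), ncol = 2))
    x[seq_len(n_per), 1] <- x[seq_len(n_per), 1] + gap / 2
    x[n_per + seq_len(n_per), 1] <- x[n_per + seq_len(n_per), 1] - gap / 2
    labeled_dataset(x, c(rep(1, n_per), rep(-1, n_per)))
  })
}

# mean intra-class minus mean inter-class fidelity of a kernel matrix
fidelity_margin <- function(K, labels) {
  same <- outer(labels, labels, `==`)
  diag(same) <- NA
  intra <- mean(K[which(same)], na.rm = TRUE)
  inter <- mean(K[which(!same)])
  intra - inter
}

# strip class/attributes from a statevector for bare numeric comparison
amps <- function(s) { attributes(s) <- NULL; s }
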