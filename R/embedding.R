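#' Quantum feature-map configuration
#'
#' Describes the IQP-style embedding circuit used throughout the package: each
#' of `reps` repetitions applies a layer of Hadamard gates to every qubit
#' followed by the commuting diagonal phase block
#' `exp(i * sum_k phi_k Z_k + i * sum_{j<k} phi_jk Z_j Z_k)`. Two-qubit phases
#' are realised in the gate path as CNOT-RZ-CNOT. The default mapping
#' functions are `phi_k(u) = 2 u_k` and `phi_jk(u) = (pi - u_j)(pi - u_k)`,
#' the standard ZZ feature map. The phase convention is fixed once:
#' `exp(i phi Z)` acts as the diagonal `(e^{+i phi}, e^{-i phi})` with qubit
#' value 0 in the +1 eigenspace of Z.
#'
#' Basis order of statevectors is lexicographic with qubit 1 as the least
#' significant bit of the basis index.
#'
#' @param n_qubits number of qubits (1 to 14).
#' @param reps number of Hadamard + phase repetitions (default 3).
#' @param single_map vectorized function `u -> phi_k` per coordinate.
#' @param pair_map vectorized function `(u_j, u_k) -> phi_jk`.
#' @param topology `"full"` (all pairs j < k, matching the double sum of the
#'   embedding unitary) or `"linear"` (consecutive pairs only).
#' @param single_jacobian,pair_jacobian optional analytic derivatives of the
#'   maps (used by gradient-based training); when omitted for non-default
#'   maps, central finite differences are used.
#' @return An object of class `embedding_config`.
#' @examples
#' cfg <- embedding_config(2)
#' state_fidelity(c(0.1, 0.7), c(0.1, 0.7), cfg)  # 1
#' @export
embedding_config <- function(n_qubits, reps = 3,
                             single_map = NULL, pair_map = NULL,
                             topology = c("full", "linear"),
                             single_jacobian = NULL, pair_jacobian = NULL) {
  n_qubits <- stop_if_not_count(n_qubits, "n_qubits")
  reps <- stop_if_not_count(reps, "reps")
  if (n_qubits > 14L)
    stop("n_qubits > 14 exceeds the desk-scale statevector limit", call. = FALSE)
  topology <- match.arg(topology)
  default_single <- is.null(single_map)
  default_pair <- is.null(pair_map)
  single_map <- single_map %||% function(u) 2 * u
  pair_map <- pair_map %||% function(uj, uk) (pi - uj) * (pi - uk)

  pairs <- if (n_qubits >= 2L) {
    if (topology == "full") {
      idx <- utils::combn(n_qubits, 2L)
      cbind(j = idx[1L, ], k = idx[2L, ])
    } else {
      cbind(j = seq_len(n_qubits - 1L), k = seq_len(n_qubits - 1L) + 1L)
    }
  } else {
    matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("j", "k")))
  }

  N <- 2L^n_qubits
  b <- 0:(N - 1L)
  ## z_q(basis) = +1 when bit (q-1) is 0
  zmat <- vapply(seq_len(n_qubits),
                 function(q) 1 - 2 * (bitwAnd(b, bitwShiftL(1L, q - 1L)) > 0L),
                 numeric(N))
  zmat <- matrix(zmat, N, n_qubits)
  zzmat <- if (nrow(pairs) > 0L)
    vapply(seq_len(nrow(pairs)),
           function(p) zmat[, pairs[p, 1L]] * zmat[, pairs[p, 2L]],
           numeric(N))
  else matrix(numeric(0), N, 0L)
  zzmat <- matrix(zzmat, N, nrow(pairs))

  structure(list(n_qubits = n_qubits, reps = reps,
                 single_map = single_map, pair_map = pair_map,
                 topology = topology, pairs = pairs,
                 zmat = zmat, zzmat = zzmat,
                 default_single = default_single, default_pair = default_pair,
                 single_jacobian = single_jacobian, pair_jacobian = pair_jacobian),
            class = "embedding_config")
}

#' @export
print.embedding_config <- function(x, ...) {
  cat(sprintf("<embedding_config> %d qubits, %d reps, %s topology, %d pair terms\n",
              x$n_qubits, x$reps, x$topology, nrow(x$pairs)))
  invisible(x)
}

#' Map a feature vector to circuit angles
#'
#' Evaluates the single-qubit and pair mapping functions of an embedding
#' configuration on one feature vector.
#'
#' @param u numeric vector of length `n_qubits`.
#' @param config an [embedding_config()].
#' @return list with `single` (length `n_qubits`) and `pair` (one angle per
#'   pair in the topology, ordered as `config$pairs`).
#' @examples
#' ma <- map_angles(c(0, 0), embedding_config(2))
#' ma$pair  # pi^2
#' @export
map_angles <- function(u, config) {
  check_embed_input(u, config)
  single <- as.numeric(config$single_map(u))
  if (length(single) != config$n_qubits)
    stop("single_map must return one angle per qubit", call. = FALSE)
  pair <- if (nrow(config$pairs) > 0L)
    as.numeric(config$pair_map(u[config$pairs[, 1L]], u[config$pairs[, 2L]]))
  else numeric(0)
  list(single = single, pair = pair)
}

check_embed_input <- function(u, config) {
  stopifnot(inherits(config, "embedding_config"))
  if (length(u) != config$n_qubits)
    stop(sprintf("feature vector length %d does not match n_qubits = %d",
                 length(u), config$n_qubits), call. = FALSE)
  if (anyNA(u) || any(!is.finite(u)))
    stop("feature vector contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

## ---- gate primitives on a complex statevector (qubit q -> bit q-1) ----

apply_h_gate <- function(state, q) {
  n <- as.integer(round(log2(length(state))))
  N <- length(state)
  bit <- bitwShiftL(1L, q - 1L)
  b <- 0:(N - 1L)
  i0 <- which(bitwAnd(b, bit) == 0L)
  i1 <- i0 + bit
  a0 <- state[i0]; a1 <- state[i1]
  s <- 1 / sqrt(2)
  state[i0] <- (a0 + a1) * s
  state[i1] <- (a0 - a1) * s
  state
}

## exp(i * phi * Z_q): e^{+i phi} on bit 0, e^{-i phi} on bit 1
apply_z_phase <- function(state, q, phi) {
  N <- length(state)
  bit <- bitwShiftL(1L, q - 1L)
  z <- 1 - 2 * (bitwAnd(0:(N - 1L), bit) > 0L)
  state * exp(1i * phi * z)
}

apply_cnot <- function(state, control, target) {
  N <- length(state)
  b <- 0:(N - 1L)
  cbit <- bitwShiftL(1L, control - 1L)
  tbit <- bitwShiftL(1L, target - 1L)
  sel <- which(bitwAnd(b, cbit) > 0L & bitwAnd(b, tbit) == 0L)
  flip <- sel + tbit
  tmp <- state[sel]
  state[sel] <- state[flip]
  state[flip] <- tmp
  state
}

hadamard_layer <- function(state, n) {
  for (q in seq_len(n)) state <- apply_h_gate(state, q)
  state
}

## one phase block via explicit gates: RZ-type phases, pair phases as
## CNOT - RZ - CNOT (target carries z_j z_k after the first CNOT)
phase_block_gates <- function(state, angles, config) {
  for (q in seq_len(config$n_qubits))
    state <- apply_z_phase(state, q, angles$single[q])
  if (nrow(config$pairs) > 0L) {
    for (p in seq_len(nrow(config$pairs))) {
      j <- config$pairs[p, 1L]; k <- config$pairs[p, 2L]
      state <- apply_cnot(state, j, k)
      state <- apply_z_phase(state, k, angles$pair[p])
      state <- apply_cnot(state, j, k)
    }
  }
  state
}

## the same diagonal as a 2^n phase vector theta_b (radians)
phase_diagonal <- function(angles, config) {
  th <- as.vector(config$zmat %*% angles$single)
  if (length(angles$pair)) th <- th + as.vector(config$zzmat %*% angles$pair)
  th
}

#' Prepare the embedded statevector of a feature vector
#'
#' Applies `reps` repetitions of (Hadamard layer, diagonal phase block) to
#' `|0...0>`, with two-qubit phases realised as CNOT-RZ-CNOT.
#'
#' @inheritParams map_angles
#' @return complex vector of `2^n_qubits` amplitudes (class `statevector`,
#'   attribute `n_qubits`), lexicographic basis order, qubit 1 = least
#'   significant bit.
#' @export
prepare_state <- function(u, config) {
  check_embed_input(u, config)
  angles <- map_angles(u, config)
  state <- c(1 + 0i, rep(0 + 0i, 2L^config$n_qubits - 1L))
  for (l in seq_len(config$reps)) {
    state <- hadamard_layer(state, config$n_qubits)
    state <- phase_block_gates(state, angles, config)
  }
  structure(state, class = "statevector", n_qubits = config$n_qubits)
}

## inverse circuit: conjugate phases then Hadamard, reps times (adjoint of
## prepare_state's unitary)
unprepare_state <- function(state, u, config) {
  angles <- map_angles(u, config)
  th <- phase_diagonal(angles, config)
  for (l in seq_len(config$reps)) {
    state <- state * exp(-1i * th)
    state <- hadamard_layer(state, config$n_qubits)
  }
  state
}

#' Fidelity between two embedded states
#'
#' `|<0...0| U(v)^dagger U(u) |0...0>|^2`, computed from exact statevectors.
#' This is the quantum kernel value `K(u, v)`; it is symmetric in its
#' arguments and lies in `[0, 1]`.
#'
#' @param u,v feature vectors of length `n_qubits`.
#' @inheritParams map_angles
#' @return scalar fidelity in `[0, 1]`.
#' @examples
#' cfg <- embedding_config(1, reps = 1)
#' state_fidelity(0.3, 0.3 + pi / 4, cfg)  # cos^2(2 * pi/4) = 0
#' @export
state_fidelity <- function(u, v, config) {
  su <- prepare_state(u, config)
  sv <- prepare_state(v, config)
  f <- Mod(sum(Conj(unclass(sv)) * unclass(su)))^2
  min(max(f, 0), 1)
}

#' Shot-sampled fidelity estimate
#'
#' Mirrors hardware semantics of the compute-uncompute overlap test: prepares
#' `U(v)^dagger U(u) |0...0>`, draws `shots` computational-basis measurement
#' outcomes, and returns the observed frequency of the all-zeros outcome — an
#' unbiased estimator of [state_fidelity()].
#'
#' @inheritParams state_fidelity
#' @param shots number of measurement shots (>= 1).
#' @param seed integer seed for the sampling draw.
#' @return scalar estimate in `[0, 1]`.
#' @export
sampled_fidelity <- function(u, v, config, shots, seed = NULL) {
  shots <- stop_if_not_count(shots, "shots")
  state <- unprepare_state(unclass(prepare_state(u, config)), v, config)
  p <- Mod(state)^2
  p <- p / sum(p)
  with_seed(seed, {
    outcomes <- sample.int(length(p), shots, replace = TRUE, prob = p)
    mean(outcomes == 1L)
  })
}

#' Dump statevector amplitudes to CSV
#'
#' Debug helper: writes basis index (and bitstring), real and imaginary part.
#' @param state a `statevector` from [prepare_state()].
#' @param path output CSV path.
#' @export
write_statevector_csv <- function(state, path) {
  n <- attr(state, "n_qubits")
  idx <- 0:(length(state) - 1L)
  bits <- vapply(idx, function(b)
    paste(rev(as.integer(intToBits(b))[seq_len(n)]), collapse = ""), character(1))
  utils::write.csv(data.frame(index = idx, bitstring = bits,
                              re = Re(state), im = Im(state)),
                   path, row.names = FALSE)
  invisible(path)
}

## ---- fast internal paths used by kernels and NQE training ----

## forward pass caching the per-repetition states (diagonal-phase form; equal
## to the gate path because the phase block is diagonal)
embed_forward_cached <- function(u, config) {
  angles <- map_angles(u, config)
  th <- phase_diagonal(angles, config)
  ph <- exp(1i * th)
  s <- c(1 + 0i, rep(0 + 0i, 2L^config$n_qubits - 1L))
  s_list <- vector("list", config$reps)
  for (l in seq_len(config$reps)) {
    s <- hadamard_layer(s, config$n_qubits) * ph
    s_list[[l]] <- s
  }
  list(psi = s, s_list = s_list, ph = ph, angles = angles)
}

## matrix of embedded states, one column per row of `x`
prepare_states_matrix <- function(x, config) {
  x <- as.matrix(x)
  vapply(seq_len(nrow(x)),
         function(i) embed_forward_cached(x[i, ], config)$psi,
         complex(2L^config$n_qubits))
}

## Jacobians of the mapping functions: dsingle (n x d), dpair (n_pairs x d)
angle_jacobian <- function(u, config) {
  n <- config$n_qubits
  if (config$default_single) {
    dsingle <- diag(2, n, n)
  } else if (!is.null(config$single_jacobian)) {
    dsingle <- config$single_jacobian(u)
  } else {
    dsingle <- numeric_jacobian(function(uu) as.numeric(config$single_map(uu)), u, n)
  }
  npair <- nrow(config$pairs)
  if (npair == 0L) {
    dpair <- matrix(0, 0L, n)
  } else if (config$default_pair) {
    dpair <- matrix(0, npair, n)
    for (p in seq_len(npair)) {
      j <- config$pairs[p, 1L]; k <- config$pairs[p, 2L]
      dpair[p, j] <- -(pi - u[k])
      dpair[p, k] <- -(pi - u[j])
    }
  } else if (!is.null(config$pair_jacobian)) {
    dpair <- config$pair_jacobian(u)
  } else {
    dpair <- numeric_jacobian(function(uu)
      as.numeric(config$pair_map(uu[config$pairs[, 1L]], uu[config$pairs[, 2L]])),
      u, npair)
  }
  list(dsingle = dsingle, dpair = dpair)
}

numeric_jacobian <- function(f, u, m, h = 1e-6) {
  J <- matrix(0, m, length(u))
  for (i in seq_along(u)) {
    up <- u; up[i] <- up[i] + h
    dn <- u; dn[i] <- dn[i] - h
    J[, i] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

## fidelity F(u, v) and its exact gradients with respect to both embedded
## feature vectors (adjoint differentiation through the repetition structure)
fidelity_with_grad <- function(u, v, config) {
  fu <- embed_forward_cached(u, config)
  fv <- embed_forward_cached(v, config)
  cc <- sum(Conj(fv$psi) * fu$psi)       # <psi_v | psi_u>
  gu <- overlap_grad_side(fu, fv$psi, u, config)      # <psi_v | d psi_u / du>
  gvc <- overlap_grad_side(fv, fu$psi, v, config)     # <psi_u | d psi_v / dv>
  f <- Mod(cc)^2
  list(fidelity = min(max(f, 0), 1),
       grad_u = 2 * Re(Conj(cc) * gu),
       grad_v = 2 * Re(Conj(cc) * Conj(gvc)))
}

## g_m = <psi_other | d psi / d u_m>; uses dtheta/du_m = zmat dsingle + zzmat dpair
overlap_grad_side <- function(fwd, psi_other, u, config) {
  L <- config$reps
  n <- config$n_qubits
  jac <- angle_jacobian(u, config)
  Dmat <- config$zmat %*% jac$dsingle
  if (nrow(config$pairs) > 0L) Dmat <- Dmat + config$zzmat %*% jac$dpair
  w <- psi_other
  e <- complex(length(psi_other))
  for (l in rev(seq_len(L))) {
    e <- e + Conj(w) * fwd$s_list[[l]]
    if (l > 1L) {                       # w_{l-1} = R_l^dagger w_l
      w <- w * Conj(fwd$ph)
      w <- hadamard_layer(w, n)
    }
  }
  1i * as.vector(t(Dmat) %*% e)
}
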