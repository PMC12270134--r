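#' Synthetic two-class expression data
#'
#' Draws a labeled dataset of two overlapping multivariate Gaussian classes,
#' emulating the statistical shape of the renal-carcinoma metastasis cohorts
#' that motivate this package: a majority (non-metastatic, internal label -1)
#' and a minority (metastatic, +1) class with imbalance near 5.44:1, tens of
#' features reducible by PCA to a handful of components, and a tunable degree
#' of class overlap. The two class means are placed at `+/- separation/2`
#' along the first coordinate; covariance is shared and diagonal by default.
#'
#' @param n_major,n_minor class sizes (majority maps to internal label -1).
#' @param d number of features.
#' @param separation Euclidean distance between the class mean vectors
#'   (0 = indistinguishable classes).
#' @param covariance either a single scalar (isotropic variance), a length-`d`
#'   vector (diagonal), or a `d x d` positive semidefinite matrix, shared by
#'   both classes.
#' @param seed integer seed; the draw is fully determined by it.
#' @return A [labeled_dataset()].
#' @examples
#' ds <- generate_two_class(n_major = 424, n_minor = 78, d = 48, seed = 1)
#' class_ratio <- sum(ds$labels == -1) / sum(ds$labels == 1)  # ~5.44
#' @export
generate_two_class <- function(n_major, n_minor, d = 48, separation = 1,
                               covariance = 1, seed = NULL) {
  n_major <- stop_if_not_count(n_major, "n_major")
  n_minor <- stop_if_not_count(n_minor, "n_minor")
  d <- stop_if_not_count(d, "d")
  if (!is.numeric(separation) || separation < 0)
    stop("separation must be a nonnegative scalar", call. = FALSE)
  R <- covariance_factor(covariance, d)

  mu_major <- c(-separation / 2, rep(0, d - 1L))[seq_len(d)]
  mu_minor <- c(+separation / 2, rep(0, d - 1L))[seq_len(d)]

  with_seed(seed, {
    zmaj <- matrix(stats::rnorm(n_major * d), n_major, d)
    zmin <- matrix(stats::rnorm(n_minor * d), n_minor, d)
    xmaj <- sweep(zmaj %*% R, 2L, mu_major, `+`)
    xmin <- sweep(zmin %*% R, 2L, mu_minor, `+`)
    labeled_dataset(rbind(xmaj, xmin),
                    c(rep(-1L, n_major), rep(1L, n_minor)),
                    sample_ids = sprintf("s%04d", seq_len(n_major + n_minor)))
  })
}

## upper-triangular factor R with t(R) %*% R = Sigma; validates PSD
covariance_factor <- function(covariance, d) {
  if (is.matrix(covariance)) {
    if (nrow(covariance) != d || ncol(covariance) != d)
      stop(sprintf("covariance matrix must be %d x %d", d, d), call. = FALSE)
    if (max(abs(covariance - t(covariance))) > 1e-10)
      stop("covariance matrix must be symmetric", call. = FALSE)
    ev <- eigen(covariance, symmetric = TRUE)
    if (min(ev$values) < -1e-10 * max(abs(ev$values), 1))
      stop(sprintf("covariance is not positive semidefinite (min eigenvalue %.3g)",
                   min(ev$values)), call. = FALSE)
    vals <- pmax(ev$values, 0)
    return(t(ev$vectors %*% (sqrt(vals) * t(ev$vectors))))
  }
  if (length(covariance) == 1L) covariance <- rep(covariance, d)
  if (length(covariance) != d)
    stop(sprintf("diagonal covariance must have length 1 or %d", d), call. = FALSE)
  if (any(covariance < 0))
    stop("covariance is not positive semidefinite (negative diagonal entry)", call. = FALSE)
  diag(sqrt(covariance), d, d)
}

## exact class densities of the generator, for Bayes-rate oracles in tests
generator_log_density_ratio <- function(x, d, separation, covariance = 1) {
  R <- covariance_factor(covariance, d)
  sigma <- t(R) %*% R
  mu_major <- c(-separation / 2, rep(0, d - 1L))[seq_len(d)]
  mu_minor <- c(+separation / 2, rep(0, d - 1L))[seq_len(d)]
  si <- solve(sigma)
  q <- function(x, mu) {
    xc <- sweep(x, 2L, mu)
    rowSums((xc %*% si) * xc)
  }
  0.5 * (q(x, mu_major) - q(x, mu_minor))  # log p_minor(x) - log p_major(x)
}
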