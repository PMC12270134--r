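test_that("zero-initialized network embeds every sample identically", {
  m <- nqe_model(3, init = "zero")
  expect_equal(nqe_forward(c(1, -2, 5), m), c(0, 0, 0))
  expect_equal(nqe_forward(c(0.1, 0.2, 0.3), m), c(0, 0, 0))
  cfg <- embedding_config(3)
  expect_equal(state_fidelity(nqe_forward(c(1, -2, 5), m),
                              nqe_forward(c(9, 9, 9), m), cfg), 1)
})

test_that("near-identity passthrough reduces the embedding to the raw feature map", {
  d <- 2
  eps <- 1e-4
  m <- nqe_model(d, hidden = d)
  m$W1 <- diag(eps, d); m$b1 <- numeric(d)
  m$W2 <- diag(1 / eps, d); m$b2 <- numeric(d)
  cfg <- embedding_config(d)
  set.seed(40)
  for (i in 1:10) {
    u <- runif(d); v <- runif(d)
    expect_equal(state_fidelity(nqe_forward(u, m), nqe_forward(v, m), cfg),
                 state_fidelity(u, v, cfg), tolerance = 1e-5)
  }
  ## repeated calls are deterministic
  expect_identical(nqe_forward(u, m), nqe_forward(u, m))
})

test_that("pair loss attains its analytic limits", {
  cfg <- embedding_config(1)
  z <- nqe_model(1, init = "zero")
  ## identical embedded states: same label -> 0, different labels -> 1
  expect_equal(pair_loss(0.3, 0.9, 1, 1, z, cfg), 0, tolerance = 1e-12)
  expect_equal(pair_loss(0.3, 0.9, 1, -1, z, cfg), 1, tolerance = 1e-12)
  ## orthogonal embedded states with the same label -> 1; tanh passthrough
  ## with atanh-coded inputs gives exactly orthogonal 1-qubit states
  cfg1 <- embedding_config(1, reps = 1)
  lin <- nqe_model(1, hidden = 1)
  lin$W1 <- matrix(1); lin$b1 <- 0; lin$W2 <- matrix(1); lin$b2 <- 0
  a <- 0.5; b <- 0.5 - pi / 4
  expect_equal(state_fidelity(tanh(atanh(a)), tanh(atanh(b)), cfg1), 0,
               tolerance = 1e-12)
  expect_equal(pair_loss(atanh(a), atanh(b), 1, 1, lin, cfg1), 1, tolerance = 1e-10)
  expect_error(pair_loss(0.3, 0.9, 1, 0, z, cfg), "-1/\\+1")
})

test_that("analytic training gradient matches central finite differences", {
  set.seed(41)
  d <- 2
  cfg <- embedding_config(d)
  m <- nqe_model(d, seed = 42)
  xj <- runif(d); xk <- runif(d)
  yj <- 1; yk <- -1
  ## analytic gradient assembled from the training internals
  cj <- qembed:::nqe_net_forward(m, xj)
  ck <- qembed:::nqe_net_forward(m, xk)
  fg <- qembed:::fidelity_with_grad(cj$out, ck$out, cfg)
  gF <- 2 * (fg$fidelity - 0.5 * (1 + yj * yk))
  bj <- qembed:::nqe_net_backward(m, xj, cj, gF * fg$grad_u)
  bk <- qembed:::nqe_net_backward(m, xk, ck, gF * fg$grad_v)
  analytic <- list(W1 = bj$W1 + bk$W1, b1 = bj$b1 + bk$b1,
                   W2 = bj$W2 + bk$W2, b2 = bj$b2 + bk$b2)
  ## numeric gradient of pair_loss by weight perturbation
  h <- 1e-6
  for (field in c("W1", "b1", "W2", "b2")) {
    num <- analytic[[field]]
    for (i in seq_along(num)) {
      mp <- m; mp[[field]][i] <- mp[[field]][i] + h
      mm <- m; mm[[field]][i] <- mm[[field]][i] - h
      num[i] <- (pair_loss(xj, xk, yj, yk, mp, cfg) -
                   pair_loss(xj, xk, yj, yk, mm, cfg)) / (2 * h)
    }
    scale <- max(abs(analytic[[field]]), 1e-3)
    expect_lt(max(abs(analytic[[field]] - num)) / scale, 1e-4)
  }
})

test_that("constant-embedding initialization yields the different-label pair fraction", {
  ## at the zero-weight stationary point every same-label pair contributes 0
  ## and every different-label pair contributes 1, so the expected batch loss
  ## is the probability that an ordered random pair has different labels
  ds <- generate_two_class(30, 10, d = 2, separation = 2, seed = 43)
  p <- 10 / 40
  expected <- 2 * p * (1 - p)
  z <- nqe_model(2, init = "zero")
  m <- train_nqe(ds, model = z,
                 config = nqe_train_config(iterations = 1000, batch_size = 10,
                                           seed = 44))
  expect_lt(abs(mean(m$loss_history) - expected), 0.02)
  ## the stationary point is preserved: weights stay exactly zero
  expect_equal(m$W1, z$W1)
})

test_that("training is seeded, bounded, and descends on separable data", {
  ds <- generate_two_class(15, 15, d = 2, separation = 3, covariance = 0.25,
                           seed = 45)
  m0 <- nqe_model(2, seed = 46)
  fit <- train_nqe(ds, model = m0, config = nqe_train_config(iterations = 200,
                                                             seed = 47))
  expect_length(fit$loss_history, 200)
  expect_true(all(fit$loss_history >= 0 & fit$loss_history <= 1))
  expect_lt(mean(fit$loss_history[151:200]), mean(fit$loss_history[1:50]))
  ## same seed -> identical run; iterations = 0 -> unchanged model
  fit2 <- train_nqe(ds, model = m0, config = nqe_train_config(iterations = 200,
                                                              seed = 47))
  expect_identical(fit$W1, fit2$W1)
  expect_identical(fit$loss_history, fit2$loss_history)
  un <- train_nqe(ds, model = m0, config = nqe_train_config(iterations = 0, seed = 1))
  expect_identical(un, m0)
  one_class <- labeled_dataset(matrix(rnorm(6), 3), rep(1, 3))
  expect_error(train_nqe(one_class), "both classes")
})

test_that("training increases the intra- vs inter-class fidelity margin", {
  ds <- generate_two_class(15, 15, d = 2, separation = 3, covariance = 0.25,
                           seed = 48)
  cfg <- embedding_config(2)
  K_pre <- quantum_kernel_matrix(ds, embed_config = cfg)$values
  fit <- train_nqe(ds, config = nqe_train_config(iterations = 400, seed = 49),
                   embed_config = cfg)
  K_post <- quantum_kernel_matrix(ds, nqe = fit, embed_config = cfg)$values
  expect_gt(fidelity_margin(K_post, ds$labels), fidelity_margin(K_pre, ds$labels))
})

test_that("model JSON persistence and loss CSV round-trip", {
  ds <- generate_two_class(8, 8, d = 2, separation = 2, seed = 50)
  fit <- train_nqe(ds, config = nqe_train_config(iterations = 5, seed = 51))
  f <- withr::local_tempfile(fileext = ".json")
  write_nqe_json(fit, f)
  back <- read_nqe_json(f)
  expect_equal(back$W1, fit$W1, tolerance = 1e-15)
  expect_equal(nqe_forward(c(0.1, 0.2), back), nqe_forward(c(0.1, 0.2), fit))
  g <- withr::local_tempfile(fileext = ".csv")
  write_loss_history_csv(fit, g)
  expect_equal(read.csv(g)$loss, fit$loss_history)
})
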