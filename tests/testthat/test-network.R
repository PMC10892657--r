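# Network forward pass, parameter encoding, normalization, and the
# Levenberg-Marquardt trainer.

test_that("forward pass matches hand-computed values and symmetries", {
  # all weights zero, output bias 5 -> constant prediction
  p <- network_params(matrix(0, 13, 3), rep(0, 13), rep(0, 13), 5)
  expect_equal(nn_forward(p, matrix(rnorm(30), 10, 3)), rep(5, 10))

  # single unit: tanh(0.5) computed by hand
  p1 <- network_params(matrix(1, 1, 1), 0, 1, 0)
  expect_equal(nn_forward(p1, matrix(0.5)), tanh(0.5), tolerance = 1e-12)
  expect_equal(round(nn_forward(p1, matrix(0.5)), 5), 0.46212)

  # hidden-unit permutation leaves predictions unchanged
  set.seed(4)
  p <- init_network(3, 13, seed = 5)
  X <- matrix(rnorm(60), 20, 3)
  perm <- sample(13)
  pp <- network_params(p$W1[perm, ], p$b1[perm], p$W2[, perm], p$b2)
  expect_equal(nn_forward(pp, X), nn_forward(p, X))

  # tanh sign-flip symmetry of a hidden unit
  ps <- p
  ps$W1[1, ] <- -ps$W1[1, ]
  ps$b1[1] <- -ps$b1[1]
  ps$W2[1, 1] <- -ps$W2[1, 1]
  expect_equal(nn_forward(ps, X), nn_forward(p, X))

  expect_error(nn_forward(p, matrix(0, 2, 4)),
               class = "ringcast_argument_error")
})

test_that("flatten/unflatten is an exact inverse with the documented sizes", {
  expect_identical(n_network_params(3, 13), 66L)
  expect_identical(n_network_params(6, 13), 105L)
  for (k in c(1, 3, 6)) {
    p <- init_network(k, 13, seed = k)
    v <- flatten_params(p)
    expect_length(v, n_network_params(k, 13))
    expect_equal(unflatten_params(v, k, 13), p)
  }
  expect_error(unflatten_params(rep(0, 10), 3, 13),
               class = "ringcast_argument_error")
})

test_that("min-max normalization maps endpoints and inverts exactly", {
  set.seed(6)
  X <- matrix(rnorm(80, sd = 10), 20, 4)
  colnames(X) <- letters[1:4]
  r <- feature_ranges(X)
  Xn <- normalize_features(X, r)
  expect_equal(apply(Xn, 2, min), rep(-1, 4), ignore_attr = TRUE)
  expect_equal(apply(Xn, 2, max), rep(1, 4), ignore_attr = TRUE)
  mid <- matrix((r[1, ] + r[2, ]) / 2, nrow = 1)
  expect_equal(as.vector(normalize_features(mid, r)), rep(0, 4))
  expect_lt(max(abs(denormalize_features(Xn, r) - X)), 1e-12)

  X[, 2] <- 7  # constant column
  expect_error(normalize_features(X, feature_ranges(X)), "b",
               class = "ringcast_argument_error")
})

test_that("feature assembly has the canonical columns per scope", {
  prof <- fixed_profile(ring = 80.3, middle = 84.8)
  ser <- extract_angles(generate_session(prof, noiseless_config())[[1]])
  fi <- build_features(ser, mode = "individual")
  expect_identical(names(fi), c("theta1_deg", "omega1_deg_s", "alpha1_deg_s2",
                                "beta1_deg"))
  fm <- build_features(ser, prof, mode = "multi")
  expect_identical(names(fm),
                   c("theta1_deg", "omega1_deg_s", "alpha1_deg_s2",
                     "ring_length_mm", "middle_length_mm", "training_years",
                     "beta1_deg"))
  expect_true(all(fm$ring_length_mm == 80.3))
  expect_true(all(fm$middle_length_mm == 84.8))
  expect_error(build_features(ser, mode = "multi"),
               class = "ringcast_argument_error")
})

test_that("analytic Jacobian agrees with central differences", {
  set.seed(8)
  for (case in list(c(2, 3), c(3, 5), c(6, 4))) {
    k <- case[1]
    h <- case[2]
    p <- init_network(k, h, seed = k * 10 + h)
    X <- matrix(rnorm(6 * k), 6, k)
    J <- nn_jacobian(p, X)
    v <- flatten_params(p)
    eps <- 1e-6
    Jn <- vapply(seq_along(v), function(i) {
      vp <- v; vm <- v
      vp[i] <- vp[i] + eps
      vm[i] <- vm[i] - eps
      (nn_forward(unflatten_params(vp, k, h), X) -
         nn_forward(unflatten_params(vm, k, h), X)) / (2 * eps)
    }, numeric(6))
    expect_lt(max(abs(J - Jn)) / max(abs(Jn)), 1e-5)
  }
})

test_that("MSE gradient from the Jacobian matches finite differences", {
  set.seed(9)
  k <- 3; h <- 4
  p <- init_network(k, h, seed = 1)
  X <- matrix(rnorm(30), 10, k)
  y <- rnorm(10)
  v <- flatten_params(p)
  r <- nn_forward(p, X) - y
  g <- 2 * crossprod(nn_jacobian(p, X), r)[, 1] / 10
  mse_at <- function(w) mean((nn_forward(unflatten_params(w, k, h), X) - y)^2)
  eps <- 1e-6
  gn <- vapply(seq_along(v), function(i) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + eps
    vm[i] <- vm[i] - eps
    (mse_at(vp) - mse_at(vm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g - gn)), 1e-6)
})

test_that("LM training converges on representable targets with monotone loss", {
  # zero epochs: parameters unchanged
  p0 <- init_network(1, 13, seed = 2)
  x <- matrix(seq(-1, 1, length.out = 50), ncol = 1)
  y <- 2 * x[, 1] + 1
  same <- train_lm(p0, x, y, train_config(max_epochs = 0))
  expect_equal(same$params, p0)

  # noiseless linear target is fit essentially exactly
  fit <- train_lm(p0, x, y, train_config(max_epochs = 200))
  expect_lt(tail(fit$loss_history, 1), 1e-6)
  expect_true(all(diff(fit$loss_history) <= 0))

  # universal-approximation sanity case: sin on [-pi, pi], 13 hidden units
  xs <- matrix(seq(-pi, pi, length.out = 200), ncol = 1)
  fit2 <- train_lm(init_network(1, 13, seed = 1), xs, sin(xs[, 1]),
                   train_config(max_epochs = 300))
  expect_lt(tail(fit2$loss_history, 1), 1e-3)
  expect_true(all(diff(fit2$loss_history) <= 0))
})

test_that("the mini-batch gradient-descent trainer also reduces the loss", {
  prob <- tiny_sine_problem()
  cfg <- train_config(trainer = "sgd", max_epochs = 50, seed = 3)
  fit <- train_sgd(init_network(1, 13, seed = 3), prob$X, prob$y, cfg)
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1] / 2)
  # deterministic given the seed
  fit2 <- train_sgd(init_network(1, 13, seed = 3), prob$X, prob$y, cfg)
  expect_identical(fit$loss_history, fit2$loss_history)
})
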