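# GA and SSA optimizers: fitness plumbing, benchmark convergence, bound
# feasibility, determinism, and the seeded-training variants.

test_that("weight-vector fitness equals an independent two-line oracle", {
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  expect_equal(fitness_mse(rep(0, 66), X, rep(0, 20), 3), 0)
  # all-zero candidate predicts 0 everywhere -> MSE is mean(y^2)
  expect_equal(fitness_mse(rep(0, 66), X, y, 3), mean(y^2))
  v <- runif(66, -1, 1)
  oracle <- mean((nn_forward(unflatten_params(v, 3, 13), X) - y)^2)
  expect_equal(fitness_mse(v, X, y, 3), oracle)
  f <- make_mse_fitness(X, y, 3)
  expect_equal(f(v), oracle)
  expect_error(fitness_mse(rep(0, 10), X, y, 3),
               class = "ringcast_argument_error")
})

test_that("constant fitness yields a flat history at that constant", {
  ga <- ga_optimize(function(v) 7, 3,
                    ga_config(pop_size = 10, n_generations = 5, seed = 1))
  expect_true(all(ga$history == 7))
  expect_equal(ga$best_fitness, 7)
  ssa <- ssa_optimize(function(v) 7, 3,
                      ssa_config(pop_size = 10, n_iterations = 5, seed = 1))
  expect_true(all(ssa$history == 7))
})

test_that("GA locates the optimum of a 1-D quadratic", {
  hits <- vapply(1:20, function(s) {
    res <- ga_optimize(function(v) (v[1] - 2)^2, 1,
                       ga_config(bounds = c(-10, 10), seed = s))
    abs(res$best_vector[1] - 2) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("GA and SSA solve the 5-D sphere benchmark reliably", {
  sphere <- function(v) sum(v^2)
  ga_best <- vapply(1:20, function(s) {
    ga_optimize(sphere, 5, ga_config(bounds = c(-5, 5), seed = s))$best_fitness
  }, numeric(1))
  ssa_best <- vapply(1:20, function(s) {
    ssa_optimize(sphere, 5, ssa_config(bounds = c(-5, 5), seed = s))$best_fitness
  }, numeric(1))
  expect_gte(mean(ga_best < 1e-2), 0.9)
  expect_gte(mean(ssa_best < 1e-2), 0.9)
  # SSA should not underperform the GA's median on the same seeds
  expect_lte(median(ssa_best), median(ga_best))
})

test_that("histories are monotone and all candidates stay within bounds", {
  sphere <- function(v) sum(v^2)
  # record every evaluated candidate through the fitness closure
  for (alg in c("ga", "ssa")) {
    seen <- new.env()
    seen$worst <- -Inf
    probe <- function(v) {
      seen$worst <- max(seen$worst, max(abs(v)))
      sphere(v)
    }
    res <- if (alg == "ga") {
      ga_optimize(probe, 4, ga_config(pop_size = 20, n_generations = 30,
                                      bounds = c(-1, 1), seed = 2))
    } else {
      ssa_optimize(probe, 4, ssa_config(pop_size = 20, n_iterations = 30,
                                        bounds = c(-1, 1), seed = 2))
    }
    expect_true(all(diff(res$history) <= 0))
    expect_lte(seen$worst, 1)
    expect_equal(res$best_fitness, tail(res$history, 1))
  }
})

test_that("optimizers are deterministic given config and seed", {
  f <- function(v) sum((v - 1)^2)
  a <- ga_optimize(f, 3, ga_config(pop_size = 10, n_generations = 10, seed = 9))
  b <- ga_optimize(f, 3, ga_config(pop_size = 10, n_generations = 10, seed = 9))
  expect_identical(a, b)
  c1 <- ssa_optimize(f, 3, ssa_config(pop_size = 10, n_iterations = 10, seed = 9))
  c2 <- ssa_optimize(f, 3, ssa_config(pop_size = 10, n_iterations = 10, seed = 9))
  expect_identical(c1, c2)
})

test_that("seeded_training wires the variants and respects the budget", {
  prob <- tiny_sine_problem()
  tc <- train_config(max_epochs = 30)

  bp <- seeded_training(prob$X, prob$y, "bp", train = tc, seed = 1)
  expect_null(bp$opt)
  expect_s3_class(bp$params, "network_params")

  counter <- new.env(); counter$n <- 0L
  # instrumented upper bound on fitness evaluations: pop + pop * generations
  ga_small <- ga_config(pop_size = 10, n_generations = 5, seed = 1)
  d <- n_network_params(1, 13)
  probe <- function(v) { counter$n <- counter$n + 1L; sum(v^2) }
  res <- ga_optimize(probe, d, ga_small)
  expect_identical(counter$n, res$evaluations)
  expect_lte(res$evaluations, 10L + 10L * 5L)

  gabp <- seeded_training(prob$X, prob$y, "ga-bp", train = tc,
                          ga = ga_config(pop_size = 10, n_generations = 5),
                          seed = 1)
  expect_s3_class(gabp$opt, "opt_result")
  expect_equal(gabp$opt$method, "ga")

  ssabp <- seeded_training(prob$X, prob$y, "ssa-bp", train = tc,
                           ssa = ssa_config(pop_size = 10, n_iterations = 5),
                           seed = 1)
  expect_equal(ssabp$opt$method, "ssa")
  # the refined fit starts from the searched vector: final loss no worse
  expect_lte(tail(ssabp$loss_history, 1), ssabp$opt$best_fitness)
})

test_that("SSA-initialized training matches or beats plain BP in training MSE", {
  prob <- tiny_sine_problem(80)
  tc <- train_config(max_epochs = 20)
  meta <- ssa_config(pop_size = 20, n_iterations = 20)
  wins <- vapply(1:10, function(s) {
    bp <- seeded_training(prob$X, prob$y, "bp", train = tc, seed = s)
    ssabp <- seeded_training(prob$X, prob$y, "ssa-bp", train = tc,
                             ssa = meta, seed = s)
    tail(ssabp$loss_history, 1) <= tail(bp$loss_history, 1) * (1 + 1e-9)
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})
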