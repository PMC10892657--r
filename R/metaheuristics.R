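# Real-coded genetic algorithm and canonical sparrow search algorithm used to
# optimize the network's initial weight vector (training-set MSE as fitness).

#' Configure the genetic algorithm
#'
#' Defaults follow the study settings: population 50, 100 generations,
#' crossover probability 0.6, mutation probability 0.2. Operators are
#' tournament-2 selection, arithmetic crossover, per-gene Gaussian mutation
#' (SD = 0.1 x bound range) and single-individual elitism.
#'
#' @param pop_size Even population size.
#' @param n_generations Number of generations.
#' @param p_crossover,p_mutation Crossover (per pair) and mutation (per gene)
#'   probabilities.
#' @param bounds Length-2 `c(low, high)` recycled per dimension, or a 2 x dim
#'   matrix.
#' @param seed Integer seed.
#' @export
ga_config <- function(pop_size = 50L, n_generations = 100L,
                      p_crossover = 0.6, p_mutation = 0.2,
                      bounds = c(-3, 3), seed = 1L) {
  if (pop_size < 2 || pop_size %% 2 != 0) arg_error("pop_size must be even and >= 2")
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1) {
    arg_error("probabilities must lie in [0, 1]")
  }
  structure(
    list(pop_size = as.integer(pop_size),
         n_generations = as.integer(n_generations),
         p_crossover = p_crossover, p_mutation = p_mutation,
         bounds = bounds, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Configure the sparrow search algorithm
#'
#' Defaults follow the study settings: population 50, 100 iterations,
#' explorer ratio 0.7, vigilante ratio 0.2. Unstated algorithmic constants
#' take their canonical values: safety threshold ST = 0.8, alarm value R2
#' drawn uniform per iteration, alpha drawn uniform per explorer update, and
#' the worse-ranked half of followers disperses.
#'
#' @param pop_size Population size (>= 4).
#' @param n_iterations Number of iterations.
#' @param explorer_ratio Fraction of the population acting as explorers
#'   (producers).
#' @param vigilante_ratio Fraction taking anti-predation steps each iteration
#'   (drawn from the whole population).
#' @param safety_threshold ST in (0, 1).
#' @param bounds As in [ga_config()].
#' @param seed Integer seed.
#' @export
ssa_config <- function(pop_size = 50L, n_iterations = 100L,
                       explorer_ratio = 0.7, vigilante_ratio = 0.2,
                       safety_threshold = 0.8, bounds = c(-3, 3), seed = 1L) {
  if (pop_size < 4) arg_error("pop_size must be >= 4")
  ratios <- c(explorer_ratio, vigilante_ratio)
  if (any(ratios <= 0 | ratios >= 1)) arg_error("ratios must lie in (0, 1)")
  if (safety_threshold <= 0 || safety_threshold >= 1) {
    arg_error("safety_threshold must lie in (0, 1)")
  }
  structure(
    list(pop_size = as.integer(pop_size),
         n_iterations = as.integer(n_iterations),
         explorer_ratio = explorer_ratio,
         vigilante_ratio = vigilante_ratio,
         safety_threshold = safety_threshold,
         bounds = bounds, seed = as.integer(seed)),
    class = "ssa_config"
  )
}

expand_bounds <- function(bounds, dim) {
  b <- as.matrix(bounds)
  if (length(b) == 2L) b <- matrix(rep(as.numeric(bounds), dim), nrow = 2L)
  if (nrow(b) != 2L || ncol(b) != dim) {
    arg_error("bounds must be c(low, high) or a 2 x dim matrix")
  }
  if (any(b[1L, ] >= b[2L, ])) arg_error("bounds must satisfy low < high")
  b
}

new_opt_result <- function(best_vector, best_fitness, history, mean_history,
                           evaluations, method) {
  structure(
    list(best_vector = best_vector, best_fitness = best_fitness,
         history = history, mean_history = mean_history,
         evaluations = as.integer(evaluations), method = method),
    class = "opt_result"
  )
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> %s: best fitness %.6g after %d evaluations (%d recorded iterations)\n",
              x$method, x$best_fitness, x$evaluations, length(x$history) - 1L))
  invisible(x)
}

#' Optimize with a real-coded genetic algorithm
#'
#' Tournament-2 selection, arithmetic crossover (probability `p_crossover`
#' per pair), per-gene Gaussian mutation with SD = 0.1 x (high - low), 1-elitism,
#' candidates clipped to bounds. Deterministic given the seed. The best-so-far
#' history (initial population best, then one entry per generation) is
#' non-increasing by elitism.
#'
#' @param fitness Function mapping a numeric vector of length `dim` to a
#'   scalar to be minimized.
#' @param dim Search-space dimension.
#' @param config A [ga_config()].
#' @return An `opt_result` with fields `best_vector`, `best_fitness`,
#'   `history`, `mean_history`, `evaluations`.
#' @export
ga_optimize <- function(fitness, dim, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"), dim >= 1)
  b <- expand_bounds(config$bounds, dim)
  lo <- b[1L, ]
  hi <- b[2L, ]
  mut_sd <- 0.1 * (hi - lo)
  np <- config$pop_size
  with_seed(config$seed, {
    P <- matrix(stats::runif(np * dim, rep(lo, each = np), rep(hi, each = np)),
                nrow = np)
    f <- apply(P, 1L, fitness)
    evals <- np
    history <- min(f)
    mean_history <- mean(f)
    for (gen in seq_len(config$n_generations)) {
      elite_i <- which.min(f)
      newP <- matrix(0, np, dim)
      newP[1L, ] <- P[elite_i, ]
      newf <- numeric(np)
      newf[1L] <- f[elite_i]
      row <- 2L
      while (row <= np) {
        pick <- function() {
          cand <- sample.int(np, 2L)
          cand[which.min(f[cand])]
        }
        p1 <- P[pick(), ]
        p2 <- P[pick(), ]
        if (stats::runif(1) < config$p_crossover) {
          u <- stats::runif(1)
          c1 <- u * p1 + (1 - u) * p2
          c2 <- (1 - u) * p1 + u * p2
        } else {
          c1 <- p1
          c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (row > np) break
          mask <- stats::runif(dim) < config$p_mutation
          if (any(mask)) {
            child[mask] <- child[mask] + stats::rnorm(sum(mask), 0, mut_sd[mask])
          }
          newP[row, ] <- clamp(child, lo, hi)
          row <- row + 1L
        }
      }
      newf[2:np] <- apply(newP[2:np, , drop = FALSE], 1L, fitness)
      evals <- evals + np - 1L
      P <- newP
      f <- newf
      history <- c(history, min(min(f), history[length(history)]))
      mean_history <- c(mean_history, mean(f))
    }
    best_i <- which.min(f)
    new_opt_result(P[best_i, ], history[length(history)], history,
                   mean_history, evals, "ga")
  })
}

#' Optimize with the sparrow search algorithm
#'
#' Canonical update rules. Per iteration the population is ranked by fitness;
#' the best `explorer_ratio` fraction are explorers: when the alarm value
#' `R2 < ST` each explorer j contracts as `x * exp(-j / (alpha * iter_max))`
#' (alpha uniform in (0, 1]), otherwise it takes a Gaussian step `x + Q`.
#' Followers in the worse-ranked half disperse
#' (`Q * exp((x_worst - x) / j^2)`); the rest move toward the best explorer
#' with random per-dimension signs. A random `vigilante_ratio` fraction then
#' takes anti-predation steps relative to the global best. All candidates are
#' clipped to bounds and the global best is tracked, so the best-so-far
#' history is non-increasing.
#'
#' @inheritParams ga_optimize
#' @param config An [ssa_config()].
#' @return An `opt_result`.
#' @export
ssa_optimize <- function(fitness, dim, config = ssa_config()) {
  stopifnot(inherits(config, "ssa_config"), dim >= 1)
  b <- expand_bounds(config$bounds, dim)
  lo <- b[1L, ]
  hi <- b[2L, ]
  np <- config$pop_size
  iter_max <- config$n_iterations
  with_seed(config$seed, {
    P <- matrix(stats::runif(np * dim, rep(lo, each = np), rep(hi, each = np)),
                nrow = np)
    f <- apply(P, 1L, fitness)
    evals <- np
    gbest_i <- which.min(f)
    gbest <- P[gbest_i, ]
    gbest_f <- f[gbest_i]
    history <- gbest_f
    mean_history <- mean(f)
    n_expl <- min(max(1L, round(config$explorer_ratio * np)), np - 1L)
    n_vig <- max(1L, round(config$vigilante_ratio * np))
    for (it in seq_len(iter_max)) {
      ord <- order(f)
      P <- P[ord, , drop = FALSE]
      f <- f[ord]
      f_old <- f
      worst_x <- P[np, ]
      worst_f <- f[np]
      R2 <- stats::runif(1)
      for (j in seq_len(n_expl)) {
        if (R2 < config$safety_threshold) {
          alpha <- stats::runif(1)
          P[j, ] <- P[j, ] * exp(-j / (alpha * iter_max))
        } else {
          P[j, ] <- P[j, ] + stats::rnorm(1)
        }
      }
      best_expl <- P[1L, ]
      for (j in seq.int(n_expl + 1L, np)) {
        if (j > np / 2) {
          P[j, ] <- stats::rnorm(1) * exp((worst_x - P[j, ]) / j^2)
        } else {
          A <- sample(c(-1, 1), dim, replace = TRUE)
          P[j, ] <- best_expl + abs(P[j, ] - best_expl) * A / dim
        }
      }
      vig <- sample.int(np, n_vig)
      for (j in vig) {
        if (f_old[j] > gbest_f) {
          P[j, ] <- gbest + stats::rnorm(1) * abs(P[j, ] - gbest)
        } else {
          P[j, ] <- P[j, ] + stats::runif(1, -1, 1) *
            abs(P[j, ] - worst_x) / (abs(f_old[j] - worst_f) + 1e-50)
        }
      }
      P <- t(clamp(t(P), lo, hi))
      f <- apply(P, 1L, fitness)
      evals <- evals + np
      it_best <- which.min(f)
      if (f[it_best] < gbest_f) {
        gbest_f <- f[it_best]
        gbest <- P[it_best, ]
      }
      history <- c(history, gbest_f)
      mean_history <- c(mean_history, mean(f))
    }
    new_opt_result(gbest, gbest_f, history, mean_history, evals, "ssa")
  })
}

#' Network-MSE fitness for a flattened weight vector
#'
#' Unflattens the candidate, runs the forward pass on the training features,
#' and returns the mean squared error. No gradient training happens inside
#' the fitness call: the metaheuristics rate raw initial weights, and the
#' Levenberg-Marquardt refinement runs once afterwards from the best vector.
#'
#' @param candidate Flattened weight vector.
#' @param X Training inputs.
#' @param y Training targets.
#' @param input_dim,hidden_dim Network geometry.
#' @return Scalar MSE.
#' @export
fitness_mse <- function(candidate, X, y, input_dim, hidden_dim = 13L) {
  p <- unflatten_params(candidate, input_dim, hidden_dim)
  mean((nn_forward(p, X) - y)^2)
}

#' Build an MSE-fitness closure over fixed training data
#'
#' @inheritParams fitness_mse
#' @return A function of one argument (the candidate vector).
#' @export
make_mse_fitness <- function(X, y, input_dim, hidden_dim = 13L) {
  X <- as_input_matrix(X, input_dim)
  force(y)
  function(candidate) fitness_mse(candidate, X, y, input_dim, hidden_dim)
}

#' Train a network with metaheuristic weight initialization
#'
#' The three study variants: `"bp"` trains from random initial weights;
#' `"ga-bp"` / `"ssa-bp"` first search for initial weights with the GA / SSA
#' (training-set MSE as fitness), then refine the best vector with the
#' configured trainer (Levenberg-Marquardt by default).
#'
#' @param X,y Training inputs and targets (already normalized by callers that
#'   want normalized-space training).
#' @param variant `"bp"`, `"ga-bp"` or `"ssa-bp"`.
#' @param hidden_dim Hidden-layer size.
#' @param train A [train_config()].
#' @param ga,ssa Metaheuristic configs (their `seed`/`bounds` are overridden
#'   by `seed`/`bounds` below so one call site controls reproducibility).
#' @param bounds Search bounds per weight.
#' @param seed Integer seed driving initialization and search.
#' @return A list with `params` (trained `network_params`), `loss_history`,
#'   `stop_reason`, and `opt` (the `opt_result`, or `NULL` for `"bp"`).
#' @export
seeded_training <- function(X, y, variant = c("bp", "ga-bp", "ssa-bp"),
                            hidden_dim = 13L, train = train_config(),
                            ga = ga_config(), ssa = ssa_config(),
                            bounds = c(-3, 3), seed = 1L) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  input_dim <- ncol(X)
  d <- n_network_params(input_dim, hidden_dim)
  fitness <- make_mse_fitness(X, y, input_dim, hidden_dim)
  opt <- NULL
  if (variant == "bp") {
    init <- init_network(input_dim, hidden_dim, range = 0.5, seed = seed)
  } else if (variant == "ga-bp") {
    ga$seed <- as.integer(seed)
    ga$bounds <- bounds
    opt <- ga_optimize(fitness, d, ga)
    init <- unflatten_params(opt$best_vector, input_dim, hidden_dim)
  } else {
    ssa$seed <- as.integer(seed)
    ssa$bounds <- bounds
    opt <- ssa_optimize(fitness, d, ssa)
    init <- unflatten_params(opt$best_vector, input_dim, hidden_dim)
  }
  train$seed <- as.integer(seed)
  fit <- train_network(init, X, y, train)
  list(params = fit$params, loss_history = fit$loss_history,
       stop_reason = fit$stop_reason, opt = opt)
}

#' Write an optimizer run log as CSV
#'
#' One row per recorded iteration: `iteration,best_fitness,mean_fitness`
#' (iteration 0 is the initial population).
#'
#' @param result An `opt_result`.
#' @param path Output path.
#' @export
write_opt_log <- function(result, path) {
  stopifnot(inherits(result, "opt_result"))
  utils::write.csv(
    data.frame(iteration = seq_along(result$history) - 1L,
               best_fitness = result$history,
               mean_fitness = result$mean_history),
    path, row.names = FALSE)
  invisible(path)
}
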