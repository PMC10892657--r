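# Single-hidden-layer regression network (tansig hidden units, linear output)
# with analytic Jacobian and full-batch Levenberg-Marquardt training.

#' Construct network parameters
#'
#' Holds the weights of a 1-hidden-layer network `yhat = W2 tanh(W1 x + b1) +
#' b2`. The canonical flattened ordering (used as the metaheuristic search
#' space) is row-major `W1`, then `b1`, then `W2`, then `b2`, for a total of
#' `input_dim * hidden_dim + 2 * hidden_dim + 1` parameters.
#'
#' @param W1 hidden x input weight matrix.
#' @param b1 hidden bias vector.
#' @param W2 1 x hidden output weight matrix (or length-hidden vector).
#' @param b2 Output bias scalar.
#' @return An object of class `network_params`.
#' @export
network_params <- function(W1, b1, W2, b2) {
  W1 <- as.matrix(W1)
  W2 <- matrix(as.numeric(W2), nrow = 1L)
  h <- nrow(W1)
  if (length(b1) != h || ncol(W2) != h || length(b2) != 1L) {
    arg_error("inconsistent network parameter shapes")
  }
  vals <- c(W1, b1, W2, b2)
  if (!all(is.finite(vals))) arg_error("network parameters must be finite")
  structure(
    list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2),
         input_dim = ncol(W1), hidden_dim = h),
    class = "network_params"
  )
}

#' Number of free parameters of a network geometry
#' @param input_dim,hidden_dim Layer sizes.
#' @export
n_network_params <- function(input_dim, hidden_dim = 13L) {
  as.integer(input_dim * hidden_dim + 2L * hidden_dim + 1L)
}

#' Random initial network weights
#'
#' Uniform on `[-range, range]`, the plain-BP baseline initialization (the
#' GA/SSA variants override it with an optimized vector).
#'
#' @param input_dim,hidden_dim Layer sizes.
#' @param range Half-width of the uniform initialization interval.
#' @param seed Optional integer seed.
#' @export
init_network <- function(input_dim, hidden_dim = 13L, range = 0.5,
                         seed = NULL) {
  with_seed(seed, {
    d <- n_network_params(input_dim, hidden_dim)
    unflatten_params(stats::runif(d, -range, range), input_dim, hidden_dim)
  })
}

#' Flatten network parameters into the canonical search vector
#' @param params A `network_params`.
#' @return Numeric vector (row-major W1, b1, W2, b2).
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "network_params"))
  c(as.vector(t(params$W1)), params$b1, as.vector(params$W2), params$b2)
}

#' Rebuild network parameters from a flattened vector
#' @param v Numeric vector of length `n_network_params(input_dim, hidden_dim)`.
#' @param input_dim,hidden_dim Layer sizes.
#' @export
unflatten_params <- function(v, input_dim, hidden_dim = 13L) {
  d <- n_network_params(input_dim, hidden_dim)
  if (length(v) != d) {
    arg_error(sprintf("expected %d parameters, got %d", d, length(v)))
  }
  k <- input_dim * hidden_dim
  W1 <- matrix(v[seq_len(k)], nrow = hidden_dim, ncol = input_dim, byrow = TRUE)
  b1 <- v[k + seq_len(hidden_dim)]
  W2 <- matrix(v[k + hidden_dim + seq_len(hidden_dim)], nrow = 1L)
  b2 <- v[d]
  network_params(W1, b1, W2, b2)
}

as_input_matrix <- function(X, input_dim) {
  X <- as.matrix(X)
  if (ncol(X) != input_dim) {
    arg_error(sprintf("input has %d columns; network expects %d",
                      ncol(X), input_dim))
  }
  storage.mode(X) <- "double"
  X
}

hidden_activations <- function(params, X) {
  n <- nrow(X)
  tanh(X %*% t(params$W1) +
         matrix(params$b1, n, params$hidden_dim, byrow = TRUE))
}

#' Forward pass of the network
#'
#' @param params A `network_params`.
#' @param X Matrix (rows = samples) with `input_dim` columns.
#' @return Numeric vector of predictions, one per row.
#' @export
nn_forward <- function(params, X) {
  stopifnot(inherits(params, "network_params"))
  X <- as_input_matrix(X, params$input_dim)
  if (nrow(X) == 0L) return(numeric(0))
  H <- hidden_activations(params, X)
  as.vector(tcrossprod(H, params$W2)) + params$b2
}

#' Analytic Jacobian of the forward pass
#'
#' Returns the n x d matrix of partial derivatives of each prediction with
#' respect to the flattened parameter vector (canonical ordering), computed
#' layer-by-layer in closed form. This is the Jacobian of the predictions (and
#' hence of the residuals `yhat - y`) used by the Levenberg-Marquardt trainer.
#'
#' @inheritParams nn_forward
#' @export
nn_jacobian <- function(params, X) {
  stopifnot(inherits(params, "network_params"))
  X <- as_input_matrix(X, params$input_dim)
  h <- params$hidden_dim
  k <- params$input_dim
  H <- hidden_activations(params, X)
  S <- (1 - H^2) * matrix(params$W2, nrow(X), h, byrow = TRUE)
  J_W1 <- S[, rep(seq_len(h), each = k), drop = FALSE] *
    X[, rep(seq_len(k), times = h), drop = FALSE]
  cbind(J_W1, S, H, rep(1, nrow(X)))
}

#' Configure network training
#'
#' Defaults follow the standard full-batch Levenberg-Marquardt schedule: the
#' damping parameter mu starts at `1e-3`, is divided by 10 after an accepted
#' step and multiplied by 10 after a rejected one, and training stops at
#' `max_epochs`, when the MSE gradient drops below `grad_tol`, or when mu
#' exceeds `mu_max`. An alternative mini-batch gradient-descent trainer
#' (`trainer = "sgd"`, learning rate 0.01, batch size 32) is provided for
#' fidelity experiments against toolbox-style configurations.
#'
#' @param max_epochs Maximum accepted LM steps (or SGD epochs).
#' @param mu_init,mu_increase,mu_decrease,mu_max LM damping schedule.
#' @param grad_tol Infinity-norm tolerance on the MSE gradient.
#' @param trainer `"lm"` (default) or `"sgd"`.
#' @param learn_rate,batch_size SGD settings (ignored by LM).
#' @param seed Integer seed (used by the SGD shuffle; LM is deterministic).
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 1000L, mu_init = 1e-3,
                         mu_increase = 10, mu_decrease = 0.1, mu_max = 1e10,
                         grad_tol = 1e-7, trainer = c("lm", "sgd"),
                         learn_rate = 0.01, batch_size = 32L, seed = 1L) {
  trainer <- match.arg(trainer)
  if (max_epochs < 0) arg_error("max_epochs must be >= 0")
  if (mu_increase <= 1 || mu_decrease >= 1 || mu_decrease <= 0) {
    arg_error("mu_increase must be > 1 and mu_decrease in (0, 1)")
  }
  structure(
    list(max_epochs = as.integer(max_epochs), mu_init = mu_init,
         mu_increase = mu_increase, mu_decrease = mu_decrease,
         mu_max = mu_max, grad_tol = grad_tol, trainer = trainer,
         learn_rate = learn_rate, batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# Solve (A + mu I) delta = b; Cholesky with an SVD pseudo-inverse fallback for
# ill-conditioned systems.
damped_solve <- function(A, mu, b) {
  Ad <- A + diag(mu, nrow(A))
  out <- tryCatch({
    R <- chol(Ad)
    backsolve(R, forwardsolve(t(R), b))
  }, error = function(e) NULL)
  if (is.null(out)) {
    sv <- svd(Ad)
    pos <- sv$d > max(sv$d[1], 1) * 1e-12
    out <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
    out <- as.vector(out)
  }
  as.vector(out)
}

#' Train the network with full-batch Levenberg-Marquardt
#'
#' Per epoch: compute the residuals `r` (predicted minus observed targets)
#' and the analytic Jacobian
#' `J`, then solve `(J'J + mu I) delta = J'r` and propose `p - delta`. A step
#' is accepted (and mu divided by 10) when it lowers the MSE; otherwise mu is
#' multiplied by 10 and the step retried, up to `mu_max`. The loss history
#' records the initial MSE followed by each accepted step's MSE and is
#' therefore non-increasing.
#'
#' @param params Initial `network_params`.
#' @param X Training inputs (rows = samples).
#' @param y Training targets.
#' @param config A [train_config()].
#' @return A list with `params` (trained), `loss_history`, `epochs`
#'   (accepted steps), and `stop_reason` (`"max_epochs"`, `"grad_tol"` or
#'   `"mu_max"`).
#' @export
train_lm <- function(params, X, y, config = train_config()) {
  stopifnot(inherits(params, "network_params"))
  X <- as_input_matrix(X, params$input_dim)
  if (nrow(X) != length(y)) arg_error("X rows and y length differ")
  if (nrow(X) < 2L) arg_error("need at least 2 training samples")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    arg_error("training data must be finite")
  }
  n <- nrow(X)
  k <- params$input_dim
  h <- params$hidden_dim
  p <- params
  r <- nn_forward(p, X) - y
  mse <- mean(r^2)
  history <- mse
  mu <- config$mu_init
  stop_reason <- "max_epochs"
  if (config$max_epochs > 0) {
    for (epoch in seq_len(config$max_epochs)) {
      J <- nn_jacobian(p, X)
      g <- 2 * crossprod(J, r)[, 1L] / n
      if (max(abs(g)) < config$grad_tol) {
        stop_reason <- "grad_tol"
        break
      }
      A <- crossprod(J)
      b <- crossprod(J, r)[, 1L]
      accepted <- FALSE
      while (!accepted) {
        delta <- damped_solve(A, mu, b)
        cand <- unflatten_params(flatten_params(p) - delta, k, h)
        rc <- nn_forward(cand, X) - y
        mc <- mean(rc^2)
        if (is.finite(mc) && mc < mse) {
          p <- cand
          r <- rc
          mse <- mc
          mu <- max(mu * config$mu_decrease, 1e-20)
          history <- c(history, mse)
          accepted <- TRUE
        } else {
          mu <- mu * config$mu_increase
          if (mu > config$mu_max) break
        }
      }
      if (!accepted) {
        stop_reason <- "mu_max"
        break
      }
    }
  }
  list(params = p, loss_history = history, epochs = length(history) - 1L,
       stop_reason = stop_reason)
}

#' Train the network with mini-batch gradient descent
#'
#' Toolbox-style alternative trainer (learning rate 0.01, batch size 32 by
#' default): per epoch the samples are shuffled, and for each mini-batch the
#' parameters take a step against the MSE gradient `2 J' r / n_batch`. The
#' loss history records the full-data MSE after each epoch and is not
#' guaranteed to be monotone.
#'
#' @inheritParams train_lm
#' @return A list with `params`, `loss_history`, `epochs`, `stop_reason`.
#' @export
train_sgd <- function(params, X, y, config = train_config(trainer = "sgd")) {
  stopifnot(inherits(params, "network_params"))
  X <- as_input_matrix(X, params$input_dim)
  if (nrow(X) != length(y)) arg_error("X rows and y length differ")
  n <- nrow(X)
  k <- params$input_dim
  h <- params$hidden_dim
  p <- params
  history <- mean((nn_forward(p, X) - y)^2)
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        rb <- nn_forward(p, Xb) - y[idx]
        g <- 2 * crossprod(nn_jacobian(p, Xb), rb)[, 1L] / length(idx)
        p <- unflatten_params(flatten_params(p) - config$learn_rate * g, k, h)
      }
      history <- c(history, mean((nn_forward(p, X) - y)^2))
    }
  })
  list(params = p, loss_history = history, epochs = config$max_epochs,
       stop_reason = "max_epochs")
}

train_network <- function(params, X, y, config) {
  if (config$trainer == "sgd") train_sgd(params, X, y, config)
  else train_lm(params, X, y, config)
}
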