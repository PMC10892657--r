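# User-facing modelling interface: fit the ring-finger MCP angle network with
# a formula + data call and interrogate it with the usual S3 methods.

#' Fit a ring-finger MCP angle prediction network
#'
#' Fits the study's single-hidden-layer regression network (13 tansig hidden
#' units, linear output) to predict the ring-finger MCP rotation angle.
#' Inputs and the target are min-max scaled to `[-1, 1]` using ranges captured
#' from the training data; training runs in the scaled space with full-batch
#' Levenberg-Marquardt, and all reported errors are in denormalized degrees.
#' The `"ga-bp"` / `"ssa-bp"` variants first optimize the initial weight
#' vector with the genetic / sparrow search algorithm (training MSE as
#' fitness) before the gradient refinement.
#'
#' @param formula Model formula, e.g. `feature_formula("individual")`:
#'   `beta1_deg ~ theta1_deg + omega1_deg_s + alpha1_deg_s2`.
#' @param data A data frame of features (see [build_features()]).
#' @param variant `"bp"`, `"ga-bp"` or `"ssa-bp"`.
#' @param hidden Hidden-layer size (13 in the study).
#' @param train A [train_config()].
#' @param ga,ssa Metaheuristic configurations.
#' @param bounds Search bounds for the initial-weight vector; the default
#'   `c(-3, 3)` covers the useful tanh input range after normalization.
#' @param seed Integer seed for initialization and search.
#' @return An object of class `mcp_bpnn` with methods [predict.mcp_bpnn()],
#'   `print`, `summary`, `coef` (flattened weights), `fitted`, `residuals`
#'   and `plot`.
#' @export
#' @examples
#' profile <- sample_subjects(1, seed = 7)
#' cfg <- generator_config(n_subjects = 1, sets_per_subject = 2,
#'                         keystrokes_per_set = 4, angle_noise_sd_deg = 0,
#'                         position_noise_sd_mm = 0, seed = 7)
#' sets <- generate_session(profile, cfg)
#' feats <- build_features(extract_angles(sets[[1]]), mode = "individual")
#' fit <- mcp_bpnn(feature_formula("individual"), feats,
#'                 train = train_config(max_epochs = 25), seed = 7)
#' fit
mcp_bpnn <- function(formula, data, variant = c("bp", "ga-bp", "ssa-bp"),
                     hidden = 13L, train = train_config(),
                     ga = ga_config(), ssa = ssa_config(),
                     bounds = c(-3, 3), seed = 1L) {
  variant <- match.arg(variant)
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  tt <- attr(mf, "terms")
  y <- unname(stats::model.response(mf))
  X <- as.matrix(mf[, -1L, drop = FALSE])
  if (nrow(X) < 2L) arg_error("need at least 2 training rows")
  x_ranges <- feature_ranges(X)
  y_range <- range(y)
  Xn <- normalize_features(X, x_ranges)
  yn <- normalize_features(y, y_range)
  res <- seeded_training(Xn, yn, variant = variant, hidden_dim = hidden,
                         train = train, ga = ga, ssa = ssa,
                         bounds = bounds, seed = seed)
  fitted_deg <- denormalize_features(nn_forward(res$params, Xn), y_range)
  structure(
    list(call = cl, terms = tt, variant = variant, hidden = as.integer(hidden),
         params = res$params, x_ranges = x_ranges, y_range = y_range,
         loss_history = res$loss_history, stop_reason = res$stop_reason,
         opt = res$opt, seed = as.integer(seed),
         train_config = train,
         fitted.values = fitted_deg, residuals = y - fitted_deg,
         y = y),
    class = "mcp_bpnn"
  )
}

model_inputs <- function(object, newdata) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata)
  as.matrix(mf)
}

#' Predict ring-finger MCP angles from a fitted network
#'
#' @param object A fitted `mcp_bpnn`.
#' @param newdata Data frame containing the model's input columns; if
#'   missing, fitted values are returned.
#' @param ... Unused.
#' @return Predicted beta1 in degrees.
#' @export
predict.mcp_bpnn <- function(object, newdata, ...) {
  if (missing(newdata) || is.null(newdata)) return(object$fitted.values)
  X <- model_inputs(object, newdata)
  Xn <- normalize_features(X, object$x_ranges)
  denormalize_features(nn_forward(object$params, Xn), object$y_range)
}

#' @export
coef.mcp_bpnn <- function(object, ...) flatten_params(object$params)

#' @export
fitted.mcp_bpnn <- function(object, ...) object$fitted.values

#' @export
residuals.mcp_bpnn <- function(object, ...) object$residuals

#' @export
print.mcp_bpnn <- function(x, ...) {
  cat(sprintf("Ring-finger MCP angle network (%s), %d -> %d -> 1\n",
              x$variant, x$params$input_dim, x$hidden))
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Training RMSE: %.4f deg over %d frames (%d LM steps, stop: %s)\n",
              sqrt(mean(x$residuals^2)), length(x$residuals),
              length(x$loss_history) - 1L, x$stop_reason))
  invisible(x)
}

#' @export
summary.mcp_bpnn <- function(object, ...) {
  out <- list(
    variant = object$variant,
    input_dim = object$params$input_dim,
    hidden = object$hidden,
    n_params = n_network_params(object$params$input_dim, object$hidden),
    n_train = length(object$residuals),
    train_rmse_deg = sqrt(mean(object$residuals^2)),
    train_mae_deg = mean(abs(object$residuals)),
    epochs = length(object$loss_history) - 1L,
    stop_reason = object$stop_reason,
    final_loss = object$loss_history[length(object$loss_history)],
    opt = object$opt,
    seed = object$seed
  )
  class(out) <- "summary.mcp_bpnn"
  out
}

#' @export
print.summary.mcp_bpnn <- function(x, ...) {
  cat(sprintf("Ring-finger MCP angle network: variant %s\n", x$variant))
  cat(sprintf("  architecture   : %d inputs -> %d tansig units -> linear output (%d weights)\n",
              x$input_dim, x$hidden, x$n_params))
  cat(sprintf("  training       : %d frames, %d accepted LM steps (stop: %s)\n",
              x$n_train, x$epochs, x$stop_reason))
  cat(sprintf("  train MAE/RMSE : %.4f / %.4f deg\n",
              x$train_mae_deg, x$train_rmse_deg))
  cat(sprintf("  final loss     : %.6g (normalized MSE)\n", x$final_loss))
  if (!is.null(x$opt)) {
    cat(sprintf("  initial weights: %s search, best fitness %.6g after %d evaluations\n",
                x$opt$method, x$opt$best_fitness, x$opt$evaluations))
  } else {
    cat(sprintf("  initial weights: random uniform (seed %d)\n", x$seed))
  }
  invisible(x)
}

#' Diagnostic plots for a fitted network
#'
#' `which = 1` draws the accepted-step loss history (log scale); `which = 2`
#' draws fitted vs observed ring-finger MCP angles on the training data.
#'
#' @param x A fitted `mcp_bpnn`.
#' @param which Subset of `1:2`.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.mcp_bpnn <- function(x, which = 1:2, ...) {
  if (1 %in% which) {
    graphics::plot(seq_along(x$loss_history) - 1L, x$loss_history, type = "l",
                   log = "y", xlab = "accepted LM step",
                   ylab = "training MSE (normalized)",
                   main = paste0("Loss history (", x$variant, ")"), ...)
  }
  if (2 %in% which) {
    graphics::plot(x$y, x$fitted.values, pch = ".",
                   xlab = "measured beta1 (deg)", ylab = "fitted beta1 (deg)",
                   main = "Fitted vs measured", ...)
    graphics::abline(0, 1, col = "red")
  }
  invisible(x)
}

#' Serialize a fitted network to JSON
#'
#' Stores the architecture, flattened weights (full precision),
#' normalization ranges and training metadata; [read_mcp_bpnn()] restores a
#' model whose predictions match the original exactly.
#'
#' @param object A fitted `mcp_bpnn`.
#' @param path File path.
#' @export
write_mcp_bpnn <- function(object, path) {
  stopifnot(inherits(object, "mcp_bpnn"))
  payload <- list(
    package_version = as.character(utils::packageVersion("ringcast")),
    variant = object$variant,
    input_dim = object$params$input_dim,
    hidden_dim = object$hidden,
    weights = flatten_params(object$params),
    input_names = colnames(object$x_ranges),
    x_ranges = list(min = object$x_ranges[1L, ], max = object$x_ranges[2L, ]),
    y_range = object$y_range,
    formula = deparse(stats::formula(object$terms)),
    seed = object$seed,
    stop_reason = object$stop_reason,
    final_loss = object$loss_history[length(object$loss_history)]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mcp_bpnn
#' @export
read_mcp_bpnn <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- unflatten_params(as.numeric(x$weights), x$input_dim, x$hidden_dim)
  x_ranges <- rbind(min = as.numeric(x$x_ranges$min),
                    max = as.numeric(x$x_ranges$max))
  colnames(x_ranges) <- x$input_names
  ff <- stats::as.formula(x$formula)
  structure(
    list(call = quote(read_mcp_bpnn()), terms = stats::terms(ff),
         variant = x$variant, hidden = as.integer(x$hidden_dim),
         params = params, x_ranges = x_ranges,
         y_range = as.numeric(x$y_range),
         loss_history = as.numeric(x$final_loss),
         stop_reason = x$stop_reason, opt = NULL,
         seed = as.integer(x$seed), train_config = NULL,
         fitted.values = NULL, residuals = NULL, y = NULL),
    class = "mcp_bpnn"
  )
}
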