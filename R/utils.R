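# Internal helpers shared across the package.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the R random-number seed, evaluates `expr`, and restores the previous
#' RNG state so callers never leak seed changes into the session.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Derive a stage seed from a master seed
#'
#' Hashes a stage label into the master seed so that every pipeline stage
#' (generation, per-variant training, ...) gets its own reproducible stream,
#' and adding one stage never perturbs another stage's results.
#'
#' @param master_seed Integer master seed.
#' @param stage Character label of the stage.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "generate")
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 100003
  as.integer((abs(as.numeric(master_seed)) %% 20011 * 100003 + h) %% 2147483647)
}

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ringcast_error", "error", "condition")))
}

arg_error <- function(msg) abort(msg, "ringcast_argument_error")

# Centred moving average; edge windows are truncated symmetrically so the
# output has the same length as the input.
moving_average <- function(x, window) {
  if (window == 1L) return(x)
  if (window %% 2 == 0 || window < 1) {
    arg_error("smoothing window must be a positive odd integer")
  }
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
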