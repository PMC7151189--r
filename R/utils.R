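#' @keywords internal
"_PACKAGE"

# Condition helpers: validation errors (bad user input, exit code 2 at the
# CLI) vs I/O errors (exit code 3).
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("distractr_validation_error", "error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("distractr_io_error", "error")))
}

#' Derive a reproducible sub-seed
#'
#' Mixes a master seed with integer components (for example a design-cell
#' index and a replicate number) into a seed below 2^31, so that every
#' (cell, replicate) pair owns its own random stream regardless of execution
#' order.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer components.
#' @return A single integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(unlist(list(...))))
  if (any(!is.finite(parts))) stop_validation("seed components must be finite")
  m <- 2147483647 # 2^31 - 1, prime; all arithmetic stays exact in doubles
  h <- 0
  for (p in parts) {
    h <- (h * 48271 + abs(p) + 1) %% m
    h <- (h * 69621 + 7) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Population (divide-by-n) standard deviation; the form under which the
# point-biserial formulas coincide exactly with the Pearson correlation.
sd_pop <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}
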