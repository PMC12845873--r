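#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rgamma sd var median quantile cor predict
#'   coef spline approx fft
#' @importFrom utils read.table write.table head tail
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seeds below 2^31, spread by a large prime multiplier.
derive_seed <- function(master_seed, index) {
  m <- 2147483629
  as.integer((as.numeric(master_seed) %% m * 48271 + as.numeric(index) * 16807) %% m)
}

abort_invalid <- function(msg) stop(msg, call. = FALSE)

notice <- function(...) message("[eegfuse] ", sprintf(...))

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)
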