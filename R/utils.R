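# Internal helpers: unit constants, classed conditions, seeded evaluation.

# 1 mmHg in Pa; 1 mL/min in m^3/s; 1 mm in m.
MMHG_PA <- 133.322
MLMIN_M3S <- 1e-6 / 60
MM_M <- 1e-3

stop_coroflow <- function(subclass, msg, ..., data = list()) {
  cond <- structure(
    class = c(paste0("coroflow_", subclass), "coroflow_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1), data = data)
  )
  stop(cond)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded generators do not disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Trapezoidal integral of y over x (both numeric, same length).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
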