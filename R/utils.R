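#' @importFrom stats rpois runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

BASES <- c("A", "C", "G", "T")

# bitmask encoding used by the Fitch pass
BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library internals never perturb user simulations.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# deterministic 32-bit LCG, independent of R's RNG; returns doubles in [0,1)
lcg_runif <- function(n, state) {
  a <- 1103515245; c <- 12345; m <- 2^31
  out <- numeric(n)
  s <- state
  for (i in seq_len(n)) {
    s <- (a * s + c) %% m
    out[i] <- s / m
  }
  list(u = out, state = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("mtp_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
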