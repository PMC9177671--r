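#' Derive a reproducible child seed from a master seed and a label
#'
#' Stage-level randomness is isolated by hashing the stage label together with
#' the run seed, so adding or reordering stochastic stages does not perturb the
#' random streams of the others.
#'
#' @param seed Master integer seed.
#' @param label Character label of the consumer (e.g. a module name).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "simulate_f2")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(paste0(label, collapse = ""))
  h <- (seed %% 2147483647)
  for (k in codes) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
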