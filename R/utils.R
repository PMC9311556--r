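# Seeding helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stream seed from a master seed
#'
#' Stable integer hash mapping (master seed, stream index) into
#' `[1, 2^31 - 2]` via a Lehmer-style multiplicative congruence, so every
#' subject/fold/classifier gets its own reproducible RNG stream.
#'
#' @param master Master seed (integer).
#' @param index Non-negative stream index.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(master) %% m) * 48271 %% m
  h <- (h + as.numeric(index) * 16807) %% m
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
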