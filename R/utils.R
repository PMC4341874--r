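# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; restore the
# caller's stream afterwards. seed = NULL uses (and advances) the caller's
# stream, the base-R convention for simulation functions.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single integer or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific random seed from a master seed
#'
#' Stable arithmetic hash of (master seed, stage label, optional cell index),
#' so that each pipeline stage gets its own reproducible stream regardless of
#' execution order. The result is a positive integer below 2^31.
#'
#' @param master Master seed (integer).
#' @param stage Stage label (character scalar).
#' @param index Optional cell index.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) *
             (31^(seq_along(utf8ToInt(as.character(stage))) %% 7)))
  as.integer((abs(master) * 7919 + h * 104729 + index * 15485863) %% 2147483629) + 1L
}

.geomean <- function(x) exp(mean(log(x)))
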