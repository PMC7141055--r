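#' Seed handling utilities
#'
#' Every stochastic operation in the package takes an explicit integer seed
#' and leaves the caller's RNG state untouched. `with_seed()` evaluates an
#' expression under a temporary RNG state; `derive_seed()` mixes a base seed
#' with arbitrary tokens (strings, integers) into a new seed, so that
#' independent sub-streams (per location, per image, per emission) can be
#' derived reproducibly from one experiment seed.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate under the seeded RNG.
#' @name rng-utils
NULL

#' @rdname rng-utils
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' @rdname rng-utils
#' @param ... Tokens (character or numeric scalars/vectors) mixed into the
#'   derived seed.
#' @return `derive_seed()`: a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds in integer range
  h <- as.numeric(seed) %% m
  for (tok in list(...)) {
    if (is.character(tok)) {
      codes <- unlist(lapply(tok, utf8ToInt), use.names = FALSE)
      codes <- c(codes, 257)  # separator so c("ab","c") != c("a","bc")
    } else {
      codes <- as.numeric(tok)
    }
    for (v in codes) {
      # 48271 is the MINSTD multiplier; simple multiplicative mixing
      h <- (h * 48271 + (v %% m) + 1) %% m
    }
  }
  as.integer(h)
}
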