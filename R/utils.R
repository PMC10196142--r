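#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rlnorm qnorm pnorm sd t.test uniroot
NULL

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# All exported stochastic functions funnel through here so that a NULL seed
# means "use the current stream" and an integer seed means "reproducible".
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
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
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Row-level simulations (one per subject x device x repetition) each need
#' their own RNG stream so that results do not depend on the order in which
#' rows are processed. A stable string hash (djb2 accumulated modulo a
#' Mersenne prime) mixed with the master seed gives an integer below 2^31.
#'
#' @param master Single integer master seed.
#' @param key Character scalar identifying the stream (e.g. "S01/Foster/1").
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "S01/Foster_pMDI/1")
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483629 # prime < 2^31, keeps intermediate products exact in doubles
  h <- 5381
  for (code in utf8ToInt(key)) {
    h <- (h * 33 + code) %% m
  }
  as.integer((h + (as.double(master) %% m) * 48271) %% 2147483587)
}

# stop() with a consistent class for input-validation failures
bad_input <- function(msg) {
  abort(msg, class = "lungdepo_input_error")
}

check_number <- function(x, name, min = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    bad_input(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (finite && !is.finite(x)) {
    bad_input(sprintf("`%s` must be finite.", name))
  }
  if (strict && x <= min) {
    bad_input(sprintf("`%s` must be > %g (got %g).", name, min, x))
  }
  if (!strict && x < min) {
    bad_input(sprintf("`%s` must be >= %g (got %g).", name, min, x))
  }
  invisible(x)
}
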