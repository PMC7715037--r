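#' @importFrom rlang abort warn %||%
#' @importFrom stats dnorm rnorm runif rbinom rpois quantile sd
#' @importFrom utils head tail
NULL

# Run code with a private RNG state so generators are pure functions of
# their seed and never disturb the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "ss_invalid_argument")
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
  force(code)
}

stop_invalid <- function(msg) abort(msg, class = "ss_invalid_argument")

check_number <- function(x, name, min = -Inf, strict_min = FALSE,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) &&
    (if (strict_min) x > min else x >= min)
  if (!ok) {
    stop_invalid(sprintf(
      "`%s` must be a single number %s %s.", name,
      if (strict_min) ">" else ">=", format(min)
    ))
  }
  invisible(x)
}

# x*log2(x) with the 0*log(0) = 0 convention used throughout entropy code
xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)

# Shannon entropy (bits) of a probability vector
entropy_bits <- function(p) -sum(xlog2x(p))
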