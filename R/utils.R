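#' @keywords internal
"_PACKAGE"

#' @useDynLib repdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm dnorm cor sd var quantile rmultinom lm.fit setNames
#' @importFrom utils head tail write.csv read.csv
NULL

# Deterministic child seeds: fold the global seed with stage labels / indices
# through a multiplicative congruential mix so every stochastic stage draws
# from its own reproducible stream. Always < 2^31.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (part in list(...)) {
    if (is.character(part)) {
      part <- sum(utf8ToInt(part) * seq_along(utf8ToInt(part)))
    }
    for (k in as.double(part)) {
      h <- (h * 69069 + k + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# evaluate fn under a local RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# empirical percentile on the sampled values: smallest value with >= q * n
# values at or below it (matches the compiled permutation code)
emp_quantile <- function(x, q) {
  xs <- sort(x)
  xs[max(1L, min(length(xs), ceiling(q * length(xs))))]
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(min), format(max)))
  }
  as.double(x)
}
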