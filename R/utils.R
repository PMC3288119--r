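#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad rnorm runif rbinom rbeta rhyper pchisq qnorm
#'   rpois sd var quantile model.matrix contr.sum setNames lm.fit complete.cases
#' @importFrom utils head
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
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
  set.seed(seed)
  force(code)
}

# Deterministic named substream: one master seed spawns per-stage seeds so
# that partial reruns of a stage are bit-reproducible. Polynomial rolling
# hash of the name; result stays below 2^31.
substream <- function(seed, name) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 32749
  (abs(as.integer(seed)) %% 65521) * 32749 + h
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
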