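#' @importFrom rlang .data abort warn .env
#' @importFrom stats qnorm pnorm rnorm runif rpois rbinom quantile median sd
#'   coef vcov nls fft ppois wilcox.test t.test predict setNames na.omit
#' @importFrom utils head tail
#' @importFrom tools md5sum
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed per named stream so that events / whiskers /
# position / spikes / calcium draw from independent reproducible streams.
substream_seed <- function(master_seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master_seed) * 10007 + h * 97) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_wt_tbl <- function(x, class, ...) {
  x <- tibble::as_tibble(x)
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}

trace_fps <- function(trace) {
  fps <- attr(trace, "fps")
  if (is.null(fps)) {
    dt <- median(diff(trace$t))
    fps <- 1 / dt
  }
  fps
}

stopifnot_prob <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
}
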