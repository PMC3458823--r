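# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn
#' @importFrom stats fft mad median approx sd var lm coef complete.cases splinefun runmed quantile
#' @importFrom utils head tail read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All package randomness goes through this so a single seed governs a
# whole run.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a run seed and a stage label, staying below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483399L)
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(x) {
  y <- atan2(sin(x), cos(x))
  y[y <= -pi] <- pi
  y
}

# Wrapped difference a - b in (-pi, pi].
phase_diff <- function(a, b) wrap_phase(a - b)

stop_fibmap <- function(msg, class) abort(msg, class = c(class, "fibmap_error"))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
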