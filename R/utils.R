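#' @importFrom stats rnorm runif rlnorm sd lm.fit shapiro.test wilcox.test
#' @importFrom utils read.csv write.csv head
NULL

# Derive a reproducible child seed from a parent seed and a stage name.
# Keeps all stage seeds below 2^31 and decoupled, so stages can be rerun
# in isolation from a single global seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_oscml <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_oscml(sprintf("'%s' must be a single finite number (got %s)", name,
                       paste(format(x), collapse = ", ")))
  bad <- if (strict) x <= lower else x < lower
  if (bad)
    stop_oscml(sprintf("'%s' must be %s %g (got %g)", name,
                       if (strict) ">" else ">=", lower, x))
  invisible(x)
}
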