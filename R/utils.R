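# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so seeded package functions do not
# disturb user-level reproducibility.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("woundseg_validation_error", "error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("woundseg_io_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_validation("`%s` must be a single finite number in [%s, %s], got %s",
                    name, format(lower), format(upper),
                    paste(format(x), collapse = ","))
  as.numeric(x)
}

check_count <- function(x, name, lower = 0L) {
  x <- check_number(x, name, lower = lower)
  if (x != round(x)) stop_validation("`%s` must be an integer, got %s", name, format(x))
  as.integer(x)
}
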