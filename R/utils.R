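#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded package functions do not
#' perturb user-level random streams.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# single place for the "is a probability" check used by several modules
check_fraction <- function(x, name, open_lo = TRUE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > 0 else x >= 0) &&
    (if (open_hi) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be a fraction in %s0,1%s", name,
                        if (open_lo) "(" else "[",
                        if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}

# draw from a "sampler spec": either a fixed numeric value or a function(n)
sample_spec <- function(spec, n) {
  if (is.function(spec)) {
    out <- spec(n)
    if (length(out) != n) stop("sampler function must return 'n' values")
    out
  } else if (is.numeric(spec) && length(spec) == 1L) {
    rep(spec, n)
  } else {
    stop("sampler spec must be a single number or a function(n)")
  }
}
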