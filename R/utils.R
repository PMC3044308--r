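#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova approx coef complete.cases cor density ks.test lm
#'   lm.fit pexp predict pf quantile residuals rnorm runif rlnorm rexp rbinom
#'   sd setNames step var vcov as.formula
#' @importFrom utils combn read.table write.table head modifyList
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic operations in the
# package route through this so that seeds are explicit function arguments.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream index.
# Double arithmetic (exact below 2^53) avoids 32-bit overflow.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}

tfd_log <- function(...) {
  if (isTRUE(getOption("tfdensity.verbose", FALSE)))
    message("[tfdensity] ", sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
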