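## Small shared numerics used across modules.

#' Error function
#'
#' `erf(x) = 2*pnorm(x*sqrt(2)) - 1`, the convention used by the annular
#' site model.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## run code under a local, restorable RNG state; seed = NULL leaves RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## scalar checks used by constructors
check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (strict && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict && x < lower) stopf("'%s' must be >= %g", name, lower)
  invisible(x)
}

## centers of 1-based pixels of size p (pixel i covers [ (i-1)p, ip ) nm)
pixel_centers <- function(n, p) (seq_len(n) - 0.5) * p

## pixel index containing coordinate x (nm), 1-based, half-open convention
pixel_index <- function(x, p) floor(x / p) + 1L
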