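#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the random-number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded package functions never
#' disturb the global random stream. A `NULL` seed evaluates `code`
#' against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a master seed
#'
#' The pipeline derives one seed per stochastic stage from a single master
#' seed by fixed offsets, so a whole run is reproducible from one integer.
#'
#' @param master integer master seed.
#' @param stage integer stage offset (each pipeline stage uses a distinct one).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.double(master) * 48271 + as.double(stage) * 16807) %% 2147483587)
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
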