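# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded sub-seed from a base seed and a stream index.
# Kept below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000003 + stream * 7919) %% 2147483629) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) stopf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper))
  invisible(x)
}

# Coerce to a sparse genes x cells integer-valued dgCMatrix.
as_count_matrix <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (any(m@x < 0)) stopf("counts must be non-negative")
  if (any(m@x != round(m@x))) stopf("counts must be integral")
  m
}
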