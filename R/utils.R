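# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Error constructors. Every user-facing failure carries a class so callers
## (and tests) can discriminate identifier errors from contract violations.
smm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "smmbn_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_identifier <- function(msg, ...) smm_stop("smmbn_identifier_error", msg, ...)
stop_contract   <- function(msg, ...) smm_stop("smmbn_contract_error", msg, ...)
stop_config     <- function(msg, ...) smm_stop("smmbn_config_error", msg, ...)
stop_degenerate <- function(msg, ...) smm_stop("smmbn_degenerate_error", msg, ...)

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic entry points funnel through this so seeds are portable
## and library calls never clobber user-level reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_contract("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Mixed-radix index of parent configurations.  `xmat` is an N x k integer
## matrix of level indices (1-based), `radix` the per-column level counts.
## First column varies fastest, matching R's array/dimension convention.
config_index <- function(xmat, radix) {
  n <- nrow(xmat)
  if (ncol(xmat) == 0L) return(rep.int(1L, n))
  idx <- xmat[, 1L] - 1L
  stride <- radix[1L]
  if (ncol(xmat) > 1L) for (j in 2L:ncol(xmat)) {
    idx <- idx + (xmat[, j] - 1L) * stride
    stride <- stride * radix[j]
  }
  idx + 1L
}

## Deterministic derived seeds: fold a base seed and a stream id into a
## reproducible child seed strictly below 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 69069 + 12345 * as.double(stream)) %% 2147483629
}

arc_key <- function(from, to) paste(from, to, sep = "->")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
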