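# Internal helpers: classed conditions and scoped RNG.

bw_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "bw_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_validation <- function(fmt, ...) bw_stop("bw_validation_error", fmt, ...)
stop_io <- function(fmt, ...) bw_stop("bw_io_error", fmt, ...)

# Run `expr` under a deterministic seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a substream seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index) * 10007 + 1) %%
    2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
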