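# internal helpers shared across the package

.EPS <- 1e-12

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
# so simulation functions do not clobber the user's random stream.
with_preserved_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-subject / per-replicate seed derivation; kept below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 2147483563 * 48271 + index * 7919) %% 2147483563)
}

# run-length encoding of an integer/NA label vector, returned as a data.frame
# of (value, start, end, length) with half-open [start, end) 0-based frames.
label_runs <- function(labels) {
  n <- length(labels)
  if (n == 0L) {
    return(data.frame(value = integer(), start = integer(),
                      end = integer(), length = integer()))
  }
  r <- rle(ifelse(is.na(labels), -1L, as.integer(labels)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(value = ifelse(r$values == -1L, NA_integer_, r$values),
             start = starts, end = ends, length = r$lengths)
}
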