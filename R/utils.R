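# Internal numerical helpers shared across the package.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise bias addition, z + b broadcast over rows (hot path; avoids sweep).
add_bias <- function(z, b) z + matrix(b, nrow(z), ncol(z), byrow = TRUE)

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never clobber user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Min-max scaling statistics computed on a training matrix; constant columns
# map to 0 so rescaled values stay valid Bernoulli probabilities.
minmax_fit <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  list(min = apply(x, 2, min), range = apply(x, 2, max) - apply(x, 2, min))
}

minmax_apply <- function(x, scaling) {
  stopifnot(is.matrix(x), ncol(x) == length(scaling$min))
  rng <- scaling$range
  rng[rng == 0] <- 1
  out <- sweep(sweep(x, 2, scaling$min, "-"), 2, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("features must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("features must be finite and non-missing", call. = FALSE)
  }
  x
}
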