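#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Multivariate hypergeometric draw: subsample `m` items without replacement
## from categories with counts `counts`. Sequential rhyper conditioning.
rmvhyper <- function(counts, m) {
  stopifnot(all(counts >= 0), m >= 0, m <= sum(counts))
  out <- numeric(length(counts))
  remaining <- sum(counts)
  left <- m
  for (i in seq_along(counts)) {
    if (left == 0) break
    remaining <- remaining - counts[i]
    if (remaining <= 0) {
      out[i] <- left
      left <- 0
      break
    }
    x <- stats::rhyper(1, counts[i], remaining, left)
    out[i] <- x
    left <- left - x
  }
  out
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1

`%||%` <- function(a, b) if (is.null(a)) b else a
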