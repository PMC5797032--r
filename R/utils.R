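# shared internal helpers

# Gauss-Hermite nodes/weights (weight exp(-z^2)) by Golub-Welsch; small k only
gauss_hermite <- function(k) {
  if (k == 1L) return(list(z = 0, w = sqrt(pi)))
  i <- seq_len(k - 1L)
  J <- matrix(0, k, k)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(z = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

# run expr under a temporary RNG seed (no-op when seed is NULL)
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# derive a child seed, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %%
               .Machine$integer.max + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
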