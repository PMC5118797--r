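## Internal numerical helpers shared across modules.

## Squared-distance matrix between two coordinate sets (n x 3, m x 3).
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

cross_dist <- function(a, b) sqrt(pmax(cross_dist2(a, b), 0))

## Deterministic Fibonacci-lattice sphere: n approximately uniform unit
## vectors, identical on every call (no RNG).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x >= 1
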