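# Internal helpers shared across modules.

# Derive a child seed from a root seed and a stage label, staying inside
# the 32-bit integer range required by set.seed().
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

ms_to_sample <- function(ms, fs) as.integer(round(ms / 1000 * fs)) + 1L
sample_to_ms <- function(idx, fs) (idx - 1L) / fs * 1000

# Euclidean distances between rows of a (n x 3) and rows of b (m x 3).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Sample skewness (moment estimator, as used for the log-transform screen).
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
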