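# Internal helpers shared across modules.

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Row-wise log-sum-exp over a matrix (returns a vector, one value per row).
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Derive a child seed from a base seed and a stage offset, kept within the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483629) + 1L
}

# Wrap an angle (radians) into (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Hash of an arbitrary R object, used to stamp run outputs with their
# configuration. Serialises to a temp file and md5-sums it (base R only).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
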