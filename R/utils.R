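# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression with a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators behave as pure functions of their spec.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Pairwise Euclidean distance matrix between two n x 3 coordinate matrices.
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3L)
  b <- matrix(as.numeric(b), ncol = 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed dihedral angle a-b-c-d in degrees, IUPAC sign convention.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- unit(n1); m2 <- unit(n2)
  x <- sum(m1 * m2)
  y <- sum(vcross(m1, m2) * unit(b2))
  atan2(y, x) * 180 / pi
}

bond_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp
# report files with a fingerprint of the run configuration.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor touches the low byte only
    # multiply with 32-bit wrap-around; doubles hold the intermediate exactly
    # only if split, so multiply in two 16-bit halves
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
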