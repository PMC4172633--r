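# Internal numerical helpers shared across the fitting code.

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- numeric(length(x))
  hi <- x > 18
  out[hi] <- x[hi] + log1p(exp(-x[hi]))
  out[!hi] <- log1p(exp(x[!hi]))
  out
}

# central-difference gradient; h scaled to the parameter magnitude
num_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

# central-difference Hessian (symmetric), for low-dimensional objectives
num_hess <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  hs <- h * pmax(1, abs(x))
  f0 <- f(x)
  for (i in seq_len(d)) {
    xp <- x; xp[i] <- x[i] + hs[i]
    xm <- x; xm[i] <- x[i] - hs[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / hs[i]^2
    if (i < d) for (j in seq((i + 1), d)) {
      xpp <- x; xpp[i] <- x[i] + hs[i]; xpp[j] <- x[j] + hs[j]
      xpm <- x; xpm[i] <- x[i] + hs[i]; xpm[j] <- x[j] - hs[j]
      xmp <- x; xmp[i] <- x[i] - hs[i]; xmp[j] <- x[j] + hs[j]
      xmm <- x; xmm[i] <- x[i] - hs[i]; xmm[j] <- x[j] - hs[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * hs[i] * hs[j])
    }
  }
  H
}

# solve A x = b through a Cholesky factor of a positive-definite A
chol_solve <- function(ch, b) {
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}

# derive a child seed from a base seed and a stream index, kept inside
# 32-bit integer range so set.seed() accepts it
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483399) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
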