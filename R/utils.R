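# Internal numeric helpers shared across modules.

# One draw from N(mean, sd^2) truncated to [lower, upper].
# Inverse-CDF in the central regime; Robert-style exponential rejection in
# the far tails where pnorm underflows.
rtnorm1 <- function(mean, sd, lower, upper) {
  if (sd <= 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  plo <- pnorm(a)
  phi <- pnorm(b)
  if (phi - plo > 1e-10) {
    z <- qnorm(runif(1L, plo, phi))
    return(mean + sd * min(max(z, a), b))
  }
  # both bounds in one tail; reflect so the mass sits above `a` with a > 0
  flip <- FALSE
  if (b < 0) {
    tmp <- a
    a <- -b
    b <- -tmp
    flip <- TRUE
  }
  alpha <- (a + sqrt(a * a + 4)) / 2
  for (i in seq_len(1000L)) {
    z <- a + rexp(1L, alpha)
    if (z <= b && runif(1L) <= exp(-(z - alpha)^2 / 2)) {
      if (flip) z <- -z
      return(mean + sd * z)
    }
  }
  # pathological truncation: fall back to the nearest bound
  if (flip) a <- -a
  mean + sd * a
}

# Shortest interval containing `cred` mass of the empirical distribution.
hpd_interval <- function(x, cred = 0.95) {
  if (!is.numeric(cred) || length(cred) != 1L || is.na(cred) ||
      cred <= 0 || cred > 1) {
    stop("`cred` must be a single value in (0, 1]", call. = FALSE)
  }
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(cred * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  i <- seq_len(n - m + 1L)
  w <- x[i + m - 1L] - x[i]
  j <- which.min(w)
  c(lower = x[j], upper = x[j + m - 1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
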