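# Independent transcriptions of the printed mean-field right-hand sides,
# written directly from the per-length balance equations (never from the
# matrix builders), used to verify M %*% N entrywise.

rhs_base_oracle <- function(N, r, a) {
  n <- length(N)
  nx <- function(i) if (i <= n) N[i] else 0
  d <- numeric(n)
  d[1] <- -r * N[1] + sum(2 * a * N[seq(2, n)])
  for (i in 2:n)
    d[i] <- r * nx(i - 1) * (i - 1) - i * r * N[i] - (i - 1) * N[i] * a +
      2 * a * nx(i + 1)
  d
}

rhs_escape_oracle <- function(N, r, a, del, dp, dpp, cc, cp) {
  n <- length(N)
  nx <- function(i) if (i <= n) N[i] else 0
  d <- numeric(n)
  d[1] <- r * (-1 + 2 * del) * N[1] + sum(2 * r * dp * N[2:n]) +
    sum(2 * a * N[2:n]) - cc * N[1]
  d[2] <- r * (1 - del) * N[1] - 2 * r * (1 - dp) * N[2] - a * N[2] +
    2 * nx(3) * a - cp * N[2]
  for (i in 3:n)
    d[i] <- r * (2 * dp - i) * N[i] +
      r * nx(i - 1) * (i - 1 - 2 * dp + 3 * dpp - i * dpp) -
      (i - 1) * N[i] * a + 2 * a * nx(i + 1) - cp * N[i]
  d
}

rhs_q_oracle <- function(N, r, a, q) {
  n <- length(N)
  nx <- function(i) if (i <= n) N[i] else 0
  d <- numeric(n)
  d[1] <- -r * N[1] + sum(2 * a * N[2:n])
  for (i in 2:n) {
    tail_sum <- if (i + 2 <= n) sum(N[(i + 2):n]) else 0
    d[i] <- -r * i * N[i] + r * (i - 1) * nx(i - 1) - a * (i - 1) * N[i] +
      2 * a * nx(i + 1) + 2 * a * q * tail_sum
  }
  d
}

rhs_force_oracle <- function(N, r, a, b) {
  n <- length(N)
  nx <- function(i) if (i <= n) N[i] else 0
  d <- numeric(n)
  d[1] <- -r * N[1] + sum(2 * a * N[2:n] * exp(b * ((2:n) - 1) / 2))
  for (i in 2:n) {
    brk <- if (i %% 2 == 0) {
      s <- if (i >= 4) sum(exp(-((2:(i / 2)) - 1)^2 * b / 2)) else 0
      a * exp(b * i^2 / 8) * (1 + 2 * s)
    } else {
      2 * a * exp(b * i^2 / 8) *
        sum(exp(-((1:((i - 1) / 2)) - 1 / 2)^2 * b / 2))
    }
    d[i] <- -r * i * N[i] - brk * N[i] + r * (i - 1) * nx(i - 1) +
      2 * a * nx(i + 1) * exp(b * i / 2)
  }
  d
}

# Total-variation distance between two distributions padded to a common
# support length.
tv_dist <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  0.5 * sum(abs(p - q))
}

random_pop <- function(n) stats::runif(n, 0, 3)

strip_op <- function(M) {
  attr(M, "params") <- NULL
  attr(M, "kind") <- NULL
  class(M) <- "matrix"
  unclass(M)
}
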