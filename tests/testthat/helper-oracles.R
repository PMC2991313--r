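# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive, direct transcription of the defining formula.

# Otsu: literal between-class variance maximization, one threshold at a
# time, class 0 = gray <= t.
oracle_otsu <- function(h) {
  g <- 0:255
  n <- sum(h)
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(t + 1)] * g[1:(t + 1)]) / sum(h[1:(t + 1)])
    mu1 <- sum(h[(t + 2):256] * g[(t + 2):256]) / sum(h[(t + 2):256])
    s2 <- w0 * w1 * (mu0 - mu1)^2
    if (s2 > best + 1e-12) {
      best <- s2
      best_t <- t
    }
  }
  best_t
}

# Natural cubic spline by the textbook tridiagonal solve for the second
# derivatives (Thomas algorithm), then piecewise-cubic evaluation.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  a <- c(h[-(n - 1)], 0)
  b <- c(1, 2 * (h[-(n - 1)] + h[-1]), 1)
  cc <- c(0, h[-1])
  d <- c(0, 6 * diff(diff(y) / h), 0)
  for (i in 2:n) {
    w <- a[i - 1] / b[i - 1]
    b[i] <- b[i] - w * cc[i - 1]
    d[i] <- d[i] - w * d[i - 1]
  }
  m <- numeric(n)
  m[n] <- d[n] / b[n]
  for (i in (n - 1):1) m[i] <- (d[i] - cc[i] * m[i + 1]) / b[i]
  vapply(xout, function(q) {
    j <- max(1, min(n - 1, findInterval(q, x)))
    t1 <- x[j + 1] - q
    t2 <- q - x[j]
    (m[j] * t1^3 + m[j + 1] * t2^3) / (6 * h[j]) +
      (y[j] / h[j] - m[j] * h[j] / 6) * t1 +
      (y[j + 1] / h[j] - m[j + 1] * h[j] / 6) * t2
  }, numeric(1))
}

# Flood-fill connected components, 26-connectivity, recursion-free stack.
oracle_label_cc <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ijk <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        i <- ijk[1] + dx; j <- ijk[2] + dy; k <- ijk[3] + dz
        if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) next
        lin <- i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nxt
          stack <- c(stack, lin)
        }
      }
    }
  }
  lab
}

# Canonical size-multiset of a labeling (labels themselves are arbitrary).
cc_sizes <- function(lab) sort(tabulate(lab[lab > 0]))
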