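# Independent brute-force oracles used to cross-check the package's linear
# algebra and statistics. Deliberately slow, loop-based, and written without
# reference to the implementation they check.

oracle_correlation <- function(x) {
  g <- nrow(x)
  out <- matrix(0, g, g, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      xi <- x[i, ]; xj <- x[j, ]
      num <- sum((xi - mean(xi)) * (xj - mean(xj)))
      den <- sqrt(sum((xi - mean(xi))^2)) * sqrt(sum((xj - mean(xj))^2))
      out[i, j] <- num / den
    }
  }
  out
}

oracle_tom <- function(a) {
  g <- nrow(a)
  k <- numeric(g)
  for (i in seq_len(g)) k[i] <- sum(a[i, -i])
  tom <- diag(g)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(g)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      denom <- min(k[i], k[j]) + 1 - a[i, j]
      tom[i, j] <- if (denom > 0) (l + a[i, j]) / denom else 0
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Step-up BH from first principles: adj_(i) = min over j >= i of p_(j)*m/j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (rank in seq_len(m)) {
    vals <- numeric(0)
    for (j in rank:m) vals <- c(vals, p[ord[j]] * m / j)
    adj[ord[rank]] <- min(1, min(vals))
  }
  adj
}

# Product-limit estimator by explicit risk-set bookkeeping.
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (r in seq_along(ts)) {
    at_risk <- sum(times >= ts[r])
    d <- sum(times == ts[r] & events == 1)
    s <- s * (1 - d / at_risk)
    out$survival[r] <- s
  }
  out
}

# Two-group log-rank chi-square via explicit O-E / hypergeometric-variance
# tabulation at each distinct event time.
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ts <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in ts) {
    n_all <- sum(times >= tt)
    n1 <- sum(times >= tt & grp == 1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & grp == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n_all)
    if (n_all > 1) {
      v <- v + d * (n1 / n_all) * (1 - n1 / n_all) * (n_all - d) / (n_all - 1)
    }
  }
  o_minus_e^2 / v
}

# Power iteration on the gene-gene covariance of row-standardized data:
# leading eigenvector -> sample-space score.
oracle_first_pc <- function(xs, iters = 2000L) {
  cc <- xs %*% t(xs)
  v <- rep(1, nrow(cc))
  for (i in seq_len(iters)) {
    v <- cc %*% v
    v <- v / sqrt(sum(v^2))
  }
  score <- drop(t(xs) %*% v)
  score / sd(score)
}

rand_expression <- function(g, n, seed, prefix = "g") {
  set.seed(seed)
  matrix(rnorm(g * n), g, n,
         dimnames = list(paste0(prefix, seq_len(g)), paste0("s", seq_len(n))))
}

two_group_phenotype <- function(n_a, n_b) {
  tibble::tibble(
    sample_id = c(paste0("s", seq_len(n_a + n_b))),
    condition = factor(rep(c("normal", "tumor"), c(n_a, n_b)),
                       levels = c("normal", "tumor"))
  )
}
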