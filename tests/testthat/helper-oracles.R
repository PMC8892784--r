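# Independent brute-force oracles used to freeze expected values.

# BH step-up computed literally from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p >= p[i] - 1e-15)
    q[i] <- min(vapply(js, function(j) {
      m * p[j] / rank(p, ties.method = "max")[j]
    }, 0), 1)
  }
  q
}

# Kendall tau-b straight from the pairwise definition.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
      if (dx * dy > 0) conc <- conc + 1
      if (dx * dy < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Exact two-sided Mann-Whitney p by full enumeration of group
# assignments (no ties).
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  m <- length(a)
  u_of <- function(idx) {
    aa <- pooled[idx]
    bb <- pooled[-idx]
    sum(outer(aa, bb, ">"))
  }
  u_obs <- u_of(seq_len(m))
  mid <- m * (n - m) / 2
  combos <- utils::combn(n, m, simplify = FALSE)
  us <- vapply(combos, u_of, 0)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
}

# Tie-corrected Kruskal-Wallis H from its defining formula.
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  groups <- factor(groups)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) {
      length(ri) * (mean(ri) - (n + 1) / 2)^2
    }))
  t <- table(values)
  h / (1 - sum(t^3 - t) / (n^3 - n))
}

# One-sided hypergeometric upper-tail sum for a 2x2 enrichment table:
# drawing `size` genes out of (size + m0_size), observing >= n_up white
# balls out of (n_up + m0_up) white in total.
oracle_hypergeom_tail <- function(n_up, size, m0_up, m0_size) {
  white <- n_up + m0_up
  black <- (size - n_up) + (m0_size - m0_up)
  ks <- n_up:min(white, size)
  sum(stats::dhyper(ks, white, black, size))
}

# Circular absolute difference in hours on a 24 h clock.
circ_diff <- function(a, b) abs((a - b + 12) %% 24 - 12)

# All n! permutations of 1..n as rows.
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
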