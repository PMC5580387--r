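# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# Brute-force Fisher oracle: enumerate every 2x2 table with the observed
# margins, weight each by its unnormalized product of binomial
# coefficients, and normalize explicitly.  No hypergeometric formula, no
# log-space.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d
  xs <- 0:r1
  w <- vapply(xs, function(x) {
    if (x > c1 || r1 - x > c2) return(0)
    choose(c1, x) * choose(c2, r1 - x)
  }, numeric(1))
  probs <- w / sum(w)
  p_obs <- probs[xs == a]
  mean_a <- sum(xs * probs)
  p_one <- if (a >= mean_a) sum(probs[xs >= a]) else sum(probs[xs <= a])
  p_two <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_one = min(1, p_one), p_two = min(1, p_two))
}

# Clopper-Pearson oracle: bisection on the binomial tail, no beta quantile.
oracle_cp <- function(k, n, level = 0.95) {
  a2 <- (1 - level) / 2
  bisect <- function(f) {
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else {
    # smallest p with P(X >= k | p) >= a2
    bisect(function(p) (1 - stats::pbinom(k - 1, n, p)) - a2)
  }
  upper <- if (k == n) 1 else {
    # largest p with P(X <= k | p) >= a2
    bisect(function(p) a2 - stats::pbinom(k, n, p))
  }
  c(lower = lower, upper = upper)
}

# Conditional-likelihood odds-ratio oracle: golden-section style search via
# optimize() on the log conditional likelihood.
oracle_or_cmle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d
  lo <- max(0, r1 - c2); hi <- min(r1, c1)
  support <- lo:hi
  loglik <- function(log_psi) {
    terms <- lchoose(c1, support) + lchoose(c2, r1 - support) +
      support * log_psi
    (lchoose(c1, a) + lchoose(c2, b) + a * log_psi) -
      (max(terms) + log(sum(exp(terms - max(terms)))))
  }
  exp(stats::optimize(loglik, c(-20, 20), maximum = TRUE,
                      tol = 1e-10)$maximum)
}

# All 2x2 tables (a,b,c,d) whose four margins are all <= m and which have
# no degenerate (all-zero) row or column.
all_tables_margins_le <- function(m) {
  grid <- expand.grid(a = 0:m, b = 0:m, c = 0:m, d = 0:m)
  keep <- with(grid,
    a + b <= m & c + d <= m & a + c <= m & b + d <= m &
      a + b > 0 & c + d > 0 & a + c > 0 & b + d > 0)
  grid[keep, , drop = FALSE]
}
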