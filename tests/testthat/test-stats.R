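test_that("hypergeometric pmf matches exact integer arithmetic", {
  # C(5,5) * C(83,27) / C(88,32) = 201376 / 39175752, computed here from
  # binomial coefficients held as exact doubles
  expect_equal(hypergeom_pmf(5, N = 88, K = 5, n = 32), 201376 / 39175752,
               tolerance = 1e-12)
  expect_equal(hypergeom_pmf(0, N = 10, K = 0, n = 4), 1)
  expect_equal(sum(hypergeom_pmf(0:9, N = 20, K = 7, n = 9)), 1,
               tolerance = 1e-12)
  expect_equal(hypergeom_pmf(8, N = 20, K = 7, n = 9), 0)  # outside support
  expect_error(hypergeom_pmf(1, N = 10, K = 12, n = 3), "domain")
  expect_error(hypergeom_pmf(1, N = 10, K = 3, n = 12), "domain")
})

test_that("pmf normalizes to 1 for randomized parameters", {
  set.seed(19)
  for (i in 1:50) {
    N <- sample(1:200, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    ks <- max(0, n - (N - K)):min(K, n)
    expect_equal(sum(hypergeom_pmf(ks, N, K, n)), 1, tolerance = 1e-12)
  }
})

test_that("fisher_exact reproduces the reference comparison", {
  res <- fisher_exact(contingency_2x2(5, 27, 0, 56))
  expect_equal(res$p_two_sided, 201376 / 39175752, tolerance = 1e-12)
  expect_equal(res$p_one_sided, res$p_two_sided, tolerance = 1e-12)
  expect_equal(format_p(res$p_two_sided), "0.005")
  expect_true(res$significant)
  expect_identical(res$odds_ratio, Inf)
})

test_that("fisher_exact handles trivial and degenerate tables", {
  expect_equal(fisher_exact(contingency_2x2(0, 10, 0, 10))$p_two_sided, 1)
  expect_equal(fisher_exact(contingency_2x2(3, 3, 3, 3))$p_two_sided, 1)
  # unit margins
  expect_equal(fisher_exact(contingency_2x2(1, 0, 0, 1))$p_two_sided, 1)
  # degenerate margin: all of column one empty
  res <- fisher_exact(contingency_2x2(0, 5, 0, 7))
  expect_equal(res$p_two_sided, 1)
  expect_match(res$method, "degenerate")
  expect_error(contingency_2x2(0, 0, 0, 0), "margin")
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_exact agrees with the brute-force oracle", {
  set.seed(5)
  tabs <- all_tables_margins_le(8)
  pick <- tabs[sample(nrow(tabs), 400), ]
  for (i in seq_len(nrow(pick))) {
    a <- pick$a[i]; b <- pick$b[i]; c <- pick$c[i]; d <- pick$d[i]
    got <- fisher_exact(contingency_2x2(a, b, c, d))
    want <- oracle_fisher(a, b, c, d)
    expect_equal(got$p_two_sided, want$p_two, tolerance = 1e-12,
                 info = paste(a, b, c, d))
    expect_equal(got$p_one_sided, want$p_one, tolerance = 1e-12,
                 info = paste(a, b, c, d))
  }
})

test_that("two-sided p is invariant under simultaneous row and column swap", {
  set.seed(11)
  for (i in 1:100) {
    x <- sample(0:12, 4, replace = TRUE)
    if (sum(x) == 0) next
    p1 <- fisher_exact(contingency_2x2(x[1], x[2], x[3], x[4]))$p_two_sided
    p2 <- fisher_exact(contingency_2x2(x[4], x[3], x[2], x[1]))$p_two_sided
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("one-sided p is monotone as the table moves into the tail", {
  # fixed margins: shift mass from (a, d) to (b, c) step by step
  r1 <- 12; r2 <- 20; c1 <- 10
  amax <- min(r1, c1)
  ps <- vapply(0:amax, function(a) {
    t <- contingency_2x2(a, r1 - a, c1 - a, r2 - (c1 - a))
    fisher_exact(t)$p_one_sided
  }, numeric(1))
  mean_a <- r1 * c1 / (r1 + r2)
  upper <- which(0:amax >= ceiling(mean_a))
  expect_true(all(diff(ps[upper]) <= 1e-12))
})

test_that("incidence gives the reference proportions and exact CIs", {
  inc <- incidence(5, 32)
  expect_equal(inc$proportion, 0.15625)
  expect_equal(format_pct(inc$proportion), "15.6%")
  cp <- oracle_cp(5, 32)
  expect_equal(inc$ci_low, unname(cp["lower"]), tolerance = 1e-8)
  expect_equal(inc$ci_high, unname(cp["upper"]), tolerance = 1e-8)

  inc0 <- incidence(0, 56)
  expect_equal(inc0$proportion, 0)
  expect_equal(inc0$ci_low, 0)
  expect_equal(format_pct(inc0$proportion), "0.0%")
  cp0 <- oracle_cp(0, 56)
  expect_equal(inc0$ci_high, unname(cp0["upper"]), tolerance = 1e-8)

  incn <- incidence(7, 7)
  expect_equal(incn$ci_high, 1)

  expect_error(incidence(1, 0), "undefined-incidence")
  expect_error(incidence(5, 3), "0 <= k <= n")
})

test_that("CI bounds match the bisection oracle over a parameter sweep", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    k <- sample(0:n, 1)
    level <- sample(c(0.9, 0.95, 0.99), 1)
    inc <- incidence(k, n, level)
    cp <- oracle_cp(k, n, level)
    expect_equal(inc$ci_low, unname(cp["lower"]), tolerance = 1e-7)
    expect_equal(inc$ci_high, unname(cp["upper"]), tolerance = 1e-7)
    expect_true(inc$ci_low <= inc$proportion && inc$proportion <= inc$ci_high)
  }
})

test_that("odds ratio is the conditional MLE, with zero-cell divergence", {
  expect_identical(odds_ratio(contingency_2x2(5, 27, 0, 56)), Inf)
  expect_identical(odds_ratio(contingency_2x2(0, 27, 5, 56)), 0)
  expect_equal(odds_ratio(contingency_2x2(1, 1, 1, 1)), 1, tolerance = 1e-6)
  # numeric-maximization oracle, plus the standard implementation
  expect_equal(odds_ratio(contingency_2x2(3, 1, 1, 3)),
               oracle_or_cmle(3, 1, 1, 3), tolerance = 1e-5)
  expect_equal(odds_ratio(contingency_2x2(3, 1, 1, 3)),
               unname(stats::fisher.test(matrix(c(3, 1, 1, 3), 2))$estimate),
               tolerance = 1e-4)
  set.seed(2)
  for (i in 1:20) {
    x <- sample(1:10, 4, replace = TRUE)  # all cells positive: finite MLE
    expect_equal(odds_ratio(contingency_2x2(x[1], x[2], x[3], x[4])),
                 oracle_or_cmle(x[1], x[2], x[3], x[4]), tolerance = 1e-4,
                 info = paste(x, collapse = ","))
  }
})

test_that("compare_incidence builds the table and excludes non-C7-region calls", {
  mk_calls <- function(ids) {
    structure(data.frame(specimen_id = seq_along(ids), identity = ids,
                         stringsAsFactors = FALSE),
              class = c("identity_table", "data.frame"))
  }
  # identical groups: p = 1
  res <- compare_incidence(mk_calls(rep(c("CT", "C7"), c(2, 8))),
                           mk_calls(rep(c("CT", "C7"), c(2, 8))))
  expect_equal(res$test$p_two_sided, 1)
  expect_false(res$test$significant)

  # unit-margin table via single-record groups
  res <- compare_incidence(mk_calls("CT"), mk_calls("C7"))
  expect_equal(res$test$p_two_sided, 1)

  # T1 and INDETERMINATE are excluded and counted
  res <- compare_incidence(mk_calls(c("CT", "C7", "T1", "INDETERMINATE")),
                           mk_calls(c("C7", "C7", "T1")))
  expect_equal(res$excluded_A, 2)
  expect_equal(res$excluded_B, 1)
  expect_equal(res$incidence_A$n, 2)
  expect_equal(res$incidence_B$n, 2)

  expect_error(compare_incidence(mk_calls(c("T1", "T1")), mk_calls("C7")),
               "undefined-comparison")
})

test_that("reporting helpers round half-up at the printed digit", {
  expect_equal(format_pct(0.15625), "15.6%")
  expect_equal(format_pct(0.125), "12.5%")
  expect_equal(format_p(0.0625), "0.063")    # half-up, not half-even
  expect_equal(format_p(0.0051403), "0.005")
})
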