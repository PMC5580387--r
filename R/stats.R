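# Exact small-sample inference built from first principles: hypergeometric
# enumeration, Fisher's exact test (minimum-likelihood two-sided rule),
# Clopper-Pearson intervals, conditional-MLE odds ratio.

#' Construct and validate a 2x2 contingency table
#'
#' Rows are populations (e.g. fossil vs extant), columns outcomes
#' (transitional C/T vs not):
#' \preformatted{        outcome  !outcome
#'   pop1      a        b
#'   pop2      c        d}
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  if (sum(x) == 0) stop("table has no positive margin", call. = FALSE)
  structure(as.list(stats::setNames(as.integer(x), names(x))),
            class = "contingency_2x2")
}

as_matrix_2x2 <- function(t) {
  matrix(c(t$a, t$c, t$b, t$d), 2, 2,
         dimnames = list(population = c("A", "B"), outcome = c("yes", "no")))
}

#' Hypergeometric probability mass
#'
#' P(X = k) when drawing `n` items without replacement from a population of
#' size `N` containing `K` successes: choose(K,k) choose(N-K,n-k) /
#' choose(N,n), evaluated in log space for numerical stability.  Zero
#' outside the support.  Vectorized over `k`.
#'
#' @param k Number of successes drawn (vectorized).
#' @param N Population size.
#' @param K Successes in the population (0 <= K <= N).
#' @param n Number of draws (0 <= n <= N).
#' @return Probabilities.
#' @export
#' @examples
#' hypergeom_pmf(5, N = 88, K = 5, n = 32)
hypergeom_pmf <- function(k, N, K, n) {
  if (N < 0 || K < 0 || K > N || n < 0 || n > N) {
    stop("domain error: require 0 <= K <= N and 0 <= n <= N", call. = FALSE)
  }
  out <- numeric(length(k))
  ok <- k >= max(0, n - (N - K)) & k <= min(K, n) & k == round(k)
  out[ok] <- exp(lchoose(K, k[ok]) + lchoose(N - K, n - k[ok]) - lchoose(N, n))
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins: under the null of no association the count
#' in cell `a` follows the hypergeometric distribution.  The one-sided
#' p-value sums tables at least as extreme as the observed one in the
#' observed direction; the two-sided p-value uses the minimum-likelihood
#' rule (sum of probabilities of all tables whose point probability does
#' not exceed the observed one), the convention of standard statistical
#' software.  The odds ratio is the conditional maximum-likelihood estimate
#' ([odds_ratio()]).
#'
#' A degenerate margin (an all-zero row or column) makes the test
#' undefined; `p = 1` is returned with a note in `method`.
#'
#' @param t A [contingency_2x2()] (or 2x2 matrix).
#' @param alpha Significance level for the `significant` verdict.
#' @return Object of class `exact_test_result`: `table`, `p_one_sided`,
#'   `p_two_sided`, `odds_ratio`, `or_method`, `alpha`, `significant`,
#'   `method`.
#' @export
#' @examples
#' fisher_exact(contingency_2x2(5, 27, 0, 56))$p_two_sided
fisher_exact <- function(t, alpha = 0.05) {
  if (is.matrix(t)) t <- contingency_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  stopifnot(inherits(t, "contingency_2x2"))
  m <- t$a + t$c          # column 1 margin
  n2 <- t$b + t$d         # column 2 margin
  r1 <- t$a + t$b         # row 1 margin
  N <- m + n2
  note <- "hypergeometric enumeration, minimum-likelihood two-sided rule"
  if (m == 0 || n2 == 0 || r1 == 0 || t$c + t$d == 0) {
    res <- list(table = t, p_one_sided = 1, p_two_sided = 1,
                odds_ratio = NA_real_, or_method = "conditional MLE",
                alpha = alpha, significant = FALSE,
                method = paste(note, "(degenerate margin: p = 1)"))
    class(res) <- "exact_test_result"
    return(res)
  }
  support <- max(0, r1 - n2):min(r1, m)
  d <- hypergeom_pmf(support, N = N, K = m, n = r1)
  p_obs <- d[support == t$a]
  mean_a <- r1 * m / N
  p_one <- if (t$a >= mean_a) {
    sum(d[support >= t$a])
  } else {
    sum(d[support <= t$a])
  }
  # relative tolerance guards ties against floating-point jitter, as in
  # standard implementations
  p_two <- sum(d[d <= p_obs * (1 + 1e-7)])
  p_one <- min(1, p_one)
  p_two <- min(1, p_two)
  res <- list(table = t, p_one_sided = p_one, p_two_sided = p_two,
              odds_ratio = odds_ratio(t), or_method = "conditional MLE",
              alpha = alpha, significant = p_two < alpha, method = note)
  class(res) <- "exact_test_result"
  res
}

#' Conditional maximum-likelihood odds ratio
#'
#' Estimates the odds ratio of a 2x2 table under the noncentral
#' hypergeometric model (conditioning on both margins), by solving for the
#' value at which the conditional expectation of cell `a` equals its
#' observed count.  The estimate diverges to `+Inf` (or `0`) when the
#' observed count sits at the upper (lower) end of its support, i.e. with a
#' zero cell in the corresponding position.
#'
#' @param t A [contingency_2x2()] (or 2x2 matrix).
#' @return Positive real, `0`, or `Inf`; `NA` for a degenerate margin.
#' @export
odds_ratio <- function(t) {
  if (is.matrix(t)) t <- contingency_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  stopifnot(inherits(t, "contingency_2x2"))
  m <- t$a + t$c
  n2 <- t$b + t$d
  r1 <- t$a + t$b
  if (m == 0 || n2 == 0 || r1 == 0 || t$c + t$d == 0) return(NA_real_)
  lo <- max(0, r1 - n2)
  hi <- min(r1, m)
  if (lo == hi) return(NA_real_)      # support is a single point
  if (t$a == hi) return(Inf)
  if (t$a == lo) return(0)
  support <- lo:hi
  logdc <- lchoose(m, support) + lchoose(n2, r1 - support)
  cond_mean <- function(log_psi) {
    w <- logdc + support * log_psi
    w <- exp(w - max(w))
    sum(support * w) / sum(w)
  }
  f <- function(log_psi) cond_mean(log_psi) - t$a
  # bracket the root on the log scale
  lo_t <- -1; hi_t <- 1
  while (f(lo_t) > 0 && lo_t > -50) lo_t <- lo_t * 2
  while (f(hi_t) < 0 && hi_t < 50) hi_t <- hi_t * 2
  exp(stats::uniroot(f, c(lo_t, hi_t), tol = 1e-10)$root)
}

#' Incidence with exact binomial confidence interval
#'
#' Proportion `k/n` with the exact central Clopper-Pearson interval, the
#' standard exact method for small samples: the bounds are the beta
#' quantiles `qbeta(alpha/2; k, n-k+1)` and `qbeta(1-alpha/2; k+1, n-k)`,
#' with the conventional endpoint values at `k = 0` and `k = n`.
#'
#' @param k Number of events (here, transitional C/T calls).
#' @param n Denominator (here, C7 + C/T calls); must be >= 1.
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `incidence_result`: `k`, `n`, `proportion`,
#'   `ci_low`, `ci_high`, `ci_level`, `method`.
#' @export
#' @examples
#' incidence(5, 32)
incidence <- function(k, n, ci_level = 0.95) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("undefined-incidence: denominator n must be >= 1", call. = FALSE)
  }
  if (is.na(k) || k < 0 || k > n) stop("require 0 <= k <= n", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0,1)")
  a2 <- (1 - ci_level) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a2, k + 1, n - k)
  structure(list(k = as.integer(k), n = as.integer(n), proportion = k / n,
                 ci_low = lo, ci_high = hi, ci_level = ci_level,
                 method = "Clopper-Pearson exact central"),
            class = "incidence_result")
}

#' Compare transitional-vertebra incidence between two classified datasets
#'
#' Builds the 2x2 table `[[CT_A, C7_A], [CT_B, C7_B]]` from two identity
#' tables (output of [classify_dataset()]), runs the exact test, and
#' reports both group incidences with exact confidence intervals.  T1 and
#' INDETERMINATE calls are excluded from the denominators (and counted in
#' the report): the incidence of interest is among last-cervical-region
#' vertebrae.
#'
#' @param calls_A,calls_B Identity tables.
#' @param alpha Significance level.
#' @param ci_level Confidence level for the incidence intervals.
#' @return Object of class `incidence_comparison`: `test`
#'   ([fisher_exact()] result), `incidence_A`, `incidence_B`, `excluded_A`,
#'   `excluded_B` (counts of T1 + INDETERMINATE removed per group).
#' @export
compare_incidence <- function(calls_A, calls_B, alpha = 0.05,
                              ci_level = 0.95) {
  grp <- function(calls) {
    ct <- sum(calls$identity == "CT")
    c7 <- sum(calls$identity == "C7")
    excl <- nrow(calls) - ct - c7
    list(ct = ct, c7 = c7, excluded = excl)
  }
  A <- grp(calls_A)
  B <- grp(calls_B)
  if (A$ct + A$c7 == 0 || B$ct + B$c7 == 0) {
    stop("undefined-comparison: a group has no C7/CT calls after exclusion",
         call. = FALSE)
  }
  t <- contingency_2x2(A$ct, A$c7, B$ct, B$c7)
  structure(list(
    test = fisher_exact(t, alpha = alpha),
    incidence_A = incidence(A$ct, A$ct + A$c7, ci_level),
    incidence_B = incidence(B$ct, B$ct + B$c7, ci_level),
    excluded_A = A$excluded, excluded_B = B$excluded
  ), class = "incidence_comparison")
}

# Half-up rounding at the reported digit (round() in R rounds half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Format a proportion as a percent, one decimal, half-up
#' @param p Proportion in [0,1].
#' @return String like `"15.6%"`.
#' @export
format_pct <- function(p) {
  sprintf("%.1f%%", round_half_up(100 * p, 1))
}

#' Format a p-value to three decimals, half-up
#' @param p Probability.
#' @return String like `"0.005"`.
#' @export
format_p <- function(p) sprintf("%.3f", round_half_up(p, 3))

#' @export
print.exact_test_result <- function(x, ...) {
  cat("Fisher's exact test (", x$method, ")\n", sep = "")
  print(as_matrix_2x2(x$table))
  cat(sprintf("p (one-sided) = %s, p (two-sided) = %s\n",
              format_p(x$p_one_sided), format_p(x$p_two_sided)))
  cat(sprintf("odds ratio (%s) = %s; %ssignificant at alpha = %g\n",
              x$or_method, format(x$odds_ratio),
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @export
print.incidence_result <- function(x, ...) {
  cat(sprintf("incidence %d/%d = %s  [%s CI %.1f%%-%.1f%%, %s]\n",
              x$k, x$n, format_pct(x$proportion),
              paste0(100 * x$ci_level, "%"),
              100 * x$ci_low, 100 * x$ci_high, x$method))
  invisible(x)
}

#' @export
print.incidence_comparison <- function(x, ...) {
  cat("Group A: "); print(x$incidence_A)
  cat("Group B: "); print(x$incidence_B)
  if (x$excluded_A || x$excluded_B) {
    cat(sprintf("excluded (T1/indeterminate): A=%d, B=%d\n",
                x$excluded_A, x$excluded_B))
  }
  print(x$test)
  invisible(x)
}
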