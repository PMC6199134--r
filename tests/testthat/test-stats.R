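# Brute-force hypergeometric oracle built from factorials only.
oracle_table_prob <- function(a, b, c, d) {
  lf <- lfactorial
  exp(lf(a + b) + lf(c + d) + lf(a + c) + lf(b + d) -
        lf(a + b + c + d) - lf(a) - lf(b) - lf(c) - lf(d))
}
oracle_midp <- function(a, b, c, d) {
  k <- a + c
  p <- 0
  for (x in 0:k) {
    bb <- a + b - x; cc <- k - x; dd <- d - a + x
    if (bb < 0 || cc < 0 || dd < 0) next
    pr <- oracle_table_prob(x, bb, cc, dd)
    if (x > a) p <- p + pr
    if (x == a) p <- p + pr / 2
  }
  p
}

test_that("odds ratio follows the (A/C)/(B/D) definition", {
  expect_equal(round(odds_ratio(7, 15, 1, 14), 2), 6.53)
  expect_equal(round(odds_ratio(7, 15, 1, 14), 1), 6.5)
  expect_equal(odds_ratio(1, 1, 1, 1), 1)
  expect_equal(odds_ratio(2, 3, 4, 5), (2 / 4) / (3 / 5))
  expect_warning(or0 <- odds_ratio(3, 3, 0, 5), "undefined")
  expect_true(is.na(or0))
  expect_equal(odds_ratio(3, 3, 0, 5, correction = TRUE),
               (3.5 / 0.5) / (3.5 / 5.5))
  expect_error(odds_ratio(-1, 2, 3, 4), "non-negative")
})

test_that("mid-P equals brute-force enumeration and undercuts ordinary p", {
  res <- fisher_midp_one_tailed(7, 15, 1, 14)
  expect_equal(round(res$midp, 3), 0.041)
  expect_equal(res$midp, oracle_midp(7, 15, 1, 14), tolerance = 1e-12)
  # small table: enumeration over the whole 4-table support
  r2 <- fisher_midp_one_tailed(2, 1, 1, 2)
  expect_equal(r2$midp, oracle_midp(2, 1, 1, 2), tolerance = 1e-12)
  expect_lte(r2$midp, r2$p_ordinary)
  # support masses sum to one
  set.seed(3)
  for (i in 1:25) {
    t <- sample(0:8, 4, replace = TRUE)
    if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0) next
    r <- fisher_midp_one_tailed(t[1], t[2], t[3], t[4])
    m <- t[1] + t[2]; n <- t[3] + t[4]; k <- t[1] + t[3]
    supp <- max(0, k - n):min(k, m)
    expect_equal(sum(stats::dhyper(supp, m, n, k)), 1, tolerance = 1e-12)
    expect_lte(r$midp, r$p_ordinary + 1e-15)
  }
  expect_error(fisher_midp_one_tailed(0, 0, 0, 0), "impossible")
})

test_that("logistic fit matches the closed-form two-group solution", {
  d <- data.frame(x = rep(c(0, 1), each = 4),
                  died = c(1, 0, 0, 0, 1, 1, 1, 0))
  fit <- logistic_mortality(d, "x", covariates = character(0))
  # log-odds difference: log((3/1)/(1/3)) = log 9
  expect_equal(fit$estimate[fit$term == "x"], log(9), tolerance = 1e-4)
  expect_equal(fit$or[fit$term == "x"], 9, tolerance = 1e-3)
  expect_false(attr(fit, "separation"))
})

test_that("logistic and 2x2 odds ratios agree on a binary predictor", {
  set.seed(8)
  x <- rbinom(400, 1, 0.5)
  died <- rbinom(400, 1, plogis(-1 + 1.2 * x))
  a <- sum(x == 1 & died == 1); b <- sum(x == 1 & died == 0)
  cc <- sum(x == 0 & died == 1); d <- sum(x == 0 & died == 0)
  fit <- logistic_mortality(data.frame(x, died), "x",
                            covariates = character(0))
  expect_equal(fit$or[fit$term == "x"], odds_ratio(a, b, cc, d),
               tolerance = 1e-6)
})

test_that("complete separation is flagged, not silently estimated", {
  d <- data.frame(x = c(1:5, 11:15), died = rep(c(0, 1), each = 5))
  fit <- logistic_mortality(d, "x", covariates = character(0))
  expect_true(attr(fit, "separation"))
})

test_that("runs test exact mode equals full enumeration", {
  for (n1 in 2:5) for (n2 in 2:5) {
    pmf <- autoresus:::runs_exact_pmf(n1, n2)
    # enumerate every arrangement of n1 TRUE among n1+n2 positions
    counts <- integer(length(pmf))
    combs <- utils::combn(n1 + n2, n1)
    for (j in seq_len(ncol(combs))) {
      s <- rep(FALSE, n1 + n2)
      s[combs[, j]] <- TRUE
      r <- 1L + sum(diff(as.integer(s)) != 0)
      counts[r] <- counts[r] + 1L
    }
    enum <- counts / ncol(combs)
    expect_equal(pmf, enum, tolerance = 1e-12)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
  # maximal alternation: P(R <= r_max) must be 1
  alt <- rep(c(TRUE, FALSE), 5)
  expect_equal(runs_test(alt)$p, 1, tolerance = 1e-12)
})

test_that("coupling regression reports slope, R2 and linearity", {
  x <- seq(5, 60, 5)
  # exact collinearity makes summary.lm warn about a perfect fit
  fit <- suppressWarnings(coupling_regression(2 + 1.5 * x, x))
  expect_equal(fit$slope, 1.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$p_nonzero_slope, 1e-10)
  # parabola: residual signs run in blocks, runs test flags curvature
  xp <- seq(-6, 5, 1)
  fitp <- coupling_regression((xp - 0)^2, xp)
  expect_lt(fitp$runs_test_p, 0.05)
  # censored pairs are excluded by the caller contract
  expect_error(coupling_regression(c(1, 2), c(1, 2)), "insufficient")
  expect_equal(coupling_regression(c(1, 2, NA, 4, 331),
                                   c(1, 2, 3, NA, 5))$n, 3)
})

test_that("slope comparison behaves at both extremes", {
  set.seed(14)
  x <- seq(1, 15)
  y1 <- 1 * x + rnorm(15, 0, 0.1)
  y2 <- 2 * x + rnorm(15, 0, 0.1)
  fa <- coupling_regression(y1, x)
  fb <- coupling_regression(y2, x)
  expect_lt(compare_slopes(fa, fb)$p, 0.01)
  expect_equal(compare_slopes(fa, fa)$p, 1, tolerance = 1e-9)
  # equal true slopes: no signal expected
  y3 <- 1 * x + rnorm(15, 0, 0.5)
  expect_gt(compare_slopes(fa, coupling_regression(y3, x))$p, 0.01)
})

test_that("variance F test matches the direct CDF evaluation", {
  x <- c(1, 2, 3); y <- c(2, 4, 9)
  res <- variance_f_test(x, y)
  fstat <- var(x) / var(y)
  p_direct <- 2 * min(pf(fstat, 2, 2), 1 - pf(fstat, 2, 2))
  expect_equal(res$f, fstat, tolerance = 1e-12)
  expect_equal(res$p, p_direct, tolerance = 1e-12)
  expect_equal(variance_f_test(c(1, 2, 3), c(4, 5, 6))$p, 1)
  expect_error(variance_f_test(c(1, 1), c(2, 2)), "degenerate")
})
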