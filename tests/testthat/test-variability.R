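# Direct-summation oracle, written independently of the implementation.
oracle_descriptors <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sd_ <- sqrt(sum((x - m)^2) / (n - 1))
  ss <- 0
  for (i in seq_len(n - 1)) ss <- ss + (x[i + 1] - x[i])^2
  rmssd <- sqrt(ss / (n - 1))
  sd1 <- rmssd / sqrt(2)
  sd2 <- sqrt(max(0, 2 * sd_^2 - sd1^2))
  list(sd = sd_, cv = sd_ / m, rmssd = rmssd, sd1 = sd1, sd2 = sd2,
       area = pi * sd1 * sd2)
}

test_that("constant and alternating series give the textbook values", {
  d <- interval_descriptors(rep(0.25, 4))
  expect_equal(d$sd, 0)
  expect_equal(d$rmssd, 0)
  expect_equal(d$cv, 0)
  expect_equal(d$poincare_area, 0)
  d2 <- interval_descriptors(c(0.2, 0.3, 0.2, 0.3, 0.2))
  expect_equal(d2$rmssd, 0.1)
})

test_that("descriptors match the direct-summation oracle", {
  set.seed(11)
  for (rep in 1:20) {
    x <- stats::runif(sample(3:40, 1), 0.05, 0.5)
    d <- interval_descriptors(x)
    o <- oracle_descriptors(x)
    expect_equal(d$sd, o$sd, tolerance = 1e-12)
    expect_equal(d$cv, o$cv, tolerance = 1e-12)
    expect_equal(d$rmssd, o$rmssd, tolerance = 1e-12)
    expect_equal(d$sd1, o$sd1, tolerance = 1e-12)
    expect_equal(d$sd2, o$sd2, tolerance = 1e-12)
    expect_equal(d$poincare_area, o$area, tolerance = 1e-12)
    # structural identities
    expect_equal(d$sd1, d$rmssd / sqrt(2), tolerance = 1e-14)
    expect_equal(d$poincare_area, pi * d$sd1 * d$sd2, tolerance = 1e-14)
  }
})

test_that("descriptors are scale-equivariant and cv scale-free", {
  set.seed(12)
  x <- stats::runif(25, 0.1, 0.4)
  k <- 3.7
  d <- interval_descriptors(x)
  dk <- interval_descriptors(k * x)
  expect_equal(dk$sd, k * d$sd, tolerance = 1e-12)
  expect_equal(dk$rmssd, k * d$rmssd, tolerance = 1e-12)
  expect_equal(dk$sd1, k * d$sd1, tolerance = 1e-12)
  expect_equal(dk$sd2, k * d$sd2, tolerance = 1e-12)
  expect_equal(dk$poincare_area, k^2 * d$poincare_area, tolerance = 1e-12)
  expect_equal(dk$cv, d$cv, tolerance = 1e-12)
})

test_that("sd and cv are permutation-invariant but rmssd is not", {
  x <- c(0.2, 0.21, 0.3, 0.31, 0.2, 0.21)     # paired ordering
  y <- c(0.2, 0.3, 0.21, 0.31, 0.2, 0.21)     # permutation with big jumps
  dx <- interval_descriptors(x)
  dy <- interval_descriptors(y)
  expect_equal(dx$sd, dy$sd, tolerance = 1e-12)
  expect_equal(dx$cv, dy$cv, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(dx$rmssd, dy$rmssd)))
})

test_that("short or invalid series are rejected", {
  expect_error(interval_descriptors(c(0.2, 0.3)), "insufficient")
  expect_error(interval_descriptors(c(0.2, -0.1, 0.3)), "positive")
})
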