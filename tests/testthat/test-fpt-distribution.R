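test_that("timescales satisfy the sum/product rate identities", {
  ts <- fpt_timescales(0.5, 0.2, 0.1)
  expect_equal(unname(ts["alpha"]), 6.449490, tolerance = 1e-6)
  expect_equal(unname(ts["beta"]), 1.550510, tolerance = 1e-6)

  # degenerate symmetric no-return case
  ts0 <- fpt_timescales(1, 1, 0)
  expect_equal(unname(ts0), c(1, 1))

  set.seed(11)
  for (i in 1:10000) {
    k <- stats::rlnorm(3, 0, 1.5)
    ts <- fpt_timescales(k[1], k[2], k[3])
    s <- sum(k); p <- k[1] * k[2]
    expect_equal(sum(ts), s / p, tolerance = 1e-10)
    expect_equal(prod(ts), 1 / p, tolerance = 1e-10)
    expect_gte(ts["alpha"], ts["beta"])
  }

  expect_error(fpt_timescales(0, 1), "positive")
  expect_error(fpt_timescales(1, 1, -1), "non-negative")
})

test_that("rates_from_timescales inverts timescales (both roots)", {
  ts <- fpt_timescales(0.5, 0.2, 0.1)
  r <- fpt_rates(ts["alpha"], ts["beta"], k2_minus = 0.1)
  # one root recovers the generating rates, the other is the swap
  hit <- apply(r, 1, function(row)
    isTRUE(all.equal(unname(row), c(0.5, 0.2), tolerance = 1e-8)) ||
      isTRUE(all.equal(unname(row), c(0.2, 0.5), tolerance = 1e-8)))
  expect_true(any(hit))
  # round trip for both roots
  for (i in 1:2) {
    ts2 <- fpt_timescales(r[i, "k1_plus"], r[i, "k2_plus"], 0.1)
    expect_equal(unname(ts2), unname(ts), tolerance = 1e-8)
  }

  expect_equal(unname(fpt_rates(1, 1, 0)[1, ]), c(1, 1), tolerance = 1e-12)
  expect_error(fpt_rates(10, 1, k2_minus = 100), "no positive rates")
})

test_that("density matches arithmetic oracle, is normalized, reduces cleanly", {
  # direct arithmetic
  expect_equal(dfpt(1, alpha = 2, beta = 1), exp(-0.5) - exp(-1))
  expect_equal(dfpt(0, alpha = 2, beta = 1), 0)
  # mixed with c = 0 equals pure
  tau <- seq(0, 20, by = 0.5)
  expect_equal(dfpt(tau, 4, 0.5, c = 0), dfpt(tau, 4, 0.5))
  # argument order must not matter
  expect_equal(dfpt(tau, 0.5, 4, c = 0.1), dfpt(tau, 4, 0.5, c = 0.1))

  # normalization and non-negativity, pure and mixed, including c near 1/beta
  cases <- list(c(2, 1, 0), c(4, 0.5, 0.1), c(6.449, 1.551, 0.05),
                c(4, 0.5, 1.9), c(3, 3, 0), c(3, 3, 0.2))
  for (p in cases) {
    expect_true(all(dfpt(tau, p[1], p[2], p[3]) >= 0))
    norm <- stats::integrate(function(x) dfpt(x, p[1], p[2], p[3]), 0, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(norm, 1, tolerance = 1e-8)
  }

  expect_error(dfpt(-1, 2, 1), "non-negative")
  expect_error(dfpt(1, 2, 1, c = 2), "x > 1")
})

test_that("CDF is consistent with the density and has correct limits", {
  expect_equal(pfpt(0, 2, 1), 0)
  expect_equal(pfpt(2, 2, 1), 1 - (2 * exp(-1) - exp(-2)))
  expect_equal(pfpt(150, 2, 1), 1, tolerance = 1e-9)

  for (p in list(c(2, 1, 0), c(4, 0.5, 0.1), c(3, 3, 0.15))) {
    qs <- c(0.5, 1, 2, 5, 10)
    num <- vapply(qs, function(q)
      stats::integrate(function(x) dfpt(x, p[1], p[2], p[3]), 0, q,
                       rel.tol = 1e-10)$value, numeric(1))
    expect_equal(pfpt(qs, p[1], p[2], p[3]), num, tolerance = 1e-8)
    expect_true(all(diff(pfpt(seq(0, 50, 0.1), p[1], p[2], p[3])) >= 0))
  }
})

test_that("degenerate alpha == beta is the analytic limit", {
  tau <- c(0.3, 1, 3, 8)
  eps <- 1e-11
  expect_equal(dfpt(tau, 2, 2), dfpt(tau, 2 * (1 + eps), 2),
               tolerance = 1e-6)
  expect_equal(pfpt(tau, 2, 2, c = 0.1), pfpt(tau, 2 * (1 + eps), 2, c = 0.1),
               tolerance = 1e-6)
  expect_equal(dfpt(1, 2, 2), exp(-0.5) / 4)  # tau e^{-tau/a} / a^2
})

test_that("closed-form moments agree with numeric integration", {
  # pure: mean = alpha + beta, var = alpha^2 + beta^2
  m <- fpt_moments(6.449, 1.551)
  expect_equal(unname(m["mean"]), 8.0, tolerance = 1e-4)
  expect_equal(unname(m["var"]), 6.449^2 + 1.551^2)

  # mixed example: alpha*beta = 10.00226, mean = alpha+beta - 10.00226*0.05
  m2 <- fpt_moments(6.449, 1.551, c = 0.05)
  expect_equal(unname(m2["mean"]), 8.0 - 6.449 * 1.551 * 0.05)
  expect_equal(fpt_moments(4, 0.5, 0), fpt_moments(4, 0.5))

  for (p in list(c(2, 1, 0), c(4, 0.5, 0.1), c(6.449, 1.551, 0.05),
                 c(3, 3, 0.2))) {
    num <- numeric_fpt_moments(p[1], p[2], p[3])
    cf <- fpt_moments(p[1], p[2], p[3])
    expect_equal(unname(cf["mean"]), num$mean, tolerance = 1e-6)
    expect_equal(unname(cf["var"]), num$var, tolerance = 1e-6)
  }
  expect_error(fpt_moments(4, 0.5, c = 3), "x > 1")
})

test_that("a strongly limiting rate reduces the CDF to a single exponential", {
  tau <- seq(0, 400, by = 2)
  sup_prev <- Inf
  for (ratio in c(10, 100, 1000)) {
    ts <- fpt_timescales(k1_plus = 1 / ratio, k2_plus = 1, k2_minus = 0)
    sup <- max(abs(pfpt(tau, ts["alpha"], ts["beta"]) -
                     (1 - exp(-tau / ts["alpha"]))))
    expect_lt(sup, sup_prev)
    sup_prev <- sup
  }
  expect_lt(sup_prev, 1e-3)
})

test_that("quantile function inverts the CDF and deviates sample correctly", {
  p <- c(0.05, 0.25, 0.5, 0.9, 0.99)
  q <- qfpt(p, 4, 0.5, c = 0.1)
  expect_equal(pfpt(q, 4, 0.5, c = 0.1), p, tolerance = 1e-7)

  set.seed(3)
  x <- rfpt(40000, 4, 0.5, c = 0.1)
  m <- fpt_moments(4, 0.5, 0.1)
  expect_equal(mean(x), unname(m["mean"]),
               tolerance = 4 * sqrt(m["var"] / 40000) / m["mean"])
})
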