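# Forward loss model and the inverse estimators.

test_that("forward_ratio reproduces its closed forms and the recursion", {
  # no loss, equal fitness: ratio unchanged
  expect_equal(forward_ratio(0, 1, 7, 0.5), 0.5)
  # beta = 1 closed form (1 + R0) (1 - m)^-n - 1, hand-computable
  expect_equal(forward_ratio(0.001, 1, 10, 0), (1 / 0.999)^10 - 1,
               tolerance = 1e-12)
  expect_equal(forward_ratio(0.002, 1, 6, 0.01), 1.01 / 0.998^6 - 1,
               tolerance = 1e-12)
  # unequal fitness: step-by-step recursion oracle
  expect_equal(forward_ratio(0.001, 1.1, 10, 0),
               recur_ratio(0.001, 1.1, 10, 0), tolerance = 1e-12)
  expect_equal(forward_ratio(0.004, 0.9, 6, 0.02),
               recur_ratio(0.004, 0.9, 6, 0.02), tolerance = 1e-12)
  # pure fitness drift at m = 0
  expect_equal(forward_ratio(0, 1.25, 8, 0.3), 0.3 * 2^(8 * (1 / 1.25 - 1)),
               tolerance = 1e-12)
})

test_that("forward_ratio rejects invalid rates and fitness ratios", {
  expect_error(forward_ratio(-0.1, 1, 5, 0), "loss rate")
  expect_error(forward_ratio(1, 1, 5, 0), "loss rate")
  expect_error(forward_ratio(0.01, 0, 5, 0), "beta")
  expect_error(forward_ratio(0.01, 1, -1, 0), "n must be")
})

test_that("forward_ratio is strictly monotone in m and in n", {
  for (beta in c(0.9, 1, 1.1)) {
    ms <- seq(0, 0.05, length.out = 20)
    rn <- vapply(ms, forward_ratio, numeric(1), beta = beta, n = 8,
                 R0 = 0.01)
    expect_true(all(diff(rn) > 0))
  }
  ns <- seq(1, 20, length.out = 30)
  rn <- vapply(ns, function(n) forward_ratio(0.002, 1, n, 0), numeric(1))
  expect_true(all(diff(rn) > 0))
})

test_that("beta1 estimator inverts the forward model exactly", {
  rn <- forward_ratio(0.001, 1, 10, 0)
  expect_equal(estimate_m_beta1(0, rn, 10)$m, 0.001, tolerance = 1e-10)
  expect_equal(estimate_m_beta1(0.3, 0.3, 7)$m, 0)
  # printed closed form evaluated directly
  expect_equal(estimate_m_beta1(0, 1, 10)$m, 1 - 2^(-1 / 10),
               tolerance = 1e-12)
  expect_error(estimate_m_beta1(0, 0.1, 0), "n must be positive")
  # Rn < R0 yields a negative rate, reported rather than clamped
  expect_lt(estimate_m_beta1(0.05, 0.03, 5)$m, 0)
})

test_that("general estimator agrees with the beta = 1 closed form", {
  grid <- expand.grid(m = c(1e-4, 1e-3, 1e-2), n = c(2, 10, 20),
                      R0 = c(0, 0.05))
  for (i in seq_len(nrow(grid))) {
    rn <- forward_ratio(grid$m[i], 1, grid$n[i], grid$R0[i])
    exact <- estimate_m_beta1(grid$R0[i], rn, grid$n[i])$m
    for (mode in c("self_consistent", "conventional")) {
      est <- estimate_m_general(grid$R0[i], rn, grid$n[i], beta = 1,
                                mode = mode)
      expect_lt(abs(est$m - exact), 1e-10)
      expect_lt(abs(est$residual), 1e-12)
    }
  }
})

test_that("self-consistent estimator round-trips the forward model", {
  set.seed(101)
  for (i in 1:40) {
    m <- runif(1, 1e-5, 2e-2); beta <- runif(1, 0.8, 1.25)
    n <- runif(1, 2, 20); R0 <- runif(1, 0, 0.05)
    rn <- forward_ratio(m, beta, n, R0)
    est <- estimate_m_general(R0, rn, n, beta = beta,
                              mode = "self_consistent")
    expect_lt(abs(est$m - m) / m, 1e-6)
  }
})

test_that("pure-fitness drift is estimated as zero loss", {
  rn <- forward_ratio(0, 1.05, 8, 0.2)
  expect_equal(rn, 0.2 * 2^(8 * (1 / 1.05 - 1)), tolerance = 1e-12)
  expect_lt(abs(estimate_m_general(0.2, rn, 8, beta = 1.05)$m), 1e-10)
  for (beta in c(0.85, 1.2)) {
    rn <- forward_ratio(0, beta, 12, 0.01)
    expect_lt(abs(estimate_m_general(0.01, rn, 12, beta = beta)$m), 1e-10)
  }
})

test_that("the two fitness conventions differ for beta != 1 as derived", {
  # the printed q-equation multiplies MC- by 2^beta per MC+ generation, the
  # physical model by 2^(1/beta); at beta > 1 the printed convention
  # attributes more of the MC- excess to growth, hence returns a smaller m
  rn <- forward_ratio(0.002, 1.2, 10, 0)
  sc <- estimate_m_general(0, rn, 10, beta = 1.2, mode = "self_consistent")
  fs <- estimate_m_general(0, rn, 10, beta = 1.2, mode = "conventional")
  expect_equal(sc$m, 0.002, tolerance = 1e-8)
  expect_lt(fs$m, sc$m)
})

test_that("impossible ratio pairs raise a bracket error naming the range", {
  expect_error(estimate_m_general(0, 1e9, 0.1, beta = 1), "bracket")
})

test_that("linear estimator matches its arithmetic and stays within 5%", {
  expect_equal(estimate_m_linear(0, 0.0100552, 10)$m,
               0.0100552 / (10 * 1.0100552), tolerance = 1e-12)
  expect_equal(estimate_m_linear(0.2, 0.2, 9)$m, 0)
  expect_equal(estimate_m_linear(0.001, 0.003, 10)$m, 0.002 / (10 * 1.003),
               tolerance = 1e-12)
  # relative deviation from the exact inverse small whenever m n <= 0.05,
  # and growing with the cumulative loss m n
  devs <- sapply(c(0.005, 0.01, 0.03, 0.05, 0.1, 0.2), function(mn) {
    m <- mn / 10
    rn <- forward_ratio(m, 1, 10, 0.01)
    abs(estimate_m_linear(0.01, rn, 10)$m - m) / m
  })
  expect_true(all(devs[1:4] <= 0.05))
  expect_true(all(diff(devs) > 0))
})

test_that("division numbers follow from OD ratios and dilution", {
  expect_equal(generations_from_od(0.05, 3.2), 6)
  expect_equal(generations_from_od(0.05, 0.05), 0)
  expect_equal(generations_from_od(1.6, 1.6, 50), log2(50))
  expect_error(generations_from_od(0, 1), "positive")
  expect_error(generations_from_od(1, -2), "positive")
})

test_that("loss rate versus beta curves are consistent and monotone", {
  single <- loss_rate_vs_beta(0, 0.01, 10, 1.0)
  expect_equal(single$m, estimate_m_beta1(0, 0.01, 10)$m,
               tolerance = 1e-10)
  grid <- seq(0.5, 2, by = 0.1)
  rn <- forward_ratio(0.003, 1, 8, 0.01)
  sc <- loss_rate_vs_beta(0.01, rn, 8, grid, mode = "self_consistent")
  fs <- loss_rate_vs_beta(0.01, rn, 8, grid, mode = "conventional")
  expect_true(all(is.finite(sc$m)) && all(is.finite(fs$m)))
  expect_true(all(diff(sc$m) > 0))   # slower MC- growth needs more loss
  expect_true(all(diff(fs$m) < 0))   # printed convention runs the other way
  # each curve point with m >= 0 round-trips through the forward model it
  # inverts (strong fitness advantages of MC- cells can explain the data
  # with negative m, which forward_ratio's domain excludes)
  for (i in which(sc$m >= 0)) {
    expect_equal(forward_ratio(sc$m[i], grid[i], 8, 0.01), rn,
                 tolerance = 1e-6)
  }
  expect_error(loss_rate_vs_beta(0, 0.01, 10, c(1, -1)), "positive")
})
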