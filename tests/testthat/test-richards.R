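test_that("richards_weight matches the growth formula and its limits", {
  p <- richards_params(40, 20, 0.2, 1)
  # asymptote and half-curve point (B e^{-kt} = 1 gives W = A/2 at N = 1)
  expect_equal(richards_weight(p, 1e6), 40)
  expect_equal(richards_weight(p, log(20) / 0.2), 20)
  # independent arithmetic evaluation at an asymmetric parameter set
  p2 <- richards_params(45, 15, 0.25, 0.8)
  expect_equal(richards_weight(p2, 18), oracle_weight(45, 15, 0.25, 0.8, 18),
               tolerance = 1e-12)
  # overflow safety far before anthesis: weight -> 0, never NaN
  expect_true(is.finite(richards_weight(p, -1e4)))
  expect_equal(richards_weight(p, -1e4), 0, tolerance = 1e-12)
})

test_that("invalid Richards parameters are rejected", {
  expect_error(richards_params(-1, 20, 0.2, 1), "strictly positive")
  expect_error(richards_params(40, 20, 0, 1), "strictly positive")
  expect_error(richards_params(40, NA, 0.2, 1), "strictly positive")
})

test_that("richards_rate is the derivative of richards_weight", {
  p <- richards_params(40, 20, 0.2, 1)
  h <- 1e-5
  for (t in c(0, 5, 12.3, 25, 36)) {
    fd <- (richards_weight(p, t + h) - richards_weight(p, t - h)) / (2 * h)
    expect_equal(richards_rate(p, t), fd, tolerance = 1e-6)
  }
  expect_equal(richards_rate(p, 1e5), 0, tolerance = 1e-12)
  expect_true(all(richards_rate(p, seq(-20, 60, 2)) > 0))
})

test_that("weight is monotone in t and traits scale linearly with A", {
  for (ps in random_richards(20, seed = 11)) {
    p <- richards_params(as.list(ps))
    w <- richards_weight(p, seq(-10, 60, length.out = 200))
    expect_true(all(diff(w) >= 0))
    tr1 <- filling_traits(p)
    p2 <- richards_params(2 * ps[["A"]], ps[["B"]], ps[["k"]], ps[["N"]])
    tr2 <- filling_traits(p2)
    expect_equal(tr2$GFR_max, 2 * tr1$GFR_max)
    expect_equal(tr2$GFR_mean, 2 * tr1$GFR_mean)
    expect_equal(tr2$T_fast, tr1$T_fast)   # durations independent of A
  }
})

test_that("filling traits reduce to the logistic closed forms at N = 1", {
  tr <- filling_traits(richards_params(40, 20, 0.2, 1))
  expect_equal(tr$GFR_max, 0.2 * 40 / 4)        # k A / 4
  expect_equal(tr$GFR_mean, 40 * 0.2 / 6)       # A k / (2 (N + 2))
  expect_lt(tr$GFR_mean, tr$GFR_max)
  expect_true(tr$T1 < tr$T2 && tr$T2 < tr$T3)
  expect_equal(tr$T_slow, tr$T1)
  expect_equal(tr$T_fast, tr$T2 - tr$T1)
  expect_equal(tr$T_slight, tr$T3 - tr$T2)
})

test_that("phase end-times are the third-derivative zeros and the 99% point", {
  for (ps in random_richards(25, seed = 7)) {
    p <- richards_params(as.list(ps))
    tr <- filling_traits(p)
    zeros <- sort(oracle_d3_zeros(ps[["A"]], ps[["B"]], ps[["k"]], ps[["N"]]))
    expect_length(zeros, 2L)
    expect_equal(tr$T1, zeros[1], tolerance = 1e-6)
    expect_equal(tr$T2, zeros[2], tolerance = 1e-6)
    om <- oracle_rate_max(ps[["A"]], ps[["B"]], ps[["k"]], ps[["N"]])
    expect_equal(tr$GFR_max, om$objective, tolerance = 1e-8)
    expect_equal(richards_weight(p, tr$T3) / ps[["A"]], 0.99, tolerance = 1e-10)
  }
})

test_that("T_fast does not depend on B", {
  for (B in c(1, 2, 5, 10, 20, 50)) {
    tr <- filling_traits(richards_params(40, B, 0.2, 0.9))
    base <- filling_traits(richards_params(40, 1, 0.2, 0.9))
    expect_equal(tr$T_fast, base$T_fast, tolerance = 1e-12)
    expect_equal(tr$T_slight, base$T_slight, tolerance = 1e-12)
    # both boundaries shift by ln(B)/k
    expect_equal(tr$T1 - base$T1, log(B) / 0.2, tolerance = 1e-10)
  }
})

test_that("a curve already past its slow phase at anthesis is flagged, not clamped", {
  # tiny B puts T1 well before t = 0
  tr <- filling_traits(richards_params(40, 0.5, 0.2, 1))
  expect_lt(tr$T1, 0)
  expect_identical(tr$quality_flag, "nonpositive_T1")
})

test_that("noiseless generated series are recovered exactly", {
  t <- seq(0, 36, by = 6)
  truth <- c(A = 42, B = 18, k = 0.22, N = 0.9)
  w <- oracle_weight(42, 18, 0.22, 0.9, t)
  fit <- fit_richards(t, w)
  expect_true(fit$diagnostics$converged)
  expect_equal(unlist(fit$params), truth, tolerance = 1e-4)
  expect_lt(fit$diagnostics$rss, 1e-10)
})

test_that("fit rejects undersized or malformed series", {
  expect_error(fit_richards(c(0, 6, 12, 18), c(2, 8, 20, 30)), "at least 5")
  expect_error(fit_richards(c(0, 6, 6, 18, 24), c(2, 8, 10, 30, 33)),
               "strictly increasing")
  expect_error(fit_richards(seq(0, 24, 6), c(2, -1, 10, 30, 33)), "positive")
})

test_that("fitted N stays near 1 for logistic data", {
  t <- seq(0, 36, by = 6)
  w <- oracle_weight(40, 20, 0.2, 1, t)
  set.seed(3)
  fit <- fit_richards(t, w + rnorm(length(t), 0, 0.2))
  expect_true(fit$diagnostics$converged)
  expect_equal(fit$params$N, 1, tolerance = 0.1)
})

test_that("A is recovered within 5% under the trial noise level", {
  t <- seq(0, 36, by = 6)
  w0 <- oracle_weight(42, 18, 0.22, 0.9, t)
  ok <- 0L; rel_err <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    fit <- fit_richards(t, pmax(w0 + rnorm(length(t), 0, 0.5), 0.1))
    rel_err[s] <- abs(fit$params$A - 42) / 42
    if (fit$diagnostics$converged && rel_err[s] < 0.05) ok <- ok + 1L
  }
  expect_gte(ok / 50, 0.95)
  expect_lt(median(rel_err), 0.02)
})
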