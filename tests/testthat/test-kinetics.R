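test_that("bound fraction follows first-order release decay", {
  p <- digestion_params(O = 1, k1 = 1, k2 = 0.1)
  expect_equal(bound_fraction(0, p), 1)
  expect_equal(bound_fraction(1, p), exp(-1), tolerance = 1e-12)
  expect_lt(bound_fraction(1e6, p), 1e-300)
  d <- seq(0, 10, by = 0.1)
  expect_true(all(diff(bound_fraction(d, p)) < 0))
  expect_error(bound_fraction(-1, p), "nonnegative")
})

test_that("apparent occupancy matches the closed-form solution and its limits", {
  p <- digestion_params(1, 1, 0.1)
  expect_equal(apparent_occupancy(0, p), 0)
  # at the maximum the curve height equals exp(-k2 d*) analytically
  dstar <- time_of_maximum(p)
  expect_equal(apparent_occupancy(dstar, p), exp(-0.1 * dstar),
               tolerance = 1e-10)
  # degenerate equal-rates limiting form O k d exp(-k d)
  expect_equal(apparent_occupancy(0.5, digestion_params(0.5, 2, 2)),
               0.5 * 1 * exp(-1), tolerance = 1e-12)
  # linear in O, bounded by O, unimodal
  p2 <- digestion_params(0.3, 1, 0.1)
  d <- seq(0, 50, by = 0.05)
  expect_equal(apparent_occupancy(d, p2), 0.3 * apparent_occupancy(d, p))
  expect_true(all(apparent_occupancy(d, p) <= 1))
  s <- sign(diff(apparent_occupancy(d, p)))
  expect_equal(sum(diff(s[s != 0]) != 0), 1)  # one sign change: unimodal
})

test_that("closed form agrees with numerical integration of the rate equations", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  pars <- random_params(50)
  worst <- 0
  for (i in seq_len(nrow(pars))) {
    O <- pars$O[i]; k1 <- pars$k1[i]; k2 <- pars$k2[i]
    d <- seq(0, 5 / k2, length.out = 40)
    sol <- ode_oracle(d, O, k1, k2)
    cf_N <- apparent_occupancy(d, pars[i, ])
    cf_B <- O * bound_fraction(d, pars[i, ])
    # floor the denominator where the solution underflows toward zero
    relN <- abs(cf_N - sol$N) / pmax(abs(sol$N), 1e-6 * O)
    relB <- abs(cf_B - sol$B) / pmax(abs(sol$B), 1e-6 * O)
    worst <- max(worst, relN[-1], relB)
  }
  expect_lt(worst, 1e-6)
})

test_that("mass bookkeeping: released plus bound never exceeds the initial pool", {
  set.seed(7)
  pars <- random_params(20)
  for (i in seq_len(nrow(pars))) {
    p <- as.list(pars[i, ])
    d <- c(0, 10^seq(-3, 2, length.out = 50))
    fB <- bound_fraction(d, p)
    fN <- apparent_occupancy(d, p) / p$O
    expect_true(all(fB + fN <= 1 + 1e-12))
    expect_equal(fB[1] + fN[1], 1)
  }
  # equality throughout when nothing decays (k2 = 0)
  p0 <- list(O = 1, k1 = 2, k2 = 0)
  d <- seq(0, 5, by = 0.1)
  expect_equal(bound_fraction(d, p0) + apparent_occupancy(d, p0),
               rep(1, length(d)), tolerance = 1e-12)
})

test_that("k2 = 0 gives a monotone saturating curve O(1 - exp(-k1 d))", {
  p <- list(O = 0.7, k1 = 1.5, k2 = 0)
  d <- seq(0, 10, by = 0.1)
  expect_equal(apparent_occupancy(d, p), 0.7 * (1 - exp(-1.5 * d)),
               tolerance = 1e-12)
  expect_identical(time_of_maximum(p), Inf)
})

test_that("time of maximum solves the release-equals-decay condition", {
  p <- digestion_params(1, 1, 0.1)
  expect_equal(time_of_maximum(p), log(10) / 0.9, tolerance = 1e-12)
  expect_equal(time_of_maximum(digestion_params(1, 2, 2)), 0.5)
  # rate-time rescaling: doubling both rates halves d*
  expect_equal(time_of_maximum(digestion_params(1, 2, 0.2)),
               time_of_maximum(p) / 2, tolerance = 1e-12)
  # grid search oracle across random parameter sets
  set.seed(202)
  pars <- random_params(50)
  for (i in seq_len(nrow(pars))) {
    p <- as.list(pars[i, ])
    ds <- time_of_maximum(p)
    g <- seq(ds / 50, ds * 5, length.out = 20001)
    dg <- g[which.max(apparent_occupancy(g, p))]
    expect_lt(abs(dg - ds) / ds, 1e-3)
    # stationarity: derivative vanishes at d*
    expect_lt(abs(qmnase:::apparent_occupancy_deriv(ds, p)), 1e-8 * p$O)
  }
})

test_that("apparent occupancy is continuous across the equal-rates degeneracy", {
  for (delta in c(1e-9, -1e-9)) {
    p_near <- list(O = 0.8, k1 = 2, k2 = 2 * (1 + delta))
    lim <- 0.8 * 2 * 0.7 * exp(-2 * 0.7)
    expect_equal(apparent_occupancy(0.7, p_near, eps = 1e-12), lim,
                 tolerance = 1e-6)
  }
})

test_that("tail slope of log apparent occupancy converges to -k2", {
  set.seed(303)
  for (i in 1:20) {
    k2 <- exp(runif(1, log(0.01), log(1)))
    k1 <- k2 * exp(runif(1, log(2), log(100)))  # canonical ordering k1 > k2
    O <- runif(1, 0.1, 1)
    p <- list(O = O, k1 = k1, k2 = k2)
    d <- c(30, 31) / k2  # d >> 1/k2
    slope <- diff(log(apparent_occupancy(d, p))) / diff(d)
    expect_lt(abs(slope + k2) / k2, 0.01)
  }
})

test_that("MACC titration fit recovers the slope and the sign convention", {
  up <- fit_macc(c(10, 20, 30), c(1, 2, 4))
  expect_equal(up$a, 10 / log(2), tolerance = 1e-10)
  expect_equal(up$macc, -10 / log(2), tolerance = 1e-10)
  expect_identical(up$label, "inaccessible")
  down <- fit_macc(c(30, 20, 10), c(1, 2, 4))
  expect_equal(down$macc, 10 / log(2), tolerance = 1e-10)
  expect_identical(down$label, "accessible")
  flat <- fit_macc(c(5, 5, 5), c(1, 2, 4))
  expect_equal(flat$a, 0)
  expect_identical(flat$label, "neutral")
  expect_error(fit_macc(c(1, 2), c(3, 3)), "distinct")
})

test_that("model MACC score flips sign exactly once, at the count maximum", {
  set.seed(404)
  pars <- rbind(data.frame(O = 1, k1 = 1, k2 = 0.1), random_params(20))
  for (i in seq_len(nrow(pars))) {
    p <- as.list(pars[i, ])
    ds <- time_of_maximum(p)
    d <- ds * 10^seq(-2, 2, length.out = 201)
    sc <- macc_model_score(d, p)
    expect_true(all(sc[d < ds * 0.999] < 0))
    expect_true(all(sc[d > ds * 1.001] > 0))
    expect_lt(abs(macc_model_score(ds, p)), 1e-8 * p$O)
    # finite-difference oracle: score has the opposite sign of the local trend
    h <- ds * 1e-6
    fd <- (apparent_occupancy(d + h, p) - apparent_occupancy(pmax(d - h, 0), p))
    expect_true(all(sign(sc[abs(fd) > 1e-12]) == -sign(fd[abs(fd) > 1e-12])))
  }
  expect_error(macc_model_score(0, list(O = 1, k1 = 1, k2 = 0.1)), "d > 0")
})
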