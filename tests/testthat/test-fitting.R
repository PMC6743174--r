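test_that("noiseless model counts are recovered to high precision", {
  truth <- list(O = 0.8, k1 = 1.0, k2 = 0.05)
  y <- apparent_occupancy(default_times, truth)
  fit <- digestion_fit(default_times, y)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.8, 1.0, 0.05), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, data.frame(d = 0)), 0)
})

test_that("degenerate inputs are flagged unfit, never an exception", {
  f0 <- digestion_fit(default_times, rep(0, 6))
  expect_true(f0$unfit)
  expect_false(f0$converged)
  expect_true(all(is.na(coef(f0))))
  expect_error(predict(f0), "unfit")
  f2 <- digestion_fit(default_times, c(0, 3, 0, 0, 2, 0))
  expect_true(f2$unfit)  # only two positive points
  expect_error(digestion_fit(c(1, 2), c(1, 2)), "3 time points")
  expect_error(digestion_fit(default_times, rep(-1, 6)), "nonnegative")
})

test_that("fitted O scales with the counts while rates are invariant", {
  set.seed(12)
  y <- simulate_counts(list(O = 0.6, k1 = 1.2, k2 = 0.08),
                       default_times, 500)$counts
  f1 <- digestion_fit(default_times, y)
  f2 <- digestion_fit(default_times, y * 37)
  expect_equal(unname(coef(f2)["O"]), 37 * unname(coef(f1)["O"]),
               tolerance = 1e-5)
  expect_equal(coef(f2)[c("k1", "k2")], coef(f1)[c("k1", "k2")],
               tolerance = 1e-5)
})

test_that("reported k2 is the tail exponent even for swapped-rate truths", {
  # (k1, k2) and (k2, k1) generate the same curve up to amplitude; the fit
  # must come back in the canonical orientation k2 <= k1
  y <- apparent_occupancy(default_times, list(O = 1, k1 = 0.05, k2 = 0.8))
  fit <- digestion_fit(default_times, y)
  expect_lt(coef(fit)["k2"], coef(fit)["k1"])
  expect_equal(unname(coef(fit)[c("k1", "k2")]), c(0.8, 0.05),
               tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
})

test_that("the three parameters control distinct curve features", {
  p <- list(O = 0.5, k1 = 1, k2 = 0.05)
  d <- seq(0.1, 60, length.out = 200)
  base <- apparent_occupancy(d, p)
  # sensitivity to O is the curve itself (exact proportionality)
  sO <- (apparent_occupancy(d, list(O = 0.5 * 1.01, k1 = 1, k2 = 0.05)) - base)
  expect_equal(sO, 0.01 * base, tolerance = 1e-9)
  # k1 sensitivity concentrates at small d, k2 sensitivity at large d
  s1 <- abs(apparent_occupancy(d, list(O = 0.5, k1 = 1.01, k2 = 0.05)) - base)
  s2 <- abs(apparent_occupancy(d, list(O = 0.5, k1 = 1, k2 = 0.0505)) - base)
  expect_gt(which.max(s2), which.max(s1))
  expect_lt(d[which.max(s1)], time_of_maximum(p))
  expect_gt(d[which.max(s2)], time_of_maximum(p))
})

test_that("Monte-Carlo recovery at peak expectation 1000 is accurate for typical loci", {
  set.seed(2024)
  n <- 200
  errs <- t(vapply(seq_len(n), function(i) {
    tr <- list(O = runif(1, 0.2, 1), k1 = rlnorm(1, 0, 0.5),
               k2 = rlnorm(1, log(0.05), 0.5))
    sc <- simulate_counts(tr, default_times, 1000)
    f <- digestion_fit(default_times, sc$counts)
    c(abs(coef(f)["O"] - sc$O_scaled) / sc$O_scaled,
      abs(coef(f)["k1"] - tr$k1) / tr$k1)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.10)  # O
  expect_lt(median(errs[, 2]), 0.10)  # k1
})

test_that("fragile classification is strict at the threshold", {
  expect_true(classify_fragile(12))
  expect_false(classify_fragile(1.0))
  expect_false(classify_fragile(10.0))
  expect_true(classify_fragile(10.5, threshold = 10))
  expect_false(classify_fragile(10.5, threshold = 20))
})

test_that("time classes index the strongest signal with early tie-break", {
  expect_equal(assign_time_class(c(1, 2, 9, 4, 3, 1)), 3L)
  expect_equal(assign_time_class(c(9, 2, 3, 4, 3, 1)), 1L)
  expect_equal(assign_time_class(c(1, 7, 7, 4, 3, 1)), 2L)  # tie: earlier
  expect_warning(assign_time_class(rep(2, 6)), "equal")
})

test_that("occupancy bins are equal-count quantiles, lowest first", {
  expect_equal(bin_by_occupancy(c(0.9, 0.1, 0.5), n_bins = 3), c(3L, 1L, 2L))
  expect_error(bin_by_occupancy(c(1, 2), n_bins = 9), "fewer")
  # constant O: deterministic assignment by input order
  expect_equal(bin_by_occupancy(rep(0.5, 6), n_bins = 3),
               c(1L, 1L, 2L, 2L, 3L, 3L))
  # quantile oracle on uniform occupancies
  set.seed(99)
  O <- runif(900)
  bins <- bin_by_occupancy(O, 9)
  expect_equal(as.vector(table(bins)), rep(100L, 9))
  means <- as.vector(tapply(O, bins, mean))
  # empirical-quantile noise at n = 900 is ~sqrt(p(1-p)/n) ~ 0.015
  expect_true(all(abs(means - (2 * (1:9) - 1) / 18) < 0.05))
})

test_that("batch fitting keeps every locus and flags the degenerate ones", {
  y <- apparent_occupancy(default_times, list(O = 0.5, k1 = 1, k2 = 0.05))
  counts <- rbind(a = y, b = 2 * y, c = rep(0, 6))
  tab <- fit_loci(counts, default_times, n_bins = 2)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$locus, c("a", "b", "c"))
  expect_true(tab$unfit[3])
  expect_equal(tab$O[2] / tab$O[1], 2, tolerance = 1e-4)
  expect_equal(tab$occupancy_bin[1:2], c(1L, 2L))
  expect_true(is.na(tab$occupancy_bin[3]))
  # deterministic rerun
  expect_identical(tab, fit_loci(counts, default_times, n_bins = 2))
})

test_that("model object methods are coherent", {
  set.seed(5)
  y <- simulate_counts(list(O = 0.7, k1 = 1, k2 = 0.05), default_times, 800)$counts
  fit <- digestion_fit(default_times, y)
  expect_s3_class(fit, "digestion_fit")
  expect_output(print(fit), "k1")
  s <- summary(fit)
  expect_equal(s$d_max, time_of_maximum(as.list(coef(fit))), tolerance = 1e-10)
  expect_output(print(s), "peak")
  expect_equal(deviance(fit), fit$rss)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(6L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
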