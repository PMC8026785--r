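test_that("biexponential parent-fraction fit matches the measured decay", {
  pf <- fit_parent_fraction(c(15, 30, 60, 120, 240),
                            c(0.37, 0.295, 0.19, 0.146, 0.044))
  expect_true(pf$converged)
  expect_equal(pf$A1 + (1 - pf$A1), 1)            # pf(0) = 1 by construction
  expect_lt(abs(predict(pf, 60) - 0.19), 0.035)   # within the measured SEM
  # fractions all 1: no decay at all
  pf1 <- fit_parent_fraction(c(5, 15, 60, 120), rep(1, 4))
  expect_equal(predict(pf1, c(0, 30, 200)), rep(1, 3))
})

test_that("noiseless biexponential samples are recovered across a rate grid", {
  times <- c(5, 15, 30, 60, 90, 120, 180, 240)
  for (A1 in c(0.3, 0.6, 0.9))
    for (l1 in c(0.05, 0.1, 0.2))
      for (l2 in c(0.001, 0.005, 0.02)) {
        f <- A1 * exp(-l1 * times) + (1 - A1) * exp(-l2 * times)
        pf <- fit_parent_fraction(times, f)
        expect_lt(rel_err(pf$A1, A1), 1e-3)
        expect_lt(rel_err(pf$lambda1, l1), 1e-3)
        expect_lt(rel_err(pf$lambda2, l2), 1e-3)
      }
})

test_that("the biexponential never fits worse than a single exponential", {
  # nested-model dominance on randomized synthetic sample sets
  set.seed(42)
  times <- c(5, 15, 30, 60, 90, 120, 180, 240)
  for (i in 1:20) {
    A1 <- runif(1, 0.3, 0.9)
    f <- A1 * exp(-runif(1, 0.02, 0.2) * times) +
      (1 - A1) * exp(-runif(1, 0.001, 0.02) * times)
    f <- pmin(pmax(f + rnorm(length(f), 0, 0.02), 0), 1)
    pf <- fit_parent_fraction(times, f)
    single_rss <- stats::optimize(function(l) sum((exp(-l * times) - f)^2),
                                  c(0, 1))$objective
    expect_lte(pf$rss, single_rss + 1e-10)
  }
})

test_that("parent-fraction fitting rejects invalid input", {
  expect_error(fit_parent_fraction(c(10, 20, 30), c(0.9, 0.5, 0.3)),
               "insufficient")
  expect_error(fit_parent_fraction(c(10, 20, 30, 25), c(0.9, 0.5, 0.3, 0.2)),
               "increasing")
  expect_error(fit_parent_fraction(c(10, 20, 30, 40), c(1.2, 0.5, 0.3, 0.2)),
               "0, 1")
})

test_that("the metabolite-corrected input is plasma times parent fraction", {
  b <- blood_series(c(10, 60), c(120, 60), c(100, 50))
  pf <- structure(list(A1 = 1, lambda1 = 0, lambda2 = 0), class = "pf_model")
  expect_equal(build_mcaif(b, pf)$values, b$plasma)  # pf == 1: identity
  # forced arithmetic: pf(10) = 0.5, pf(60) = 0.2 via two known points
  pf2 <- fit_parent_fraction(c(1e-3, 10, 60, 240),
                             c(1, 0.5, 0.2, 0.05))
  v <- build_mcaif(b, pf2)$values
  expect_equal(v, b$plasma * predict(pf2, b$times))
  expect_true(all(v <= b$plasma))
})

test_that("corrected values never exceed plasma and rise with the fraction", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    b <- blood_series(sort(runif(n, 0.1, 120)), runif(n, 1, 100),
                      runif(n, 1, 100))
    pf_lo <- structure(list(A1 = 0.7, lambda1 = 0.1, lambda2 = 0.01),
                       class = "pf_model")
    pf_hi <- structure(list(A1 = 0.7, lambda1 = 0.05, lambda2 = 0.005),
                       class = "pf_model")
    lo <- build_mcaif(b, pf_lo)$values
    hi <- build_mcaif(b, pf_hi)$values
    expect_true(all(lo <= b$plasma))
    expect_true(all(lo <= hi))     # pointwise larger pf never lowers the mcAIF
  }
})

test_that("free fraction is the ultrafiltrate to plasma ratio", {
  expect_equal(free_fraction(50, 50)$fp, 1)
  expect_equal(free_fraction(21.3, 50)$fp, 0.426)
  r <- free_fraction(replicates = c(0.42, 0.43, 0.44))
  expect_equal(r$fp, 0.43)
  expect_equal(r$sem, stats::sd(c(0.42, 0.43, 0.44)) / sqrt(3))
  expect_error(free_fraction(10, 0), "positive")
})

test_that("plasma to whole-blood ratio is the elementwise division", {
  t <- c(1, 5, 30, 60)
  b <- blood_series(t, c(10, 20, 8, 4), c(10, 20, 8, 4))
  r <- plasma_wb_ratio(b)
  expect_equal(r$ratio, rep(1, 4))
  expect_equal(r$sd, 0)
  b2 <- blood_series(t, c(10, 20, 8, 4), 0.9 * c(10, 20, 8, 4))
  expect_equal(plasma_wb_ratio(b2)$mean, 0.90)
  set.seed(1)
  wb <- runif(10, 1, 50); pl <- runif(10, 1, 50)
  b3 <- blood_series(sort(runif(10, 0, 100)), wb, pl)
  expect_equal(plasma_wb_ratio(b3)$ratio, pl / wb)
})

test_that("blood and parent-fraction tables round-trip through CSV", {
  b <- blood_series(c(0.5, 1, 5), c(10, 50, 20), c(9, 45, 18))
  path <- tempfile(fileext = ".csv")
  write_blood_table(b, path)
  b2 <- read_blood_table(path)
  expect_equal(b2$plasma, b$plasma)
  expect_equal(b2$times, b$times)
  pfs <- data.frame(time_min = c(5, 15, 60), parent_fraction = c(0.8, 0.4, 0.2))
  write_pf_table(pfs, path)
  expect_equal(read_pf_table(path), pfs)
})
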