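test_that("analytic forward model matches stiff ODE integration", {
  # frame averaging resolved at dt = 0.02 min for the sub-0.1% comparison
  sim <- simulate_tissue(ref_params, ref_input, ref_frames, dt = 0.02)$values
  fo <- ode_oracle_frames(ref_params, ref_input, ref_frames)
  keep <- fo > 0.01 * max(fo)
  expect_lt(max(abs(sim[keep] - fo[keep]) / fo[keep]), 1e-3)
  # randomized admissible parameter sets
  set.seed(13)
  for (i in 1:8) {
    p <- compartment_params(runif(1, 0.1, 0.8), runif(1, 0.02, 0.2),
                            runif(1, 0.005, 0.1), runif(1, 0.01, 0.1))
    sim <- simulate_tissue(p, ref_input, ref_frames, dt = 0.02)$values
    fo <- ode_oracle_frames(p, ref_input, ref_frames)
    keep <- fo > 0.01 * max(fo)
    expect_lt(max(abs(sim[keep] - fo[keep]) / fo[keep]), 1e-3)
  }
})

test_that("two-tissue model with k3 = 0 collapses to the one-tissue model", {
  p2 <- compartment_params(0.37, 0.047, 0, 0.05)
  p1 <- compartment_params(0.37, 0.047, 0, 0)
  expect_equal(simulate_tissue(p2, ref_input, ref_frames)$values,
               simulate_tissue(p1, ref_input, ref_frames)$values,
               tolerance = 1e-10)
  p0 <- compartment_params(0, 0.047, 0.03, 0.028)
  expect_equal(simulate_tissue(p0, ref_input, ref_frames)$values,
               rep(0, nrow(ref_frames)))
})

test_that("noiseless fits recover the generating microparameters", {
  f <- fit_region("2tcm", ref_tac, ref_input)
  expect_true(f$converged)
  expect_lt(rel_err(f$params$K1, 0.37), 0.01)
  expect_lt(rel_err(f$params$k2, 0.047), 0.01)
  expect_lt(rel_err(f$params$k3, 0.03), 0.01)
  expect_lt(rel_err(f$params$k4, 0.028), 0.01)
  expect_lt(rel_err(f$VT, ref_vt), 0.005)
  expect_equal(f$VT, f$VND * (1 + f$BPND), tolerance = 1e-10)
  expect_true(f$reliable)
})

test_that("irreversible kinetics pin k4 at the bound and drop BP_ND", {
  p <- compartment_params(0.37, 0.047, 0.03, 0)
  tc <- simulate_tissue(p, ref_input, ref_frames, region = "irr")
  f <- fit_region("2tcm", tc, ref_input)
  expect_true(f$irreversible_limit)
  expect_true(is.na(f$BPND))
  expect_true(is.na(f$VT))
  expect_false(f$reliable)
})

test_that("AIC prefers the two-tissue model on two-tissue data", {
  f1 <- fit_region("1tcm", ref_tac, ref_input)
  f2 <- fit_region("2tcm", ref_tac, ref_input)
  expect_lt(f2$aic, f1$aic)
  # Monte-Carlo at study-like noise: 2TCM wins in the majority of replicates
  cfgn <- study_config()
  set.seed(31)
  wins <- 0L
  for (i in 1:12) {
    v <- ref_tac$values
    sd <- cfgn$noise_scale * sqrt(pmax(v, 0.02 * max(v)) / ref_frames$dur)
    tc <- tac("rep", ref_frames, v + rnorm(length(v), 0, sd))
    wins <- wins +
      (fit_region("2tcm", tc, ref_input)$aic <
         fit_region("1tcm", tc, ref_input)$aic)
  }
  expect_gt(wins, 6)
})

test_that("AIC formula behaves as n log(rss/n) + 2k", {
  expect_equal(compute_aic(10, 33, 4) - compute_aic(10, 33, 2), 4)
  expect_equal(compute_aic(5, 33, 4) - compute_aic(10, 33, 4), -33 * log(2))
  expect_error(compute_aic(0, 33, 4), "positive")
  expect_error(compute_aic(10, 4, 4), "more frames")
  # comparison invariant to common rescaling of activities (weights follow);
  # needs a noisy curve so the residual scale is meaningful
  set.seed(77)
  v <- ref_tac$values
  nv <- v + rnorm(length(v), 0, 1.2 * sqrt(pmax(v, 0.02 * max(v)) /
                                             ref_frames$dur))
  tcn <- tac("x", ref_frames, nv)
  sc <- 3.7
  tc2 <- tac("x", ref_frames, nv * sc)
  in2 <- input_function(ref_input$times, ref_input$values * sc)
  d1 <- fit_region("2tcm", tcn, ref_input)$aic -
    fit_region("1tcm", tcn, ref_input)$aic
  d2 <- fit_region("2tcm", tc2, in2)$aic - fit_region("1tcm", tc2, in2)$aic
  expect_equal(d1, d2, tolerance = 1e-3)
})

test_that("coupled fit recovers a shared V_ND and equals the single fit when regions agree", {
  tacs <- make_tacs(noiseless_cfg, ref_input, "test", seed = 1,
                    include_whole_brain = FALSE)
  cf <- fit_coupled(tacs, ref_input)
  expect_lt(rel_err(cf$shared_VND, 7.89), 0.01)
  bps <- vapply(cf$per_region, function(f) f$BPND, numeric(1))
  expect_lt(rel_err(mean(bps), mean(default_region_truth()$BP)), 0.02)
  for (f in cf$per_region)
    expect_equal(f$params$K1 / f$params$k2, cf$shared_VND, tolerance = 1e-10)
  # identical regions: coupled estimates equal the unconstrained fit
  two <- list(a = tac("a", ref_frames, ref_tac$values),
              b = tac("b", ref_frames, ref_tac$values))
  cf2 <- fit_coupled(two, ref_input)
  fu <- fit_region("2tcm", ref_tac, ref_input)
  expect_lt(rel_err(cf2$shared_VND, fu$VND), 0.01)
  expect_lt(rel_err(cf2$per_region$a$VT, fu$VT), 0.01)
})

test_that("forcing one V_ND on regions with different truths costs residual", {
  pA <- compartment_params(0.37, 0.37 / 6, 0.03, 0.028)
  pB <- compartment_params(0.37, 0.37 / 10, 0.03, 0.028)
  tacs <- list(a = simulate_tissue(pA, ref_input, ref_frames, region = "a"),
               b = simulate_tissue(pB, ref_input, ref_frames, region = "b"))
  cf <- fit_coupled(tacs, ref_input)
  rss_unc <- sum(vapply(tacs, function(tc)
    fit_region("2tcm", tc, ref_input)$rss, numeric(1)))
  expect_gt(cf$rss, rss_unc)
})

test_that("coupling does not worsen V_T accuracy when the constraint is true", {
  cfgn <- study_config()
  err_c <- c(); err_u <- c()
  for (s in 1:2) {
    tacs <- make_tacs(cfgn, ref_input, "test", seed = 400 + s,
                      include_whole_brain = FALSE)
    truth_vt <- 7.89 * (1 + default_region_truth()$BP)
    fits <- lapply(tacs, function(tc) fit_region("2tcm", tc, ref_input))
    cf <- fit_coupled(tacs, ref_input, region_fits = fits)
    vt_u <- vapply(fits, function(f) f$VT, numeric(1))
    vt_c <- vapply(cf$per_region, function(f) f$VT, numeric(1))
    ok <- is.finite(vt_u) & is.finite(vt_c)
    err_u <- c(err_u, abs(vt_u - truth_vt)[ok] / truth_vt[ok])
    err_c <- c(err_c, abs(vt_c - truth_vt)[ok] / truth_vt[ok])
  }
  expect_lte(mean(err_c), mean(err_u))
})

test_that("tissue free fraction is f_p over V_ND", {
  expect_equal(derive_fnd(1, 1), 1)
  expect_equal(derive_fnd(0.426, 7.89), 0.054, tolerance = 1e-2)
  expect_equal(derive_fnd(0.5, 10), 0.05)
  expect_error(derive_fnd(0.4, 0), "positive")
})
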