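test_that("SUV conversion divides by dose per body weight", {
  fr <- frame_schedule(c(0, 1), c(1, 2))
  tc <- tac("wb", fr, c(50, 30))
  s <- to_suv(tc, injected_dose_MBq = 150, body_weight_kg = 5)
  expect_equal(s$values[1], 50 / (150000 / 5000))
  # C equal to dose/weight everywhere: SUV 1
  tc1 <- tac("wb", fr, rep(150 / 5, 2))
  expect_equal(to_suv(tc1, 150, 5)$values, c(1, 1))
  # doubling the dose halves SUV pointwise
  expect_equal(to_suv(tc, 300, 5)$values, s$values / 2)
  expect_error(to_suv(tc, 0, 5), "positive")
})

test_that("normalisation anchors at the last frame before the drug", {
  fr <- frame_schedule(c(0, 60, 80, 90), c(60, 80, 90, 120))
  tc <- tac("wb", fr, c(2, 4, 8, 6))
  nt <- normalize_at(tc, t_norm = 90)
  expect_equal(nt$anchor_index, 3L)            # frame ending exactly at 90
  expect_equal(nt$values, c(0.25, 0.5, 1, 0.75))
  expect_equal(normalize_at(tac("c", fr, rep(3, 4)), 90)$values, rep(1, 4))
  tc0 <- tac("z", fr, c(1, 1, 0, 1))
  expect_error(normalize_at(tc0, 90), "anchor")
})

test_that("percent displacement is (baseline - displaced)/baseline", {
  fr <- frame_schedule(seq(0, 110, 10), seq(10, 120, 10))
  b1 <- normalize_at(tac("wb", fr, rep(0.8, 12) * 10), 90)
  d <- normalize_at(tac("wb", fr, rep(0.8, 12) * 10), 90)
  pd <- percent_displacement(b1, d, eval_time = 20)
  expect_equal(pd$series$percent, rep(0, 12))  # identical curves
  # forced arithmetic at the evaluation frame
  bv <- c(rep(1, 9), 0.9, 0.85, 0.8)
  dv <- c(rep(1, 9), 0.6, 0.5, 0.4)
  b2 <- structure(list(times = fr$mid, values = bv, frames = fr), class = "normalized_tac")
  d2 <- structure(list(times = fr$mid, values = dv, frames = fr), class = "normalized_tac")
  pd2 <- percent_displacement(b2, d2, eval_time = 25, drug_time = 90)
  expect_equal(pd2$percent, 100 * (0.8 - 0.4) / 0.8)
})

test_that("full blockade displaces about the displaceable fraction", {
  cfg <- study_config(protocol = "4h", noise_scale = 0)
  inp <- make_input_function(cfg, 1, seed = 5)$truth_input
  base <- make_tacs(cfg, inp, "test", seed = 5)
  disp <- make_displacement_arm(cfg, inp, occupancy_profile(1, 90, "step"),
                                seed = 5)
  md <- list(injected_dose_MBq = 150, body_weight_kg = 5.2,
             drug_time_min = 90)
  r <- run_displacement(base$whole_brain, disp$whole_brain, md,
                        eval_after = 90)
  expect_gt(r$percent, 45)
  expect_lt(r$percent, 55)
  # occupancy 0 arm reproduces the baseline under the same seed
  null <- make_displacement_arm(cfg, inp, occupancy_profile(0, 90, "step"),
                                seed = 5)
  r0 <- run_displacement(base$whole_brain, null$whole_brain, md,
                         eval_after = 90)
  expect_lt(abs(r0$percent), 0.5)
})

test_that("displacement grows with competitor occupancy at every post-drug time", {
  cfg <- study_config(protocol = "4h", noise_scale = 0)
  inp <- make_input_function(cfg, 1, seed = 5)$truth_input
  base <- make_tacs(cfg, inp, "test", seed = 5)
  md <- list(injected_dose_MBq = 150, body_weight_kg = 5.2,
             drug_time_min = 90)
  prev <- NULL
  for (occ in c(0.3, 0.6, 1)) {
    arm <- make_displacement_arm(cfg, inp, occupancy_profile(occ, 90, "step"),
                                 seed = 5)
    r <- run_displacement(base$whole_brain, arm$whole_brain, md,
                          eval_after = 90)
    post <- r$series$percent[r$series$time > 95]
    if (!is.null(prev)) expect_true(all(post >= prev - 1e-6))
    prev <- post
  }
})

test_that("occupancy arithmetic follows the single-site isotherm", {
  expect_equal(occupancy_isotherm(30e-9, 30e-9), 0.5)
  expect_equal(occupancy_isotherm(0, 30e-9), 0)
  expect_gt(occupancy_isotherm(2.5e-3, 30e-9), 0.98)
  # strictly increasing in C, decreasing in KD
  cs <- seq(1e-9, 1e-6, length.out = 20)
  expect_true(all(diff(occupancy_isotherm(cs, 30e-9)) > 0))
  expect_true(all(diff(occupancy_isotherm(1e-7, cs)) < 0))
  expect_error(occupancy_isotherm(1, 0), "positive")
})

test_that("implied BP_ND inverts the displaceable fraction", {
  expect_equal(implied_bpnd(0.5), 1)
  expect_equal(implied_bpnd(0), 0)
  expect_equal(implied_bpnd(0.517), 0.517 / 0.483, tolerance = 1e-12)
  bp <- seq(0, 10, length.out = 50)
  expect_equal(implied_bpnd(bp / (1 + bp)), bp, tolerance = 1e-12)
  expect_error(implied_bpnd(1), "1")
})

test_that("occupancy from displacement scales by the maximal displacement", {
  expect_equal(occupancy_from_displacement(50, 50), 100)
  expect_equal(occupancy_from_displacement(40, 50), 80)
  expect_equal(occupancy_from_displacement(20, 50), 40)
  expect_error(occupancy_from_displacement(60, 50), "exceeds")
})
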