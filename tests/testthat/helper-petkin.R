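# Shared fixtures: one noiseless study configuration, its input function,
# and a reference two-tissue TAC used across test files. Built once per run.

rel_err <- function(x, truth) abs(x - truth) / abs(truth)

noiseless_cfg <- study_config(noise_scale = 0)
ref_input <- make_input_function(noiseless_cfg, 1, seed = 1)$truth_input
ref_frames <- study_frames("2h")
ref_params <- compartment_params(K1 = 0.37, k2 = 0.047, k3 = 0.03, k4 = 0.028)
ref_vt <- (0.37 / 0.047) * (1 + 0.03 / 0.028)
ref_tac <- simulate_tissue(ref_params, ref_input, ref_frames,
                           region = "striatum")

# Independent numerical oracle: stiff ODE integration of the two-compartment
# mass balance, frame-averaged by trapezoid on a fine grid.
ode_oracle_frames <- function(params, input, frames, dt = 0.005) {
  tg <- seq(0, max(frames$end), by = dt)
  cp <- stats::approxfun(c(0, input$times), c(0, input$values), rule = 2)
  deriv <- function(t, y, p) {
    list(c(params$K1 * cp(t) - (params$k2 + params$k3) * y[1] +
             params$k4 * y[2],
           params$k3 * y[1] - params$k4 * y[2]))
  }
  sol <- deSolve::ode(c(0, 0), tg, deriv, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  ct <- sol[, 2] + sol[, 3]
  cum <- c(0, cumsum(diff(tg) * (ct[-1] + ct[-length(ct)]) / 2))
  (stats::approx(tg, cum, frames$end)$y -
     stats::approx(tg, cum, frames$start)$y) / frames$dur
}
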