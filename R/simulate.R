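#' Acquisition frame schedule
#'
#' @param start Frame start times, minutes.
#' @param end Frame end times, minutes; `end > start`, frames non-overlapping
#'   and increasing.
#' @return A `frame_schedule`: data frame with `start`, `end`, `mid`, `dur`.
#' @export
frame_schedule <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (any(end <= start)) stop("every frame must have end > start")
  if (any(diff(start) <= 0) || any(start[-1] < end[-length(end)] - 1e-9))
    stop("frames must be increasing and non-overlapping")
  structure(data.frame(start = start, end = end,
                       mid = (start + end) / 2, dur = end - start),
            class = c("frame_schedule", "data.frame"))
}

#' Regional time-activity curve
#'
#' @param region Region label.
#' @param frames A [frame_schedule()].
#' @param values Frame-mean activity, kBq/cc (or SUV); one per frame, finite.
#' @return A `tac` object.
#' @export
tac <- function(region, frames, values) {
  stopifnot(inherits(frames, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != nrow(frames)) stop("one value per frame required")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(region = as.character(region), frames = frames,
                 values = values), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames, %.1f-%.1f min, peak %.2f\n", x$region,
              nrow(x$frames), x$frames$start[1], max(x$frames$end),
              max(x$values)))
  invisible(x)
}

#' Compartment-model rate constants
#'
#' Micro-parameters of the one- or two-tissue compartment model. `k3 = k4 = 0`
#' reduces to the one-tissue model.
#'
#' @param K1 Plasma-to-tissue influx, mL/cm^3/min; > 0.
#' @param k2 Tissue-to-plasma efflux, 1/min; > 0.
#' @param k3,k4 Exchange with the specifically bound compartment, 1/min; >= 0.
#' @param vB Fractional blood volume in the signal, `[0, 1)`; default 0.
#' @return A `compartment_params` list.
#' @export
compartment_params <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  if (K1 < 0 || k2 <= 0 || k3 < 0 || k4 < 0 || vB < 0 || vB >= 1)
    stop("invalid rate constants: need K1 >= 0, k2 > 0, k3,k4 >= 0, 0 <= vB < 1")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "compartment_params")
}

# Macroparameters. V_T is undefined (infinite) when k3 > 0 but k4 = 0.
macro_params <- function(p) {
  vnd <- p$K1 / p$k2
  bp <- if (p$k3 == 0) 0 else if (p$k4 > 0) p$k3 / p$k4 else NA_real_
  list(VND = vnd, BPND = bp, VT = vnd * (1 + bp))
}

# Convolution of a piecewise-linear input with exp(-theta t) on a uniform
# grid, exact for linear segments: y[i+1] = E y[i] + a (1-E)/theta + b (dt -
# (1-E)/theta)/theta with a = cp[i], b = slope. stats::filter does the
# recursion in C.
exp_conv <- function(theta, dt, cp) {
  n <- length(cp)
  if (n < 2) return(numeric(n))
  a <- cp[-n]
  b <- (cp[-1] - a) / dt
  if (theta > 0) {
    E <- exp(-theta * dt)
    g <- a * (1 - E) / theta + b * (dt - (1 - E) / theta) / theta
  } else {
    E <- 1
    g <- a * dt + b * dt^2 / 2
  }
  y <- stats::filter(g, E, method = "recursive")
  c(0, as.numeric(y))
}

# Impulse-response constants of the 2TCM: theta (eigen-rates) and phi
# (amplitudes). Handles the 1TCM special case k3 = k4 = 0.
tcm_impulse <- function(p) {
  s <- p$k2 + p$k3 + p$k4
  disc <- s^2 - 4 * p$k2 * p$k4
  stopifnot(disc >= -1e-12)          # impossible for non-negative rates
  root <- sqrt(max(disc, 0))
  th1 <- (s + root) / 2
  th2 <- (s - root) / 2
  if (th1 - th2 < 1e-10) {           # repeated root; perturb negligibly
    th1 <- th1 + 1e-8
  }
  ph1 <- p$K1 * (th1 - p$k3 - p$k4) / (th1 - th2)
  ph2 <- p$K1 * (p$k3 + p$k4 - th2) / (th1 - th2)
  list(theta = c(th1, th2), phi = c(ph1, ph2))
}

#' Simulate a tissue time-activity curve
#'
#' Analytic forward model of the one- or two-tissue compartment system:
#' `C_T(t) = [phi1 exp(-theta1 t) + phi2 exp(-theta2 t)] (x) Cp(t)`, where the
#' eigen-rates are `theta_{1,2} = ((k2+k3+k4) +/- sqrt((k2+k3+k4)^2 - 4 k2
#' k4))/2`. The convolution is evaluated on a fine uniform grid (exact for a
#' piecewise-linear input) and averaged over each frame; with `vB > 0` a
#' whole-blood contribution `vB * C_wb` is added and the tissue term scaled by
#' `1 - vB`.
#'
#' @param params A [compartment_params()].
#' @param input An `input_function` covering the frame range.
#' @param frames A [frame_schedule()].
#' @param dt Convolution grid step, minutes (default 0.05).
#' @param region Label for the returned TAC.
#' @return A [tac()] of frame-mean activities.
#' @export
simulate_tissue <- function(params, input, frames, dt = 0.05,
                            region = "simulated") {
  stopifnot(inherits(params, "compartment_params"),
            inherits(input, "input_function"),
            inherits(frames, "frame_schedule"))
  t_end <- max(frames$end)
  check_input_coverage(input, t_end)
  fine <- fine_tissue_curve(params, input, t_end, dt)
  vals <- frame_average(fine$t, fine$ct, frames)
  if (params$vB > 0) {
    wb <- wb_values(input, fine$t)
    vals <- (1 - params$vB) * vals + params$vB * frame_average(fine$t, wb, frames)
  }
  tac(region, frames, vals)
}

# Arterial sampling routinely stops slightly before the scan does; the input
# is then held at its last value. More than 15 min of extrapolation is an
# error.
check_input_coverage <- function(input, t_end, tol = 15) {
  if (max(input$times) < t_end - tol)
    stop("input function does not cover the frame range")
  invisible(TRUE)
}

# Fine-grid C_T(t) (tissue only, no blood volume).
fine_tissue_curve <- function(params, input, t_end, dt = 0.05) {
  tg <- seq(0, t_end, by = dt)
  if (tg[length(tg)] < t_end) tg <- c(tg, t_end)
  cp <- input_values(input, tg)
  im <- tcm_impulse(params)
  ct <- im$phi[1] * exp_conv(im$theta[1], dt, cp) +
        im$phi[2] * exp_conv(im$theta[2], dt, cp)
  list(t = tg, ct = ct, cp = cp)
}

# Whole-blood curve for the vB term; falls back to plasma/0.9 when the input
# has no source blood series.
wb_values <- function(input, t) {
  if (!is.null(input$source_blood)) {
    b <- input$source_blood
    stats::approx(c(0, b$times), c(0, b$whole_blood), xout = t, rule = 2)$y
  } else {
    input_values(input, t) / 0.9
  }
}

# Mean of a fine-grid curve over each frame (trapezoid / frame duration).
frame_average <- function(tg, y, frames) {
  cum <- c(0, cumsum(diff(tg) * (y[-1] + y[-length(y)]) / 2))
  cum_at <- function(x) stats::approx(tg, cum, xout = x, rule = 2)$y
  (cum_at(frames$end) - cum_at(frames$start)) / frames$dur
}
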