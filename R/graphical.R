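#' Logan graphical analysis
#'
#' Estimates the total distribution volume V_T as the asymptotic slope of the
#' Logan plot: ordinary least squares of `int_0^t C_T / C_T(t)` against
#' `int_0^t C_p / C_T(t)` over frames whose mid-time is at or beyond `tstar`.
#' Tissue integrals use trapezoids on the frame mid-time nodes with a `(0,0)`
#' anchor; the plasma integral is the exact integral of the piecewise-linear
#' input function up to each mid-time.
#'
#' @param tc A [tac()].
#' @param input An `input_function`.
#' @param tstar Linearity start time, minutes (default 60).
#' @return A `graphical_fit`: `VT` (slope, mL/cm^3), `intercept` (min),
#'   `tstar`, `r_squared`, `n_points`, `method`.
#' @examples
#' # On one-tissue kinetics the Logan slope equals K1/k2 exactly.
#' @export
logan_fit <- function(tc, input, tstar = 60) {
  d <- graphical_data(tc, input, tstar)
  x <- d$int_cp / d$ct
  y <- d$int_ct / d$ct
  fit <- stats::lm(y ~ x)
  structure(list(VT = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 tstar = tstar, r_squared = summary(fit)$r.squared,
                 n_points = length(x), method = "logan",
                 region = tc$region),
            class = "graphical_fit")
}

#' Multilinear analysis MA1
#'
#' Ichise's first multilinear rearrangement of the Logan relation: for
#' `t >= tstar`, regress `C_T(t)` on the running plasma and tissue integrals,
#' `C_T(t) = b1 * int C_p + b2 * int C_T`, and report `V_T = -b1 / b2`. MA1
#' avoids the noise-dependent negative bias of the Logan slope by keeping the
#' noisy `C_T` out of the denominator.
#'
#' @inheritParams logan_fit
#' @return A `graphical_fit` with `method = "ma1"`.
#' @export
ma1_fit <- function(tc, input, tstar = 60) {
  d <- graphical_data(tc, input, tstar)
  fit <- stats::lm(d$ct ~ 0 + d$int_cp + d$int_ct)
  b <- stats::coef(fit)
  structure(list(VT = unname(-b[1] / b[2]), intercept = unname(1 / b[2]),
                 tstar = tstar, r_squared = summary(fit)$r.squared,
                 n_points = length(d$ct), method = "ma1",
                 region = tc$region),
            class = "graphical_fit")
}

#' @export
print.graphical_fit <- function(x, ...) {
  cat(sprintf("%s fit, region '%s': VT = %.3f mL/cm^3 (t* = %g min, %d points, r^2 = %.4f)\n",
              toupper(x$method), x$region, x$VT, x$tstar, x$n_points,
              x$r_squared))
  invisible(x)
}

# Shared plumbing: running integrals at frame mid-times and the post-t* window.
graphical_data <- function(tc, input, tstar) {
  stopifnot(inherits(tc, "tac"))
  mids <- tc$frames$mid
  ct <- tc$values
  # tissue integral: trapezoid on mid-time nodes anchored at (0, 0)
  tt <- c(0, mids); vv <- c(0, ct)
  int_ct <- cumsum(c(0, diff(tt) * (vv[-1] + vv[-length(vv)]) / 2))[-1]
  int_cp <- input_integral(input, mids)
  sel <- mids >= tstar
  if (any(sel & ct <= 0)) {
    warning("excluding frames with non-positive activity from the graphical window")
    sel <- sel & ct > 0
  }
  if (sum(sel) < 3)
    stop("fewer than 3 usable frames beyond tstar")
  list(t = mids[sel], ct = ct[sel], int_ct = int_ct[sel],
       int_cp = int_cp[sel])
}

# Exact running integral of the piecewise-linear input (with its (0,0)
# pre-sample rise) evaluated at arbitrary times.
input_integral <- function(input, t) {
  tt <- input$times; vv <- input$values
  if (tt[1] > 0) { tt <- c(0, tt); vv <- c(0, vv) }
  grid <- sort(unique(c(tt, t)))
  vg <- stats::approx(tt, vv, xout = grid, rule = 2)$y
  cum <- cumsum(c(0, diff(grid) * (vg[-1] + vg[-length(vg)]) / 2))
  cum[match(t, grid)]
}
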