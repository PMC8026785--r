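#' Akaike information criterion from a weighted residual sum of squares
#'
#' `AIC = n ln(rss/n) + 2k`, the least-squares form used for compartment
#' model selection. Only differences between models fitted to the same data
#' with the same weights are meaningful.
#'
#' @param rss Weighted residual sum of squares; > 0.
#' @param n_frames Number of fitted frames; must exceed `n_params`.
#' @param n_params Number of fitted parameters.
#' @return The AIC value.
#' @export
compute_aic <- function(rss, n_frames, n_params) {
  if (!is.finite(rss) || rss <= 0) stop("rss must be positive and finite")
  if (n_frames <= n_params) stop("need more frames than parameters")
  n_frames * log(rss / n_frames) + 2 * n_params
}

#' Free fraction in tissue
#'
#' `f_ND = f_p / V_ND`: the tissue free fraction implied by the plasma free
#' fraction and the non-displaceable distribution volume.
#'
#' @param fp Plasma free fraction, in `(0, 1]`.
#' @param vnd Non-displaceable distribution volume, mL/cm^3; > 0.
#' @return `fp / vnd`.
#' @export
derive_fnd <- function(fp, vnd) {
  if (vnd <= 0) stop("vnd must be positive")
  if (fp <= 0 || fp > 1) stop("fp must lie in (0, 1]")
  fp / vnd
}

# Frame weights ~ duration / activity (approximate count statistics); a floor
# of 1% of the curve maximum guards near-zero frames. Normalised to mean 1 so
# the weighted RSS stays on the data scale.
tac_weights <- function(tc) {
  eps <- 0.01 * max(tc$values)
  w <- tc$frames$dur / pmax(tc$values, eps)
  w / mean(w)
}

# Parameter vector layout per model.
par_names <- function(model, fit_vB) {
  nm <- if (model == "1tcm") c("K1", "k2") else c("K1", "k2", "k3", "k4")
  if (fit_vB) c(nm, "vB") else nm
}

par_bounds <- function(model, fit_vB) {
  nm <- par_names(model, fit_vB)
  lower <- c(K1 = 1e-6, k2 = 1e-6, k3 = 0, k4 = 0, vB = 0)[nm]
  upper <- c(K1 = 2, k2 = 1, k3 = 1, k4 = 1, vB = 0.1)[nm]
  list(lower = lower, upper = upper)
}

pars_to_cp <- function(par, model, fit_vB) {
  vB <- if (fit_vB) par[["vB"]] else 0
  if (model == "1tcm")
    compartment_params(par[["K1"]], par[["k2"]], 0, 0, vB)
  else
    compartment_params(par[["K1"]], par[["k2"]], par[["k3"]], par[["k4"]], vB)
}

# Fast frame-value evaluator closing over the precomputed input grid.
make_model_fun <- function(tc, input, model, fit_vB, dt = 0.05) {
  t_end <- max(tc$frames$end)
  check_input_coverage(input, t_end)
  tg <- seq(0, t_end, by = dt)
  if (tg[length(tg)] < t_end) tg <- c(tg, t_end)
  cp <- input_values(input, tg)
  wb <- if (fit_vB) wb_values(input, tg) else NULL
  frames <- tc$frames
  function(par) {
    p <- pars_to_cp(par, model, fit_vB)
    im <- tcm_impulse(p)
    ct <- im$phi[1] * exp_conv(im$theta[1], dt, cp) +
          im$phi[2] * exp_conv(im$theta[2], dt, cp)
    v <- frame_average(tg, ct, frames)
    if (fit_vB && p$vB > 0)
      v <- (1 - p$vB) * v + p$vB * frame_average(tg, wb, frames)
    v
  }
}

# Fixed 10 x 4 Latin hypercube (stratified levels, fixed permutations) used
# for deterministic multi-start; columns map to K1, k2, k3, k4 on log scales.
lhs_starts <- function(model, fit_vB) {
  u <- (cbind(c(1, 4, 7, 10, 2, 5, 8, 3, 6, 9),
              c(6, 1, 9, 3, 10, 4, 7, 2, 8, 5),
              c(9, 5, 2, 7, 4, 10, 1, 8, 3, 6),
              c(3, 8, 5, 1, 7, 2, 10, 6, 9, 4)) - 0.5) / 10
  K1 <- exp(log(0.02) + u[, 1] * (log(1.5) - log(0.02)))
  k2 <- exp(log(0.005) + u[, 2] * (log(0.5) - log(0.005)))
  k3 <- exp(log(0.002) + u[, 3] * (log(0.3) - log(0.002)))
  k4 <- exp(log(0.002) + u[, 4] * (log(0.3) - log(0.002)))
  s <- cbind(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (model == "1tcm") s <- s[, c("K1", "k2")]
  if (fit_vB) s <- cbind(s, vB = 0.03)
  s
}

# Central-difference jacobian respecting box bounds.
num_jacobian <- function(f, par, lower, upper) {
  f0 <- f(par)
  J <- matrix(0, length(f0), length(par))
  for (i in seq_along(par)) {
    h <- max(1e-7, 1e-5 * abs(par[i]))
    up <- pmin(par[i] + h, upper[i]); lo <- pmax(par[i] - h, lower[i])
    p1 <- par; p1[i] <- up
    p2 <- par; p2[i] <- lo
    J[, i] <- (f(p1) - f(p2)) / (up - lo)
  }
  colnames(J) <- names(par)
  J
}

delta_se <- function(grad, cov) {
  v <- drop(t(grad) %*% cov %*% grad)
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

#' Fit a compartment model to one regional TAC
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt, box-bounded, 10
#' deterministic Latin-hypercube starts) of the one- or two-tissue
#' compartment model. Weights are proportional to frame duration over frame
#' activity. Standard errors come from the Gauss-Newton covariance (inverse
#' weighted normal matrix scaled by the reduced chi-square); SEs of the
#' macroparameters `V_T = (K1/k2)(1 + k3/k4)`, `V_ND = K1/k2` and
#' `BP_ND = k3/k4` follow by the delta method. An estimate is flagged
#' `reliable` when the fit converged and the %SE of `V_T` is below 25%.
#'
#' A 2TCM fit in which `k4` collapses to its lower bound of 0 is reported
#' with the `irreversible_limit` flag set and `BP_ND`/`V_T` missing rather
#' than infinite.
#'
#' @param model `"1tcm"` or `"2tcm"`.
#' @param tc A [tac()].
#' @param input An `input_function` covering the frames.
#' @param fit_vB Also fit a fractional blood volume in `[0, 0.1]`? Default
#'   `FALSE` (vB fixed at 0).
#' @param dt Convolution grid step, minutes.
#' @param starts Optional matrix of start values overriding the built-in
#'   multi-start set (columns named as the parameters).
#' @return A `fit_result`.
#' @export
fit_region <- function(model = c("2tcm", "1tcm"), tc, input, fit_vB = FALSE,
                       dt = 0.05, starts = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(tc, "tac"))
  w <- tac_weights(tc)
  sw <- sqrt(w)
  obs <- tc$values
  fun <- make_model_fun(tc, input, model, fit_vB, dt)
  b <- par_bounds(model, fit_vB)
  resid_fun <- function(par) sw * (fun(par) - obs)
  if (is.null(starts)) starts <- lhs_starts(model, fit_vB)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[i, names(b$lower)], b$lower), b$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun, lower = b$lower,
                         upper = b$upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, ok = fit$info %in% 1:4)
  }
  if (is.null(best))
    return(empty_fit_result(model, tc$region, length(obs)))

  finalize_fit(best, model, fit_vB, tc, resid_fun, b)
}

empty_fit_result <- function(model, region, n) {
  structure(list(model = model, region = region, params = NULL, se = NULL,
                 percent_se = NULL, covariance = NULL, rss = NA_real_,
                 aic = NA_real_, VT = NA_real_, VND = NA_real_,
                 BPND = NA_real_, macro_se = NULL, converged = FALSE,
                 reliable = FALSE, irreversible_limit = FALSE, n = n),
            class = "fit_result")
}

finalize_fit <- function(best, model, fit_vB, tc, resid_fun, b) {
  par <- best$par
  n <- length(tc$values)
  k <- length(par)
  rss <- best$rss
  J <- num_jacobian(resid_fun, par, b$lower, b$upper)
  s2 <- rss / (n - k)
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e) {
    matrix(NA_real_, k, k, dimnames = list(names(par), names(par)))
  })
  se <- sqrt(pmax(diag(cov), 0))
  pct <- 100 * se / abs(unlist(par))

  p <- pars_to_cp(par, model, fit_vB)
  irrev <- model == "2tcm" && p$k3 > 0 && p$k4 < 1e-6
  vnd <- p$K1 / p$k2
  if (model == "1tcm") {
    bp <- 0; vt <- vnd
    g_vt <- c(K1 = 1 / p$k2, k2 = -p$K1 / p$k2^2)
  } else if (irrev) {
    bp <- NA_real_; vt <- NA_real_; g_vt <- NULL
  } else {
    bp <- p$k3 / p$k4
    vt <- vnd * (1 + bp)
    g_vt <- c(K1 = (1 + bp) / p$k2, k2 = -vnd * (1 + bp) / p$k2,
              k3 = vnd / p$k4, k4 = -vnd * bp / p$k4)
  }
  idx <- function(g) { v <- rep(0, k); names(v) <- names(par)
                       v[names(g)] <- g; v }
  ok_cov <- all(is.finite(cov))
  macro_se <- list(
    VT = if (!is.null(g_vt) && ok_cov) delta_se(idx(g_vt), cov) else NA_real_,
    VND = if (ok_cov) delta_se(idx(c(K1 = 1 / p$k2, k2 = -vnd / p$k2)), cov)
          else NA_real_,
    BPND = if (model == "2tcm" && !irrev && ok_cov)
             delta_se(idx(c(k3 = 1 / p$k4, k4 = -bp / p$k4)), cov)
           else NA_real_)
  vt_pct <- if (is.finite(vt) && is.finite(macro_se$VT)) 100 * macro_se$VT / vt
            else NA_real_
  structure(list(model = model, region = tc$region, params = p,
                 se = se, percent_se = pct, covariance = cov, rss = rss,
                 aic = compute_aic(rss, n, k), VT = vt, VND = vnd, BPND = bp,
                 macro_se = macro_se, vt_percent_se = vt_pct,
                 converged = isTRUE(best$ok),
                 reliable = isTRUE(best$ok) && !irrev &&
                   is.finite(vt_pct) && vt_pct < 25,
                 irreversible_limit = irrev, n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit, region '%s'%s\n", toupper(x$model), x$region,
              if (x$irreversible_limit) " [k4 at lower bound]" else ""))
  if (!is.null(x$params))
    cat(sprintf("  K1=%.4f k2=%.4f k3=%.4f k4=%.4f | VT=%.2f VND=%.2f BPND=%s\n",
                x$params$K1, x$params$k2, x$params$k3, x$params$k4,
                x$VT, x$VND, format(round(x$BPND, 3))))
  cat(sprintf("  AIC=%.2f, converged=%s, reliable=%s\n", x$aic, x$converged,
              x$reliable))
  invisible(x)
}

#' Coupled two-tissue fit with a shared V_ND across regions
#'
#' Simultaneous weighted nonlinear least squares over all regional TACs with
#' one global non-displaceable distribution volume: the parameter vector is
#' `{V_ND} + {K1, k3, k4 per region}` and each region's efflux is tied as
#' `k2 = K1 / V_ND`. Starting values come from unconstrained per-region 2TCM
#' fits (shared V_ND initialised at their median K1/k2, with scaled
#' alternates). Per-region standard errors are read off the joint covariance.
#'
#' @param tacs List of [tac()] objects (>= 2) sharing the input function.
#' @param input An `input_function`.
#' @param dt Convolution grid step, minutes.
#' @param region_fits Optional list of unconstrained 2TCM `fit_result`s to
#'   initialise from (skips refitting them).
#' @return A `coupled_fit_result`: `shared_VND`, `shared_VND_se`,
#'   `per_region` (named list of `fit_result`s), `rss`, `aic`, `converged`.
#' @export
fit_coupled <- function(tacs, input, dt = 0.05, region_fits = NULL) {
  if (length(tacs) < 2) stop("coupled fit needs at least 2 regions")
  regions <- vapply(tacs, function(x) x$region, character(1))
  names(tacs) <- regions
  if (is.null(region_fits))
    region_fits <- lapply(tacs, function(tc) fit_region("2tcm", tc, input,
                                                        dt = dt))
  nr <- length(tacs)
  funs <- lapply(tacs, function(tc) make_model_fun(tc, input, "2tcm", FALSE, dt))
  sws <- lapply(tacs, function(tc) sqrt(tac_weights(tc)))
  obs <- lapply(tacs, function(tc) tc$values)

  # par = c(VND, K1_1, k3_1, k4_1, ..., K1_R, k3_R, k4_R)
  unpack <- function(par, r) {
    o <- 1 + 3 * (r - 1)
    c(K1 = par[[o + 1]], k2 = par[[o + 1]] / par[[1]],
      k3 = par[[o + 2]], k4 = par[[o + 3]])
  }
  resid_fun <- function(par) {
    unlist(lapply(seq_len(nr), function(r) {
      sws[[r]] * (funs[[r]](unpack(par, r)) - obs[[r]])
    }), use.names = FALSE)
  }
  lower <- c(0.2, rep(c(1e-6, 0, 0), nr))
  upper <- c(60, rep(c(2, 1, 1), nr))

  vnd0 <- stats::median(vapply(region_fits, function(f)
    if (is.null(f$params)) NA_real_ else f$VND, numeric(1)), na.rm = TRUE)
  if (!is.finite(vnd0)) vnd0 <- 5
  reg0 <- unlist(lapply(region_fits, function(f) {
    if (is.null(f$params)) c(0.3, 0.02, 0.02)
    else c(f$params$K1, max(f$params$k3, 1e-3), max(f$params$k4, 1e-3))
  }), use.names = FALSE)

  best <- NULL
  for (sc in c(1, 0.7, 1.4)) {
    p0 <- pmin(pmax(c(vnd0 * sc, reg0), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, ok = fit$info %in% 1:4)
  }
  if (is.null(best)) stop("coupled fit failed from all starts")

  par <- unlist(best$par)
  ntot <- sum(lengths(obs))
  k <- length(par)
  J <- num_jacobian(resid_fun, par, lower, upper)
  s2 <- best$rss / (ntot - k)
  cov <- tryCatch(solve(crossprod(J)) * s2,
                  error = function(e) matrix(NA_real_, k, k))
  vnd <- par[1]
  vnd_se <- sqrt(max(cov[1, 1], 0))

  per_region <- lapply(seq_len(nr), function(r) {
    o <- 1 + 3 * (r - 1)
    pr <- unpack(par, r)
    p <- compartment_params(pr[["K1"]], pr[["k2"]], pr[["k3"]], pr[["k4"]])
    irrev <- p$k3 > 0 && p$k4 < 1e-6
    bp <- if (irrev) NA_real_ else p$k3 / p$k4
    vt <- if (irrev) NA_real_ else vnd * (1 + bp)
    sub <- c(1, o + 1, o + 2, o + 3)      # VND, K1, k3, k4 rows of cov
    covr <- cov[sub, sub]
    ok_cov <- all(is.finite(covr))
    g_vt <- c(1 + ifelse(irrev, 0, bp), 0,
              if (irrev) 0 else vnd / p$k4,
              if (irrev) 0 else -vnd * bp / p$k4)
    macro_se <- list(
      VT = if (!irrev && ok_cov) delta_se(g_vt, covr) else NA_real_,
      VND = vnd_se,
      BPND = if (!irrev && ok_cov)
               delta_se(c(0, 0, 1 / p$k4, -bp / p$k4), covr) else NA_real_)
    se <- sqrt(pmax(diag(covr), 0))
    names(se) <- c("VND", "K1", "k3", "k4")
    vt_pct <- if (is.finite(vt) && is.finite(macro_se$VT))
                100 * macro_se$VT / vt else NA_real_
    structure(list(model = "2tcmc", region = regions[r], params = p, se = se,
                   percent_se = 100 * se / abs(c(vnd, p$K1, p$k3, p$k4)),
                   covariance = covr, rss = NA_real_, aic = NA_real_,
                   VT = vt, VND = vnd, BPND = bp, macro_se = macro_se,
                   vt_percent_se = vt_pct, converged = isTRUE(best$ok),
                   reliable = isTRUE(best$ok) && !irrev &&
                     is.finite(vt_pct) && vt_pct < 25,
                   irreversible_limit = irrev, n = length(obs[[r]])),
              class = "fit_result")
  })
  names(per_region) <- regions
  structure(list(shared_VND = vnd, shared_VND_se = vnd_se,
                 per_region = per_region, joint_covariance = cov,
                 rss = best$rss,
                 aic = compute_aic(best$rss, ntot, k),
                 converged = isTRUE(best$ok)),
            class = "coupled_fit_result")
}

#' @export
print.coupled_fit_result <- function(x, ...) {
  cat(sprintf("Coupled 2TCM fit: %d regions, shared VND = %.3f (SE %.3f)\n",
              length(x$per_region), x$shared_VND, x$shared_VND_se))
  for (f in x$per_region)
    cat(sprintf("  %-16s K1=%.3f k3/k4=%s VT=%.2f\n", f$region, f$params$K1,
                format(round(f$BPND, 3)), f$VT))
  invisible(x)
}
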