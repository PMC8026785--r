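#' Arterial blood series
#'
#' Container for serial arterial samples: whole-blood and plasma activity,
#' decay-corrected to injection time, as a function of minutes post-injection.
#'
#' @param times Sample times in minutes post-injection; strictly increasing,
#'   first time >= 0.
#' @param whole_blood Whole-blood activity in kBq/cc, same length as `times`.
#' @param plasma Plasma activity in kBq/cc, same length as `times`.
#'
#' @return An object of class `blood_series` (a list with fields `times`,
#'   `whole_blood`, `plasma`).
#' @export
blood_series <- function(times, whole_blood, plasma) {
  times <- as.numeric(times)
  whole_blood <- as.numeric(whole_blood)
  plasma <- as.numeric(plasma)
  if (length(times) != length(whole_blood) || length(times) != length(plasma))
    stop("times, whole_blood and plasma must have equal length")
  if (any(!is.finite(times)) || times[1] < 0 || any(diff(times) <= 0))
    stop("times must be finite, strictly increasing and start at >= 0")
  if (any(whole_blood < 0) || any(plasma < 0))
    stop("activities must be non-negative")
  structure(list(times = times, whole_blood = whole_blood, plasma = plasma),
            class = "blood_series")
}

#' @export
print.blood_series <- function(x, ...) {
  cat(sprintf("Arterial blood series: %d samples, %.2f-%.1f min\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Evaluate a parent-fraction model
#'
#' @param object A `pf_model`.
#' @param times Times in minutes.
#' @param ... Unused.
#' @return Predicted intact parent fraction, in `[0, 1]`.
#' @export
predict.pf_model <- function(object, times, ...) {
  object$A1 * exp(-object$lambda1 * times) +
    (1 - object$A1) * exp(-object$lambda2 * times)
}

#' @export
print.pf_model <- function(x, ...) {
  cat(sprintf(
    "Biexponential parent-fraction model: pf(t) = %.3f exp(-%.4f t) + %.3f exp(-%.4f t)\n",
    x$A1, x$lambda1, 1 - x$A1, x$lambda2))
  cat(sprintf("  RSS = %.3g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}

# Sum of squares of the constrained biexponential on the fraction scale.
pf_rss <- function(par, times, fractions) {
  p <- predict.pf_model(list(A1 = par[1], lambda1 = par[2], lambda2 = par[3]),
                        times)
  sum((p - fractions)^2)
}

#' Fit a biexponential parent-fraction decay model
#'
#' Fits `pf(t) = A1 exp(-lambda1 t) + (1 - A1) exp(-lambda2 t)` to measured
#' intact-parent fractions by least squares on the fraction scale. The
#' intercept is constrained to `pf(0) = 1` (the injected tracer is 100%
#' parent) by the `A2 = 1 - A1` reparameterisation. A multi-start
#' Levenberg-Marquardt search over log-spaced rate pairs guards against
#' local minima; components are ordered so `lambda1 >= lambda2`.
#'
#' @param times Sample times in minutes; distinct, increasing, at least 4.
#' @param fractions Measured parent fractions in `[0, 1]`, same length.
#'
#' @return A `pf_model`: list with `A1`, `lambda1`, `lambda2`, `rss`,
#'   `converged`, and the data fitted.
#' @examples
#' pf <- fit_parent_fraction(c(15, 30, 60, 120, 240),
#'                           c(0.37, 0.295, 0.19, 0.146, 0.044))
#' predict(pf, 60)
#' @export
fit_parent_fraction <- function(times, fractions) {
  times <- as.numeric(times); fractions <- as.numeric(fractions)
  if (length(times) < 4)
    stop("insufficient data: at least 4 parent-fraction samples are required")
  if (length(fractions) != length(times))
    stop("times and fractions must have equal length")
  if (any(diff(times) <= 0)) stop("times must be distinct and increasing")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")

  resid_fun <- function(par) {
    predict.pf_model(list(A1 = par[1], lambda1 = par[2], lambda2 = par[3]),
                     times) - fractions
  }

  # Degenerate but legal: constant fraction 1 needs no decay at all.
  if (all(fractions == 1)) {
    out <- list(A1 = 1, lambda1 = 0, lambda2 = 0, rss = 0, converged = TRUE,
                times = times, fractions = fractions)
    class(out) <- "pf_model"
    return(out)
  }

  l_fast <- exp(seq(log(0.01), log(0.5), length.out = 4))
  l_slow <- exp(seq(log(5e-4), log(0.05), length.out = 3))
  best <- NULL
  for (lf in l_fast) for (ls in l_slow) {
    start <- c(A1 = 0.6, lambda1 = lf, lambda2 = ls)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun,
                         lower = c(0, 0, 0), upper = c(1, 10, 10),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss,
                   ok = fit$info %in% 1:4)
  }
  if (is.null(best))
    stop("fit failure: no biexponential candidate converged")

  par <- best$par
  # fast component first
  if (par[3] > par[2]) par <- c(1 - par[1], par[3], par[2])
  out <- list(A1 = unname(par[1]), lambda1 = unname(par[2]),
              lambda2 = unname(par[3]), rss = best$rss,
              converged = isTRUE(best$ok), times = times,
              fractions = fractions)
  class(out) <- "pf_model"
  if (!out$converged)
    warning("parent-fraction fit did not fully converge; returning best candidate")
  out
}

#' Build the metabolite-corrected arterial input function
#'
#' Multiplies the measured plasma activity by the modelled intact-parent
#' fraction at each blood-sampling time: `Cp(t_i) = plasma(t_i) * pf(t_i)`.
#' No resampling is done; between samples the input is interpolated linearly,
#' and before the first sample it rises linearly from `(0, 0)`.
#'
#' @param blood A [blood_series()].
#' @param pf A `pf_model` from [fit_parent_fraction()].
#'
#' @return An `input_function`: list with `times`, `values` (kBq/cc),
#'   `source_blood`, `pf_model`.
#' @export
build_mcaif <- function(blood, pf) {
  stopifnot(inherits(blood, "blood_series"), inherits(pf, "pf_model"))
  vals <- blood$plasma * predict(pf, blood$times)
  structure(list(times = blood$times, values = vals,
                 source_blood = blood, pf_model = pf),
            class = "input_function")
}

#' Construct an input function from sampled values
#'
#' Lower-level constructor used when metabolite-corrected plasma values are
#' already available (e.g. simulated truth curves).
#'
#' @param times Minutes post-injection, strictly increasing.
#' @param values Metabolite-corrected plasma activity, kBq/cc, non-negative.
#' @param source_blood Optional [blood_series()] the values derive from.
#' @param pf_model Optional `pf_model` applied.
#' @return An `input_function`.
#' @export
input_function <- function(times, values, source_blood = NULL, pf_model = NULL) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(values < 0)) stop("input-function values must be non-negative")
  structure(list(times = times, values = values, source_blood = source_blood,
                 pf_model = pf_model), class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("Input function: %d samples, peak %.1f kBq/cc at %.2f min\n",
              length(x$times), max(x$values), x$times[which.max(x$values)]))
  invisible(x)
}

#' Evaluate an input function by linear interpolation
#'
#' Before the first sample the curve rises linearly from `(0, 0)`; after the
#' last sample the last value is held.
#'
#' @param input An `input_function`.
#' @param t Times (minutes) to evaluate at.
#' @return Interpolated activity values.
#' @export
input_values <- function(input, t) {
  tt <- input$times; vv <- input$values
  if (tt[1] > 0) { tt <- c(0, tt); vv <- c(0, vv) }
  stats::approx(tt, vv, xout = t, rule = 2)$y
}

#' Plasma free fraction from ultrafiltration counts
#'
#' `f_p = CFP / CP`, the ratio of free (ultrafiltrable) to total plasma
#' counts. With replicate pairs, per-replicate ratios are averaged and the
#' SEM reported.
#'
#' @param ultrafiltrate_counts Free (ultrafiltrate) counts; scalar or vector.
#' @param plasma_counts Total plasma counts (> 0); scalar or vector matching.
#' @param replicates Optional numeric vector of pre-computed replicate
#'   ratios; overrides the counts if given.
#' @return List with `fp` (mean fraction), `sem` (NA for a single
#'   measurement), `ratios`.
#' @export
free_fraction <- function(ultrafiltrate_counts, plasma_counts,
                          replicates = NULL) {
  if (!is.null(replicates)) {
    ratios <- as.numeric(replicates)
  } else {
    if (any(plasma_counts <= 0)) stop("plasma counts must be positive")
    ratios <- ultrafiltrate_counts / plasma_counts
  }
  n <- length(ratios)
  list(fp = mean(ratios),
       sem = if (n > 1) stats::sd(ratios) / sqrt(n) else NA_real_,
       ratios = ratios)
}

#' Plasma to whole-blood activity ratio
#'
#' Pointwise `plasma / whole_blood` with its time-averaged mean and SD.
#' Samples with zero whole-blood activity are excluded with a warning.
#'
#' @param blood A [blood_series()].
#' @return List with `times`, `ratio`, `mean`, `sd`.
#' @export
plasma_wb_ratio <- function(blood) {
  stopifnot(inherits(blood, "blood_series"))
  ok <- blood$whole_blood > 0
  if (!all(ok))
    warning(sprintf("%d samples with zero whole-blood activity excluded",
                    sum(!ok)))
  r <- blood$plasma[ok] / blood$whole_blood[ok]
  list(times = blood$times[ok], ratio = r, mean = mean(r), sd = stats::sd(r))
}

#' Read / write blood and parent-fraction tables
#'
#' Delimited text (comma or tab, inferred from the header line) with columns
#' `time_min`, `whole_blood_kBq_cc`, `plasma_kBq_cc` for blood tables and
#' `time_min`, `parent_fraction` for parent-fraction tables. A header is
#' required; the decimal separator is the point.
#'
#' @param path File path.
#' @return `read_blood_table`: a [blood_series()]; `read_pf_table`: a data
#'   frame with `time_min`, `parent_fraction`.
#' @export
read_blood_table <- function(path) {
  d <- read_delim_auto(path)
  need <- c("time_min", "whole_blood_kBq_cc", "plasma_kBq_cc")
  if (!all(need %in% names(d)))
    stop("blood table must have columns: ", paste(need, collapse = ", "))
  blood_series(d$time_min, d$whole_blood_kBq_cc, d$plasma_kBq_cc)
}

#' @rdname read_blood_table
#' @param blood A [blood_series()].
#' @export
write_blood_table <- function(blood, path) {
  utils::write.csv(data.frame(time_min = blood$times,
                              whole_blood_kBq_cc = blood$whole_blood,
                              plasma_kBq_cc = blood$plasma),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_blood_table
#' @export
read_pf_table <- function(path) {
  d <- read_delim_auto(path)
  need <- c("time_min", "parent_fraction")
  if (!all(need %in% names(d)))
    stop("parent-fraction table must have columns: ",
         paste(need, collapse = ", "))
  d[need]
}

#' @rdname read_blood_table
#' @param pf_samples Data frame with `time_min`, `parent_fraction`.
#' @export
write_pf_table <- function(pf_samples, path) {
  utils::write.csv(pf_samples[c("time_min", "parent_fraction")], path,
                   row.names = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                    stringsAsFactors = FALSE)
}
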