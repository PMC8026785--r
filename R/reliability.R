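#' Absolute test-retest variability
#'
#' `aTRV = 100 * |test - retest| / mean(test, retest)`, in percent. Symmetric
#' in its arguments and invariant to common rescaling.
#'
#' @param test,retest Positive paired estimates (vectors recycle pairwise).
#' @return aTRV in percent.
#' @export
atrv <- function(test, retest) {
  if (any(test <= 0) || any(retest <= 0))
    stop("test and retest values must be positive")
  100 * abs(test - retest) / ((test + retest) / 2)
}

# Two-way ANOVA mean squares for an n x k complete matrix (subjects x
# sessions), the decomposition behind the ICC formulas.
icc_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intra-class correlation for test-retest reliability
#'
#' Two-way mixed-effects, single-measure ICC from the standard ANOVA
#' mean-squares decomposition. The default `"agreement"` variant (absolute
#' agreement, ICC(A,1)) charges session-level shifts against reliability:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`. The
#' `"consistency"` variant ICC(C,1) ignores them:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE)`.
#'
#' @param pairs A matrix or data frame with one row per subject and one
#'   column per session (e.g. test, retest); rows with missing cells are
#'   dropped.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return List with `icc`, `type`, `n` (complete subjects), `degenerate`
#'   (TRUE when there is no between-subject variance, in which case `icc` is
#'   NA).
#' @export
icc <- function(pairs, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as.matrix(pairs)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2)
    return(list(icc = NA_real_, type = type, n = nrow(m), degenerate = FALSE))
  ms <- icc_mean_squares(m)
  if (ms$MSR < .Machine$double.eps && ms$MSE < .Machine$double.eps)
    return(list(icc = NA_real_, type = type, n = ms$n, degenerate = TRUE))
  val <- if (type == "agreement")
    (ms$MSR - ms$MSE) /
      (ms$MSR + (ms$k - 1) * ms$MSE + ms$k / ms$n * (ms$MSC - ms$MSE))
  else
    (ms$MSR - ms$MSE) / (ms$MSR + (ms$k - 1) * ms$MSE)
  list(icc = val, type = type, n = ms$n, degenerate = FALSE)
}

#' Agreement between two quantification methods
#'
#' OLS of `y` on `x` plus the mean percent bias `mean(100 * (y - x) / x)`,
#' summarising how one V_T estimator tracks another across regions/scans.
#'
#' @param x,y Paired estimates, equal length >= 3.
#' @return List with `slope`, `intercept`, `r_squared`, `mean_percent_bias`.
#' @export
method_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 3) stop("need at least 3 pairs")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       mean_percent_bias = mean(100 * (y - x) / x))
}

#' Region-level reliability summary from a long estimates table
#'
#' Takes the long-format table produced by the quantification pipeline
#' (columns `subject`, `session` in `{"test","retest"}`, `region`, `method`,
#' `VT`, `reliable`) and, per region, averages per-subject aTRV over subjects
#' with both sessions reliable and computes the ICC across those complete
#' pairs. Unreliable estimates (%SE >= 25) never enter the summary.
#'
#' @param estimates Long data frame as above.
#' @param method Method label to summarise (e.g. `"2tcmc"`, `"logan"`).
#' @param icc_type Passed to [icc()].
#' @return Data frame with one row per region: `region`, `n_pairs`,
#'   `mean_aTRV`, `ICC`.
#' @export
reliability_table <- function(estimates, method,
                              icc_type = c("agreement", "consistency")) {
  icc_type <- match.arg(icc_type)
  d <- estimates[estimates$method == method & estimates$reliable &
                   is.finite(estimates$VT), , drop = FALSE]
  regions <- unique(estimates$region)
  out <- lapply(regions, function(rg) {
    dr <- d[d$region == rg, ]
    wide <- merge(dr[dr$session == "test", c("subject", "VT")],
                  dr[dr$session == "retest", c("subject", "VT")],
                  by = "subject", suffixes = c("_test", "_retest"))
    n <- nrow(wide)
    if (n == 0)
      return(data.frame(region = rg, n_pairs = 0L, mean_aTRV = NA_real_,
                        ICC = NA_real_))
    data.frame(region = rg, n_pairs = n,
               mean_aTRV = mean(atrv(wide$VT_test, wide$VT_retest)),
               ICC = icc(wide[, c("VT_test", "VT_retest")], icc_type)$icc)
  })
  do.call(rbind, out)
}
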