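#' Convert a TAC to standardised uptake values
#'
#' `SUV(t) = C(t) [kBq/cc] / (injected dose [kBq] / body weight [g])`.
#'
#' @param tc A [tac()] in kBq/cc.
#' @param injected_dose_MBq Injected activity, MBq; > 0.
#' @param body_weight_kg Body weight, kg; > 0.
#' @return A [tac()] in SUV units.
#' @export
to_suv <- function(tc, injected_dose_MBq, body_weight_kg) {
  if (injected_dose_MBq <= 0 || body_weight_kg <= 0)
    stop("dose and weight must be positive")
  # kBq/cc over (MBq*1000 kBq) / (kg*1000 g) = dose/weight in kBq/g
  tac(tc$region, tc$frames,
      tc$values / (injected_dose_MBq / body_weight_kg))
}

#' Normalise a TAC to its value just before drug administration
#'
#' Divides the curve by the value of the last frame ending at or before
#' `t_norm` (the frame immediately preceding the intervention), producing a
#' unitless curve equal to 1 at the anchor frame.
#'
#' @param tc A [tac()] (typically in SUV units).
#' @param t_norm Normalisation time, minutes post-injection (default 90).
#' @return A `normalized_tac`: list with `times` (frame mid-times), `values`,
#'   `anchor_index`, `anchor_time`, `frames`.
#' @export
normalize_at <- function(tc, t_norm = 90) {
  idx <- which(tc$frames$end <= t_norm + 1e-9)
  if (length(idx) == 0) stop("no frame ends at or before the normalisation time")
  a <- max(idx)
  if (tc$values[a] <= 0) stop("non-positive activity at the anchor frame")
  structure(list(times = tc$frames$mid, values = tc$values / tc$values[a],
                 anchor_index = a, anchor_time = tc$frames$mid[a],
                 frames = tc$frames, region = tc$region),
            class = "normalized_tac")
}

#' Percent displacement relative to an averaged baseline
#'
#' Baseline curves (already normalised) are averaged pointwise; displacement
#' at time `t` is `100 * (B(t) - D(t)) / B(t)`, reported at the frame
#' covering `drug_time + eval_time` together with the full post-drug series.
#'
#' @param baselines A `normalized_tac` or list of them sharing one frame grid.
#' @param displaced A `normalized_tac` on the same grid.
#' @param eval_time Evaluation time, minutes post-drug; > 0.
#' @param drug_time Drug administration time, minutes post-injection
#'   (default 90).
#' @return List with `percent` (value at the evaluation frame),
#'   `eval_time`, `series` (data frame `time`, `baseline`, `displaced`,
#'   `percent`), `baseline_mean`.
#' @export
percent_displacement <- function(baselines, displaced, eval_time,
                                 drug_time = 90) {
  if (inherits(baselines, "normalized_tac")) baselines <- list(baselines)
  if (eval_time <= 0) stop("eval_time must be positive (minutes post-drug)")
  grids <- lapply(c(baselines, list(displaced)), function(x) x$times)
  if (any(vapply(grids, function(g)
        length(g) != length(grids[[1]]) || any(abs(g - grids[[1]]) > 1e-6),
        logical(1))))
    stop("all curves must share one frame grid")
  B <- rowMeans(do.call(cbind, lapply(baselines, function(x) x$values)))
  D <- displaced$values
  t_eval <- drug_time + eval_time
  fr <- displaced$frames
  hit <- which(fr$start <= t_eval & t_eval <= fr$end)
  if (length(hit) == 0) stop("evaluation time falls outside the frame grid")
  pct <- 100 * (B - D) / B
  list(percent = pct[hit[1]], eval_time = eval_time,
       series = data.frame(time = displaced$times, baseline = B,
                           displaced = D, percent = pct),
       baseline_mean = B)
}

#' Receptor occupancy from a single-site binding isotherm
#'
#' `occ = C / (C + K_D)` at free ligand concentration `C`. Any consistent
#' concentration units may be used for both arguments.
#'
#' @param free_conc Free ligand concentration; >= 0.
#' @param kd Dissociation constant, same units; > 0.
#' @return Occupancy as a fraction in `[0, 1)`.
#' @export
occupancy_isotherm <- function(free_conc, kd) {
  if (any(kd <= 0)) stop("kd must be positive")
  if (any(free_conc < 0)) stop("free_conc must be non-negative")
  free_conc / (free_conc + kd)
}

#' Binding potential implied by a maximal displaceable fraction
#'
#' If a fraction `f` of total uptake is displaceable at full target
#' occupancy, then `BP_ND = f / (1 - f)` (the inverse of
#' `f = BP_ND / (1 + BP_ND)`).
#'
#' @param max_displaceable_fraction Fraction in `[0, 1)`.
#' @return Implied non-displaceable binding potential.
#' @export
implied_bpnd <- function(max_displaceable_fraction) {
  f <- max_displaceable_fraction
  if (any(f < 0 | f >= 1)) stop("fraction must lie in [0, 1)")
  f / (1 - f)
}

#' Occupancy implied by a sub-maximal displacement
#'
#' Scales an observed percent displacement by the maximal (full-occupancy)
#' displacement: `occ = 100 * observed / max`.
#'
#' @param observed_pct Observed displacement, percent; `0 <= observed <= max`.
#' @param max_pct Maximal displacement at full occupancy, percent; in
#'   `(0, 100]`.
#' @return Occupancy in percent.
#' @export
occupancy_from_displacement <- function(observed_pct, max_pct) {
  if (any(max_pct <= 0 | max_pct > 100)) stop("max_pct must lie in (0, 100]")
  if (any(observed_pct < 0)) stop("observed_pct must be non-negative")
  if (any(observed_pct > max_pct))
    stop("observed displacement exceeds the stated maximum (inconsistent inputs)")
  100 * observed_pct / max_pct
}
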