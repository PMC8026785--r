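# Evaluate an expression under a temporary RNG seed, restoring global state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Study frame schedules
#'
#' The 2-h acquisition uses fine early frames (6 x 0.5 min, 4 x 1 min,
#' 4 x 2 min, 7 x 5 min, 7 x 10 min; 28 frames to 120 min); the 4-h schedule
#' appends 12 further 10-min frames (40 frames to 240 min).
#'
#' @param protocol `"2h"` or `"4h"`.
#' @return A [frame_schedule()].
#' @export
study_frames <- function(protocol = c("2h", "4h")) {
  protocol <- match.arg(protocol)
  dur <- c(rep(0.5, 6), rep(1, 4), rep(2, 4), rep(5, 7), rep(10, 7))
  if (protocol == "4h") dur <- c(dur, rep(10, 12))
  e <- cumsum(dur)
  frame_schedule(c(0, e[-length(e)]), e)
}

#' Arterial sampling schedule
#'
#' 16 samples in the first 5 min, 3 samples every 5 min (10-20 min), then
#' 10-min samples; 28 samples for the 2-h protocol. The 4-h protocol appends
#' 6 samples every 20 min over the last two hours (34 in total).
#'
#' @param protocol `"2h"` or `"4h"`.
#' @return Sampling times in minutes.
#' @export
blood_sampling_times <- function(protocol = c("2h", "4h")) {
  protocol <- match.arg(protocol)
  t <- c(seq(0.25, 3, by = 0.25), 3.5, 4, 4.5, 5,   # 16 in first 5 min
         10, 15, 20,
         seq(30, 110, by = 10))
  if (protocol == "4h") t <- c(t, seq(140, 240, by = 20))
  t
}

# Times of the larger metabolite samples (parent-fraction measurements).
metabolite_sampling_times <- function(protocol = c("2h", "4h")) {
  protocol <- match.arg(protocol)
  t <- c(5, 15, 30, 60, 90, 120)
  if (protocol == "4h") t <- c(t, 180, 240)
  t
}

#' Synthetic study configuration
#'
#' Ground truth for the synthetic-data generator, defaulting to the study
#' conditions the analysis targets: seven brain regions with a shared
#' non-displaceable distribution volume `V_ND = 7.89` mL/cm^3, grey-matter
#' influx averaging `K1 = 0.37` mL/cm^3/min, region `k3/k4` averaging 1.07
#' (with `k4 = 0.028` 1/min), a biexponential parent fraction, a
#' linear-rise-plus-triexponential-washout plasma curve, a stable
#' plasma/whole-blood ratio of 0.90, and front-loaded arterial sampling
#' (28 samples over 2 h, 34 over 4 h).
#'
#' @param n_subjects Number of subjects (default 4).
#' @param protocol `"2h"` or `"4h"` acquisition/sampling protocol.
#' @param regions Data frame with `region`, `K1`, `BP` (k3/k4) columns; the
#'   default encodes the region truth above.
#' @param VND Shared non-displaceable distribution volume, mL/cm^3.
#' @param k4 Dissociation rate, 1/min (common to all regions).
#' @param pf_truth Parent-fraction truth `list(A1, lambda1, lambda2)`.
#' @param input_shape Plasma-curve shape: `list(t_peak, peak, w, a)` with
#'   washout weights `w` (sum 1) and rates `a` (1/min).
#' @param plasma_wb_ratio Plasma over whole-blood activity ratio.
#' @param noise_scale TAC noise scale (0 = noiseless); frame noise SD is
#'   `noise_scale * sqrt(value / duration)`.
#' @param pf_jitter_sd Gaussian jitter SD of parent-fraction samples (applied
#'   only when `noise_scale > 0`), clipped to `[0, 1]`.
#' @param session_k1_sd SD of the multiplicative session-level K1
#'   perturbation applied to retest scans (clipped at +/- 5%).
#' @param subject_cv Between-subject coefficients of variation of the truth,
#'   `list(K1, VND, BP)`; log-normal multiplicative factors drawn once per
#'   subject (only when `noise_scale > 0`), giving the between-subject V_T
#'   spread that test-retest reliability is measured against.
#' @param injected_dose_MBq,body_weight_kg Scan metadata for SUV conversion.
#' @param drug_time Displacement drug administration time, minutes.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 4,
                         protocol = c("2h", "4h"),
                         regions = default_region_truth(),
                         VND = 7.89,
                         k4 = 0.028,
                         pf_truth = list(A1 = 0.80, lambda1 = 0.10,
                                         lambda2 = 0.0095),
                         input_shape = list(t_peak = 0.75, peak = 80,
                                            w = c(0.75, 0.20, 0.05),
                                            a = c(2.0, 0.12, 0.01)),
                         plasma_wb_ratio = 0.90,
                         noise_scale = 1.2,
                         pf_jitter_sd = 0.02,
                         session_k1_sd = 0.02,
                         subject_cv = list(K1 = 0.08, VND = 0.15, BP = 0.10),
                         injected_dose_MBq = 150,
                         body_weight_kg = 5.2,
                         drug_time = 90) {
  protocol <- match.arg(protocol)
  stopifnot(n_subjects >= 1, VND > 0, k4 > 0,
            all(c("region", "K1", "BP") %in% names(regions)),
            all(regions$K1 > 0), all(regions$BP >= 0),
            pf_truth$A1 >= 0, pf_truth$A1 <= 1,
            pf_truth$lambda1 >= 0, pf_truth$lambda2 >= 0,
            all(input_shape$w > 0), all(input_shape$a > 0),
            noise_scale >= 0, plasma_wb_ratio > 0)
  structure(list(n_subjects = n_subjects, protocol = protocol,
                 regions = regions, VND = VND, k4 = k4,
                 pf_truth = pf_truth, input_shape = input_shape,
                 plasma_wb_ratio = plasma_wb_ratio,
                 noise_scale = noise_scale, pf_jitter_sd = pf_jitter_sd,
                 session_k1_sd = session_k1_sd, subject_cv = subject_cv,
                 injected_dose_MBq = injected_dose_MBq,
                 body_weight_kg = body_weight_kg, drug_time = drug_time),
            class = "study_config")
}

#' @rdname study_config
#' @export
default_region_truth <- function() {
  data.frame(
    region = c("striatum", "thalamus", "cerebellum", "white_matter",
               "frontal_cortex", "temporal_cortex", "parietal_cortex"),
    K1 = c(0.40, 0.39, 0.37, 0.25, 0.36, 0.35, 0.35),
    BP = c(1.16, 1.03, 1.24, 0.73, 1.25, 1.00, 1.08))
}

# True (noise-free) total plasma activity at arbitrary times.
plasma_shape <- function(shape, t) {
  w <- shape$w / sum(shape$w)
  tau <- t - shape$t_peak
  wash <- function(x) colSums(w * exp(-outer(shape$a, pmax(x, 0))))
  ifelse(t <= 0, 0,
         ifelse(t < shape$t_peak, shape$peak * t / shape$t_peak,
                shape$peak * wash(tau)))
}

pf_truth_values <- function(pf, t) {
  pf$A1 * exp(-pf$lambda1 * t) + (1 - pf$A1) * exp(-pf$lambda2 * t)
}

#' Generate one subject's arterial data
#'
#' Samples the configured plasma curve at the protocol sampling times (with a
#' small log-normal subject-level amplitude factor when `noise_scale > 0`),
#' derives whole blood from the configured plasma/whole-blood ratio, and
#' draws parent-fraction measurements as biexponential truth plus Gaussian
#' jitter clipped to `[0, 1]`.
#'
#' @param cfg A [study_config()].
#' @param subject Subject index (enters the derived seed).
#' @param seed Integer seed; mandatory.
#' @return List with `blood` ([blood_series()]), `pf_samples` (data frame
#'   `time_min`, `parent_fraction`), and `truth_input` (the
#'   metabolite-corrected `input_function` at the sampling times, used to
#'   drive TAC generation).
#' @export
make_input_function <- function(cfg, subject = 1, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  times <- blood_sampling_times(cfg$protocol)
  with_local_seed(seed * 1000L + subject, {
    amp <- if (cfg$noise_scale > 0) exp(stats::rnorm(1, 0, 0.05)) else 1
    plasma <- amp * plasma_shape(cfg$input_shape, times)
    blood <- blood_series(times, plasma / cfg$plasma_wb_ratio, plasma)
    mt <- metabolite_sampling_times(cfg$protocol)
    pf_sd <- if (cfg$noise_scale > 0) cfg$pf_jitter_sd else 0
    pf <- pmin(pmax(pf_truth_values(cfg$pf_truth, mt) +
                      stats::rnorm(length(mt), 0, pf_sd), 0), 1)
    truth_input <- input_function(
      times, plasma * pf_truth_values(cfg$pf_truth, times),
      source_blood = blood)
    list(blood = blood,
         pf_samples = data.frame(time_min = mt, parent_fraction = pf),
         truth_input = truth_input)
  })
}

# True compartment parameters for one region of a config.
region_params <- function(cfg, r, k1_factor = 1) {
  K1 <- cfg$regions$K1[r] * k1_factor
  compartment_params(K1, K1 / cfg$VND, cfg$regions$BP[r] * cfg$k4, cfg$k4)
}

#' Generate regional TACs for one scan session
#'
#' Forward-simulates the two-tissue model at the configured region truths
#' (shared `V_ND`), adds Gaussian noise with variance proportional to
#' `value / frame_duration`, and appends a `whole_brain` composite (mean of
#' the regional curves). Retest sessions apply one multiplicative
#' session-level K1 perturbation (SD `session_k1_sd`, clipped at +/- 5%).
#'
#' @param cfg A [study_config()].
#' @param input The `input_function` driving the kinetics (typically
#'   `truth_input` from [make_input_function()]).
#' @param session `"test"` or `"retest"`.
#' @param seed Integer seed; mandatory.
#' @param include_whole_brain Append the composite curve? Default TRUE.
#' @return Named list of [tac()] objects.
#' @export
make_tacs <- function(cfg, input, session = c("test", "retest"), seed,
                      include_whole_brain = TRUE) {
  session <- match.arg(session)
  if (missing(seed)) stop("an explicit seed is required")
  frames <- study_frames(cfg$protocol)
  with_local_seed(seed * 1000L + 500L + (session == "retest"), {
    k1f <- 1
    if (session == "retest" && cfg$noise_scale > 0)
      k1f <- 1 + max(-0.05, min(0.05, stats::rnorm(1, 0, cfg$session_k1_sd)))
    tacs <- lapply(seq_len(nrow(cfg$regions)), function(r) {
      tc <- simulate_tissue(region_params(cfg, r, k1f), input, frames,
                            region = cfg$regions$region[r])
      if (cfg$noise_scale > 0) {
        sd <- cfg$noise_scale *
          sqrt(pmax(tc$values, 0.02 * max(tc$values)) / frames$dur)
        tc$values <- tc$values + stats::rnorm(length(sd), 0, sd)
      }
      tc
    })
    names(tacs) <- cfg$regions$region
    if (include_whole_brain) {
      wb <- rowMeans(do.call(cbind, lapply(tacs, function(x) x$values)))
      tacs$whole_brain <- tac("whole_brain", frames, wb)
    }
    tacs
  })
}

#' Occupancy profile for a displacement arm
#'
#' Target occupancy over time after a competitor bolus at `onset`:
#' `"step"` rises instantly to `occ_max` (fast-penetrating competitor);
#' `"exp"` rises as `occ_max * (1 - exp(-rate * (t - onset)))` (slow brain
#' penetrance).
#'
#' @param occ_max Plateau occupancy in `[0, 1]`.
#' @param onset Drug administration time, minutes post-injection.
#' @param type `"step"` or `"exp"`.
#' @param rate Rise rate for `"exp"`, 1/min.
#' @return A function `occ(t)` returning occupancy in `[0, 1]`.
#' @export
occupancy_profile <- function(occ_max, onset = 90, type = c("step", "exp"),
                              rate = 0.05) {
  type <- match.arg(type)
  if (occ_max < 0 || occ_max > 1) stop("occ_max must lie in [0, 1]")
  if (type == "step")
    function(t) ifelse(t >= onset, occ_max, 0)
  else
    function(t) ifelse(t >= onset, occ_max * (1 - exp(-rate * (t - onset))), 0)
}

# Numerical two-tissue solution with time-varying k3(t) = k3 * (1 - occ(t)).
ode_tissue_frames <- function(params, input, frames, occ_fun = NULL,
                              dt = 0.05) {
  t_end <- max(frames$end)
  tg <- seq(0, t_end, by = dt)
  if (tg[length(tg)] < t_end) tg <- c(tg, t_end)
  cp <- stats::approxfun(c(0, input$times), c(0, input$values), rule = 2)
  occ <- if (is.null(occ_fun)) function(t) 0 else occ_fun
  deriv <- function(t, y, parms) {
    k3t <- params$k3 * (1 - occ(t))
    list(c(params$K1 * cp(t) - (params$k2 + k3t) * y[1] + params$k4 * y[2],
           k3t * y[1] - params$k4 * y[2]))
  }
  sol <- deSolve::ode(c(C1 = 0, C2 = 0), tg, deriv, NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  ct <- sol[, "C1"] + sol[, "C2"]
  frame_average(tg, ct, frames)
}

#' Generate a displacement-arm TAC table
#'
#' Integrates the two-tissue system with a time-varying association rate
#' `k3(t) = k3 * (1 - occ(t))`, where `occ(t)` is the competitor occupancy
#' profile, then adds the configured TAC noise. With `occ = 0` everywhere and
#' the same seed the output equals a baseline arm.
#'
#' @param cfg A [study_config()] (use `protocol = "4h"` for the study design).
#' @param input The driving `input_function`.
#' @param occ_fun An [occupancy_profile()] function; values must lie in
#'   `[0, 1]`.
#' @param seed Integer seed; mandatory.
#' @param include_whole_brain Append the composite curve? Default TRUE.
#' @return Named list of [tac()] objects.
#' @export
make_displacement_arm <- function(cfg, input, occ_fun, seed,
                                  include_whole_brain = TRUE) {
  if (missing(seed)) stop("an explicit seed is required")
  frames <- study_frames(cfg$protocol)
  probe <- occ_fun(seq(0, max(frames$end), length.out = 101))
  if (any(probe < 0 | probe > 1)) stop("occupancy profile must lie in [0, 1]")
  with_local_seed(seed * 1000L + 500L, {
    tacs <- lapply(seq_len(nrow(cfg$regions)), function(r) {
      v <- ode_tissue_frames(region_params(cfg, r), input, frames, occ_fun)
      tc <- tac(cfg$regions$region[r], frames, v)
      if (cfg$noise_scale > 0) {
        sd <- cfg$noise_scale *
          sqrt(pmax(tc$values, 0.02 * max(tc$values)) / frames$dur)
        tc$values <- tc$values + stats::rnorm(length(sd), 0, sd)
      }
      tc
    })
    names(tacs) <- cfg$regions$region
    if (include_whole_brain) {
      wb <- rowMeans(do.call(cbind, lapply(tacs, function(x) x$values)))
      tacs$whole_brain <- tac("whole_brain", frames, wb)
    }
    tacs
  })
}

#' Subject-level ground truth
#'
#' Clone of the study config with one log-normal multiplicative perturbation
#' of `K1` (per region), `VND`, and `BP` per subject, at the configured
#' between-subject CVs. With `noise_scale = 0` the config is returned
#' unchanged (fully deterministic truth).
#'
#' @param cfg A [study_config()].
#' @param subject Subject index.
#' @param seed Integer seed.
#' @return A `study_config` holding this subject's truth.
#' @export
subject_truth <- function(cfg, subject, seed) {
  if (cfg$noise_scale == 0) return(cfg)
  with_local_seed(seed * 1000L + 777L + subject, {
    cfg$regions$K1 <- cfg$regions$K1 *
      exp(stats::rnorm(1, 0, cfg$subject_cv$K1))
    cfg$VND <- cfg$VND * exp(stats::rnorm(1, 0, cfg$subject_cv$VND))
    cfg$regions$BP <- cfg$regions$BP *
      exp(stats::rnorm(1, 0, cfg$subject_cv$BP))
    cfg
  })
}

#' Generate a complete synthetic test-retest study
#'
#' Per subject: arterial blood series, parent-fraction samples, and test and
#' retest regional TAC tables, all driven by the configured ground truth.
#' Regeneration with the same config and seed is bit-identical.
#'
#' @param cfg A [study_config()].
#' @param seed Integer seed; mandatory.
#' @return A `synthetic_study`: list with `config`, `seed`, and `subjects`
#'   (each with `blood`, `pf_samples`, `truth_input`, `tacs` = list(test,
#'   retest)).
#' @export
make_study <- function(cfg, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
    inp <- make_input_function(cfg, s, seed)
    truth <- subject_truth(cfg, s, seed)
    list(blood = inp$blood, pf_samples = inp$pf_samples,
         truth_input = inp$truth_input, truth = truth,
         tacs = list(test = make_tacs(truth, inp$truth_input, "test",
                                      seed + 7L * s),
                     retest = make_tacs(truth, inp$truth_input, "retest",
                                        seed + 7L * s)))
  })
  names(subjects) <- paste0("subject", seq_len(cfg$n_subjects))
  structure(list(config = cfg, seed = seed, subjects = subjects),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d subjects, %s protocol, noise %.2f, seed %d\n",
              x$config$n_subjects, x$config$protocol, x$config$noise_scale,
              x$seed))
  invisible(x)
}
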